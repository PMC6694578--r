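# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain loops over dense structures and share no
# code with the package internals.

# Quadratic position-pair enumeration of windowed co-occurrence counting.
brute_count <- function(stream, window) {
  pairs <- character()
  for (doc in stream) {
    L <- length(doc)
    if (L < 2) next
    for (p in seq_len(L - 1)) {
      for (q in (p + 1):min(p + window, L)) {
        pairs <- c(pairs, paste0(doc[p], "\r", doc[q]))
      }
    }
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(term1 = character(), term2 = character(), n = numeric()))
  }
  tab <- table(pairs)
  key <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- tibble::tibble(
    term1 = vapply(key, `[`, character(1), 1),
    term2 = vapply(key, `[`, character(1), 2),
    n = as.numeric(tab)
  )
  out[order(out$term1, out$term2), ]
}

# Dense adjacency representation of a cooc_matrix.
as_dense <- function(m) {
  vocab <- cooc_vocabulary(m)
  M <- matrix(0, length(vocab), length(vocab), dimnames = list(vocab, vocab))
  for (r in seq_len(nrow(m))) {
    M[m$term1[r], m$term2[r]] <- m$n[r]
  }
  M
}

# Neighbour sets by explicit scans of the dense matrix.
oracle_sets <- function(M, a, c) {
  vocab <- rownames(M)
  b_a <- character()
  b_c <- character()
  for (j in vocab) {
    if (any(M[a, j] > 0)) b_a <- c(b_a, j)
    if (any(M[j, c] > 0)) b_c <- c(b_c, j)
  }
  b_a <- setdiff(b_a, c(a, c))
  b_c <- setdiff(b_c, c(a, c))
  list(b_a = b_a, b_c = b_c, shared = intersect(b_a, b_c))
}

# Contingency cells for every measure by nested loops.
oracle_cells <- function(m, a, c, measure) {
  M <- as_dense(m)
  sets <- oracle_sets(M, a, c)
  total <- sum(M)
  out_w <- function(terms) if (length(terms) == 0) 0 else sum(M[terms, , drop = FALSE])
  in_w <- function(terms) if (length(terms) == 0) 0 else sum(M[, terms, drop = FALSE])
  switch(measure,
    ltc = length(sets$shared),
    direct = list(
      n11 = sum(M[a, c, drop = FALSE]),
      n1p = out_w(a), np1 = in_w(c), npp = total
    ),
    mwa = {
      n11 <- 0
      for (b in sets$shared) {
        n11 <- n11 + min(sum(M[a, b]), sum(M[b, c]))
      }
      list(n11 = n11, n1p = out_w(a), np1 = in_w(c), npp = total)
    },
    lta = list(
      n11 = length(sets$shared), n1p = length(sets$b_a),
      np1 = length(sets$b_c), npp = length(rownames(M))
    ),
    sbc = {
      if (length(sets$shared) == 0) return(NULL)
      n11 <- 0
      for (b in sets$shared) for (cc in c) n11 <- n11 + M[b, cc]
      list(n11 = n11, n1p = out_w(sets$shared), np1 = in_w(c), npp = total)
    },
    lsa = {
      if (length(sets$b_a) == 0 || length(sets$b_c) == 0) return(NULL)
      n11 <- 0
      for (i in sets$b_a) for (j in sets$b_c) n11 <- n11 + M[i, j]
      list(n11 = n11, n1p = out_w(sets$b_a), np1 = in_w(sets$b_c), npp = total)
    }
  )
}

# A general random directed graph over n terms. Direct edges between the
# query pair (t1, t2) are excluded so weight-based contingency tables stay
# within the LBD (never-co-occurring) setting the measures target.
random_general_graph <- function(n_terms, n_edges, seed, max_weight = 9) {
  set.seed(seed)
  vocab <- paste0("t", seq_len(n_terms))
  from <- sample(vocab, n_edges, replace = TRUE)
  to <- sample(vocab, n_edges, replace = TRUE)
  w <- sample.int(max_weight, n_edges, replace = TRUE)
  keep <- !((from == "t1" & to == "t2") | (from == "t2" & to == "t1"))
  edges <- tibble::tibble(term1 = from[keep], term2 = to[keep], n = w[keep])
  edges <- dplyr::summarise(
    dplyr::group_by(edges, term1, term2),
    n = sum(n), .groups = "drop"
  )
  cooc_matrix(edges, vocabulary = vocab)
}

# PR AUC (step convention) computed directly from a label sequence.
oracle_pr_auc <- function(labels) {
  P <- sum(labels)
  tp <- 0
  auc <- 0
  prev_recall <- 0
  for (k in seq_along(labels)) {
    if (labels[k]) tp <- tp + 1
    recall <- tp / P
    if (recall > prev_recall) {
      auc <- auc + (recall - prev_recall) * (tp / k)
      prev_recall <- recall
    }
  }
  auc
}

# All distinct orderings of a logical label vector.
combinat_permutations <- function(labels) {
  n <- length(labels)
  pos <- sum(labels)
  idx_sets <- utils::combn(n, pos, simplify = FALSE)
  lapply(idx_sets, function(idx) {
    out <- rep(FALSE, n)
    out[idx] <- TRUE
    out
  })
}

# Mann-Whitney AUROC: fraction of (true, false) pairs with the true pair
# ranked above (earlier than) the false pair.
mwu_auc <- function(labels) {
  pos <- which(labels)
  neg <- which(!labels)
  wins <- 0
  for (i in pos) for (j in neg) wins <- wins + (i < j)
  wins / (length(pos) * length(neg))
}

# Strip a cooc_matrix (or any edge frame) to a plain tibble for comparison.
plain_edges <- function(m) {
  tibble::tibble(term1 = m$term1, term2 = m$term2, n = as.numeric(m$n))
}
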