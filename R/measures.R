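#' Association measure names
#'
#' The measures understood by [assoc_table()] and [score_pairs()]:
#' `direct` (raw co-occurrence weights between the query sets), `mwa`
#' (minimum weight association), `lta` (linking term association), `sbc`
#' (shared B-to-C set association), `lsa` (linking set association), and
#' the `ltc` baseline (linking term count, a raw count with no
#' association equation).
#'
#' @return Character vector of measure names.
#' @export
assoc_measures <- function() c("ltc", "direct", "mwa", "lta", "sbc", "lsa")

new_undefined_table <- function(reason) {
  structure(list(reason = reason), class = "lbd_undefined")
}

#' @export
print.lbd_undefined <- function(x, ...) {
  cat(sprintf("<undefined association: %s>\n", x$reason))
  invisible(x)
}

check_query <- function(matrix, a, c) {
  a <- unique(as.character(a))
  c <- unique(as.character(c))
  if (length(a) == 0 || length(c) == 0) {
    rlang::abort("start and target sets must be non-empty")
  }
  if (length(intersect(a, c)) > 0) {
    rlang::abort("start and target sets must be disjoint")
  }
  check_terms_known(matrix, union(a, c), "query term")
  list(a = a, c = c)
}

# Sum of weights from set `from` to set `to`.
weight_between <- function(matrix, from, to) {
  sum(matrix$n[matrix$term1 %in% from & matrix$term2 %in% to])
}

#' Linking term count
#'
#' The classic ABC-model baseline: the number of distinct linking terms
#' shared by the start set and the target set, `|B_A intersect B_C|`. A
#' raw count, not an association statistic; larger means more indirect
#' evidence connects the pair.
#'
#' @inheritParams linking_sets
#' @return A single non-negative integer.
#' @examples
#' ltc(fig2_graph(), "A", "C")  # 2
#' @export
ltc <- function(matrix, a, c) {
  check_cooc(matrix)
  q <- check_query(matrix, a, c)
  length(linking_sets(matrix, q$a, q$c)$shared)
}

#' Contingency tables for direct and indirect association measures
#'
#' Builds the 2x2 contingency table a given measure defines for a query
#' pair `(A, C)` over a directed co-occurrence matrix. With `S` the shared
#' linking set, `B_A`/`B_C` the out-/in-neighbour sets (query terms
#' excluded), and `w_ij` the directed counts:
#'
#' * `direct` — `n11 = sum w_ac`; `n1p` = out-weight of `A`; `np1` =
#'   in-weight of `C`; `npp` = total weight. Zero `n11` whenever the pair
#'   never directly co-occurs, which is exactly the LBD setting.
#' * `mwa` — like `direct`, but `n11 = sum over b in S of
#'   min(w(A,b), w(b,C))`: each A-B-C path carries at most its minimum
#'   capacity, keeping `n11 <= min(n1p, np1)`.
#' * `lta` — set cardinalities instead of weights: `n11 = |S|`,
#'   `n1p = |B_A|`, `np1 = |B_C|`, `npp = |V|` (vocabulary size,
#'   overridable via `vocab_size`).
#' * `sbc` — the shared set stands proxy for `A`: `n11` = weight from `S`
#'   to `C`, `n1p` = out-weight of `S`, `np1` = in-weight of `C`,
#'   `npp` = total. Undefined when `S` is empty.
#' * `lsa` — both sides replaced by their neighbour sets: `n11` = weight
#'   from `B_A` to `B_C`, `n1p` = out-weight of `B_A`, `np1` = in-weight
#'   of `B_C`, `npp` = total. Undefined when either proxy set is empty.
#'
#' @inheritParams linking_sets
#' @param measure One of `"direct"`, `"mwa"`, `"lta"`, `"sbc"`, `"lsa"`.
#' @param vocab_size Override for the `|V|` total used by `lta`; defaults
#'   to the matrix vocabulary size.
#' @return An [contingency_table()] object, or an undefined marker (class
#'   `lbd_undefined`, see [is_undefined()]) for SBC/LSA degeneracies.
#' @examples
#' assoc_table(fig2_graph(), "A", "C", measure = "mwa")$n11  # 7
#' @export
assoc_table <- function(matrix, a, c, measure = "direct", vocab_size = NULL) {
  check_cooc(matrix)
  measure <- match.arg(measure, c("direct", "mwa", "lta", "sbc", "lsa"))
  q <- check_query(matrix, a, c)
  a <- q$a
  c <- q$c
  total <- sum(matrix$n)
  switch(measure,
    direct = contingency_table(
      n11 = weight_between(matrix, a, c),
      n1p = sum(matrix$n[matrix$term1 %in% a]),
      np1 = sum(matrix$n[matrix$term2 %in% c]),
      npp = total
    ),
    mwa = {
      ls <- linking_sets(matrix, a, c)
      n11 <- if (length(ls$shared) == 0) 0 else {
        sum(vapply(ls$shared, function(b) {
          min(weight_between(matrix, a, b), weight_between(matrix, b, c))
        }, numeric(1)))
      }
      contingency_table(
        n11 = n11,
        n1p = sum(matrix$n[matrix$term1 %in% a]),
        np1 = sum(matrix$n[matrix$term2 %in% c]),
        npp = total
      )
    },
    lta = {
      ls <- linking_sets(matrix, a, c)
      npp <- if (is.null(vocab_size)) length(attr(matrix, "vocabulary")) else vocab_size
      contingency_table(
        n11 = length(ls$shared),
        n1p = length(ls$b_a),
        np1 = length(ls$b_c),
        npp = npp
      )
    },
    sbc = {
      ls <- linking_sets(matrix, a, c)
      if (length(ls$shared) == 0) return(new_undefined_table("empty shared set"))
      contingency_table(
        n11 = weight_between(matrix, ls$shared, c),
        n1p = sum(matrix$n[matrix$term1 %in% ls$shared]),
        np1 = sum(matrix$n[matrix$term2 %in% c]),
        npp = total
      )
    },
    lsa = {
      ls <- linking_sets(matrix, a, c)
      if (length(ls$b_a) == 0 || length(ls$b_c) == 0) {
        return(new_undefined_table("empty proxy set"))
      }
      contingency_table(
        n11 = weight_between(matrix, ls$b_a, ls$b_c),
        n1p = sum(matrix$n[matrix$term1 %in% ls$b_a]),
        np1 = sum(matrix$n[matrix$term2 %in% ls$b_c]),
        npp = total
      )
    }
  )
}

#' Score a single query pair
#'
#' Builds the measure's contingency table for `(a, c)` and applies the
#' association equation; `measure = "ltc"` returns the raw linking term
#' count and ignores `equation`. Degenerate constructions propagate an
#' undefined score (see [is_undefined()]).
#'
#' @inheritParams assoc_table
#' @param equation Association equation for [assoc_score()]; default
#'   `"x2"`.
#' @return A single numeric score (class `lbd_score`).
#' @export
score_pair <- function(matrix, a, c, measure = "lta", equation = "x2",
                       vocab_size = NULL) {
  check_cooc(matrix)
  if (!is.character(measure) || length(measure) != 1 ||
      !measure %in% assoc_measures()) {
    rlang::abort(paste0(
      "unknown measure; registered measures: ",
      paste(assoc_measures(), collapse = ", ")
    ))
  }
  if (identical(measure, "ltc")) {
    return(defined_score(ltc(matrix, a, c)))
  }
  tab <- assoc_table(matrix, a, c, measure = measure, vocab_size = vocab_size)
  if (inherits(tab, "lbd_undefined")) {
    return(undefined_score(tab$reason))
  }
  assoc_score(tab, equation)
}

#' Score a data frame of query pairs
#'
#' The tidy entry point for ranking: takes a data frame of term pairs,
#' scores each with the chosen measure and equation, and returns the
#' pairs with `score` and `reason` columns. Undefined scores come back as
#' `NA` with the degeneracy named in `reason`; [rank_with_tie_penalty()]
#' places them last.
#'
#' @inheritParams score_pair
#' @param pairs A data frame whose first two columns (or columns `term1`,
#'   `term2` if present) give start and target terms.
#' @return A tibble: the input pairs plus `measure`, `equation`, `score`
#'   (numeric, `NA` when undefined) and `reason` (`NA` when defined).
#' @examples
#' pairs <- tibble::tibble(term1 = "A", term2 = "C")
#' score_pairs(fig2_graph(), pairs, measure = "ltc")
#' @export
score_pairs <- function(matrix, pairs, measure = "lta", equation = "x2",
                        vocab_size = NULL) {
  check_cooc(matrix)
  pairs <- tibble::as_tibble(pairs)
  if (all(c("term1", "term2") %in% names(pairs))) {
    t1 <- pairs$term1
    t2 <- pairs$term2
  } else if (ncol(pairs) >= 2) {
    t1 <- pairs[[1]]
    t2 <- pairs[[2]]
  } else {
    rlang::abort("`pairs` must have at least two columns of terms")
  }
  vocab <- attr(matrix, "vocabulary")
  scored <- purrr::map2(as.character(t1), as.character(t2), function(s, t) {
    # pairs outside the matrix vocabulary are undefined, not an error, so
    # evaluation can drop them and report a reduced n
    if (!(s %in% vocab) || !(t %in% vocab)) {
      sc <- undefined_score("out of vocabulary")
    } else if (identical(s, t)) {
      sc <- undefined_score("identical terms")
    } else {
      sc <- score_pair(matrix, s, t, measure = measure, equation = equation,
                       vocab_size = vocab_size)
    }
    list(score = as.numeric(sc), reason = undefined_reason(sc))
  })
  dplyr::mutate(
    pairs,
    measure = measure,
    equation = if (identical(measure, "ltc")) NA_character_ else equation,
    score = purrr::map_dbl(scored, "score"),
    reason = purrr::map_chr(scored, "reason")
  )
}
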