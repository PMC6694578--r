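#' Intrinsic evaluation against a human relatedness gold standard
#'
#' Computes Spearman's rank correlation between machine scores and human
#' relatedness judgements over a set of term pairs. Pairs whose machine
#' score is undefined or missing are dropped and the usable-pair count `n`
#' reduced, so methods that cannot score every pair are compared on the
#' pairs they can score. Ranks are tie-corrected (average ranks, the
#' standard Spearman treatment).
#'
#' @param gold A data frame with columns `term1`, `term2`, `score`
#'   (human judgement). Pairs are unordered and must be unique.
#' @param scored A data frame with columns `term1`, `term2`, `score`
#'   (machine score, `NA` when undefined) — typically the output of
#'   [score_pairs()]. Matching is order-insensitive.
#' @return A one-row tibble with `rho` (Spearman correlation), `n`
#'   (pairs actually compared), `n_gold` (gold pairs), and `n_dropped`.
#' @examples
#' gold <- tibble::tibble(term1 = letters[1:4], term2 = LETTERS[1:4],
#'                        score = 1:4)
#' scored <- dplyr::mutate(gold, score = c(2, 1, 4, 3))
#' spearman_eval(gold, scored)$rho  # 0.6
#' @export
spearman_eval <- function(gold, scored) {
  gold <- tibble::as_tibble(gold)
  scored <- tibble::as_tibble(scored)
  for (d in list(gold, scored)) {
    if (!all(c("term1", "term2", "score") %in% names(d))) {
      rlang::abort("data frames must have columns term1, term2, score")
    }
  }
  gkey <- pair_key(gold$term1, gold$term2)
  if (anyDuplicated(gkey)) rlang::abort("duplicate pair in gold standard")
  skey <- pair_key(scored$term1, scored$term2)
  idx <- match(gkey, skey)
  machine <- scored$score[idx]
  keep <- !is.na(machine)
  n <- sum(keep)
  if (n < 2) rlang::abort("insufficient defined pairs for correlation (n < 2)")
  rho <- spearman_rho(gold$score[keep], machine[keep])
  tibble::tibble(
    rho = rho, n = n, n_gold = nrow(gold), n_dropped = nrow(gold) - n
  )
}

# Spearman's rho on average ranks. The classical d^2 formula is used when
# both rankings are tie-free (it is exact there, giving self-correlation
# of exactly 1); with ties it falls back to Pearson on average ranks, the
# standard tie correction.
spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
}

# Order-insensitive pair key.
pair_key <- function(t1, t2) {
  paste0(pmin(as.character(t1), as.character(t2)), "\r",
         pmax(as.character(t1), as.character(t2)))
}

#' Compare two independent Spearman correlations (Fisher r-to-z)
#'
#' Tests whether two correlation coefficients measured on independent
#' samples differ, via the Fisher transformation:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'            {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-sided p-value from the standard normal.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, both > 3.
#' @return A one-row tibble with columns `z` and `p`.
#' @examples
#' fisher_r_to_z(0.7038, 392, 0.5315, 390)
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    rlang::abort("correlations must be strictly inside (-1, 1)")
  }
  if (n1 <= 3 || n2 <= 3) rlang::abort("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

pair_occurs <- function(matrix, t1, t2, directed = FALSE) {
  key <- paste0(matrix$term1, "\r", matrix$term2)
  hit <- paste0(t1, "\r", t2) %in% key
  if (!directed) hit <- hit | paste0(t2, "\r", t1) %in% key
  hit
}

#' Time-slicing silver-standard labels
#'
#' Builds a labelled link-prediction dataset from a corpus split at a
#' cutoff date. For every start/target combination `(s, t)` with
#' `s != t`: pairs already co-occurring in the pre-cutoff matrix are
#' removed (they are known knowledge, not discoveries); of the rest, pairs
#' that co-occur in the post-cutoff matrix are labelled `TRUE` (a future
#' discovery) and the remainder `FALSE`. By default a pair counts as
#' occurring if either direction has a nonzero count; set
#' `directed = TRUE` to require the `(s, t)` direction.
#'
#' @param pre,post [cooc_matrix()] objects for the pre- and post-cutoff
#'   segments.
#' @param starts,targets Character vectors of start and target terms
#'   (non-empty). `targets` defaults to the whole pre-cutoff vocabulary.
#' @param directed Require directional occurrence? Default `FALSE`.
#' @return A tibble with columns `term1`, `term2`, `label` (logical).
#' @export
timeslice_labels <- function(pre, post, starts, targets = cooc_vocabulary(pre),
                             directed = FALSE) {
  check_cooc(pre)
  check_cooc(post)
  starts <- unique(as.character(starts))
  targets <- unique(as.character(targets))
  if (length(starts) == 0 || length(targets) == 0) {
    rlang::abort("starts and targets must be non-empty")
  }
  grid <- tidyr::expand_grid(term1 = starts, term2 = targets)
  grid <- grid[grid$term1 != grid$term2, , drop = FALSE]
  in_pre <- pair_occurs(pre, grid$term1, grid$term2, directed)
  grid <- grid[!in_pre, , drop = FALSE]
  grid$label <- pair_occurs(post, grid$term1, grid$term2, directed)
  grid
}

#' Rank scored pairs with the false-first tie penalty
#'
#' Sorts labelled, scored pairs by descending score for threshold-based
#' evaluation. Methods that assign many tied scores would otherwise get
#' credit for an ordering they never produced, so within every group of
#' tied scores all false pairs are placed before all true pairs — the
#' worst ordering the method could have produced. Pairs with undefined
#' (`NA`) scores form the final tie group, below every defined score.
#'
#' @param scored A data frame with a numeric `score` column (`NA` allowed)
#'   and a logical or 0/1 `label` column.
#' @return The input rows sorted, with an integer `rank` column prepended
#'   to the ordering.
#' @export
rank_with_tie_penalty <- function(scored) {
  scored <- tibble::as_tibble(scored)
  if (!all(c("score", "label") %in% names(scored))) {
    rlang::abort("`scored` must have `score` and `label` columns")
  }
  lab <- as.logical(scored$label)
  if (any(is.na(lab))) rlang::abort("labels must be TRUE/FALSE (or 0/1)")
  scored$label <- lab
  ranked <- scored[order(-ifelse(is.na(scored$score), -Inf, scored$score), lab), ,
                   drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  ranked
}

check_ranked <- function(ranked, need_pos = TRUE, need_neg = TRUE) {
  if (!all(c("label", "rank") %in% names(ranked))) {
    rlang::abort("expected a ranked pair list from rank_with_tie_penalty()")
  }
  if (need_pos && sum(ranked$label) == 0) {
    rlang::abort("undefined recall: no true pairs in the ranked list")
  }
  if (need_neg && sum(!ranked$label) == 0) {
    rlang::abort("no false pairs in the ranked list")
  }
  invisible(ranked)
}

#' Precision-recall curve over a ranked pair list
#'
#' Thresholds the ranked list at every rank `k`: pairs at rank `<= k`
#' are predicted true. Precision is `TP_k / k` and recall `TP_k / P`.
#' The area under the curve uses rectangular (step) integration — the
#' sum, over ranks where recall increases, of the recall increment times
#' the precision at that rank — anchored at recall 0. Step integration
#' avoids the optimistic bias of linear interpolation between PR points.
#'
#' @param ranked Output of [rank_with_tie_penalty()] (any data frame with
#'   `rank` and logical `label` columns, sorted by rank).
#' @return An object of class `lbd_pr_curve` with fields `points`
#'   (tibble: `rank`, `recall`, `precision`), `auc`, `n_pos`, `n_neg`.
#'   [tidy()] returns the points, [glance()] the summary,
#'   [ggplot2::autoplot()] draws the curve.
#' @examples
#' ranked <- rank_with_tie_penalty(tibble::tibble(
#'   score = c(4, 3, 2, 1), label = c(TRUE, FALSE, TRUE, FALSE)
#' ))
#' pr_curve(ranked)$auc  # 5/6
#' @export
pr_curve <- function(ranked) {
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  check_ranked(ranked, need_pos = TRUE, need_neg = FALSE)
  lab <- as.logical(ranked$label)
  P <- sum(lab)
  tp <- cumsum(lab)
  k <- seq_along(lab)
  recall <- tp / P
  precision <- tp / k
  d_recall <- diff(c(0, recall))
  auc <- sum(d_recall * precision)
  structure(
    list(
      points = tibble::tibble(rank = k, recall = recall, precision = precision),
      auc = auc, n_pos = P, n_neg = sum(!lab)
    ),
    class = "lbd_pr_curve"
  )
}

#' ROC curve and area under it
#'
#' Thresholds the ranked list at every rank and traces (false positive
#' rate, true positive rate) points; the area is computed by trapezoidal
#' integration anchored at (0, 0). Tie handling happens upstream in
#' [rank_with_tie_penalty()]. On tie-free inputs the area equals the
#' Mann-Whitney U statistic divided by `P * N`.
#'
#' @inheritParams pr_curve
#' @return `roc_curve()` returns an object of class `lbd_roc_curve` with
#'   fields `points` (tibble: `rank`, `fpr`, `tpr`), `auc`, `n_pos`,
#'   `n_neg`; `roc_auc()` returns the area alone.
#' @examples
#' ranked <- rank_with_tie_penalty(tibble::tibble(
#'   score = c(4, 3, 2, 1), label = c(TRUE, FALSE, TRUE, FALSE)
#' ))
#' roc_auc(ranked)  # 0.75
#' @export
roc_curve <- function(ranked) {
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  check_ranked(ranked, need_pos = TRUE, need_neg = TRUE)
  lab <- as.logical(ranked$label)
  P <- sum(lab)
  N <- sum(!lab)
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  tpr <- tp / P
  fpr <- fp / N
  auc <- sum(diff(c(0, fpr)) * (utils::head(c(0, tpr), -1) + tpr) / 2)
  structure(
    list(
      points = tibble::tibble(rank = seq_along(lab), fpr = fpr, tpr = tpr),
      auc = auc, n_pos = P, n_neg = N
    ),
    class = "lbd_roc_curve"
  )
}

#' @rdname roc_curve
#' @export
roc_auc <- function(ranked) {
  roc_curve(ranked)$auc
}

#' @export
print.lbd_pr_curve <- function(x, ...) {
  cat(sprintf(
    "<lbd_pr_curve> %d ranks (%d true, %d false), PR AUC = %.4f\n",
    nrow(x$points), x$n_pos, x$n_neg, x$auc
  ))
  invisible(x)
}

#' @export
print.lbd_roc_curve <- function(x, ...) {
  cat(sprintf(
    "<lbd_roc_curve> %d ranks (%d true, %d false), AUROC = %.4f\n",
    nrow(x$points), x$n_pos, x$n_neg, x$auc
  ))
  invisible(x)
}

#' Tidiers for package result objects
#'
#' broom-style accessors: `tidy()` returns the per-rank (or per-cell)
#' detail as a tibble, `glance()` a one-row summary.
#'
#' @param x A `lbd_pr_curve`, `lbd_roc_curve`, or `lbd_contingency`.
#' @param ... Unused.
#' @return A tibble.
#' @name lbd_tidiers
NULL

#' @rdname lbd_tidiers
#' @export
tidy.lbd_pr_curve <- function(x, ...) x$points

#' @rdname lbd_tidiers
#' @export
glance.lbd_pr_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 n = x$n_pos + x$n_neg)
}

#' @rdname lbd_tidiers
#' @export
tidy.lbd_roc_curve <- function(x, ...) x$points

#' @rdname lbd_tidiers
#' @export
glance.lbd_roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 n = x$n_pos + x$n_neg)
}

#' Plot a precision-recall or ROC curve
#'
#' @param object A `lbd_pr_curve` or `lbd_roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lbd_pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Precision-recall curve (AUC = %.3f)", object$auc)
    )
}

#' @rdname autoplot.lbd_pr_curve
#' @export
autoplot.lbd_roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUROC = %.3f)", object$auc)
    )
}

#' Sample start terms from candidate categories
#'
#' Utility for building extrinsic evaluation sets: given candidate term
#' lists (one per semantic category) draw `k` terms from each without
#' replacement, reproducibly from a seed.
#'
#' @param candidates A named list of character vectors.
#' @param k Number of terms per category.
#' @param seed Integer seed.
#' @return A tibble with columns `category`, `term`.
#' @export
sample_start_terms <- function(candidates, k, seed) {
  if (!is.list(candidates) || is.null(names(candidates))) {
    rlang::abort("`candidates` must be a named list of character vectors")
  }
  if (any(vapply(candidates, length, integer(1)) < k)) {
    rlang::abort("each category must hold at least `k` candidates")
  }
  with_seed(seed, {
    purrr::imap_dfr(candidates, function(terms, cat) {
      tibble::tibble(category = cat, term = sample(as.character(terms), k))
    })
  })
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
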