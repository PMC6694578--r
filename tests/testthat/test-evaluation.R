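make_gold <- function(scores) {
  tibble::tibble(
    term1 = paste0("x", seq_along(scores)),
    term2 = paste0("y", seq_along(scores)),
    score = scores
  )
}

test_that("spearman evaluation matches hand values and drops undefined pairs", {
  gold <- make_gold(c(1, 2, 3, 4))
  expect_equal(spearman_eval(gold, gold)$rho, 1)
  neg <- dplyr::mutate(gold, score = -score)
  expect_equal(spearman_eval(gold, neg)$rho, -1)
  swapped <- dplyr::mutate(gold, score = c(2, 1, 4, 3))
  expect_equal(spearman_eval(gold, swapped)$rho, 0.6)

  # undefined scores reduce n by exactly their count
  gold5 <- make_gold(c(1, 2, 3, 4, 5))
  part <- dplyr::mutate(gold5, score = c(1, NA, 3, NA, 5))
  res <- spearman_eval(gold5, part)
  expect_equal(res$n, 3)
  expect_equal(res$n_dropped, 2)
  expect_equal(res$rho, 1)

  # matching is order-insensitive in the pair
  rev2 <- swapped
  rev2$term1 <- gold$term2
  rev2$term2 <- gold$term1
  expect_equal(spearman_eval(gold, rev2)$rho, 0.6)

  expect_error(spearman_eval(gold, dplyr::mutate(gold, score = NA_real_)),
               "insufficient defined pairs")
  expect_error(
    spearman_eval(dplyr::bind_rows(gold, gold[1, ]), gold),
    "duplicate pair"
  )
})

test_that("spearman self-correlation is exactly 1 on tie-free gold sets", {
  for (seed in 1:5) {
    set.seed(seed)
    gold <- make_gold(sample(seq(0.1, 9.9, by = 0.7)))
    expect_identical(spearman_eval(gold, gold)$rho, 1)
  }
})

test_that("fisher r-to-z matches the closed form and is antisymmetric", {
  eq <- fisher_r_to_z(0.4, 50, 0.4, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  cmp <- fisher_r_to_z(0.7038, 392, 0.5315, 390)
  expect_equal(cmp$z, 3.93, tolerance = 0.01)
  expect_lt(cmp$p, 0.001)

  expect_equal(fisher_r_to_z(0.2, 30, 0.5, 40)$z,
               -fisher_r_to_z(0.5, 40, 0.2, 30)$z)
  expect_error(fisher_r_to_z(1, 10, 0.5, 10), "strictly inside")
  expect_error(fisher_r_to_z(0.5, 3, 0.5, 10), "exceed 3")
})

test_that("time-slicing labels exclude pre pairs and label by post occurrence", {
  pre <- cooc_matrix(tibble::tibble(
    term1 = c("s1", "s2"), term2 = c("t1", "t2"), n = c(2, 2)
  ), vocabulary = c("s1", "s2", "s3", "t1", "t2", "t3", "t4"))
  post <- cooc_matrix(tibble::tibble(
    term1 = c("s1", "s3", "t3"), term2 = c("t1", "t2", "s2"), n = c(1, 1, 1)
  ))
  starts <- c("s1", "s2", "s3")
  targets <- c("t1", "t2", "t3", "t4")
  lab <- timeslice_labels(pre, post, starts, targets)
  # 12 combinations, 2 removed by the pre matrix
  expect_equal(nrow(lab), 10)
  expect_false(any(paste(lab$term1, lab$term2) %in% c("s1 t1", "s2 t2")))
  # post-only pairs true (either direction), absent pairs false
  expect_true(lab$label[lab$term1 == "s3" & lab$term2 == "t2"])
  expect_true(lab$label[lab$term1 == "s2" & lab$term2 == "t3"])
  expect_false(lab$label[lab$term1 == "s1" & lab$term2 == "t4"])
  expect_equal(sum(lab$label), 2)

  # brute-force enumeration oracle
  pre_d <- as_dense(pre)
  vocab_post <- cooc_vocabulary(post)
  post_d <- as_dense(post)
  want <- 0
  for (s in starts) for (t in targets) {
    if (s == t) next
    in_pre <- (s %in% rownames(pre_d) && t %in% rownames(pre_d) &&
                 (pre_d[s, t] > 0 || pre_d[t, s] > 0))
    if (in_pre) next
    want <- want + 1
  }
  expect_equal(nrow(lab), want)

  # directed mode requires the (s, t) orientation
  lab_dir <- timeslice_labels(pre, post, starts, targets, directed = TRUE)
  expect_false(lab_dir$label[lab_dir$term1 == "s2" & lab_dir$term2 == "t3"])
})

test_that("a pair in pre and post is excluded; start equal to target is skipped", {
  both <- cooc_matrix(tibble::tibble(term1 = "s", term2 = "t", n = 1))
  lab <- timeslice_labels(both, both, "s", c("s", "t"))
  expect_equal(nrow(lab), 0)
})

test_that("tie penalty ranks false before true only within tied scores", {
  scored <- tibble::tibble(
    pair = c("p_true", "p_false"),
    score = c(0.7, 0.7),
    label = c(TRUE, FALSE)
  )
  ranked <- rank_with_tie_penalty(scored)
  expect_equal(ranked$pair, c("p_false", "p_true"))

  distinct <- tibble::tibble(
    pair = letters[1:4],
    score = c(0.9, 0.8, 0.7, 0.6),
    label = c(TRUE, FALSE, TRUE, FALSE)
  )
  expect_equal(rank_with_tie_penalty(distinct)$pair, letters[1:4])

  # undefined scores form the final tie group, false first
  all_na <- tibble::tibble(score = c(NA, NA, NA),
                           label = c(TRUE, FALSE, TRUE))
  expect_equal(rank_with_tie_penalty(all_na)$label, c(FALSE, TRUE, TRUE))

  mixed <- tibble::tibble(score = c(NA, 0.2, NA), label = c(TRUE, TRUE, FALSE))
  expect_equal(rank_with_tie_penalty(mixed)$label, c(TRUE, FALSE, TRUE))
})

test_that("PR curve reproduces hand-computed points and step AUC", {
  ranked <- rank_with_tie_penalty(tibble::tibble(
    score = c(4, 3, 2, 1), label = c(TRUE, FALSE, TRUE, FALSE)
  ))
  curve <- pr_curve(ranked)
  expect_equal(curve$points$recall, c(0.5, 0.5, 1, 1))
  expect_equal(curve$points$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(curve$auc, 5 / 6)

  # perfect separation
  perfect <- rank_with_tie_penalty(tibble::tibble(
    score = 6:1, label = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ))
  expect_equal(pr_curve(perfect)$auc, 1)
  expect_equal(roc_auc(perfect), 1)
  reversed <- rank_with_tie_penalty(tibble::tibble(
    score = 6:1, label = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  ))
  expect_equal(roc_auc(reversed), 0)

  # one true and one false pair, tied: recall jumps 0 -> 1 at rank 2
  tied <- rank_with_tie_penalty(tibble::tibble(
    score = c(1, 1), label = c(TRUE, FALSE)
  ))
  expect_equal(pr_curve(tied)$auc, 0.5)

  expect_error(pr_curve(rank_with_tie_penalty(
    tibble::tibble(score = 1, label = FALSE)
  )), "undefined recall")
})

test_that("recall is non-decreasing and TP + FP equals the rank everywhere", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 5 + seed
    ranked <- rank_with_tie_penalty(tibble::tibble(
      score = sample(c(stats::runif(n - 2), NA, NA)),
      label = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    ))
    if (sum(ranked$label) == 0 || sum(!ranked$label) == 0) next
    pr <- pr_curve(ranked)
    expect_true(all(diff(pr$points$recall) >= 0))
    roc <- roc_curve(ranked)
    tp <- roc$points$tpr * roc$n_pos
    fp <- roc$points$fpr * roc$n_neg
    expect_equal(tp + fp, as.numeric(roc$points$rank))
  }
})

test_that("AUROC equals the Mann-Whitney statistic on tie-free rankings", {
  ranked <- rank_with_tie_penalty(tibble::tibble(
    score = c(4, 3, 2, 1), label = c(TRUE, FALSE, TRUE, FALSE)
  ))
  expect_equal(roc_auc(ranked), 0.75)
  expect_equal(roc_auc(ranked), mwu_auc(c(TRUE, FALSE, TRUE, FALSE)))
  for (seed in 1:10) {
    set.seed(seed)
    labels <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(labels) || all(labels)) next
    ranked <- rank_with_tie_penalty(tibble::tibble(
      score = seq(12, 1), label = labels
    ))
    expect_equal(roc_auc(ranked), mwu_auc(labels), info = paste("seed", seed))
  }
  # cross-check against an established implementation
  skip_if_not_installed("pROC")
  set.seed(99)
  score <- stats::runif(30)
  label <- stats::runif(30) < 0.4
  ranked <- rank_with_tie_penalty(tibble::tibble(score = score, label = label))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = label, predictor = score, quiet = TRUE, direction = "<"
  )))
  expect_equal(roc_auc(ranked), ref, tolerance = 1e-10)
})

test_that("the false-first tie rule minimises AUC over within-tie orderings", {
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  perms <- unique(combinat_permutations(labels))
  tied_scores <- rep(1, length(labels))
  penalised <- rank_with_tie_penalty(tibble::tibble(
    score = tied_scores, label = labels
  ))
  pr_pen <- pr_curve(penalised)$auc
  roc_pen <- roc_auc(penalised)
  for (perm in perms) {
    manual <- tibble::tibble(rank = seq_along(perm), label = perm)
    expect_lte(pr_pen, pr_curve(manual)$auc + 1e-12)
    expect_lte(roc_pen, roc_curve(manual)$auc + 1e-12)
  }
})

test_that("curve tidiers and plots expose the points and summary", {
  ranked <- rank_with_tie_penalty(tibble::tibble(
    score = c(4, 3, 2, 1), label = c(TRUE, FALSE, TRUE, FALSE)
  ))
  pr <- pr_curve(ranked)
  expect_equal(tidy(pr), pr$points)
  expect_equal(glance(pr)$auc, 5 / 6)
  expect_equal(glance(pr)$n, 4)
  roc <- roc_curve(ranked)
  expect_equal(glance(roc)$auc, 0.75)
  expect_s3_class(autoplot(pr), "ggplot")
  expect_s3_class(autoplot(roc), "ggplot")
})

test_that("start-term sampling is seed-reproducible and category-stratified", {
  cands <- list(drug = paste0("d", 1:20), disease = paste0("x", 1:20))
  s1 <- sample_start_terms(cands, k = 5, seed = 11)
  s2 <- sample_start_terms(cands, k = 5, seed = 11)
  expect_identical(s1, s2)
  expect_equal(table(s1$category), table(c(rep("drug", 5), rep("disease", 5))))
  expect_false(anyDuplicated(s1$term) > 0)
  expect_error(sample_start_terms(cands, k = 50, seed = 1), "at least")
})
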