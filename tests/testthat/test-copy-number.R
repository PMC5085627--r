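make_ct <- function(id, tissue, target, ct) {
  tibble::tibble(sample_id = id, tissue = tissue, target = target,
                 mean_ct = ct, sd_ct = 0.05)
}

test_that("relative content follows the delta-Ct model", {
  mt <- make_ct("s1", "tumor", "mt", 20)
  nuc <- make_ct("s1", "tumor", "nuclear", 20)
  expect_equal(relative_content(mt, nuc)$relative_content, 1)
  mt2 <- make_ct("s1", "tumor", "mt", 18)
  expect_equal(relative_content(mt2, nuc)$relative_content, 4)
  # explicit ideal efficiency is identical to the default
  expect_equal(relative_content(mt2, nuc, c(mt = 2, nuclear = 2)),
               relative_content(mt2, nuc))
  # invariance under a constant shift of both Ct means
  mt3 <- make_ct("s1", "tumor", "mt", 18 + 3.7)
  nuc3 <- make_ct("s1", "tumor", "nuclear", 20 + 3.7)
  expect_equal(relative_content(mt3, nuc3)$relative_content, 4)
  expect_error(relative_content(make_ct("a", "t", "mt", 20),
                                make_ct("b", "t", "nuclear", 20)),
               "mismatched")
  noisy <- make_ct("s1", "tumor", "mt", 20); noisy$sd_ct <- 0.8
  expect_warning(relative_content(noisy, nuc), "SD")
})

test_that("fold change is the content ratio with sane errors", {
  t8 <- tibble::tibble(sample_id = "s.t", tissue = "tumor", relative_content = 8)
  n2 <- tibble::tibble(sample_id = "s.n", tissue = "normal", relative_content = 2)
  expect_equal(fold_change(t8, n2), 4)
  n8 <- n2; n8$relative_content <- 8
  expect_equal(fold_change(t8, n8), 1)
  n0 <- n2; n0$relative_content <- 0
  expect_error(fold_change(t8, n0), "non-positive")
})

test_that("a planted 38-fold subject is recovered through noisy Ct values", {
  set.seed(14)
  ct_noise <- function(base) round(base + rnorm(3, 0, 0.15), 3)
  rec <- function(id, tissue, target, base) {
    r <- ct_noise(base)
    tibble::tibble(sample_id = id, tissue = tissue, target = target,
                   mean_ct = mean(r), sd_ct = sd(r))
  }
  content_n <- 90; fold <- 38
  nuc_n <- 24; mt_n <- nuc_n - log2(content_n)
  nuc_t <- 24.2; mt_t <- nuc_t - log2(content_n * fold)
  cn_t <- relative_content(rec("s.t", "tumor", "mt", mt_t),
                           rec("s.t", "tumor", "nuclear", nuc_t))
  cn_n <- relative_content(rec("s.n", "normal", "mt", mt_n),
                           rec("s.n", "normal", "nuclear", nuc_n))
  fc <- fold_change(cn_t, cn_n)
  expect_gt(fc, 38 * 0.75)
  expect_lt(fc, 38 / 0.75)
})

test_that("Mann-Whitney comparison matches exact enumeration", {
  # brute-force oracle: permutation distribution of U over all group
  # assignments
  exact_p <- function(x, y) {
    n1 <- length(x); pooled <- c(x, y)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(length(pooled), n1)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(8)
  for (sz in list(c(3, 3), c(4, 5), c(5, 5), c(6, 7), c(8, 8))) {
    for (rep in 1:5) {
      x <- rnorm(sz[1]); y <- rnorm(sz[2], 0.5)
      res <- cohort_compare(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_value, exact_p(x, y), tolerance = 1e-12,
                   label = paste(sz, collapse = "x"))
    }
  }
  # completely separated groups of 5: p = 2/252
  res <- cohort_compare(1:5, 6:10)
  expect_equal(res$p_value, 2 / choose(10, 5))
  # identical groups (full ties): p ~ 1 via the tie-corrected approximation
  res2 <- cohort_compare(rep(1:3, 4), rep(1:3, 4))
  expect_equal(res2$method, "normal-approximation")
  expect_gt(res2$p_value, 0.95)
  # large-sample path agrees with wilcox.test's normal approximation
  set.seed(9)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  res3 <- cohort_compare(x, y)
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res3$p_value, wt$p.value, tolerance = 1e-10)
  expect_error(cohort_compare(1, 1:5), "at least 2")
  # the paired alternative runs and is labelled
  expect_equal(cohort_compare(x[1:20], y[1:20], paired = TRUE)$method,
               "wilcoxon-signed-rank")
})

test_that("median cohort fold change is recovered within 15%", {
  meds <- vapply(1:20, function(s)
    stats::median(sim_copy_number(sim_config(seed = s))$true_fold), numeric(1))
  expect_lt(abs(mean(meds) / 4 - 1), 0.15)
})

test_that("fold changes measured from generated Ct tables track the truth", {
  cfg <- sim_config(seed = 5, n_pairs = 20, n_controls = 0,
                    n_normal_thyroid = 0)
  dir <- tempfile("cn")
  out <- generate_cohort(cfg, dir = dir)
  ct <- read_ct_table(out$paths$ct_csv)
  truth <- unlist(out$truth$fold_change)
  fc <- vapply(names(truth), function(s) {
    tm <- ct[ct$sample_id == paste0(s, ".tumor") & ct$target == "mt", ]
    tn <- ct[ct$sample_id == paste0(s, ".tumor") & ct$target == "nuclear", ]
    nm <- ct[ct$sample_id == paste0(s, ".normal") & ct$target == "mt", ]
    nn <- ct[ct$sample_id == paste0(s, ".normal") & ct$target == "nuclear", ]
    fold_change(relative_content(tm, tn), relative_content(nm, nn))
  }, numeric(1))
  expect_gt(stats::cor(log2(fc), log2(truth)), 0.97)
  expect_lt(stats::median(abs(log2(fc) - log2(truth))), 0.35)
})
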