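complete_fixture <- function(n = 5, mean = 10, sd = 3, seed = 1) {
  simulate_surgtlx(n, surgtlx_params_uniform(mean, sd), seed = seed)
}

test_that("complete-case filtering retains exactly the fully complete respondents", {
  # cohort of 28 with 9 spoiled questionnaires -> 19 analyzable
  resp <- complete_fixture(28, seed = 4)
  withr::with_seed(8, spoil <- sample(28, 9))
  for (r in spoil) {
    rows <- which(resp$respondent == r)
    resp$score[rows[sample.int(length(rows), sample(1:5, 1))]] <- NA
  }
  kept <- surgtlx_complete(resp)
  expect_equal(dplyr::n_distinct(kept$respondent), 19L)
  expect_equal(attr(kept, "n_dropped"), 9L)
  expect_setdiff <- setdiff(unique(kept$respondent), spoil)
  expect_equal(sort(unique(kept$respondent)), sort(setdiff(1:28, spoil)))

  all_complete <- complete_fixture(6, seed = 5)
  expect_equal(surgtlx_complete(all_complete), all_complete, ignore_attr = TRUE)

  one_missing <- all_complete
  one_missing$score[1] <- NA
  expect_equal(dplyr::n_distinct(surgtlx_complete(one_missing)$respondent), 5L)
})

test_that("phase and type sums are exact and bounded by the summed scale", {
  hi <- simulate_surgtlx(2, surgtlx_params_uniform(20, 0), seed = 1)
  expect_true(all(sum_over_phases(hi, "mental")$score == 60))
  lo <- simulate_surgtlx(2, surgtlx_params_uniform(0, 0), seed = 1)
  expect_true(all(sum_over_phases(lo, "mental")$score == 0))

  r <- complete_fixture(1, seed = 2)
  cells <- r %>%
    dplyr::filter(domain == "stress", surgery_type == "RAS")
  r$score[r$domain == "stress" & r$surgery_type == "RAS"] <- c(5, 7, 9)
  s <- sum_over_phases(r, "stress")
  expect_equal(s$score[s$surgery_type == "RAS"], 21)

  rnd <- complete_fixture(8, seed = 3)
  expect_true(all(dplyr::between(sum_over_phases(rnd, "temporal")$score, 0, 60)))
  expect_true(all(dplyr::between(sum_over_types(rnd, "temporal")$score, 0, 60)))

  incomplete <- rnd
  incomplete$score[incomplete$domain == "temporal"][1] <- NA
  expect_error(sum_over_phases(incomplete, "temporal"), "incomplete")
})

test_that("overall workload averages the six original domains only", {
  const <- simulate_surgtlx(3, surgtlx_params_uniform(7, 0), seed = 1)
  w <- mean_workload(const)
  expect_equal(w$workload, rep(21, 3)) # 3c with c = 7

  perturbed <- const
  perturbed$score[perturbed$domain == "satisfaction"] <- 0
  expect_equal(mean_workload(perturbed), w)
})

test_that("the Friedman statistic matches the worked example and stats::friedman.test", {
  same <- matrix(5, nrow = 6, ncol = 3)
  ft <- friedman_rank_test(same)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)

  ordered <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  ft2 <- friedman_rank_test(ordered)
  expect_equal(ft2$statistic, 8)
  expect_equal(ft2$statistic_uncorrected, 8)
  expect_equal(ft2$effect_size, 1) # 8 / (4 * 2)
  expect_equal(kendall_w(ordered), 1)

  for (seed in 1:5) {
    withr::with_seed(seed, m <- matrix(sample(1:10, 30, replace = TRUE), ncol = 3))
    ours <- friedman_rank_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
  }

  expect_error(friedman_rank_test(matrix(1, 2, 2)), "3 related conditions")
  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
})

test_that("Nemenyi p-values are symmetric, unit-diagonal and shift-monotone", {
  same <- matrix(2, nrow = 8, ncol = 3)
  p_same <- nemenyi_test(same)
  expect_equal(diag(p_same), rep(1, 3))
  expect_true(all(abs(p_same - t(p_same)) < 1e-12))
  expect_true(all(p_same[upper.tri(p_same)] > 0.999))

  ordered <- matrix(rep(c(1, 2, 3), each = 100), nrow = 100)
  p_ord <- nemenyi_test(ordered)
  expect_true(all(p_ord[upper.tri(p_ord)] < 1e-6))
})

test_that("rank statistics are invariant to monotone transforms and permutations", {
  withr::with_seed(11, m <- matrix(rnorm(19 * 3, 10, 3), ncol = 3))
  base_f <- friedman_rank_test(m)
  base_n <- nemenyi_test(m)

  warped <- t(apply(m, 1, function(row) exp(row / 4) + 100))
  expect_equal(friedman_rank_test(warped)$statistic, base_f$statistic)
  expect_equal(nemenyi_test(warped), base_n, ignore_attr = TRUE)

  perm_rows <- m[sample(nrow(m)), ]
  expect_equal(friedman_rank_test(perm_rows)$statistic, base_f$statistic)

  perm <- c(3, 1, 2)
  expect_equal(nemenyi_test(m[, perm]), base_n[perm, perm], ignore_attr = TRUE)
})

test_that("the full analysis gates the post-hoc on omnibus significance", {
  flat <- simulate_surgtlx(12, surgtlx_params_uniform(10, 2), seed = 6)
  res_flat <- surgtlx_analyze(flat)
  sig_flat <- res_flat$by_type$p_value < 0.05
  expect_true(all(purrr::map_lgl(res_flat$by_type$posthoc[!sig_flat], is.null)))

  # robotic temporal demand shifted up by ~1.5 phase-scale SD
  params <- surgtlx_params_uniform(8, 2)
  params$mean[params$domain == "temporal" & params$surgery_type == "RAS"] <- 13
  shifted <- simulate_surgtlx(19, params, seed = 7)
  res <- surgtlx_analyze(shifted)
  row <- res$by_type %>% dplyr::filter(domain == "temporal")
  expect_lt(row$p_value, 0.05)
  ph <- row$posthoc[[1]]
  expect_false(is.null(ph))
  expect_lt(ph["RAS", "OS"], 0.05)
  expect_lt(ph["RAS", "MIS"], 0.05)

  expect_error(surgtlx_analyze(flat[0, ]), "at least 2")

  td <- tidy(res)
  expect_true(all(c("comparison", "domain", "p_value") %in% names(td)))
  expect_equal(nrow(td), 14L)
  g <- glance(res)
  expect_equal(g$n, 19L)

  expect_s3_class(autoplot(res), "ggplot")
})
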