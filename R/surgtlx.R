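#' Domains of the extended workload instrument
#'
#' The six original Surgery Task Load Index domains — mental demand,
#' physical demand, temporal demand, task complexity, situational stress,
#' distractions — each scored 0-20, plus an exploratory seventh domain,
#' job satisfaction, on the same scale. Every domain is scored per surgery
#' type (OS/MIS/RAS) and per clinical phase, 63 cells per respondent.
#'
#' @return Character vector of the seven domain names.
#' @export
surgtlx_domains <- function() {
  c("mental", "physical", "temporal", "complexity", "stress",
    "distractions", "satisfaction")
}

#' @rdname surgtlx_domains
#' @export
surgtlx_original_domains <- function() setdiff(surgtlx_domains(), "satisfaction")

#' Complete-case filter for questionnaire responses
#'
#' Retains only respondents with all 63 cells present (no missing rows, no
#' `NA` scores). No imputation is applied — partially completed
#' questionnaires are simply excluded from the quantitative analysis.
#'
#' @param responses Long response tibble (`respondent`, `domain`,
#'   `surgery_type`, `phase`, `score`).
#' @return Filtered tibble; the number of dropped respondents is attached
#'   as attribute `n_dropped`.
#' @export
#' @examples
#' r <- simulate_surgtlx(10, surgtlx_params_uniform(10, 2),
#'                       missing_rate = 0.3, seed = 2)
#' nrow(surgtlx_complete(r)) %% 63 == 0
surgtlx_complete <- function(responses) {
  validate_surgtlx(responses)
  n_cells <- length(surgtlx_domains()) * length(surgery_types()) * 3L
  ok <- responses %>%
    group_by(.data$respondent) %>%
    summarise(complete = sum(!is.na(.data$score)) == n_cells, .groups = "drop")
  keep <- ok$respondent[ok$complete]
  out <- responses %>% filter(.data$respondent %in% keep)
  attr(out, "n_dropped") <- sum(!ok$complete)
  out
}

#' Phase- and type-summed scores
#'
#' `sum_over_phases()` sums a domain's scores across the three phases,
#' giving one 0-60 score per respondent per surgery type (the across-type
#' comparison). `sum_over_types()` sums across the three surgery types,
#' giving one 0-60 score per respondent per phase (the across-phase
#' comparison).
#'
#' @param responses COMPLETE responses (apply [surgtlx_complete()] first;
#'   a respondent with missing cells in the requested domain is an error).
#' @param domain One of [surgtlx_domains()].
#' @return Tibble `respondent` x condition with column `score` in [0, 60].
#' @export
sum_over_phases <- function(responses, domain) {
  sum_scores(responses, domain, "surgery_type")
}

#' @rdname sum_over_phases
#' @export
sum_over_types <- function(responses, domain) {
  sum_scores(responses, domain, "phase")
}

sum_scores <- function(responses, domain, by) {
  domain <- match.arg(domain, surgtlx_domains())
  d <- responses %>% filter(.data$domain == !!domain)
  chk <- tibble(respondent = unique(responses$respondent)) %>%
    left_join(
      d %>% group_by(.data$respondent) %>%
        summarise(n_ok = sum(!is.na(.data$score)), .groups = "drop"),
      by = "respondent"
    ) %>%
    mutate(n_ok = dplyr::coalesce(.data$n_ok, 0L))
  if (any(chk$n_ok < 9L)) {
    abort("responses contain incomplete respondents; apply surgtlx_complete() first")
  }
  d %>%
    group_by(.data$respondent, .data[[by]]) %>%
    summarise(score = sum(.data$score), .groups = "drop")
}

#' Overall workload per surgery type
#'
#' Mean workload on the six original domains (job satisfaction excluded):
#' per respondent, scores are summed across phases within each original
#' domain (0-60 scale), averaged over the six domains, then averaged over
#' respondents — one scalar per surgery type. If all 63 cells equal `c`,
#' the result is `3c` for every type.
#'
#' @param responses Complete responses.
#' @return Tibble `surgery_type`, `workload`.
#' @export
mean_workload <- function(responses) {
  validate_surgtlx(responses)
  d <- responses %>% filter(.data$domain %in% surgtlx_original_domains())
  if (any(is.na(d$score))) {
    abort("responses contain missing cells; apply surgtlx_complete() first")
  }
  d %>%
    group_by(.data$respondent, .data$surgery_type, .data$domain) %>%
    summarise(s = sum(.data$score), .groups = "drop") %>%
    group_by(.data$respondent, .data$surgery_type) %>%
    summarise(m = mean(.data$s), .groups = "drop") %>%
    group_by(.data$surgery_type) %>%
    summarise(workload = mean(.data$m), .groups = "drop")
}

#' Friedman rank test for k related conditions
#'
#' Nonparametric omnibus test on an n-respondents x k-conditions matrix of
#' related scores. Rows are ranked with average ranks for ties;
#' `statistic` is the tie-corrected chi-square
#' (identical to `stats::friedman.test()`), and the classical uncorrected
#' value `12/(n k (k+1)) * sum Rj^2 - 3 n (k+1)` is reported alongside
#' because statistical packages differ in whether they apply the tie
#' correction. The p-value uses the upper tail of the chi-square
#' distribution with k-1 degrees of freedom. The effect size is Kendall's
#' coefficient of concordance `W = statistic / (n (k - 1))` in [0, 1].
#'
#' @param x Numeric matrix or data frame: rows = respondents (n >= 2),
#'   columns = conditions (k >= 3), no missing values.
#' @return A `friedman_w` object with elements `statistic`, `p_value`,
#'   `statistic_uncorrected`, `p_value_uncorrected`, `effect_size`
#'   (Kendall's W), `mean_ranks`, `n`, `k`.
#' @export
#' @examples
#' m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4) # perfectly ordered rows
#' friedman_rank_test(m)$statistic # 8
friedman_rank_test <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("missing cells are not allowed; filter complete cases first")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) abort("need at least 2 rows (respondents)")
  if (k < 3L) abort("need at least 3 related conditions")
  r <- t(apply(x, 1L, rank))
  R <- colSums(r)
  uncorrected <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  ties <- sum(apply(r, 1L, function(u) {
    tb <- table(u)
    sum(tb^3 - tb)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  statistic <- if (denom <= 0) 0 else {
    12 * sum((R - n * (k + 1) / 2)^2) / denom
  }
  structure(
    list(
      statistic = statistic,
      p_value = pchisq(statistic, df = k - 1, lower.tail = FALSE),
      statistic_uncorrected = uncorrected,
      p_value_uncorrected = pchisq(uncorrected, df = k - 1, lower.tail = FALSE),
      effect_size = statistic / (n * (k - 1)),
      mean_ranks = setNames(R / n, colnames(x)),
      n = n, k = k
    ),
    class = "friedman_w"
  )
}

#' @export
print.friedman_w <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: chi^2 = %.4f (df = %d), p = %.4g, Kendall's W = %.4f (n = %d)\n",
    x$statistic, x$k - 1, x$p_value, x$effect_size, x$n
  ))
  invisible(x)
}

#' @export
tidy.friedman_w <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p_value,
    statistic.uncorrected = x$statistic_uncorrected,
    p.value.uncorrected = x$p_value_uncorrected,
    kendall_w = x$effect_size, df = x$k - 1, n = x$n, k = x$k
  )
}

#' @export
glance.friedman_w <- function(x, ...) tidy(x)

#' Nemenyi post-hoc test
#'
#' All-pairs comparison of mean ranks after a Friedman test: the pairwise
#' p-value comes from the studentized-range distribution applied to the
#' mean-rank difference with standard error `sqrt(k (k + 1) / (6 n))`.
#' The returned matrix is symmetric with unit diagonal.
#'
#' @inheritParams friedman_rank_test
#' @return A k x k matrix of pairwise p-values.
#' @export
nemenyi_test <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("missing cells are not allowed; filter complete cases first")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) abort("need at least 2 rows (respondents)")
  if (k < 3L) abort("need at least 3 related conditions")
  r <- t(apply(x, 1L, rank))
  mr <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  q <- abs(outer(mr, mr, "-")) / se * sqrt(2)
  p <- ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  dimnames(p) <- list(colnames(x), colnames(x))
  p
}

#' Kendall's coefficient of concordance
#'
#' `W = chi^2_F / (n (k - 1))`, the concordance across respondents of the
#' condition ranking, used as the effect-size measure for the Friedman
#' design. 0 for identical columns, 1 for a strict ordering shared by all
#' respondents.
#'
#' @inheritParams friedman_rank_test
#' @return Scalar in [0, 1].
#' @export
kendall_w <- function(x) friedman_rank_test(x)$effect_size

#' Full instrument analysis
#'
#' Applies the complete-case filter, then runs, per domain, the Friedman
#' test (with Kendall's W as effect size) across the three surgery types on
#' phase-summed scores and across the three phases on type-summed scores.
#' When an omnibus test is significant at `alpha`, the Nemenyi post-hoc is
#' run to locate the differing pairs; otherwise no post-hoc is computed.
#' No correction is applied across the seven domains.
#'
#' @param responses Long response tibble (possibly with incomplete
#'   respondents; they are dropped).
#' @param alpha Omnibus significance level gating the post-hoc (default
#'   0.05).
#' @return A `surgtlx_analysis` object: list with `by_type` and `by_phase`
#'   result tibbles (one row per domain: means per condition, chi-square,
#'   p, Kendall's W, post-hoc p-values as a list column), the filtered
#'   `responses`, `n` and `n_dropped`.
#' @export
surgtlx_analyze <- function(responses, alpha = 0.05) {
  complete <- surgtlx_complete(responses)
  n_dropped <- attr(complete, "n_dropped")
  n <- dplyr::n_distinct(complete$respondent)
  if (n < 2L) abort("need at least 2 complete respondents")

  run_layout <- function(by) {
    conds <- if (by == "surgery_type") surgery_types() else 1:3
    purrr::map(surgtlx_domains(), function(dom) {
      sums <- sum_scores(complete, dom, by)
      m <- sums %>%
        tidyr::pivot_wider(names_from = dplyr::all_of(by), values_from = "score") %>%
        arrange(.data$respondent) %>%
        select(-"respondent") %>%
        as.matrix()
      m <- m[, as.character(conds), drop = FALSE]
      ft <- friedman_rank_test(m)
      posthoc <- if (ft$p_value < alpha) list(nemenyi_test(m)) else list(NULL)
      means <- colMeans(m)
      sds <- apply(m, 2L, sd)
      tibble(
        domain = dom,
        !!!setNames(as.list(means), paste0("mean_", conds)),
        !!!setNames(as.list(sds), paste0("sd_", conds)),
        statistic = ft$statistic, p_value = ft$p_value,
        kendall_w = ft$effect_size, posthoc = posthoc
      )
    }) %>% bind_rows()
  }

  structure(
    list(
      by_type = run_layout("surgery_type"),
      by_phase = run_layout("phase"),
      responses = complete, n = n, n_dropped = n_dropped, alpha = alpha
    ),
    class = "surgtlx_analysis"
  )
}

#' @export
print.surgtlx_analysis <- function(x, ...) {
  cat(sprintf(
    "<surgtlx_analysis> %d complete respondents (%d dropped)\n",
    x$n, x$n_dropped
  ))
  cat("Across surgery types (phase-summed scores):\n")
  print(x$by_type %>% select(-"posthoc"), n = Inf)
  cat("Across phases (type-summed scores):\n")
  print(x$by_phase %>% select(-"posthoc"), n = Inf)
  invisible(x)
}

#' @export
tidy.surgtlx_analysis <- function(x, ...) {
  bind_rows(
    x$by_type %>% mutate(comparison = "surgery_type") %>% select(-"posthoc"),
    x$by_phase %>% mutate(comparison = "phase") %>% select(-"posthoc")
  ) %>%
    select("comparison", "domain", dplyr::everything())
}

#' @export
glance.surgtlx_analysis <- function(x, ...) {
  tibble(
    n = x$n, n_dropped = x$n_dropped, alpha = x$alpha,
    n_significant_by_type = sum(x$by_type$p_value < x$alpha),
    n_significant_by_phase = sum(x$by_phase$p_value < x$alpha)
  )
}
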