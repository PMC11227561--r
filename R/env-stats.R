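#' Correlation between environmental stress and the extent of adaptation
#'
#' Correlates the progenitor's relative fitness in each environment
#' (`F_ratio`; lower = more stress) with the per-environment mean
#' extent of adaptation (`f_over_F_mean`) across environments.
#'
#' @param env_fitness output of [environment_fitness_summary()] (or
#'   any data frame with `F_ratio` and `f_over_F_mean`).
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative passed to [stats::cor.test()] (`"two.sided"`
#'   default).
#' @return a list of class `correlation_result`: `coefficient`,
#'   `p_value`, `n`, `method`.
#' @export
stress_adaptation_correlation <- function(env_fitness,
                                          method = c("pearson", "spearman"),
                                          alternative = "two.sided") {
  method <- match.arg(method)
  ok <- stats::complete.cases(env_fitness$F_ratio,
                              env_fitness$f_over_F_mean)
  x <- env_fitness$F_ratio[ok]; y <- env_fitness$f_over_F_mean[ok]
  if (length(x) < 3) stop("need at least 3 environments")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = alternative))
  structure(list(coefficient = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.4g (n = %d, p = %.3g)\n", x$method,
              x$coefficient, x$n, x$p_value))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Partial rank correlation of `x` and `y` controlling for `z`:
#' all three vectors are rank-transformed (average ranks for ties) and
#' the partial Pearson formula
#' `(rxy − rxz·ryz) / sqrt((1 − rxz²)(1 − ryz²))` is applied to the
#' ranks. The p-value uses the t approximation with `n − 3` degrees of
#' freedom.
#'
#' @param x,y,z equal-length numeric vectors, `n >= 4`.
#' @param alternative `"two.sided"` (default), `"less"` or
#'   `"greater"`.
#' @return a `correlation_result`.
#' @export
partial_rank_correlation <- function(x, y, z,
                                     alternative = c("two.sided", "less",
                                                     "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 4) stop("need at least 4 observations")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("control variable perfectly correlated with x or y; ",
         "partial correlation undefined")
  }
  pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pr <- max(-1, min(1, pr))
  df <- n - 3
  tstat <- pr * sqrt(df / (1 - pr^2))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              less = stats::pt(tstat, df),
              greater = stats::pt(tstat, df, lower.tail = FALSE))
  structure(list(coefficient = pr, p_value = min(1, p), n = n,
                 method = "partial spearman"),
            class = "correlation_result")
}

#' Linear extrapolation of an early fitness gain
#'
#' Given that `fraction_between` percent of the total fitness gain
#' accrued between generations `gen_start` and `gen_end`, and assuming
#' the same per-generation rate over the first `gen_target`
#' generations, returns the percent of the total gain attributed to
#' the first `gen_target` generations.
#'
#' @param fraction_between percent of the total gain observed in the
#'   window.
#' @param gen_start,gen_end window bounds (generations,
#'   `gen_end > gen_start >= 0`).
#' @param gen_target extrapolation target (generations, > 0).
#' @return percent of the total gain.
#' @export
fitness_gain_extrapolation <- function(fraction_between, gen_start,
                                       gen_end, gen_target) {
  stopifnot(gen_end > gen_start, gen_start >= 0, gen_target > 0)
  fraction_between * gen_target / (gen_end - gen_start)
}

#' Exact two-tailed binomial sign test
#'
#' Doubles the smaller tail probability and caps at 1.
#'
#' @param k number of concordant outcomes.
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @return the two-tailed probability.
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Benefit-versus-stress trend for an engineered mutation
#'
#' Tests whether the fitness benefit of a reconstructed substitution
#' grows with environmental stress. Environments where the mutation is
#' significantly deleterious (replicate mean effect < 1 with
#' one-sample two-tailed t-test p < 0.05 against 1) are excluded; the
#' Pearson correlation between the per-environment mean effect and the
#' stress level `F_ratio` is then computed, with a one-tailed p-value
#' for a negative correlation (larger benefit at lower `F_ratio`,
#' i.e. under more stress).
#'
#' @param panel data frame with columns `environment_id`, `effect`
#'   (relative fitness of the mutated progenitor, one row per
#'   replicate) and `stress` (the environment's `F_ratio`).
#' @param deleterious_alpha significance level of the exclusion filter.
#' @return a `correlation_result` with an extra `n_excluded` field.
#' @export
benefit_stress_trend <- function(panel, deleterious_alpha = 0.05) {
  need <- c("environment_id", "effect", "stress")
  stopifnot(all(need %in% names(panel)))
  by_env <- split(panel, panel$environment_id)
  rows <- lapply(by_env, function(d) {
    m <- mean(d$effect)
    p <- if (length(d$effect) >= 2 && stats::sd(d$effect) > 0) {
      stats::t.test(d$effect, mu = 1)$p.value
    } else NA_real_
    tibble::tibble(environment_id = d$environment_id[1], mean_effect = m,
                   t_p = p, stress = d$stress[1])
  })
  tab <- dplyr::bind_rows(rows)
  excl <- tab$mean_effect < 1 & !is.na(tab$t_p) &
    tab$t_p < deleterious_alpha
  keep <- tab[!excl, ]
  if (nrow(keep) < 3) {
    stop("fewer than 3 environments survive the deleterious-effect filter")
  }
  r <- stats::cor(keep$mean_effect, keep$stress)
  df <- nrow(keep) - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- stats::pt(tstat, df)   # one-tailed, r < 0
  out <- structure(list(coefficient = r, p_value = p, n = nrow(keep),
                        method = "pearson (one-tailed, r < 0)",
                        n_excluded = sum(excl)),
                   class = "correlation_result")
  out
}

#' Home/foreign sign-concordance table and exact test
#'
#' Counts, separately for home environments (where the mutated gene
#' was identified as adaptive) and foreign environments, how often the
#' mutation's mean fitness effect is above versus below 1, and runs a
#' one-tailed Fisher exact test for the association (beneficial at
#' home, deleterious abroad). Effects exactly equal to 1 are excluded
#' from both columns.
#'
#' @param panel data frame with columns `environment_id`, `effect`
#'   (one row per replicate) and `home_or_foreign`
#'   (`"home"`/`"foreign"`).
#' @return a list of class `sign_concordance`: `table` (2x2 matrix),
#'   `p_value`, `n_ties`.
#' @export
sign_concordance_table <- function(panel) {
  need <- c("environment_id", "effect", "home_or_foreign")
  stopifnot(all(need %in% names(panel)))
  stopifnot(all(panel$home_or_foreign %in% c("home", "foreign")))
  by_env <- split(panel, panel$environment_id)
  mean_eff <- vapply(by_env, function(d) mean(d$effect), numeric(1))
  label <- vapply(by_env, function(d) d$home_or_foreign[1], character(1))
  ties <- mean_eff == 1
  mean_eff <- mean_eff[!ties]; label <- label[!ties]
  tab <- matrix(c(sum(label == "home" & mean_eff > 1),
                  sum(label == "home" & mean_eff < 1),
                  sum(label == "foreign" & mean_eff > 1),
                  sum(label == "foreign" & mean_eff < 1)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("home", "foreign"),
                                c("gt1", "lt1")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(table = tab, p_value = p, n_ties = sum(ties)),
            class = "sign_concordance")
}

#' @export
print.sign_concordance <- function(x, ...) {
  print(x$table)
  cat(sprintf("one-tailed Fisher exact p = %.3g (%d tie(s) excluded)\n",
              x$p_value, x$n_ties))
  invisible(x)
}
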