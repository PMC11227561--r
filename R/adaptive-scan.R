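#' Scan configuration for the adaptive-unit test
#'
#' @param n_sim number of Monte-Carlo repeats (default 100000).
#' @param alpha significance level applied to Bonferroni-adjusted
#'   p-values (default 0.05).
#' @param n_tests Bonferroni divisor; defaults to the number of units
#'   in the tested compartment.
#' @param seed random seed for Monte-Carlo mode.
#' @param mode `"exact"` (binomial tail; default) or `"montecarlo"`
#'   (the randomization as performed in practice).
#' @param pseudo_count add-one correction for the empirical p
#'   (`(r+1)/(n_sim+1)`)? Off by default: with thousands of tests and
#'   1e5 repeats the pseudo-count floor would make Bonferroni
#'   significance unattainable, so the plain fraction `r/n_sim` is the
#'   operative construction.
#' @param collapse_duplicates count identical substitutions shared by
#'   several replicates of one environment only once? Off by default
#'   (each replicate's hit counts separately); available for
#'   sensitivity analysis.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(n_sim = 100000L, alpha = 0.05, n_tests = NULL,
                        seed = NULL, mode = c("exact", "montecarlo"),
                        pseudo_count = FALSE,
                        collapse_duplicates = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_sim >= 1, alpha > 0, alpha < 1)
  structure(list(n_sim = as.integer(n_sim), alpha = alpha,
                 n_tests = n_tests, seed = seed, mode = mode,
                 pseudo_count = pseudo_count,
                 collapse_duplicates = collapse_duplicates),
            class = "scan_config")
}

#' Exact tail probability for a unit's hit count
#'
#' Analytic counterpart of the length-proportional randomization: with
#' `n` substitutions placed independently across the compartment and a
#' unit covering a fraction `length_fraction` of its sites, the unit's
#' hit count is Binomial(`n`, `length_fraction`); the p-value is the
#' upper tail `P(X >= k)`, computed stably in log space.
#'
#' @param k observed hits (0 <= k <= n).
#' @param n pooled substitution count in the compartment.
#' @param length_fraction unit length / compartment length (in (0,1)).
#' @return the tail probability.
#' @export
exact_unit_pvalue <- function(k, n, length_fraction) {
  stopifnot(length_fraction > 0, length_fraction < 1)
  if (any(k > n)) stop("observed hits k cannot exceed n")
  if (any(k < 0)) stop("k must be nonnegative")
  ifelse(k == 0, 1,
         stats::pbinom(k - 1, n, length_fraction, lower.tail = FALSE))
}

#' Identify putatively adaptive units in one environment
#'
#' Tests every unit of one compartment (coding genes or merged
#' noncoding units) for harboring more substitutions, pooled across
#' the environment's replicate samples, than a length-proportional
#' random placement allows. In Monte-Carlo mode each repeat re-places
#' every sample's observed substitution count across units with
#' probability proportional to unit length, pools the samples, and the
#' empirical p-value of a unit is the fraction of repeats in which its
#' simulated hit count reaches or exceeds the observed count. In exact
#' mode the binomial tail [exact_unit_pvalue()] is used. P-values are
#' Bonferroni-adjusted by the number of tests and units with adjusted
#' p below `alpha` are flagged adaptive.
#'
#' @param env_hits per-sample unit assignments for one environment and
#'   one compartment: a data frame with columns `sample_id` and
#'   `unit_id` (one row per substitution; see [substitution_hits()]).
#'   Optionally columns `chrom`, `pos`, `ref`, `alt` (needed when
#'   `collapse_duplicates = TRUE`).
#' @param units data frame with columns `unit_id` and `length` (> 0)
#'   listing every unit of the compartment.
#' @param config a [scan_config()].
#' @return a tibble (class `unit_scan_result`) with one row per unit:
#'   `unit_id`, `observed_hits`, `p_raw`, `p_adjusted`, `adaptive`,
#'   `mode`, `n_sim`.
#' @export
scan_units <- function(env_hits, units, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (any(units$length <= 0)) stop("unit of zero length")
  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id in unit table")

  if (config$collapse_duplicates && nrow(env_hits) > 0) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(env_hits))) {
      stop("collapse_duplicates requires columns ",
           paste(need, collapse = ", "))
    }
    env_hits <- dplyr::distinct(env_hits, .data$chrom, .data$pos,
                                .data$ref, .data$alt, .data$unit_id)
    env_hits$sample_id <- "pooled"
  }

  empty <- tibble::tibble(unit_id = character(), observed_hits = integer(),
                          p_raw = numeric(), p_adjusted = numeric(),
                          adaptive = logical(), mode = character(),
                          n_sim = integer())
  if (nrow(env_hits) == 0) {
    warning("no substitutions in this environment/compartment; empty scan")
    return(structure(empty, class = c("unit_scan_result", class(empty))))
  }
  unknown <- setdiff(env_hits$unit_id, units$unit_id)
  if (length(unknown)) {
    stop("substitution(s) assigned to unit(s) absent from the unit table: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }

  obs <- table(factor(env_hits$unit_id, levels = units$unit_id))
  obs <- as.integer(obs)
  n_total <- sum(obs)
  prob <- units$length / sum(units$length)
  n_tests <- if (is.null(config$n_tests)) nrow(units) else config$n_tests

  if (config$mode == "exact") {
    p_raw <- vapply(seq_along(obs), function(i) {
      if (obs[i] == 0) 1 else
        exact_unit_pvalue(obs[i], n_total, prob[i])
    }, numeric(1))
    n_sim_used <- NA_integer_
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    # placements are independent across substitutions and samples, so
    # the pooled per-repeat counts are Multinomial(n_total, prob);
    # chunked to bound memory at ~ n_units x 20000 integers
    exceed <- integer(length(obs))
    remaining <- config$n_sim
    chunk_size <- max(1L, min(20000L, config$n_sim))
    while (remaining > 0) {
      m <- min(chunk_size, remaining)
      sims <- stats::rmultinom(m, n_total, prob)
      exceed <- exceed + rowSums(sims >= obs)
      remaining <- remaining - m
    }
    p_raw <- if (config$pseudo_count) {
      (exceed + 1) / (config$n_sim + 1)
    } else {
      exceed / config$n_sim
    }
    n_sim_used <- config$n_sim
  }

  out <- tibble::tibble(
    unit_id = units$unit_id, observed_hits = obs, p_raw = p_raw,
    p_adjusted = pmin(1, p_raw * n_tests),
    adaptive = pmin(1, p_raw * n_tests) < config$alpha,
    mode = config$mode, n_sim = n_sim_used)
  structure(out, class = c("unit_scan_result", class(out)))
}

#' Scan all environments of a classified substitution table
#'
#' Splits pooled unit hits by environment and runs [scan_units()] on
#' the chosen compartment for each, with the Bonferroni divisor equal
#' to the number of units in the compartment.
#'
#' @param classified output of [classify_substitutions()] (manifest
#'   columns required).
#' @param model a `genome_model`.
#' @param compartment `"coding"` (genes) or `"noncoding"` (merged
#'   noncoding units).
#' @param config a [scan_config()].
#' @return tibble with one row per environment x unit, as
#'   [scan_units()] plus an `environment_id` column.
#' @export
adaptive_scan <- function(classified, model,
                          compartment = c("coding", "noncoding"),
                          config = scan_config()) {
  compartment <- match.arg(compartment)
  units <- if (compartment == "coding") {
    tibble::tibble(unit_id = model$genes$gene_id,
                   length = model$genes$length)
  } else {
    tibble::tibble(unit_id = model$noncoding_units$unit_id,
                   length = model$noncoding_units$length)
  }
  hits <- substitution_hits(classified)
  hits <- hits[hits$compartment == compartment & !is.na(hits$unit_id), ]
  envs <- sort(unique(classified$environment_id))
  out <- lapply(envs, function(e) {
    he <- hits[hits$environment_id == e, ]
    if (nrow(he) == 0) return(NULL)
    res <- scan_units(he, units, config)
    res$environment_id <- e
    res
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("unit_scan_result", class(res)))
}

#' Extract adaptive-unit sets per environment from scan results
#'
#' @param scan_result output of [adaptive_scan()].
#' @return named list: environment id -> character vector of adaptive
#'   unit ids (possibly empty).
#' @export
adaptive_sets <- function(scan_result) {
  envs <- unique(scan_result$environment_id)
  stats::setNames(lapply(envs, function(e) {
    scan_result$unit_id[scan_result$environment_id == e &
                          scan_result$adaptive]
  }), envs)
}
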