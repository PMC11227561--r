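#' Dice's coefficient of similarity between two sets
#'
#' `2|X ∩ Y| / (|X| + |Y|)`: 0 for disjoint sets, 1 for identical
#' sets. Undefined (NA, with a warning) when both sets are empty.
#'
#' @param x,y character vectors (treated as sets).
#' @return the coefficient, in `[0, 1]`.
#' @export
dice_coefficient <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) + length(y) == 0) {
    warning("Dice coefficient undefined for two empty sets")
    return(NA_real_)
  }
  2 * length(intersect(x, y)) / (length(x) + length(y))
}

#' Exact random expectation of the Dice coefficient
#'
#' For two sets of sizes `m1` and `m2` drawn independently and
#' uniformly from a universe of `G` items, the expected intersection
#' size is `m1*m2/G`, so the expected Dice coefficient is
#' `2*m1*m2 / (G*(m1+m2))`.
#'
#' @param m1,m2 set sizes.
#' @param G universe size.
#' @return the expected coefficient.
#' @export
dice_random_exact <- function(m1, m2, G) {
  if (m1 + m2 == 0) return(NA_real_)
  2 * m1 * m2 / (G * (m1 + m2))
}

#' Within- and between-environment Dice similarity summary
#'
#' Computes the mean Dice coefficient over all pairs of samples from
#' the same environment and over all pairs from different
#' environments, together with the random expectation if each sample's
#' adaptive set were drawn independently and uniformly from the
#' `universe_size` genes of the genome. The random expectation is the
#' exact per-pair hypergeometric value by default
#' (`2 m1 m2 / (G (m1+m2))`, averaged over the same pairs as the
#' between-environment mean), or a Monte-Carlo estimate for fidelity
#' to the resampling construction.
#'
#' @param sets named list: sample id -> character vector of adaptive
#'   unit ids.
#' @param env_labels named character vector: sample id -> environment.
#' @param universe_size number of units in the genome (G).
#' @param random_method `"exact"` or `"montecarlo"`.
#' @param n_mc Monte-Carlo draws per pair (random_method =
#'   "montecarlo").
#' @param seed seed for the Monte-Carlo mode.
#' @return a list of class `dice_summary`: `within_env_mean`,
#'   `between_env_mean`, `random_expectation`, `fold_vs_random`
#'   (between-environment mean over random), `fold_within_vs_between`,
#'   and pair counts.
#' @export
dice_summary <- function(sets, env_labels, universe_size,
                         random_method = c("exact", "montecarlo"),
                         n_mc = 1000L, seed = NULL) {
  random_method <- match.arg(random_method)
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  if (!all(names(sets) %in% names(env_labels))) {
    stop("env_labels must cover every sample in `sets`")
  }
  if (any(lengths(sets) > universe_size)) {
    stop("a set is larger than the universe")
  }
  if (!is.null(seed)) set.seed(seed)

  ids <- names(sets)
  pairs <- utils::combn(ids, 2)
  within <- c(); between <- c(); rand <- c()
  n_empty <- 0L
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    m1 <- length(unique(sets[[a]])); m2 <- length(unique(sets[[b]]))
    if (m1 + m2 == 0) { n_empty <- n_empty + 1L; next }
    d <- dice_coefficient(sets[[a]], sets[[b]])
    if (env_labels[[a]] == env_labels[[b]]) {
      within <- c(within, d)
    } else {
      between <- c(between, d)
      rand <- c(rand, if (random_method == "exact") {
        dice_random_exact(m1, m2, universe_size)
      } else {
        mean(vapply(seq_len(n_mc), function(k) {
          dice_coefficient(sample.int(universe_size, m1),
                           sample.int(universe_size, m2))
        }, numeric(1)))
      })
    }
  }
  if (n_empty > 0) {
    warning(n_empty, " pair(s) with two empty sets excluded")
  }
  within_mean <- if (length(within)) mean(within) else NA_real_
  between_mean <- if (length(between)) mean(between) else NA_real_
  rand_mean <- if (length(rand)) mean(rand) else NA_real_
  structure(list(
    within_env_mean = within_mean, between_env_mean = between_mean,
    random_expectation = rand_mean,
    fold_vs_random = between_mean / rand_mean,
    fold_within_vs_between = within_mean / between_mean,
    n_within_pairs = length(within), n_between_pairs = length(between),
    random_method = random_method), class = "dice_summary")
}

#' @export
print.dice_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Dice similarity: within-env %.4g (%d pairs), between-env %.4g ",
    "(%d pairs)\n  random expectation %.3g (%s); between/random = %.3g; ",
    "within/between = %.3g\n"),
    x$within_env_mean, x$n_within_pairs, x$between_env_mean,
    x$n_between_pairs, x$random_expectation, x$random_method,
    x$fold_vs_random, x$fold_within_vs_between))
  invisible(x)
}

#' Mean Dice similarity under replicate downsampling
#'
#' Repeatedly subsamples `k` replicates per environment, re-identifies
#' the adaptive sets on the subsample via the caller-supplied
#' `reidentify` function, and averages the resulting
#' [dice_summary()] quantities over `n_down` draws. This mirrors the
#' protocol of comparing many-replicate experiments with
#' fewer-replicate ones at equal detection power.
#'
#' @param samples_by_env named list: environment -> sample ids.
#' @param k replicates retained per environment.
#' @param n_down number of independent downsamplings.
#' @param reidentify function taking the downsampled
#'   `samples_by_env` list and returning the named `sets` list for
#'   [dice_summary()].
#' @param env_labels,universe_size,... passed on to [dice_summary()].
#' @param seed random seed.
#' @return a `dice_summary` whose numeric fields are means over the
#'   downsamplings.
#' @export
dice_downsampled <- function(samples_by_env, k, n_down, reidentify,
                             env_labels, universe_size, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fields <- c("within_env_mean", "between_env_mean", "random_expectation",
              "fold_vs_random", "fold_within_vs_between")
  acc <- matrix(NA_real_, n_down, length(fields),
                dimnames = list(NULL, fields))
  for (d in seq_len(n_down)) {
    sub <- lapply(samples_by_env, function(s) {
      if (length(s) <= k) s else sample(s, k)
    })
    sets <- reidentify(sub)
    s <- dice_summary(sets, env_labels, universe_size, ...)
    acc[d, ] <- unlist(s[fields])
  }
  out <- as.list(colMeans(acc, na.rm = TRUE))
  out$n_downsamplings <- n_down
  structure(out, class = "dice_summary_downsampled")
}

#' Per-gene overall contributions to adaptation
#'
#' In each environment with `n` adaptive genes, each of them
#' contributes `1/n` to that environment's adaptation and every other
#' gene contributes 0; a gene's overall contribution is its average
#' contribution across all environments. Summed over genes, the
#' contributions equal the fraction of environments with at least one
#' adaptive gene (conservation). The cumulative curve ranks genes by
#' the number of environments in which they were identified
#' (descending; ties broken by overall contribution, then unit id) and
#' accumulates contributions along that ranking.
#'
#' @param env_sets named list: environment id -> character vector of
#'   adaptive unit ids (empty vectors allowed).
#' @return a list of class `contribution_result`: `contributions`
#'   (tibble `unit_id`, `n_envs_identified`, `contribution`, ranked),
#'   `cumulative` (tibble `rank`, `unit_id`, `cumulative_fraction`),
#'   and `total` (= fraction of environments with any adaptive gene).
#' @export
gene_contributions <- function(env_sets) {
  n_env <- length(env_sets)
  if (n_env == 0) stop("no environments")
  contrib <- list(); freq <- list()
  for (e in names(env_sets)) {
    genes <- unique(env_sets[[e]])
    n <- length(genes)
    if (n == 0) next
    for (g in genes) {
      contrib[[g]] <- (contrib[[g]] %||% 0) + 1 / n
      freq[[g]] <- (freq[[g]] %||% 0L) + 1L
    }
  }
  if (length(contrib) == 0) {
    tab <- tibble::tibble(unit_id = character(),
                          n_envs_identified = integer(),
                          contribution = numeric())
  } else {
    tab <- tibble::tibble(
      unit_id = names(contrib),
      n_envs_identified = unname(unlist(freq[names(contrib)])),
      contribution = unname(unlist(contrib)) / n_env)
    tab <- tab[order(-tab$n_envs_identified, -tab$contribution,
                     tab$unit_id), ]
  }
  cum <- tibble::tibble(rank = seq_len(nrow(tab)), unit_id = tab$unit_id,
                        cumulative_fraction = cumsum(tab$contribution))
  structure(list(contributions = tab, cumulative = cum,
                 total = sum(tab$contribution), n_environments = n_env),
            class = "contribution_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contribution_result <- function(x, ...) {
  cat("gene contributions over", x$n_environments, "environments; total",
      format(x$total, digits = 4),
      "(= fraction of environments with any adaptive gene)\n")
  print(utils::head(x$contributions, 10))
  invisible(x)
}

#' Cross-contamination diagnostic from plate layout
#'
#' For every pair of samples the shared-substitution fraction is the
#' number of identical substitutions (same chromosome, position, ref
#' and alt) divided by the mean substitution count of the two samples.
#' Pairs on the same plate but in different rows (`X`) are compared
#' with pairs on different plates (`Y`) by a two-tailed Wilcoxon
#' rank-sum test: cross-contamination within a plate would inflate `X`
#' relative to `Y`. Same-row pairs (same environment) are excluded, as
#' their sharing may reflect parallel adaptation rather than
#' contamination.
#'
#' @param sub_table substitution table with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt` (e.g. from [load_substitutions()]).
#' @param manifest sample manifest (data frame or TSV path; see
#'   [load_substitutions()]).
#' @return a list of class `contamination_result`: `X`, `Y` (shared
#'   fractions), `mean_X`, `mean_Y`, `p_value` and `n_excluded`.
#' @export
contamination_test <- function(sub_table, manifest) {
  manifest <- read_manifest(manifest)
  key <- paste(sub_table$chrom, sub_table$pos, sub_table$ref,
               sub_table$alt, sep = ":")
  sets <- split(key, sub_table$sample_id)
  sets <- lapply(sets, unique)
  ids <- manifest$sample_id[manifest$sample_id %in% names(sets)]
  zero <- setdiff(manifest$sample_id, names(sets))
  if (length(zero)) {
    warning(length(zero), " sample(s) with zero substitutions excluded")
  }
  if (length(ids) < 2) stop("need at least two samples with substitutions")
  m <- manifest[match(ids, manifest$sample_id), ]
  pairs <- utils::combn(seq_along(ids), 2)
  X <- c(); Y <- c(); n_same_row <- 0L
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    same_plate <- m$plate[a] == m$plate[b]
    same_row <- same_plate && m$row[a] == m$row[b]
    if (same_row) { n_same_row <- n_same_row + 1L; next }
    sa <- sets[[ids[a]]]; sb <- sets[[ids[b]]]
    frac <- length(intersect(sa, sb)) / mean(c(length(sa), length(sb)))
    if (same_plate) X <- c(X, frac) else Y <- c(Y, frac)
  }
  if (length(X) == 0 || length(Y) == 0) {
    stop("need both within-plate (different-row) and between-plate pairs")
  }
  wt <- suppressWarnings(stats::wilcox.test(X, Y, exact = FALSE))
  structure(list(X = X, Y = Y, mean_X = mean(X), mean_Y = mean(Y),
                 p_value = wt$p.value, n_excluded = n_same_row),
            class = "contamination_result")
}

#' @export
print.contamination_result <- function(x, ...) {
  cat(sprintf(paste0(
    "shared-substitution fractions: within-plate/different-row mean %.4g ",
    "(n=%d), between-plate mean %.4g (n=%d); rank-sum p = %.3g\n"),
    x$mean_X, length(x$X), x$mean_Y, length(x$Y), x$p_value))
  invisible(x)
}
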