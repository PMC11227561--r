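#' Mutation spectra and neutral substitution-class expectations
#'
#' A mutation spectrum gives the relative rates of the six
#' strand-symmetric single-nucleotide change classes. Combined with a
#' set of coding sequences it yields the neutral expectation for the
#' relative numbers of synonymous, nonsynonymous and nonsense SNVs;
#' combined with genome site counts it yields the neutral
#' coding:noncoding substitution-count ratio.
#'
#' @name neutral-expectation
NULL

spectrum_classes <- c("AT_GC", "AT_CG", "AT_TA", "CG_AT", "CG_GC", "CG_TA")

#' Validate and normalize a six-class mutation spectrum
#'
#' Classes, in order: A:T→G:C, A:T→C:G, A:T→T:A, C:G→A:T, C:G→G:C,
#' C:G→T:A. Rates are normalized to sum to 1; the original scale is
#' kept in the `raw` attribute.
#'
#' @param rates six nonnegative numbers (optionally named with the
#'   class codes `AT_GC`, ..., `CG_TA`), not all zero.
#' @return a named numeric vector of class `mutation_spectrum` summing
#'   to 1.
#' @export
validate_spectrum <- function(rates) {
  if (length(rates) != 6) stop("a mutation spectrum has six classes")
  if (!is.null(names(rates)) && all(names(rates) %in% spectrum_classes)) {
    rates <- rates[spectrum_classes]
  }
  rates <- as.numeric(rates)
  if (anyNA(rates)) stop("missing rate in mutation spectrum")
  if (any(rates < 0)) stop("mutation rates must be nonnegative")
  if (sum(rates) == 0) stop("mutation spectrum cannot be all zero")
  out <- rates / sum(rates)
  names(out) <- spectrum_classes
  structure(out, raw = rates, class = c("mutation_spectrum", "numeric"))
}

#' Built-in mutation-spectrum presets
#'
#' `spectrum_merged_environments()` is the spectrum estimated from
#' mutation-accumulation lines pooled over seven environments;
#' `spectrum_ypd()` is the rich-medium (YPD) estimate. Order:
#' A:T→G:C, A:T→C:G, A:T→T:A, C:G→A:T, C:G→G:C, C:G→T:A.
#'
#' @return a `mutation_spectrum`.
#' @export
spectrum_merged_environments <- function() {
  validate_spectrum(c(0.195, 0.110, 0.077, 0.286, 0.067, 0.265))
}

#' @rdname spectrum_merged_environments
#' @export
spectrum_ypd <- function() {
  validate_spectrum(c(0.093, 0.221, 0.081, 0.314, 0.093, 0.198))
}

#' Uniform spectrum (all six classes equally likely)
#' @return a `mutation_spectrum`.
#' @export
spectrum_uniform <- function() validate_spectrum(rep(1, 6))

# strand-symmetric class of a ref -> alt base change
mutation_class <- function(ref, alt) {
  key <- paste0(toupper(ref), toupper(alt))
  map <- c(AG = "AT_GC", TC = "AT_GC", AC = "AT_CG", TG = "AT_CG",
           AT = "AT_TA", TA = "AT_TA", CA = "CG_AT", GT = "CG_AT",
           CG = "CG_GC", GC = "CG_GC", CT = "CG_TA", GA = "CG_TA")
  out <- unname(map[key])
  if (anyNA(out)) stop("not a single-base change: ", key[is.na(out)][1])
  out
}

#' Neutral expectation of SNV category proportions
#'
#' Enumerates all three possible single-nucleotide changes at every
#' coding site, weights each change by its spectrum class rate,
#' classifies it (synonymous / nonsynonymous / nonsense), and returns
#' the normalized weighted proportions. Terminal stop codons are
#' excluded from the enumeration (changes there are not cleanly
#' synonymous, nonsynonymous or nonsense); internal stop codons are
#' rejected.
#'
#' @param cds_seqs coding sequences (character vector or
#'   `DNAStringSet`), each of length divisible by 3, read 5'→3' on the
#'   coding strand.
#' @param spectrum a `mutation_spectrum` (see [validate_spectrum()]);
#'   default uniform.
#' @return a list of class `neutral_expectation` with `proportions`
#'   (named: synonymous, nonsynonymous, nonsense), `weights` (the
#'   unnormalized weighted counts) and `spectrum`.
#' @export
expected_snv_category_proportions <- function(cds_seqs,
                                              spectrum = spectrum_uniform()) {
  if (!inherits(spectrum, "mutation_spectrum")) {
    spectrum <- validate_spectrum(spectrum)
  }
  seqs <- toupper(as.character(cds_seqs))
  if (any(nchar(seqs) %% 3 != 0)) {
    stop("coding sequence length not divisible by 3")
  }
  # codon composition of the CDS set, terminal stop codons dropped
  codons <- unlist(lapply(seqs, function(s) {
    cc <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (length(cc) && translate_codon(cc[length(cc)]) == "*") {
      cc <- cc[-length(cc)]
    }
    cc
  }))
  if (length(codons) == 0) stop("no codons left to enumerate")
  if (any(vapply(codons, translate_codon, character(1)) == "*")) {
    stop("internal stop codon in coding sequence")
  }
  tab <- table(codons)

  w <- c(synonymous = 0, nonsynonymous = 0, nonsense = 0)
  bases <- c("A", "C", "G", "T")
  for (codon in names(tab)) {
    aa_old <- translate_codon(codon)
    for (p in 1:3) {
      ref <- substr(codon, p, p)
      for (alt in setdiff(bases, ref)) {
        new_codon <- codon
        substr(new_codon, p, p) <- alt
        aa_new <- translate_codon(new_codon)
        cat_ <- if (identical(aa_new, aa_old)) "synonymous"
        else if (identical(aa_new, "*")) "nonsense"
        else "nonsynonymous"
        w[cat_] <- w[cat_] +
          as.numeric(tab[[codon]]) * spectrum[[mutation_class(ref, alt)]]
      }
    }
  }
  structure(list(proportions = w / sum(w), weights = w,
                 spectrum = spectrum),
            class = "neutral_expectation")
}

#' @export
print.neutral_expectation <- function(x, ...) {
  cat("neutral SNV category proportions:\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Chi-squared test of two observed counts against an expected ratio
#'
#' Goodness-of-fit chi-squared (1 degree of freedom) of observed counts
#' `(a, b)` against expected proportions `(r/(1+r), 1/(1+r))` where `r`
#' is the expected a:b ratio. The p-value is computed in log space, so
#' astronomically small values are reported accurately.
#'
#' @param observed_count_a,observed_count_b nonnegative counts, not
#'   both zero.
#' @param expected_a_to_b_ratio expected ratio a/b under the null
#'   (> 0).
#' @return a list of class `chi2_result` with `statistic`, `df`,
#'   `p_value` and `log10_p`.
#' @export
neutral_ratio_test <- function(observed_count_a, observed_count_b,
                               expected_a_to_b_ratio) {
  a <- observed_count_a; b <- observed_count_b
  r <- expected_a_to_b_ratio
  stopifnot(a >= 0, b >= 0, r > 0)
  if (a + b == 0) stop("both counts are zero")
  expected <- (a + b) * c(r / (1 + r), 1 / (1 + r))
  stat <- sum((c(a, b) - expected)^2 / expected)
  log_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  structure(list(statistic = stat, df = 1L,
                 p_value = exp(log_p), log10_p = log_p / log(10)),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.3g (log10 p = %.2f)\n",
              x$statistic, x$df, x$p_value, x$log10_p))
  invisible(x)
}

#' Neutral expectations for a genome model
#'
#' Convenience wrapper: SNV category proportions from all coding
#' sequences of the model plus the neutral coding:noncoding
#' substitution ratio (equal per-site rates assumed, so the ratio
#' equals the coding:noncoding site-count ratio). The expected
#' frame-shifting:frame-conserving indel ratio is not derivable from a
#' six-class SNV spectrum and is passed through as a configurable
#' number (default 3, a placeholder spanning the 1- and 2-bp-dominated
#' indel length spectra; supply your own estimate from
#' mutation-accumulation data for real analyses).
#'
#' @param model a `genome_model`.
#' @param spectrum a `mutation_spectrum`.
#' @param frameshift_to_inframe_ratio expected frame-shifting to
#'   frame-conserving indel count ratio under neutrality.
#' @return a list of class `neutral_expectation` with `proportions`,
#'   `coding_noncoding_ratio` and `frameshift_to_inframe_ratio`.
#' @export
neutral_expectation <- function(model,
                                spectrum = spectrum_merged_environments(),
                                frameshift_to_inframe_ratio = 3) {
  sc <- site_counts(model)
  seqs <- vapply(model$genes$gene_id, function(g) spliced_cds(model, g),
                 character(1))
  out <- expected_snv_category_proportions(seqs, spectrum)
  out$coding_noncoding_ratio <- sc$ratio
  out$frameshift_to_inframe_ratio <- frameshift_to_inframe_ratio
  out
}
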