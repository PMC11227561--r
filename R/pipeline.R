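#' Run the variant-to-scan pipeline from files
#'
#' Convenience wrapper: load the genome and annotation, load and
#' classify the substitutions, and scan the requested compartment for
#' putatively adaptive units in every environment.
#'
#' @param fasta,gff3 genome files (see [load_genome_annotation()]).
#' @param vcfs VCF paths (see [load_substitutions()]).
#' @param manifest manifest TSV path or data frame.
#' @param compartment `"coding"` or `"noncoding"`.
#' @param config a [scan_config()].
#' @param validation passed to [load_genome_annotation()].
#' @return a list: `model`, `classified`, `scan` and `adaptive_sets`
#'   (per-environment adaptive unit ids).
#' @export
run_scan_pipeline <- function(fasta, gff3, vcfs, manifest,
                              compartment = "coding",
                              config = scan_config(),
                              validation = "strict") {
  model <- load_genome_annotation(fasta, gff3, validation = validation)
  subs <- load_substitutions(vcfs, manifest)
  classified <- classify_substitutions(subs, model)
  scan <- adaptive_scan(classified, model, compartment, config)
  list(model = model, classified = classified, scan = scan,
       adaptive_sets = adaptive_sets(scan))
}

#' Per-sample adaptive-gene sets
#'
#' A sample's ("line's") adaptive-gene set is the set of units that
#' were called adaptive in the sample's environment and are hit by at
#' least one of the sample's own substitutions — the unit of
#' comparison for Dice similarity between lines.
#'
#' @param classified output of [classify_substitutions()].
#' @param scan_result output of [adaptive_scan()].
#' @return named list: sample id -> character vector of unit ids.
#' @export
sample_adaptive_sets <- function(classified, scan_result) {
  env_sets <- adaptive_sets(scan_result)
  hits <- substitution_hits(classified)
  samples <- sort(unique(classified$sample_id))
  stats::setNames(lapply(samples, function(s) {
    d <- hits[hits$sample_id == s, ]
    e <- d$environment_id[1]
    if (is.null(e) || is.na(e) || !e %in% names(env_sets)) {
      return(character(0))
    }
    intersect(unique(d$unit_id), env_sets[[e]])
  }), samples)
}
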