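#' Load substitution calls and join the sample manifest
#'
#' Reads one or more VCF 4.x files (one per sample, or multi-sample)
#' into a flat substitution table joined to the sample manifest.
#' Multi-allelic records are split into one record per alternate
#' allele. Only records whose FILTER value is in `filters` are kept.
#' In multi-sample VCFs a record is attributed to every sample whose
#' genotype carries a non-reference allele; single-sample VCFs without
#' a genotype column are attributed to the sample named in
#' `names(vcf_sources)`.
#'
#' @param vcf_sources character vector of VCF paths, optionally named
#'   by sample id (required for VCFs without genotype columns).
#' @param manifest_source path to a tab-separated manifest with columns
#'   `sample_id environment_id replicate plate row column`, or an
#'   equivalent data frame.
#' @param filters FILTER values to keep (default `PASS` and `.`).
#' @return a tibble with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `kind` (`SNV`/`indel`) plus the manifest columns.
#' @export
load_substitutions <- function(vcf_sources, manifest_source,
                               filters = c("PASS", ".")) {
  manifest <- read_manifest(manifest_source)
  recs <- lapply(seq_along(vcf_sources), function(i) {
    path <- vcf_sources[[i]]
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) return(NULL)
    keep <- is.na(fix$FILTER) | fix$FILTER %in% filters
    gt <- v@gt
    samples <- if (!is.null(gt) && ncol(gt) > 1) colnames(gt)[-1] else {
      nm <- names(vcf_sources)[i]
      if (is.null(nm) || is.na(nm) || nm == "")
        stop("VCF ", path, " has no genotype column and no sample name ",
             "was supplied via names(vcf_sources)")
      nm
    }
    out <- list()
    for (s in samples) {
      carried <- if (!is.null(gt) && ncol(gt) > 1) {
        gtcol <- sub(":.*$", "", gt[, s])
        !is.na(gtcol) & grepl("[1-9]", gtcol)
      } else rep(TRUE, nrow(fix))
      idx <- which(keep & carried)
      if (length(idx) == 0) next
      alt_split <- strsplit(fix$ALT[idx], ",", fixed = TRUE)
      n_alt <- lengths(alt_split)
      out[[s]] <- tibble::tibble(
        sample_id = s,
        chrom = rep(fix$CHROM[idx], n_alt),
        pos = rep(as.integer(fix$POS[idx]), n_alt) - 1L,
        ref = rep(fix$REF[idx], n_alt),
        alt = unlist(alt_split))
    }
    dplyr::bind_rows(out)
  })
  tab <- dplyr::bind_rows(recs)
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character())
  }
  stopifnot(all(nchar(tab$ref) > 0), all(nchar(tab$alt) > 0))
  tab$kind <- ifelse(nchar(tab$ref) == 1 & nchar(tab$alt) == 1,
                     "SNV", "indel")
  missing <- setdiff(unique(tab$sample_id), manifest$sample_id)
  if (length(missing)) {
    stop("sample(s) in VCF absent from manifest: ",
         paste(missing, collapse = ", "))
  }
  dplyr::left_join(tab, manifest, by = "sample_id")
}

read_manifest <- function(x) {
  m <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    tibble::as_tibble(utils::read.delim(x, stringsAsFactors = FALSE))
  }
  need <- c("sample_id", "environment_id", "replicate", "plate", "row",
            "column")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = " "))
  }
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  m
}

effect_levels <- c("synonymous", "nonsynonymous", "nonsense",
                   "frameshift_indel", "inframe_indel", "noncoding")

# Per-gene index for coding-coordinate arithmetic: sorted intervals,
# spliced sequence, and cumulative offsets of each interval.
build_gene_index <- function(model) {
  idx <- list()
  for (g in model$genes$gene_id) {
    iv <- model$cds[model$cds$gene_id == g, ]
    iv <- iv[order(iv$start), ]
    w <- iv$end - iv$start
    idx[[g]] <- list(chrom = iv$chrom[1], strand = iv$strand[1],
                     start = iv$start, end = iv$end,
                     offset = cumsum(c(0L, w))[seq_along(w)],
                     length = sum(w), seq = spliced_cds(model, g))
  }
  idx
}

# 0-based genomic position -> 0-based position in the spliced CDS
cds_coord <- function(gi, pos) {
  hit <- which(pos >= gi$start & pos < gi$end)
  if (length(hit) == 0) return(NA_integer_)
  plus <- gi$offset[hit] + (pos - gi$start[hit])
  if (gi$strand == "+") plus else gi$length - 1L - plus
}

complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify substitutions against a genome model
#'
#' Each substitution is assigned one effect category: coding SNVs are
#' translated on the coding strand (reverse-complemented for minus
#' strand genes) and called `synonymous`, `nonsense` (premature stop
#' gained) or `nonsynonymous` (stop-loss changes are binned as
#' nonsynonymous); coding indels are `inframe_indel` or
#' `frameshift_indel` by whether the net length change inside the CDS
#' is a multiple of 3; everything outside CDS is `noncoding` and
#' assigned to its enclosing merged noncoding unit. A substitution in
#' the CDS overlap of several genes yields one record (category and
#' `unit_id` from the first gene by coordinate, `multi_gene` flagged)
#' but all overlapped genes are kept in the `all_unit_ids` list-column
#' for hit counting.
#'
#' @param table substitution table from [load_substitutions()] (the
#'   manifest columns are carried through but not required).
#' @param model a `genome_model`.
#' @return the input tibble with added columns `category`,
#'   `compartment` (`coding`/`noncoding`), `unit_id`, `multi_gene`,
#'   `boundary_indel` and list-column `all_unit_ids`.
#' @export
classify_substitutions <- function(table, model) {
  stopifnot(inherits(model, "genome_model"))
  if (nrow(table) == 0) {
    return(dplyr::mutate(table, category = character(),
                         compartment = character(), unit_id = character(),
                         multi_gene = logical(), boundary_indel = logical(),
                         all_unit_ids = list()))
  }
  gidx <- build_gene_index(model)
  genes_by_coord <- model$genes[order(model$genes$chrom,
                                      model$genes$span_start), ]

  cds_gr <- GenomicRanges::GRanges(
    model$cds$chrom,
    IRanges::IRanges(model$cds$start + 1L, model$cds$end),
    gene_id = model$cds$gene_id)

  ncu <- model$noncoding_units
  nc_iv <- dplyr::bind_rows(lapply(seq_len(nrow(ncu)), function(i)
    dplyr::mutate(ncu$intervals[[i]], unit_id = ncu$unit_id[i])))
  nc_gr <- if (!is.null(nc_iv) && nrow(nc_iv)) {
    GenomicRanges::GRanges(nc_iv$chrom,
                           IRanges::IRanges(nc_iv$start + 1L, nc_iv$end),
                           unit_id = nc_iv$unit_id)
  } else GenomicRanges::GRanges()

  n <- nrow(table)
  category <- character(n); unit_id <- rep(NA_character_, n)
  compartment <- character(n); multi_gene <- logical(n)
  boundary <- logical(n); all_units <- vector("list", n)

  # affected genomic footprint: SNV = the base; indel = anchor + deleted
  q_start <- table$pos + 1L
  q_end <- table$pos + nchar(table$ref)
  q_gr <- GenomicRanges::GRanges(table$chrom,
                                 IRanges::IRanges(q_start, q_end))
  hits <- GenomicRanges::findOverlaps(q_gr, cds_gr)
  hit_genes <- split(cds_gr$gene_id[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))

  for (i in seq_len(n)) {
    ch <- table$chrom[i]
    if (!ch %in% names(model$seqs)) stop("unknown chromosome: ", ch)
    chrseq <- model$seqs[[ch]]
    genome_ref <- as.character(Biostrings::subseq(
      chrseq, table$pos[i] + 1L,
      min(table$pos[i] + nchar(table$ref[i]), length(chrseq))))
    if (!identical(toupper(genome_ref), toupper(table$ref[i]))) {
      stop(sprintf(
        "ref allele mismatch at %s:%d (VCF %s, genome %s): coordinate or reference mismatch",
        ch, table$pos[i] + 1L, table$ref[i], genome_ref))
    }

    gset <- unique(hit_genes[[as.character(i)]])
    if (!is.null(gset) && length(gset) > 0) {
      compartment[i] <- "coding"
      gset <- gset[order(match(gset, genes_by_coord$gene_id))]
      all_units[[i]] <- gset
      multi_gene[i] <- length(gset) > 1
      g <- gset[1]
      unit_id[i] <- g
      gi <- gidx[[g]]
      if (table$kind[i] == "SNV") {
        category[i] <- classify_coding_snv(gi, table$pos[i], table$ref[i],
                                           table$alt[i])
      } else {
        del <- indel_net_in_cds(gi, table$pos[i], table$ref[i], table$alt[i])
        boundary[i] <- del$boundary
        category[i] <- if (del$net %% 3 == 0) "inframe_indel" else
          "frameshift_indel"
      }
    } else {
      compartment[i] <- "noncoding"
      category[i] <- "noncoding"
      if (length(nc_gr) > 0) {
        p_gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(table$pos[i] + 1L,
                                                            table$pos[i] + 1L))
        ov <- GenomicRanges::findOverlaps(p_gr, nc_gr)
        if (length(ov) > 0) {
          unit_id[i] <- nc_gr$unit_id[S4Vectors::subjectHits(ov)[1]]
        }
      }
      all_units[[i]] <- if (is.na(unit_id[i])) character(0) else unit_id[i]
    }
  }
  dplyr::mutate(table,
                category = factor(category, levels = effect_levels),
                compartment = compartment, unit_id = unit_id,
                multi_gene = multi_gene, boundary_indel = boundary,
                all_unit_ids = all_units)
}

classify_coding_snv <- function(gi, pos, ref, alt) {
  cpos <- cds_coord(gi, pos)
  codon_idx <- cpos %/% 3L
  in_codon <- cpos %% 3L
  codon <- substr(gi$seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  ref_c <- if (gi$strand == "+") ref else complement_base(ref)
  alt_c <- if (gi$strand == "+") alt else complement_base(alt)
  stopifnot(toupper(substr(codon, in_codon + 1L, in_codon + 1L)) ==
              toupper(ref_c))
  new_codon <- codon
  substr(new_codon, in_codon + 1L, in_codon + 1L) <- toupper(alt_c)
  aa_old <- translate_codon(codon)
  aa_new <- translate_codon(new_codon)
  if (identical(aa_old, aa_new)) "synonymous"
  else if (identical(aa_new, "*") && !identical(aa_old, "*")) "nonsense"
  else "nonsynonymous"   # includes stop-loss
}

# Net length change an indel causes inside the CDS of one gene. The
# VCF anchor base is shared between REF and ALT; deleted bases are the
# REF tail, inserted bases the ALT tail, attributed to the CDS if the
# base (deletion) or the anchor (insertion) lies in the CDS.
indel_net_in_cds <- function(gi, pos, ref, alt) {
  in_cds <- function(p) any(p >= gi$start & p < gi$end)
  del_pos <- if (nchar(ref) > 1) pos + seq_len(nchar(ref) - 1L) else integer(0)
  del_in <- sum(vapply(del_pos, in_cds, logical(1)))
  ins_in <- if (nchar(alt) > 1 && in_cds(pos)) nchar(alt) - 1L else 0L
  boundary <- (length(del_pos) > 0 && del_in < length(del_pos)) ||
    (nchar(alt) > 1 && !in_cds(pos))
  list(net = ins_in - del_in, boundary = boundary)
}

#' Expand classified substitutions to one row per overlapped unit
#'
#' For hit counting, a substitution lying in the CDS overlap of several
#' genes contributes one hit to each gene; category totals (see
#' [tabulate_effects()]) keep one record per substitution.
#'
#' @param classified output of [classify_substitutions()].
#' @return tibble with columns of `classified` (minus the list-column)
#'   where `unit_id` enumerates every overlapped unit.
#' @export
substitution_hits <- function(classified) {
  n_units <- lengths(classified$all_unit_ids)
  keep <- n_units > 0
  out <- classified[rep(which(keep), n_units[keep]), ]
  out$unit_id <- unlist(classified$all_unit_ids[keep])
  out$all_unit_ids <- NULL
  out
}

#' Tabulate effect categories by sample or environment
#'
#' @param classified output of [classify_substitutions()].
#' @param group_by `"environment"` or `"sample"`.
#' @return a list of class `category_counts`: `counts` (group x
#'   category, zero-completed), `totals` (per-group substitution
#'   totals; for environment grouping also the mean and SD of
#'   per-replicate totals), and `unit_hits` (per-environment pooled
#'   hits per unit, multi-gene overlaps expanded — the input to the
#'   adaptive scan).
#' @export
tabulate_effects <- function(classified,
                             group_by = c("environment", "sample")) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "environment") "environment_id" else "sample_id"
  if (!key %in% names(classified)) {
    stop("classified table lacks column ", key,
         " (was the manifest joined?)")
  }
  counts <- dplyr::count(classified, .data[[key]],
                         .data$category, .drop = FALSE)
  counts <- tidyr::complete(counts, .data[[key]], .data$category,
                            fill = list(n = 0L))
  counts <- counts[!is.na(counts$category), ]

  per_sample <- dplyr::count(classified, .data$environment_id,
                             .data$sample_id, name = "n_subs")
  totals <- if (group_by == "environment") {
    dplyr::summarise(dplyr::group_by(per_sample, .data$environment_id),
                     mean_per_replicate = mean(.data$n_subs),
                     sd_per_replicate = stats::sd(.data$n_subs),
                     n_subs = sum(.data$n_subs),
                     .groups = "drop")
  } else {
    dplyr::count(classified, .data$sample_id, name = "n_subs")
  }

  hits <- substitution_hits(classified)
  unit_hits <- dplyr::count(hits, .data$environment_id, .data$unit_id,
                            .data$compartment, name = "hits")
  structure(list(counts = counts, totals = totals, unit_hits = unit_hits,
                 group_by = group_by),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat("category_counts grouped by", x$group_by, "-",
      nrow(x$totals), "group(s)\n")
  print(x$counts, n = 12)
  invisible(x)
}

#' Write a classified substitution table as TSV
#'
#' Positions are emitted 1-based, matching the VCF convention.
#'
#' @param classified output of [classify_substitutions()].
#' @param path output path.
#' @export
write_classified_tsv <- function(classified, path) {
  out <- tibble::tibble(sample_id = classified$sample_id,
                        chrom = classified$chrom,
                        pos = classified$pos + 1L,
                        ref = classified$ref, alt = classified$alt,
                        category = as.character(classified$category),
                        unit_id = classified$unit_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
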