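#' Genome and annotation data model
#'
#' A `genome_model` bundles chromosome sequences with the coding and
#' noncoding structure of the genome: coding units (genes, possibly with
#' multi-exon CDS), annotated noncoding features (UTRs, introns, ARSs,
#' ncRNAs, LTRs, retrotransposons, telomeres, centromeres), and the
#' merged noncoding units derived from them. All coordinates are stored
#' 0-based half-open internally; GFF3/VCF conversion happens at the I/O
#' boundary.
#'
#' @param fasta_source path to a (multi-record) FASTA file, or a named
#'   character vector / `Biostrings::DNAStringSet` of chromosome
#'   sequences.
#' @param gff3_source path to a GFF3 annotation (1-based inclusive
#'   coordinates). Recognised feature types: `CDS` (grouped by gene via
#'   the `gene_id` attribute or `Parent`), `five_prime_UTR`,
#'   `three_prime_UTR`, `intron`, `ARS`, `ncRNA_gene`/`ncRNA`, `LTR`,
#'   `LTR_retrotransposon`, `telomere`, `centromere`.
#' @param validation `"strict"` enforces that every spliced CDS has
#'   length divisible by 3, begins with ATG, ends with a stop codon and
#'   carries no internal stop; `"lenient"` downgrades frame violations
#'   to a warning and skips the offending gene.
#' @param include_mito keep chromosomes whose name looks mitochondrial
#'   (`chrM`, `MT`, `Mito`, ...)? Defaults to `FALSE`: noncoding-class
#'   accounting is defined on the nuclear genome.
#' @return an object of class `genome_model`: a list with elements
#'   `seqs` (`DNAStringSet`), `genes`, `cds`, `nc_features`
#'   (tibbles), and `noncoding_units` (see [merge_noncoding_units()]).
#' @export
load_genome_annotation <- function(fasta_source, gff3_source,
                                   validation = c("strict", "lenient"),
                                   include_mito = FALSE) {
  validation <- match.arg(validation)
  seqs <- if (methods::is(fasta_source, "DNAStringSet")) {
    fasta_source
  } else if (is.character(fasta_source) && length(fasta_source) == 1 &&
             file.exists(fasta_source)) {
    Biostrings::readDNAStringSet(fasta_source)
  } else if (is.character(fasta_source) && !is.null(names(fasta_source))) {
    Biostrings::DNAStringSet(fasta_source)
  } else {
    stop("`fasta_source` must be a FASTA path, a named character vector, ",
         "or a DNAStringSet")
  }
  # FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  if (!include_mito) {
    mito <- grepl("^(chr)?(m|mt|mito)", names(seqs), ignore.case = TRUE)
    seqs <- seqs[!mito]
  }
  if (length(seqs) == 0) stop("no chromosome sequences left after filtering")

  gff <- rtracklayer::import(gff3_source, format = "gff3")
  chrom <- as.character(GenomicRanges::seqnames(gff))
  keep <- chrom %in% names(seqs)
  if (!include_mito) {
    dropped_mito <- grepl("^(chr)?(m|mt|mito)", chrom, ignore.case = TRUE)
    if (any(!keep & !dropped_mito)) {
      stop("GFF3 refers to chromosome(s) absent from the FASTA: ",
           paste(unique(chrom[!keep & !dropped_mito]), collapse = ", "))
    }
  } else if (any(!keep)) {
    stop("GFF3 refers to chromosome(s) absent from the FASTA: ",
         paste(unique(chrom[!keep]), collapse = ", "))
  }
  gff <- gff[keep]

  feat <- tibble::tibble(
    type   = as.character(gff$type),
    chrom  = as.character(GenomicRanges::seqnames(gff)),
    start  = GenomicRanges::start(gff) - 1L,   # to 0-based half-open
    end    = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    id     = gff_attr(gff, "ID"),
    name   = gff_attr(gff, "Name"),
    gene   = gff_feature_gene(gff)
  )
  too_long <- feat$end > BiocGenerics::width(seqs)[match(feat$chrom, names(seqs))]
  if (any(too_long)) {
    stop("feature(s) extend beyond their chromosome: ",
         paste(utils::head(stats::na.omit(feat$id[too_long]), 3), collapse = ", "))
  }

  cds <- feat[feat$type == "CDS", ]
  if (nrow(cds) > 0 && anyNA(cds$gene)) {
    stop("CDS feature(s) without a resolvable gene (need gene_id or Parent)")
  }
  cds <- dplyr::arrange(
    tibble::tibble(gene_id = cds$gene, chrom = cds$chrom,
                   strand = cds$strand, start = cds$start, end = cds$end),
    .data$gene_id, .data$start)
  ovl <- dplyr::group_by(cds, .data$gene_id)
  ovl <- dplyr::summarise(ovl, bad = any(.data$start[-1] < .data$end[-length(.data$end)]))
  if (any(ovl$bad)) {
    stop("overlapping CDS intervals within gene(s): ",
         paste(ovl$gene_id[ovl$bad], collapse = ", "))
  }

  genes <- dplyr::summarise(
    dplyr::group_by(cds, .data$gene_id),
    chrom = .data$chrom[1], strand = .data$strand[1],
    length = sum(.data$end - .data$start),
    span_start = min(.data$start), span_end = max(.data$end),
    .groups = "drop")

  model <- structure(
    list(seqs = seqs, seq_chr = as.list(as.character(seqs)),
         genes = genes, cds = cds,
         nc_features = classify_nc_features(feat),
         noncoding_units = NULL),
    class = "genome_model")

  model <- validate_coding_units(model, validation)
  model$noncoding_units <- merge_noncoding_units(model)
  model
}

# Resolve the gene an annotation feature belongs to: explicit gene_id
# attribute wins, then the first Parent (with any "gene:" prefix removed).
gff_feature_gene <- function(gff) {
  g <- gff_attr(gff, "gene_id")
  parent <- S4Vectors::mcols(gff)$Parent
  if (!is.null(parent)) {
    p <- vapply(as.list(parent), function(x)
      if (length(x)) sub("^(gene|mRNA|transcript):", "", x[[1]]) else NA_character_,
      character(1))
    g[is.na(g)] <- p[is.na(g)]
  }
  g
}

gff_attr <- function(gff, field) {
  x <- S4Vectors::mcols(gff)[[field]]
  if (is.null(x)) rep(NA_character_, length(gff)) else as.character(x)
}

classify_nc_features <- function(feat) {
  class_map <- c(
    five_prime_UTR = "gene_associated", three_prime_UTR = "gene_associated",
    intron = "gene_associated", ARS = "ARS", ncRNA_gene = "ncRNA",
    ncRNA = "ncRNA", LTR = "LTR", long_terminal_repeat = "LTR",
    LTR_retrotransposon = "retrotransposon", telomere = "telomere",
    centromere = "centromere")
  nc <- feat[feat$type %in% names(class_map), ]
  cls <- unname(class_map[nc$type])
  if (any(cls == "gene_associated" & is.na(nc$gene))) {
    stop("UTR/intron feature(s) without a resolvable gene")
  }
  fid <- dplyr::coalesce(nc$id, nc$name,
                         paste0(cls, "_", seq_len(nrow(nc))))
  tibble::tibble(feature_id = fid, unit_class = cls, gene_id = nc$gene,
                 chrom = nc$chrom, start = nc$start, end = nc$end)
}

validate_coding_units <- function(model, validation) {
  drop <- character(0)
  for (g in model$genes$gene_id) {
    seq <- spliced_cds(model, g)
    n <- nchar(seq)
    if (n %% 3 != 0) {
      msg <- sprintf("gene %s: spliced CDS length %d is not a multiple of 3",
                     g, n)
      if (validation == "strict") stop(msg)
      warning(msg, "; gene skipped")
      drop <- c(drop, g)
      next
    }
    if (validation == "strict") {
      aa <- translate_string(seq)
      if (substr(seq, 1, 3) != "ATG")
        stop(sprintf("gene %s: spliced CDS does not begin with ATG", g))
      if (substr(aa, nchar(aa), nchar(aa)) != "*")
        stop(sprintf("gene %s: spliced CDS does not end with a stop codon", g))
      if (grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
        stop(sprintf("gene %s: internal stop codon in CDS", g))
    }
  }
  if (length(drop)) {
    model$genes <- model$genes[!model$genes$gene_id %in% drop, ]
    model$cds <- model$cds[!model$cds$gene_id %in% drop, ]
  }
  model
}

#' Spliced coding sequence of a gene, on the coding strand
#'
#' @param model a `genome_model`.
#' @param gene_id gene identifier.
#' @return a character scalar (5' to 3' on the coding strand).
#' @export
spliced_cds <- function(model, gene_id) {
  iv <- model$cds[model$cds$gene_id == gene_id, ]
  if (nrow(iv) == 0) stop("unknown gene: ", gene_id)
  chrstr <- if (!is.null(model$seq_chr)) model$seq_chr[[iv$chrom[1]]] else
    as.character(model$seqs[[iv$chrom[1]]])
  parts <- substring(chrstr, iv$start + 1L, iv$end)
  seq <- paste(parts, collapse = "")
  if (iv$strand[1] == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  seq
}

#' Merge noncoding annotations into test units
#'
#' Builds the merged noncoding units used as the unit of analysis in
#' the noncoding compartment: all UTRs and introns of one gene collapse
#' into a single gene-associated unit; all unannotated fragments lying
#' between the same two adjacent genes collapse into one intergenic
#' unit; other annotated classes (ARS, ncRNA, LTR, retrotransposon,
#' telomere, centromere) remain individual units. Every interval is
#' intersected with the noncoding space (genome minus CDS) so that no
#' coding base is ever counted as noncoding.
#'
#' @param model a `genome_model`.
#' @return a tibble with columns `unit_id`, `unit_class`, `gene_id`
#'   (`NA` except for gene-associated units), `length`, and a
#'   list-column `intervals` of per-unit interval tibbles
#'   (`chrom`, `start`, `end`; 0-based half-open).
#' @export
merge_noncoding_units <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  chrlen <- stats::setNames(BiocGenerics::width(model$seqs), names(model$seqs))

  nc_space <- lapply(names(chrlen), function(ch) {
    cds_ch <- model$cds[model$cds$chrom == ch, ]
    cov <- IRanges::reduce(IRanges::IRanges(cds_ch$start + 1L, cds_ch$end))
    IRanges::setdiff(IRanges::IRanges(1L, chrlen[[ch]]), cov)
  })
  names(nc_space) <- names(chrlen)

  clip <- function(ch, start, end) {
    hit <- IRanges::intersect(IRanges::IRanges(start + 1L, end), nc_space[[ch]])
    if (length(hit) == 0) return(NULL)
    tibble::tibble(chrom = ch, start = IRanges::start(hit) - 1L,
                   end = IRanges::end(hit))
  }

  units <- list()
  nc <- model$nc_features

  ga <- nc[nc$unit_class == "gene_associated", ]
  for (g in unique(ga$gene_id)) {
    rows <- ga[ga$gene_id == g, ]
    iv <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i)
      clip(rows$chrom[i], rows$start[i], rows$end[i])))
    if (is.null(iv) || nrow(iv) == 0) next
    iv <- merge_intervals(iv)
    units[[length(units) + 1]] <- tibble::tibble(
      unit_id = paste0("nc:", g), unit_class = "gene_associated",
      gene_id = g, length = sum(iv$end - iv$start), intervals = list(iv))
  }

  other <- nc[nc$unit_class != "gene_associated", ]
  for (i in seq_len(nrow(other))) {
    iv <- clip(other$chrom[i], other$start[i], other$end[i])
    if (is.null(iv)) next
    units[[length(units) + 1]] <- tibble::tibble(
      unit_id = other$feature_id[i], unit_class = other$unit_class[i],
      gene_id = NA_character_, length = sum(iv$end - iv$start),
      intervals = list(iv))
  }

  # annotated noncoding coverage, to leave only unannotated fragments
  annotated <- dplyr::bind_rows(lapply(units, function(u) u$intervals[[1]]))
  for (ch in names(chrlen)) {
    ann_ch <- if (nrow(nc) && !is.null(annotated) && nrow(annotated))
      annotated[annotated$chrom == ch, ] else annotated
    free <- nc_space[[ch]]
    if (!is.null(ann_ch) && nrow(ann_ch)) {
      free <- IRanges::setdiff(free, IRanges::IRanges(ann_ch$start + 1L,
                                                      ann_ch$end))
    }
    if (length(free) == 0) next
    frag <- tibble::tibble(chrom = ch, start = IRanges::start(free) - 1L,
                           end = IRanges::end(free))
    gch <- model$genes[model$genes$chrom == ch, ]
    key <- vapply(seq_len(nrow(frag)), function(i) {
      li <- which(gch$span_end <= frag$start[i])
      left <- if (length(li)) gch$gene_id[li[which.max(gch$span_end[li])]] else "."
      ri <- which(gch$span_start >= frag$end[i])
      right <- if (length(ri)) gch$gene_id[ri[which.min(gch$span_start[ri])]] else "."
      paste0("ig:", ch, ":", left, "|", right)
    }, character(1))
    for (k in unique(key)) {
      iv <- frag[key == k, ]
      units[[length(units) + 1]] <- tibble::tibble(
        unit_id = k, unit_class = "intergenic", gene_id = NA_character_,
        length = sum(iv$end - iv$start), intervals = list(iv))
    }
  }

  if (length(units) == 0) {
    return(tibble::tibble(unit_id = character(), unit_class = character(),
                          gene_id = character(), length = integer(),
                          intervals = list()))
  }
  out <- dplyr::bind_rows(units)
  stopifnot(all(out$length > 0))
  out
}

merge_intervals <- function(iv) {
  out <- lapply(unique(iv$chrom), function(ch) {
    r <- IRanges::reduce(IRanges::IRanges(iv$start[iv$chrom == ch] + 1L,
                                          iv$end[iv$chrom == ch]))
    tibble::tibble(chrom = ch, start = IRanges::start(r) - 1L,
                   end = IRanges::end(r))
  })
  dplyr::bind_rows(out)
}

#' Coding and noncoding site counts
#'
#' Counts coding sites (bases covered by at least one CDS; a base in two
#' genes' CDS is counted once) and noncoding sites (everything else),
#' and their ratio — the neutral expectation for the coding:noncoding
#' substitution-count ratio when per-site mutation rates are equal.
#'
#' @param model a `genome_model`.
#' @return a list of class `site_counts` with `coding_sites`,
#'   `noncoding_sites`, `ratio` (NA when undefined) and `ratio_defined`.
#' @export
site_counts <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  coding <- 0L
  for (ch in unique(model$cds$chrom)) {
    cds_ch <- model$cds[model$cds$chrom == ch, ]
    coding <- coding + sum(BiocGenerics::width(
      IRanges::reduce(IRanges::IRanges(cds_ch$start + 1L, cds_ch$end))))
  }
  total <- sum(BiocGenerics::width(model$seqs))
  noncoding <- total - coding
  structure(list(coding_sites = as.integer(coding),
                 noncoding_sites = as.integer(noncoding),
                 ratio = if (noncoding > 0) coding / noncoding else NA_real_,
                 ratio_defined = noncoding > 0),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("site counts: coding", x$coding_sites, "| noncoding", x$noncoding_sites,
      "| coding:noncoding ratio",
      if (x$ratio_defined) format(x$ratio, digits = 4) else "undefined", "\n")
  invisible(x)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$seqs), "chromosome(s),",
      sum(BiocGenerics::width(x$seqs)), "bp;",
      nrow(x$genes), "coding unit(s);",
      nrow(x$noncoding_units), "merged noncoding unit(s)\n")
  invisible(x)
}

#' Write a genome model back to FASTA + GFF3
#'
#' Coordinates are converted back to GFF3's 1-based inclusive
#' convention. Reloading the written pair reproduces unit coordinates
#' and lengths exactly.
#'
#' @param model a `genome_model`.
#' @param fasta_path,gff3_path output paths.
#' @return the paths, invisibly.
#' @export
write_genome_annotation <- function(model, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(model$seqs, fasta_path)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(model$genes))) {
    g <- model$genes[i, ]
    lines <- c(lines, paste(g$chrom, "adaptoscan", "gene",
                            g$span_start + 1L, g$span_end, ".", g$strand, ".",
                            paste0("ID=", g$gene_id), sep = "\t"))
  }
  for (i in seq_len(nrow(model$cds))) {
    r <- model$cds[i, ]
    lines <- c(lines, paste(r$chrom, "adaptoscan", "CDS",
                            r$start + 1L, r$end, ".", r$strand, "0",
                            paste0("ID=cds_", r$gene_id, "_", i,
                                   ";Parent=", r$gene_id,
                                   ";gene_id=", r$gene_id), sep = "\t"))
  }
  rev_map <- c(gene_associated = NA, ARS = "ARS", ncRNA = "ncRNA_gene",
               LTR = "LTR", retrotransposon = "LTR_retrotransposon",
               telomere = "telomere", centromere = "centromere")
  nf <- model$nc_features
  for (i in seq_len(nrow(nf))) {
    r <- nf[i, ]
    type <- if (r$unit_class == "gene_associated") {
      if (grepl("^5utr", r$feature_id)) "five_prime_UTR"
      else if (grepl("^3utr", r$feature_id)) "three_prime_UTR"
      else if (grepl("intron", r$feature_id)) "intron"
      else "five_prime_UTR"
    } else rev_map[[r$unit_class]]
    attrs <- paste0("ID=", r$feature_id)
    if (!is.na(r$gene_id)) attrs <- paste0(attrs, ";gene_id=", r$gene_id)
    lines <- c(lines, paste(r$chrom, "adaptoscan", type,
                            r$start + 1L, r$end, ".", "+", ".", attrs,
                            sep = "\t"))
  }
  writeLines(lines, gff3_path)
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}
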