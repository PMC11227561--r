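#' Simulation configuration for synthetic evolution experiments
#'
#' Defaults describe a small but structurally realistic experiment:
#' 20 environments x 12 replicate populations, a two-chromosome toy
#' genome of 200 single-exon genes with a coding:noncoding site ratio
#' of 2.68, progenitor stress levels drawn uniformly from the
#' 0.68-1.06 relative-fitness band, a background substitution rate
#' that rises with stress (`u = lambda0 * (1 + kappa * (1 - s))`),
#' two planted adaptive genes per environment hit independently in
#' each replicate with probability `pi_hit`, and logistic growth
#' curves sampled every 10 min for 24 h with multiplicative lognormal
#' noise. Fitness effects of adaptation rise with stress
#' (`b = effect_b0 + effect_slope * (1 - s)`), which builds a negative
#' stress-adaptation correlation into the data.
#'
#' @param n_genes,codons_min,codons_max gene count and per-gene codon
#'   count range (codons include start and stop).
#' @param n_chromosomes chromosomes the genes are distributed over.
#' @param coding_noncoding_ratio target coding:noncoding site ratio.
#' @param utr_fraction fraction of genes receiving annotated UTRs.
#' @param utr5_len,utr3_len annotated UTR lengths (nt).
#' @param n_ars,n_ncrna numbers of ARS / ncRNA noncoding features.
#' @param n_environments,n_replicates experiment size.
#' @param stress_range range the stress levels `s = F_i/F_SC` are
#'   drawn from.
#' @param lambda0 baseline expected substitutions per sample at
#'   `s = 1`.
#' @param kappa stress scaling of the substitution rate.
#' @param indel_fraction fraction of background substitutions that are
#'   small indels.
#' @param n_adaptive_per_env planted adaptive genes per environment.
#' @param pi_hit per-replicate probability that a planted gene is hit.
#' @param type_mix named probabilities for planted-hit categories
#'   (`nonsense`, `frameshift_indel`, `nonsynonymous`).
#' @param effect_b0,effect_slope fitness-benefit law of adaptation.
#' @param mu_sc progenitor growth rate in the base medium (per min).
#' @param carrying_capacity,d0 logistic growth parameters (density
#'   units).
#' @param od_noise_sd lognormal sdlog of multiplicative OD noise.
#' @param duration_min,interval_min growth-curve sampling scheme.
#' @param n_sc_replicates,n_progenitor_replicates,n_evolved_measured
#'   numbers of growth-curve measurements: base-medium progenitor
#'   replicates, per-environment progenitor replicates, and evolved
#'   populations measured per environment.
#' @param rows_per_plate,columns_per_plate plate layout (one
#'   environment per row, one replicate per column).
#' @param contam_fraction,contam_pairs optional cross-contamination:
#'   for `contam_pairs` donor/recipient pairs (same plate, different
#'   rows) copy this fraction of the donor's substitutions into the
#'   recipient.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, codons_min = 60L, codons_max = 250L,
                       n_chromosomes = 2L, coding_noncoding_ratio = 2.68,
                       utr_fraction = 0.5, utr5_len = 50L, utr3_len = 80L,
                       n_ars = 6L, n_ncrna = 4L,
                       n_environments = 20L, n_replicates = 12L,
                       stress_range = c(0.68, 1.06),
                       lambda0 = 1.0, kappa = 6, indel_fraction = 0.15,
                       n_adaptive_per_env = 2L, pi_hit = 0.5,
                       type_mix = c(nonsense = 0.4, frameshift_indel = 0.4,
                                    nonsynonymous = 0.2),
                       effect_b0 = 0.05, effect_slope = 0.5,
                       mu_sc = 0.007, carrying_capacity = 1.0, d0 = 0.005,
                       od_noise_sd = 0.01, duration_min = 1440L,
                       interval_min = 10L, n_sc_replicates = 6L,
                       n_progenitor_replicates = 3L,
                       n_evolved_measured = 5L,
                       rows_per_plate = 8L, columns_per_plate = 12L,
                       contam_fraction = 0, contam_pairs = 0L) {
  stopifnot(n_genes >= 1, codons_min >= 4, codons_max >= codons_min,
            coding_noncoding_ratio > 0, pi_hit >= 0, pi_hit <= 1,
            lambda0 >= 0, all(stress_range > 0), od_noise_sd >= 0,
            contam_fraction >= 0, contam_fraction <= 1,
            n_replicates <= columns_per_plate)
  type_mix <- type_mix / sum(type_mix)
  structure(as.list(environment()), class = "sim_config")
}

sense_codons <- function() {
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"), paste0),
                                c("A", "C", "G", "T"), paste0))
  all_codons[Biostrings::GENETIC_CODE[all_codons] != "*"]
}

#' Simulate a toy genome with coding and noncoding structure
#'
#' Genes are single-exon ATG...stop open reading frames without
#' internal stop codons, placed on random strands with intergenic gaps
#' sized so that the genome hits the configured coding:noncoding site
#' ratio; a fraction of genes receives annotated UTRs and a few gaps
#' receive ARS / ncRNA features. Deterministic under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed random seed.
#' @return a list: `model` (a strict-validated `genome_model`) and
#'   `ledger` (gene coordinates, lengths and feature placements).
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ng <- config$n_genes
  codons <- sample(config$codons_min:config$codons_max, ng, replace = TRUE)
  gene_len <- 3L * codons
  coding_total <- sum(gene_len)
  noncoding_total <- round(coding_total / config$coding_noncoding_ratio)

  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = ng)
  n_gaps <- ng + config$n_chromosomes   # gap before each gene + trailing
  # room for a downstream UTR of one gene and an upstream UTR of the
  # next inside the same gap, without overlap
  min_gap <- config$utr5_len + config$utr3_len + 12L
  if (noncoding_total < n_gaps * min_gap) {
    stop("infeasible packing: noncoding budget too small for ", n_gaps,
         " gaps of at least ", min_gap, " nt")
  }
  w <- stats::rexp(n_gaps)
  extra <- noncoding_total - n_gaps * min_gap
  gap_len <- min_gap + floor(w / sum(w) * extra)
  short <- noncoding_total - sum(gap_len)
  if (short > 0) {   # distribute rounding remainder
    add <- sample.int(n_gaps, short, replace = TRUE)
    gap_len <- gap_len + tabulate(add, n_gaps)
  }

  sense <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")

  seqs <- character(config$n_chromosomes)
  genes <- list(); nc_feat <- list(); gi <- 0L
  gap_ptr <- 0L
  gap_registry <- list()   # free gap intervals for ARS/ncRNA placement
  for (ch in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%02d", ch)
    parts <- character(0); cursor <- 0L
    for (g in which(chrom_of == ch)) {
      gap_ptr <- gap_ptr + 1L
      gap <- paste(sample(bases, gap_len[gap_ptr], replace = TRUE),
                   collapse = "")
      gap_start <- cursor
      parts <- c(parts, gap); cursor <- cursor + gap_len[gap_ptr]
      strand <- sample(c("+", "-"), 1)
      cds <- paste0("ATG",
                    paste(sample(sense, codons[g] - 2L, replace = TRUE),
                          collapse = ""),
                    sample(stops, 1))
      gseq <- if (strand == "+") cds else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      gid <- sprintf("gene%03d", g)
      genes[[gid]] <- tibble::tibble(gene_id = gid, chrom = chrom,
                                     strand = strand, start = cursor,
                                     end = cursor + gene_len[g])
      # annotated UTRs in the flanking gaps (annotation only)
      if (stats::runif(1) < config$utr_fraction) {
        up <- tibble::tibble(
          feature_id = paste0(if (strand == "+") "5utr_" else "3utr_", gid),
          unit_class = "gene_associated", gene_id = gid, chrom = chrom,
          start = cursor - (if (strand == "+") config$utr5_len else
            config$utr3_len), end = cursor)
        down_len <- if (strand == "+") config$utr3_len else config$utr5_len
        down <- tibble::tibble(
          feature_id = paste0(if (strand == "+") "3utr_" else "5utr_", gid),
          unit_class = "gene_associated", gene_id = gid, chrom = chrom,
          start = cursor + gene_len[g], end = cursor + gene_len[g] + down_len)
        nc_feat[[length(nc_feat) + 1L]] <- up
        nc_feat[[length(nc_feat) + 1L]] <- down
      } else {
        gap_registry[[length(gap_registry) + 1L]] <-
          list(chrom = chrom, start = gap_start, end = cursor)
      }
      parts <- c(parts, gseq); cursor <- cursor + gene_len[g]
      gi <- gi + 1L
    }
    gap_ptr <- gap_ptr + 1L
    trailing <- paste(sample(bases, gap_len[gap_ptr], replace = TRUE),
                      collapse = "")
    parts <- c(parts, trailing); cursor <- cursor + gap_len[gap_ptr]
    seqs[ch] <- paste(parts, collapse = "")
    names(seqs)[ch] <- chrom
  }

  # ARS / ncRNA features inside UTR-free gaps
  n_feat <- config$n_ars + config$n_ncrna
  if (n_feat > 0 && length(gap_registry) > 0) {
    pick <- sample(seq_along(gap_registry),
                   min(n_feat, length(gap_registry)))
    classes <- c(rep("ARS", config$n_ars), rep("ncRNA", config$n_ncrna))
    for (i in seq_along(pick)) {
      gp <- gap_registry[[pick[i]]]
      width <- min(60L, gp$end - gp$start - 4L)
      if (width < 10) next
      s0 <- gp$start + 2L
      nc_feat[[length(nc_feat) + 1L]] <- tibble::tibble(
        feature_id = sprintf("%s_%02d", tolower(classes[i]), i),
        unit_class = classes[i], gene_id = NA_character_,
        chrom = gp$chrom, start = s0, end = s0 + width)
    }
  }

  cds <- dplyr::bind_rows(genes)
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  gene_tab <- dplyr::summarise(
    dplyr::group_by(cds, .data$gene_id),
    chrom = .data$chrom[1], strand = .data$strand[1],
    length = sum(.data$end - .data$start),
    span_start = min(.data$start), span_end = max(.data$end),
    .groups = "drop")
  nc_feat <- lapply(nc_feat, function(f) {
    f$start <- as.integer(f$start); f$end <- as.integer(f$end); f
  })
  nc_features <- if (length(nc_feat)) dplyr::bind_rows(nc_feat) else
    tibble::tibble(feature_id = character(), unit_class = character(),
                   gene_id = character(), chrom = character(),
                   start = integer(), end = integer())

  model <- structure(
    list(seqs = Biostrings::DNAStringSet(seqs), seq_chr = as.list(seqs),
         genes = gene_tab, cds = cds, nc_features = nc_features,
         noncoding_units = NULL),
    class = "genome_model")
  model <- validate_coding_units(model, "strict")
  model$noncoding_units <- merge_noncoding_units(model)

  ledger <- list(seed = seed,
                 gene_lengths = stats::setNames(gene_len,
                                                sprintf("gene%03d", 1:ng)),
                 coding_total = coding_total,
                 noncoding_total = sum(BiocGenerics::width(model$seqs)) -
                   coding_total)
  list(model = model, ledger = ledger)
}

# translate a whole coding sequence into a protein string (vectorized
# genetic-code lookup; stops render as "*")
translate_string <- function(seq) {
  n <- nchar(seq)
  codons <- substring(toupper(seq), seq(1, n, 3), seq(3, n, 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# brute-force category of a coding-strand change at spliced position
# cpos (0-based): re-translate the whole mutant CDS and compare
bruteforce_snv_category <- function(spliced, cpos, alt_coding,
                                    p_old = NULL) {
  mutant <- spliced
  substr(mutant, cpos + 1L, cpos + 1L) <- toupper(alt_coding)
  if (is.null(p_old)) p_old <- translate_string(spliced)
  p_new <- translate_string(mutant)
  if (identical(p_old, p_new)) return("synonymous")
  diff_at <- which(strsplit(p_old, "")[[1]] != strsplit(p_new, "")[[1]])[1]
  new_aa <- substr(p_new, diff_at, diff_at)
  old_aa <- substr(p_old, diff_at, diff_at)
  if (new_aa == "*" && old_aa != "*") "nonsense" else "nonsynonymous"
}

# draw a targeted coding mutation of the requested category in a
# single-exon gene; returns genomic pos (0-based), ref, alt, kind
plant_coding_mutation <- function(model, gene_row, type,
                                  max_tries = 200L, cache = NULL) {
  g <- gene_row
  chrseq <- if (!is.null(model$seq_chr)) model$seq_chr[[g$chrom]] else
    as.character(model$seqs[[g$chrom]])
  spliced <- if (!is.null(cache)) cache$spliced[[g$gene_id]] else
    spliced_cds(model, g$gene_id)
  p_old <- if (!is.null(cache)) cache$protein[[g$gene_id]] else
    translate_string(spliced)
  len <- nchar(spliced)
  if (type == "frameshift_indel") {
    # anchor strictly inside the CDS so the +/-1 nt lands in coding
    anchor <- g$span_start + sample(seq_len(g$length - 3L), 1)
    if (stats::runif(1) < 0.5) {
      ref <- substr(chrseq, anchor + 1L, anchor + 2L)
      alt <- substr(ref, 1, 1)
    } else {
      ref <- substr(chrseq, anchor + 1L, anchor + 1L)
      alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1))
    }
    return(list(pos = anchor, ref = ref, alt = alt, kind = "indel",
                category = "frameshift_indel"))
  }
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    cpos <- sample(seq_len(len - 3L), 1) - 1L   # spare the terminal stop
    ref_c <- substr(spliced, cpos + 1L, cpos + 1L)
    alts <- sample(setdiff(bases, ref_c))
    for (alt_c in alts) {
      if (bruteforce_snv_category(spliced, cpos, alt_c, p_old) == type) {
        if (g$strand == "+") {
          pos <- g$span_start + cpos
          ref <- ref_c; alt <- alt_c
        } else {
          pos <- g$span_end - 1L - cpos
          ref <- complement_base(ref_c); alt <- complement_base(alt_c)
        }
        return(list(pos = pos, ref = ref, alt = alt, kind = "SNV",
                    category = type))
      }
    }
  }
  stop("could not generate a ", type, " mutation in ", g$gene_id)
}

#' Simulate per-environment substitution tables with planted adaptive genes
#'
#' Per sample, the background substitution count is Poisson with rate
#' `u_i = lambda0 * (1 + kappa * (1 - s_i))` and positions are uniform
#' over the genome; each environment's planted adaptive genes are
#' additionally hit in each replicate with probability `pi_hit`, the
#' hit's effect category drawn from `type_mix` and realised by direct
#' codon enumeration. Optional cross-contamination copies a fraction
#' of a donor sample's records into a same-plate, different-row
#' recipient. All true categories and placements are recorded in the
#' ledger.
#'
#' @param model a `genome_model` from [simulate_genome()] (single-exon
#'   genes assumed for planted hits).
#' @param config a [sim_config()].
#' @param seed random seed.
#' @param planted optional named list environment -> gene ids to plant
#'   (defaults to `n_adaptive_per_env` genes sampled per environment;
#'   use `planted = list()`-free `n_adaptive_per_env = 0` for a null
#'   experiment).
#' @return a list: `table` (substitution records with true categories
#'   and `planted` flags), `manifest`, `environments` (stress levels,
#'   rates, planted genes), `contamination` (injected pairs), `seed`.
#' @export
simulate_substitutions <- function(model, config = sim_config(),
                                   seed = 1L, planted = NULL) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "sim_config"))
  set.seed(seed)
  E <- config$n_environments; R <- config$n_replicates
  env_ids <- sprintf("env%03d", seq_len(E))
  s <- stats::runif(E, config$stress_range[1], config$stress_range[2])
  u <- pmax(config$lambda0 * (1 + config$kappa * (1 - s)), 0.01)

  if (is.null(planted)) {
    planted <- stats::setNames(lapply(seq_len(E), function(i) {
      if (config$n_adaptive_per_env == 0) character(0) else
        sample(model$genes$gene_id, config$n_adaptive_per_env)
    }), env_ids)
  } else {
    stopifnot(all(names(planted) %in% env_ids) || length(planted) == 0)
    bad <- setdiff(unlist(planted), model$genes$gene_id)
    if (length(bad)) stop("planted gene absent from genome: ", bad[1])
  }

  manifest <- do.call(rbind, lapply(seq_len(E), function(i) {
    data.frame(sample_id = sprintf("%s_r%02d", env_ids[i], seq_len(R)),
               environment_id = env_ids[i], replicate = seq_len(R),
               plate = (i - 1L) %/% config$rows_per_plate + 1L,
               row = (i - 1L) %% config$rows_per_plate + 1L,
               column = seq_len(R), stringsAsFactors = FALSE)
  }))
  manifest <- tibble::as_tibble(manifest)

  chrlen <- BiocGenerics::width(model$seqs)
  chrnames <- names(model$seqs)
  chrseq_chr <- lapply(chrnames, function(ch) as.character(model$seqs[[ch]]))
  names(chrseq_chr) <- chrnames
  bases <- c("A", "C", "G", "T")
  cds_by_chr <- split(model$cds, model$cds$chrom)
  spl <- vapply(model$genes$gene_id, function(g) spliced_cds(model, g),
                character(1))
  cache <- list(spliced = as.list(spl),
                protein = as.list(vapply(spl, translate_string,
                                         character(1))))

  # record accumulator: plain vectors, one tibble at the end
  acc <- new.env(parent = emptyenv())
  acc$sample_id <- character(0); acc$chrom <- character(0)
  acc$pos <- integer(0); acc$ref <- character(0); acc$alt <- character(0)
  acc$kind <- character(0); acc$true_category <- character(0)
  acc$true_unit <- character(0); acc$planted <- logical(0)
  push <- function(sid, ch, pos, ref, alt, kind, cat_, unit, pl) {
    acc$sample_id <- c(acc$sample_id, sid)
    acc$chrom <- c(acc$chrom, ch); acc$pos <- c(acc$pos, pos)
    acc$ref <- c(acc$ref, ref); acc$alt <- c(acc$alt, alt)
    acc$kind <- c(acc$kind, kind)
    acc$true_category <- c(acc$true_category, cat_)
    acc$true_unit <- c(acc$true_unit, unit)
    acc$planted <- c(acc$planted, pl)
  }

  for (i in seq_len(E)) {
    for (r in seq_len(R)) {
      sid <- sprintf("%s_r%02d", env_ids[i], r)
      n <- stats::rpois(1, u[i])
      for (k in seq_len(n)) {
        ch <- sample(chrnames, 1, prob = chrlen)
        is_indel <- stats::runif(1) < config$indel_fraction
        pos <- sample.int(chrlen[[which(chrnames == ch)]] - 5L, 1)
        sq <- chrseq_chr[[ch]]
        if (!is_indel) {
          ref <- substr(sq, pos + 1L, pos + 1L)
          alt <- sample(setdiff(bases, ref), 1)
          kind <- "SNV"
        } else {
          width <- sample(1:3, 1)
          if (stats::runif(1) < 0.5) {
            ref <- substr(sq, pos + 1L, pos + 1L + width)
            alt <- substr(ref, 1, 1)
          } else {
            ref <- substr(sq, pos + 1L, pos + 1L)
            alt <- paste0(ref, paste(sample(bases, width, replace = TRUE),
                                     collapse = ""))
          }
          kind <- "indel"
        }
        cu <- true_category(model, cds_by_chr, ch, pos, ref, alt, kind,
                            cache)
        push(sid, ch, pos, ref, alt, kind, cu$category, cu$unit, FALSE)
      }
      for (g in planted[[env_ids[i]]]) {
        if (stats::runif(1) >= config$pi_hit) next
        type <- sample(names(config$type_mix), 1, prob = config$type_mix)
        grow <- model$genes[model$genes$gene_id == g, ]
        mut <- plant_coding_mutation(model, grow, type, cache = cache)
        push(sid, grow$chrom, mut$pos, mut$ref, mut$alt, mut$kind,
             mut$category, g, TRUE)
      }
    }
  }
  tab <- tibble::tibble(
    sample_id = acc$sample_id, chrom = acc$chrom, pos = acc$pos,
    ref = acc$ref, alt = acc$alt, kind = acc$kind,
    true_category = acc$true_category, true_unit = acc$true_unit,
    planted = acc$planted)

  contam <- NULL
  if (config$contam_fraction > 0 && config$contam_pairs > 0) {
    pairs <- list()
    for (k in seq_len(config$contam_pairs)) {
      donor <- sample(manifest$sample_id, 1)
      drow <- manifest[manifest$sample_id == donor, ]
      cand <- manifest$sample_id[manifest$plate == drow$plate &
                                   manifest$row != drow$row]
      if (length(cand) == 0) next
      recip <- sample(cand, 1)
      dsub <- tab[tab$sample_id == donor, ]
      n_copy <- ceiling(config$contam_fraction * nrow(dsub))
      if (n_copy == 0) next
      copied <- dsub[sample.int(nrow(dsub), n_copy), ]
      copied$sample_id <- recip
      tab <- dplyr::bind_rows(tab, copied)
      pairs[[k]] <- tibble::tibble(donor = donor, recipient = recip,
                                   n_copied = n_copy)
    }
    contam <- dplyr::bind_rows(pairs)
  }
  # drop duplicate records within a sample (re-draws at same site)
  tab <- dplyr::distinct(tab, .data$sample_id, .data$chrom, .data$pos,
                         .data$ref, .data$alt, .keep_all = TRUE)
  tab <- dplyr::left_join(tab, manifest, by = "sample_id")

  env_tab <- tibble::tibble(environment_id = env_ids, stress_s = s,
                            expected_rate = u,
                            planted_genes = unname(planted[env_ids]))
  list(table = tab, manifest = manifest, environments = env_tab,
       contamination = contam, seed = seed)
}

# ledger-side truth category: brute-force translation for coding SNVs,
# net-length rule for indels, noncoding otherwise
true_category <- function(model, cds_by_chr, ch, pos, ref, alt, kind,
                          cache = NULL) {
  cds_ch <- cds_by_chr[[ch]]
  if (is.null(cds_ch)) return(list(category = "noncoding",
                                   unit = NA_character_))
  foot_end <- pos + nchar(ref)  # anchor + deleted bases
  hit <- cds_ch[cds_ch$start < foot_end & cds_ch$end > pos, ]
  if (nrow(hit) == 0) return(list(category = "noncoding",
                                  unit = NA_character_))
  g <- hit$gene_id[1]
  grow <- model$genes[model$genes$gene_id == g, ]
  if (kind == "indel") {
    del_pos <- if (nchar(ref) > 1) pos + seq_len(nchar(ref) - 1L) else
      integer(0)
    del_in <- sum(del_pos >= grow$span_start & del_pos < grow$span_end)
    ins_in <- if (nchar(alt) > 1 && pos >= grow$span_start &&
                  pos < grow$span_end) nchar(alt) - 1L else 0L
    net <- ins_in - del_in
    return(list(category = if (net %% 3 == 0) "inframe_indel" else
      "frameshift_indel", unit = g))
  }
  spliced <- if (!is.null(cache)) cache$spliced[[g]] else
    spliced_cds(model, g)
  p_old <- if (!is.null(cache)) cache$protein[[g]] else NULL
  cpos <- if (grow$strand == "+") pos - grow$span_start else
    grow$span_end - 1L - pos
  alt_c <- if (grow$strand == "+") alt else complement_base(alt)
  list(category = bruteforce_snv_category(spliced, cpos, alt_c, p_old),
       unit = g)
}

#' Write per-sample VCF files for a simulated substitution table
#'
#' One VCF 4.2 file per sample (named `<sample_id>.vcf`), with contig
#' headers, PASS records and a homozygous-alternate genotype column.
#' Samples without substitutions get a header-only file so the sample
#' set is preserved.
#'
#' @param sim output of [simulate_substitutions()].
#' @param model the `genome_model` the table was simulated from.
#' @param dir output directory (created if needed).
#' @return named character vector of VCF paths.
#' @export
write_substitution_vcfs <- function(sim, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(model$seqs),
                      BiocGenerics::width(model$seqs)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  paths <- character(0)
  for (s in sim$manifest$sample_id) {
    d <- sim$table[sim$table$sample_id == s, ]
    d <- d[order(d$chrom, d$pos), ]
    path <- file.path(dir, paste0(s, ".vcf"))
    lines <- c(header,
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\t",
                      "FORMAT\t", s))
    if (nrow(d) > 0) {
      lines <- c(lines, paste(d$chrom, d$pos + 1L, ".", d$ref, d$alt, ".",
                              "PASS", ".", "GT", "1/1", sep = "\t"))
    }
    writeLines(lines, path)
    paths[s] <- path
  }
  paths
}

#' Simulate growth curves for an experiment
#'
#' Derives true growth rates from the simulated stress levels and the
#' planted fitness-benefit law, then emits logistic OD trajectories:
#' the progenitor in the base medium (defining the reference rate),
#' the progenitor in every environment (`n_progenitor_replicates`
#' each) and `n_evolved_measured` evolved populations per environment,
#' whose extent of adaptation is `1 + b` with
#' `b = effect_b0 + effect_slope * (1 - s)` when the environment has
#' planted genes (1 otherwise). Density follows
#' `d(t) = K d0 e^{rt} / (K + d0 (e^{rt} - 1))` with multiplicative
#' lognormal noise; OD equals density under the identity calibration.
#'
#' @param environments the `environments` table from
#'   [simulate_substitutions()].
#' @param config a [sim_config()].
#' @param seed random seed.
#' @return a list: `curves` (long tibble `sample_id, environment_id,
#'   role, time_min, od`), `true_rates` (per curve) and `sc_reference`
#'   (the true base-medium rate).
#' @export
simulate_growth_curves <- function(environments, config = sim_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "sim_config"), config$od_noise_sd >= 0)
  set.seed(seed)
  times <- seq(0L, config$duration_min, by = config$interval_min)
  K <- config$carrying_capacity; d0 <- config$d0

  logistic_od <- function(rate) {
    d <- K * d0 * exp(rate * times) / (K + d0 * (exp(rate * times) - 1))
    if (config$od_noise_sd > 0) {
      d <- d * stats::rlnorm(length(d), 0, config$od_noise_sd)
    }
    d
  }

  specs <- list()
  for (j in seq_len(config$n_sc_replicates)) {
    specs[[length(specs) + 1L]] <- tibble::tibble(
      sample_id = sprintf("SC_prog_%d", j), environment_id = "SC",
      role = "sc_progenitor", rate = config$mu_sc)
  }
  for (i in seq_len(nrow(environments))) {
    e <- environments$environment_id[i]; s_i <- environments$stress_s[i]
    R_i <- config$mu_sc * (1 + log2(s_i))
    if (R_i <= 0) stop("stress level ", s_i, " implies non-positive rate")
    for (j in seq_len(config$n_progenitor_replicates)) {
      specs[[length(specs) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_prog_%d", e, j), environment_id = e,
        role = "progenitor", rate = R_i)
    }
    adapted <- length(environments$planted_genes[[i]]) > 0
    b <- if (adapted) config$effect_b0 +
      config$effect_slope * (1 - s_i) else 0
    r_evo <- R_i * (1 + log2(1 + b))
    for (j in seq_len(config$n_evolved_measured)) {
      specs[[length(specs) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_evo_%d", e, j), environment_id = e,
        role = "evolved", rate = r_evo)
    }
  }
  spec_tab <- dplyr::bind_rows(specs)
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(spec_tab)), function(i) {
    tibble::tibble(sample_id = spec_tab$sample_id[i],
                   environment_id = spec_tab$environment_id[i],
                   role = spec_tab$role[i], time_min = times,
                   od = logistic_od(spec_tab$rate[i]))
  }))
  list(curves = curves, true_rates = spec_tab,
       sc_reference = config$mu_sc)
}

#' Emit a complete synthetic dataset to a directory
#'
#' Writes the genome (FASTA + GFF3), per-sample VCFs, sample manifest,
#' growth curves, an identity OD calibration table, a YAML echo of the
#' configuration and a JSON truth ledger. All randomness derives from
#' `seed` (genome: `seed`; substitutions: `seed + 1`; curves:
#' `seed + 2`).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory objects (`model`,
#'   `sim`, `growth`) and the file `paths`.
#' @export
end_to_end_fixture <- function(config = sim_config(), seed = 1L,
                               out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(config, seed)
  sim <- simulate_substitutions(gen$model, config, seed + 1L)
  growth <- simulate_growth_curves(sim$environments, config, seed + 2L)

  paths <- list(fasta = file.path(out_dir, "genome.fasta"),
                gff3 = file.path(out_dir, "genome.gff3"),
                vcf_dir = file.path(out_dir, "vcf"),
                manifest = file.path(out_dir, "manifest.tsv"),
                curves = file.path(out_dir, "curves.tsv"),
                calibration = file.path(out_dir, "calibration.tsv"),
                config = file.path(out_dir, "config.yaml"),
                ledger = file.path(out_dir, "truth_ledger.json"))
  write_genome_annotation(gen$model, paths$fasta, paths$gff3)
  paths$vcfs <- write_substitution_vcfs(sim, gen$model, paths$vcf_dir)
  utils::write.table(sim$manifest, paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(growth$curves, paths$curves, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(od = c(0, 2), density = c(0, 2)),
                     paths$calibration, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- config
  cfg$type_mix <- as.list(cfg$type_mix)
  yaml::write_yaml(cfg[!vapply(cfg, is.function, logical(1))],
                   paths$config)
  ledger <- list(
    seed = seed,
    genome = gen$ledger,
    environments = lapply(seq_len(nrow(sim$environments)), function(i)
      list(environment_id = sim$environments$environment_id[i],
           stress = sim$environments$stress_s[i],
           expected_rate = sim$environments$expected_rate[i],
           planted_genes = sim$environments$planted_genes[[i]])),
    substitutions = sim$table[, c("sample_id", "chrom", "pos", "ref",
                                  "alt", "kind", "true_category",
                                  "true_unit", "planted")],
    contamination = sim$contamination,
    true_growth_rates = growth$true_rates)
  jsonlite::write_json(ledger, paths$ledger, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(model = gen$model, sim = sim, growth = growth,
                 paths = paths, config = config))
}
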