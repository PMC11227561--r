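toy_model <- function() {
  toy <- toy_single_gene()
  list(model = load_genome_annotation(toy$fasta, toy$gff), toy = toy)
}

# build a substitution row without going through a VCF
sub_row <- function(model, pos0, ref, alt, sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, chrom = "chr1", pos = pos0,
                 ref = ref, alt = alt,
                 kind = ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                               "SNV", "indel"))
}

test_that("VCF loading joins the manifest, splits multi-allelics, enforces coverage", {
  dir <- tempfile("vcf"); dir.create(dir)
  v1 <- write_test_vcf(file.path(dir, "S1.vcf"), "S1", list(
    list(chrom = "chr1", pos1 = 150, ref = "A", alt = "G"),
    list(chrom = "chr1", pos1 = 200, ref = "C", alt = "A,T"),
    list(chrom = "chr1", pos1 = 300, ref = "G", alt = "T",
         filter = "lowqual")))
  man <- manifest_for("S1")
  tab <- load_substitutions(c(S1 = v1), man)
  expect_equal(nrow(tab), 3)           # 1 + multi-allelic split into 2
  expect_setequal(tab$alt[tab$pos == 199], c("A", "T"))
  expect_true(all(tab$environment_id == "env1"))
  expect_equal(tab$pos[1], 149)        # 0-based internally

  # sample absent from the manifest is an error naming the sample
  v9 <- write_test_vcf(file.path(dir, "S9.vcf"), "S9", list(
    list(chrom = "chr1", pos1 = 10, ref = "A", alt = "C")))
  expect_error(load_substitutions(c(S9 = v9), man), "S9")
})

test_that("coding SNVs are classified through the genetic code", {
  tm <- toy_model(); model <- tm$model
  orf <- tm$toy$orf
  # third codon base positions in genome coordinates: gene starts at 100
  # find a codon where we can force each category
  # codon 2 occupies orf positions 4-6 (1-based), genome 103-105 (0-based)
  codon <- substr(orf, 4, 6)
  # synonymous: GGT->GGA style third-position change if available; build
  # generically with the genetic code as the oracle
  aa <- Biostrings::GENETIC_CODE[[codon]]
  found_syn <- FALSE; found_mis <- FALSE
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      new_codon <- codon; substr(new_codon, p, p) <- alt
      new_aa <- Biostrings::GENETIC_CODE[[new_codon]]
      pos0 <- 100 + 3 + (p - 1)
      cl <- classify_substitutions(
        sub_row(model, pos0, substr(codon, p, p), alt), model)
      expected <- if (new_aa == aa) "synonymous" else if (new_aa == "*")
        "nonsense" else "nonsynonymous"
      expect_equal(as.character(cl$category), expected)
      expect_equal(cl$unit_id, "geneA")
    }
  }
})

test_that("explicit genetic-code cases: GGT third position and TGG nonsense", {
  # construct a gene whose second codon is GGT and third is TGG
  set.seed(10)
  orf <- paste0("ATG", "GGT", "TGG",
                paste(rep("GAA", 46), collapse = ""), "TAA")
  chr <- paste0(random_dna(100), orf, random_dna(200))
  dir <- tempfile("g"); dir.create(dir)
  fasta <- write_fasta(c(chr1 = chr), file.path(dir, "g.fasta"))
  gff <- write_gff(gff_line("chr1", "CDS", 101, 100 + nchar(orf), "+",
                            "gene_id=gX"), file.path(dir, "g.gff3"))
  model <- load_genome_annotation(fasta, gff)
  # GGT -> GGA (Gly -> Gly): genomic 0-based 105, T->A
  cl <- classify_substitutions(sub_row(model, 105, "T", "A"), model)
  expect_equal(as.character(cl$category), "synonymous")
  # TGG -> TAG: second codon position of codon 3, genomic 107, G->A
  cl <- classify_substitutions(sub_row(model, 107, "G", "A"), model)
  expect_equal(as.character(cl$category), "nonsense")
})

test_that("minus-strand genes are classified on the coding strand", {
  # same gX gene placed on the minus strand: genome holds the reverse
  # complement; a genomic change maps to its complement in the CDS
  set.seed(11)
  orf <- paste0("ATG", "TGG", paste(rep("GAA", 47), collapse = ""), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  chr <- paste0(random_dna(100), rc, random_dna(200))
  dir <- tempfile("g"); dir.create(dir)
  fasta <- write_fasta(c(chr1 = chr), file.path(dir, "g.fasta"))
  gff <- write_gff(gff_line("chr1", "CDS", 101, 100 + nchar(orf), "-",
                            "gene_id=gM"), file.path(dir, "g.gff3"))
  model <- load_genome_annotation(fasta, gff)
  # coding-strand TGG codon occupies CDS positions 4-6; its middle G is
  # CDS position 5 (1-based) -> genomic 0-based: end-1-cpos = position
  gene <- model$genes
  cpos <- 4                                  # 0-based in spliced CDS
  gpos <- gene$span_end - 1 - cpos
  genomic_ref <- substr(chr, gpos + 1, gpos + 1)
  expect_equal(genomic_ref, "C")             # complement of coding G
  # coding G->A (TGG->TAG, nonsense) is genomic C->T
  cl <- classify_substitutions(sub_row(model, gpos, "C", "T"), model)
  expect_equal(as.character(cl$category), "nonsense")
})

test_that("indels follow the mod-3 rule and noncoding positions get units", {
  tm <- toy_model(); model <- tm$model
  chr <- tm$toy$chr
  # 2-nt deletion inside the CDS (anchor at 0-based 150)
  ref3 <- substr(chr, 151, 153)
  cl <- classify_substitutions(
    sub_row(model, 150, ref3, substr(ref3, 1, 1)), model)
  expect_equal(as.character(cl$category), "frameshift_indel")
  # 3-nt deletion
  ref4 <- substr(chr, 151, 154)
  cl <- classify_substitutions(
    sub_row(model, 150, ref4, substr(ref4, 1, 1)), model)
  expect_equal(as.character(cl$category), "inframe_indel")
  # noncoding SNV in the 3'UTR -> gene-associated unit
  ref1 <- substr(chr, 451, 451)
  alt1 <- setdiff(c("A", "C", "G", "T"), ref1)[1]
  cl <- classify_substitutions(sub_row(model, 450, ref1, alt1), model)
  expect_equal(as.character(cl$category), "noncoding")
  expect_equal(cl$unit_id, "nc:geneA")
})

test_that("reference-allele mismatch is reported as a coordinate error", {
  tm <- toy_model(); model <- tm$model
  ref <- substr(tm$toy$chr, 151, 151)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(
    classify_substitutions(sub_row(model, 150, wrong, "A"), model),
    "mismatch")
})

test_that("classification agrees with a whole-protein re-translation oracle", {
  cfg <- small_sim_config()
  gen <- simulate_genome(cfg, seed = 21)
  model <- gen$model
  set.seed(22)
  # random coding SNVs across many genes
  rows <- list()
  for (k in 1:120) {
    g <- model$genes[sample.int(nrow(model$genes), 1), ]
    pos <- sample(g$span_start:(g$span_end - 1), 1)
    ref <- substr(model$seq_chr[[g$chrom]], pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    rows[[k]] <- sub_row(model, pos, ref, alt,
                         sample_id = paste0("S", k))
    rows[[k]]$chrom <- g$chrom
    rows[[k]]$gene <- g$gene_id
  }
  tab <- dplyr::bind_rows(rows)
  cl <- classify_substitutions(tab[, 1:6], model)
  # oracle: mutate the whole spliced CDS, translate with Biostrings,
  # compare protein sequences
  for (k in seq_len(nrow(tab))) {
    g <- model$genes[model$genes$gene_id == tab$gene[k], ]
    spl <- spliced_cds(model, g$gene_id)
    cpos <- if (g$strand == "+") tab$pos[k] - g$span_start else
      g$span_end - 1 - tab$pos[k]
    alt_c <- if (g$strand == "+") tab$alt[k] else
      chartr("ACGT", "TGCA", tab$alt[k])
    mut <- spl; substr(mut, cpos + 1, cpos + 1) <- alt_c
    p0 <- as.character(Biostrings::translate(Biostrings::DNAString(spl),
                                             no.init.codon = TRUE))
    p1 <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(mut),
                            no.init.codon = TRUE)))
    expected <- if (p0 == p1) "synonymous" else {
      d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
      if (substr(p1, d, d) == "*" && substr(p0, d, d) != "*") "nonsense"
      else "nonsynonymous"
    }
    expect_equal(as.character(cl$category[k]), expected,
                 label = paste("substitution", k))
  }
})

test_that("category counts sum correctly and match the generator ledger", {
  cfg <- small_sim_config()
  gen <- simulate_genome(cfg, seed = 31)
  sim <- simulate_substitutions(gen$model, cfg, seed = 32)
  cl <- classify_substitutions(sim$table, gen$model)
  # exact agreement with the truth ledger
  expect_identical(as.character(cl$category), cl$true_category)
  # coding SNVs decompose into syn + nonsyn + nonsense in every grouping
  coding_snv <- cl$kind == "SNV" & cl$compartment == "coding"
  expect_equal(
    sum(cl$category %in% c("synonymous", "nonsynonymous", "nonsense")),
    sum(coding_snv))
  tab <- tabulate_effects(cl, group_by = "environment")
  totals_by_cat <- dplyr::summarise(
    dplyr::group_by(tab$counts, .data$environment_id),
    n = sum(.data$n), .groups = "drop")
  expect_equal(totals_by_cat$n,
               tab$totals$n_subs[match(totals_by_cat$environment_id,
                                       tab$totals$environment_id)])
})

test_that("per-environment replicate means and SDs are right", {
  # hand-built table: 3 replicates with 7 substitutions each
  tm <- toy_model(); model <- tm$model
  chr <- tm$toy$chr
  rows <- list()
  for (r in 1:3) for (k in 1:7) {
    pos <- 500 + k * 10
    ref <- substr(chr, pos + 1, pos + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    rows[[length(rows) + 1]] <- sub_row(model, pos, ref, alt,
                                        sample_id = paste0("S", r))
  }
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::left_join(tab, manifest_for(paste0("S", 1:3)),
                          by = "sample_id")
  cl <- classify_substitutions(tab, model)
  te <- tabulate_effects(cl, group_by = "environment")
  expect_equal(te$totals$mean_per_replicate, 7)
  expect_equal(te$totals$sd_per_replicate, 0)
})
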