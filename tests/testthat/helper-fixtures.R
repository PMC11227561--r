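# Fixture builders: everything is generated in code at test time.

sense_codon_pool <- function() {
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"), paste0),
                                c("A", "C", "G", "T"), paste0))
  all_codons[Biostrings::GENETIC_CODE[all_codons] != "*"]
}

# an ATG...stop open reading frame with no internal stops
random_orf <- function(n_codons) {
  paste0("ATG",
         paste(sample(sense_codon_pool(), n_codons - 2, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

write_gff <- function(body_lines, path) {
  writeLines(c("##gff-version 3", body_lines), path)
  path
}

gff_line <- function(chrom, type, start1, end1, strand = "+",
                     attrs = ".") {
  paste(chrom, "test", type, start1, end1, ".", strand, ".", attrs,
        sep = "\t")
}

# one 1000-nt chromosome with a 300-nt (100-codon) plus-strand gene at
# 0-based [100, 400), a 5'UTR at [50, 100) and a 3'UTR at [400, 520)
toy_single_gene <- function(dir = NULL, seed = 42) {
  if (is.null(dir)) {
    dir <- tempfile("toy")
    dir.create(dir)
  }
  set.seed(seed)
  orf <- random_orf(100)
  chr <- paste0(random_dna(100), orf, random_dna(600))
  fasta <- write_fasta(c(chr1 = chr), file.path(dir, "toy.fasta"))
  gff <- write_gff(c(
    gff_line("chr1", "gene", 101, 400, "+", "ID=geneA"),
    gff_line("chr1", "CDS", 101, 400, "+", "ID=cdsA;Parent=geneA;gene_id=geneA"),
    gff_line("chr1", "five_prime_UTR", 51, 100, "+",
             "ID=5utr_geneA;gene_id=geneA"),
    gff_line("chr1", "three_prime_UTR", 401, 520, "+",
             "ID=3utr_geneA;gene_id=geneA")
  ), file.path(dir, "toy.gff3"))
  list(fasta = fasta, gff = gff, orf = orf, chr = chr)
}

# simple VCF writer for hand-built records
write_test_vcf <- function(path, sample_id, records,
                           contigs = c(chr1 = 1000L),
                           filter = "PASS") {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample_id))
  for (r in records) {
    lines <- c(lines, paste(r$chrom, r$pos1, ".", r$ref, r$alt, ".",
                            r$filter %||% filter, ".", "GT", "1/1",
                            sep = "\t"))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manifest_for <- function(sample_ids, environment_id = "env1") {
  tibble::tibble(sample_id = sample_ids, environment_id = environment_id,
                 replicate = seq_along(sample_ids), plate = 1L, row = 1L,
                 column = seq_along(sample_ids))
}

# independent oracle: enumerate every single-nucleotide change of every
# CDS position one by one, classify by whole-codon translation
enumerate_expectation <- function(seqs, spectrum) {
  class_of <- function(ref, alt) {
    key <- paste0(ref, alt)
    c(AG = "AT_GC", TC = "AT_GC", AC = "AT_CG", TG = "AT_CG",
      AT = "AT_TA", TA = "AT_TA", CA = "CG_AT", GT = "CG_AT",
      CG = "CG_GC", GC = "CG_GC", CT = "CG_TA", GA = "CG_TA")[[key]]
  }
  w <- c(synonymous = 0, nonsynonymous = 0, nonsense = 0)
  for (s in seqs) {
    n <- nchar(s)
    last_codon <- substr(s, n - 2, n)
    limit <- if (Biostrings::GENETIC_CODE[[last_codon]] == "*") n - 3 else n
    for (i in seq_len(limit)) {
      codon_i <- ((i - 1) %/% 3) * 3 + 1
      codon <- substr(s, codon_i, codon_i + 2)
      p <- i - codon_i + 1
      ref <- substr(s, i, i)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        nc <- codon; substr(nc, p, p) <- alt
        a0 <- Biostrings::GENETIC_CODE[[codon]]
        a1 <- Biostrings::GENETIC_CODE[[nc]]
        k <- if (a0 == a1) "synonymous" else if (a1 == "*") "nonsense"
        else "nonsynonymous"
        w[k] <- w[k] + spectrum[[class_of(ref, alt)]]
      }
    }
  }
  w / sum(w)
}

small_sim_config <- function(...) {
  defaults <- list(n_genes = 40L, codons_min = 50L, codons_max = 150L,
                   n_environments = 6L, n_ars = 2L, n_ncrna = 2L,
                   utr5_len = 20L, utr3_len = 30L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
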