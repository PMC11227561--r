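test_that("simulated genomes are strict ORFs at the requested site ratio", {
  cfg <- small_sim_config()
  gen <- simulate_genome(cfg, seed = 100)
  model <- gen$model
  expect_equal(nrow(model$genes), 40)
  # every CDS is a start..stop ORF without internal stops (construction
  # invariant, revalidated here)
  for (g in model$genes$gene_id) {
    s <- spliced_cds(model, g)
    expect_equal(nchar(s) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 3), "ATG")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  sc <- site_counts(model)
  expect_lt(abs(sc$ratio - 2.68) / 2.68, 0.01)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_sim_config()
  g1 <- simulate_genome(cfg, seed = 101)
  g2 <- simulate_genome(cfg, seed = 101)
  expect_identical(as.character(g1$model$seqs), as.character(g2$model$seqs))
  expect_identical(g1$model$cds, g2$model$cds)
  s1 <- simulate_substitutions(g1$model, cfg, seed = 102)
  s2 <- simulate_substitutions(g2$model, cfg, seed = 102)
  expect_identical(s1$table, s2$table)
  c1 <- simulate_growth_curves(s1$environments, cfg, seed = 103)
  c2 <- simulate_growth_curves(s2$environments, cfg, seed = 103)
  expect_identical(c1$curves, c2$curves)
  # and a different seed changes the data
  g3 <- simulate_genome(cfg, seed = 104)
  expect_false(identical(as.character(g1$model$seqs),
                         as.character(g3$model$seqs)))
})

test_that("degenerate rates: zero background, certain planting", {
  cfg <- small_sim_config(lambda0 = 0, pi_hit = 1,
                          n_adaptive_per_env = 1L, n_environments = 2L)
  gen <- simulate_genome(cfg, seed = 110)
  sim <- simulate_substitutions(gen$model, cfg, seed = 111)
  counts <- table(sim$table$sample_id)
  expect_true(all(counts == 1))
  expect_equal(nrow(sim$table), 2 * cfg$n_replicates)
  expect_true(all(sim$table$planted))
  for (i in 1:2) {
    e <- sim$environments$environment_id[i]
    expect_setequal(unique(sim$table$true_unit[
      sim$table$environment_id == e]),
      sim$environments$planted_genes[[i]])
  }
})

test_that("background substitution counts follow the stress rate law", {
  cfg <- small_sim_config(n_environments = 30L, n_replicates = 24L,
                          lambda0 = 2, kappa = 6, columns_per_plate = 24L,
                          n_adaptive_per_env = 0L, rows_per_plate = 30L)
  gen <- simulate_genome(cfg, seed = 120)
  sim <- simulate_substitutions(gen$model, cfg, seed = 121)
  per_sample <- dplyr::count(sim$table, .data$environment_id,
                             .data$sample_id)
  # zero-substitution samples are absent from the table; complete them
  full <- tidyr::complete(
    dplyr::mutate(per_sample, n = as.numeric(.data$n)),
    environment_id = sim$environments$environment_id,
    sample_id, fill = list(n = 0))
  obs <- dplyr::summarise(dplyr::group_by(per_sample, .data$environment_id),
                          mean_n = sum(.data$n) / cfg$n_replicates,
                          .groups = "drop")
  obs <- dplyr::left_join(obs, sim$environments, by = "environment_id")
  # per-environment means track u_i within ~4 Poisson SEs
  se <- sqrt(obs$expected_rate / cfg$n_replicates)
  expect_true(all(abs(obs$mean_n - obs$expected_rate) < 4 * se + 0.2))
  # and counts rise with stress overall
  expect_gt(cor(obs$mean_n, 1 - obs$stress_s), 0.5)
})

test_that("emitted files reproduce the in-memory truth (ledger consistency)", {
  cfg <- small_sim_config(n_environments = 3L)
  dir <- tempfile("fix"); dir.create(dir)
  fix <- end_to_end_fixture(cfg, seed = 130, out_dir = dir)
  expect_true(all(file.exists(unlist(fix$paths[c("fasta", "gff3",
                                                 "manifest", "curves",
                                                 "calibration", "config",
                                                 "ledger")]))))
  # reload genome from the emitted files: same units
  model2 <- load_genome_annotation(fix$paths$fasta, fix$paths$gff3)
  by_gene <- function(m) dplyr::arrange(
    m$cds[, c("gene_id", "start", "end")], .data$gene_id)
  expect_identical(by_gene(model2), by_gene(fix$model))
  # reload substitutions from the emitted VCFs: identical records
  tab2 <- load_substitutions(fix$paths$vcfs, fix$paths$manifest)
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$pos, d$ref,
                                d$alt))
  expect_identical(key(tab2), key(fix$sim$table))
  # classifying the reloaded records reproduces the ledger categories
  cl <- classify_substitutions(tab2, model2)
  truth <- fix$sim$table
  idx <- match(paste(cl$sample_id, cl$chrom, cl$pos, cl$ref, cl$alt),
               paste(truth$sample_id, truth$chrom, truth$pos, truth$ref,
                     truth$alt))
  expect_identical(as.character(cl$category), truth$true_category[idx])
  # the ledger file itself round-trips through JSON
  led <- jsonlite::read_json(fix$paths$ledger, simplifyVector = TRUE)
  expect_equal(nrow(led$substitutions), nrow(fix$sim$table))
  expect_equal(led$seed, 130)
})

test_that("noiseless growth curves return the exact exponential-phase rate", {
  cfg <- small_sim_config(od_noise_sd = 0, n_environments = 2L)
  env <- tibble::tibble(environment_id = c("env001", "env002"),
                        stress_s = c(1, 0.8),
                        expected_rate = c(1, 2),
                        planted_genes = list(character(0), "gene001"))
  gc <- simulate_growth_curves(env, cfg, seed = 140)
  rates <- growth_rates(gc$curves)
  truth <- gc$true_rates
  m <- match(rates$sample_id, truth$sample_id)
  # the logistic slows growth near saturation; the windowed maximum
  # slope recovers the exponential-phase rate within 5%
  expect_true(all(abs(rates$rate - truth$rate[m]) / truth$rate[m] < 0.05))
})

test_that("noisy growth curves recover true rates within 10% almost always", {
  cfg <- small_sim_config(od_noise_sd = 0.01, n_environments = 10L,
                          n_evolved_measured = 18L)
  set.seed(141)
  env <- tibble::tibble(environment_id = sprintf("env%03d", 1:10),
                        stress_s = runif(10, 0.7, 1.05),
                        expected_rate = 1,
                        planted_genes = rep(list("gene001"), 10))
  gc <- simulate_growth_curves(env, cfg, seed = 142)
  rates <- growth_rates(gc$curves)
  truth <- gc$true_rates
  m <- match(rates$sample_id, truth$sample_id)
  rel_err <- abs(rates$rate - truth$rate[m]) / truth$rate[m]
  expect_gte(mean(rel_err < 0.10), 0.95)
  expect_gte(length(rel_err), 200)
})

test_that("the built-in effect law produces a negative stress-adaptation correlation", {
  cfg <- small_sim_config(n_environments = 24L, od_noise_sd = 0.005,
                          rows_per_plate = 24L)
  gen <- simulate_genome(cfg, seed = 150)
  sim <- simulate_substitutions(gen$model, cfg, seed = 151)
  gc <- simulate_growth_curves(sim$environments, cfg, seed = 152)
  rates <- growth_rates(gc$curves)
  truth_roles <- gc$true_rates[match(rates$sample_id,
                                     gc$true_rates$sample_id), ]
  rates$role <- truth_roles$role
  sc_ref <- mean(rates$rate[rates$role == "sc_progenitor"])
  prog <- rates[rates$role == "progenitor", ]
  prog$replicate <- as.integer(sub(".*_prog_", "", prog$sample_id))
  evo <- rates[rates$role == "evolved", ]
  evo$population <- as.integer(sub(".*_evo_", "", evo$sample_id))
  fit <- environment_fitness_summary(
    prog[, c("environment_id", "replicate", "rate")],
    evo[, c("environment_id", "population", "rate")],
    sc_ref, split_rule = "first_two_vs_third")
  r <- stress_adaptation_correlation(fit)
  expect_lt(r$coefficient, -0.5)
  # stress levels recovered from curves track the simulated truth
  m <- match(fit$environment_id, sim$environments$environment_id)
  expect_gt(cor(fit$F_ratio, sim$environments$stress_s[m]), 0.95)
})
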