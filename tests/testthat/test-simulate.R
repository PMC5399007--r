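test_that("an event-free panel is balanced everywhere in truth", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 10L,
                           n_accessions = 3L, seed = 2L)
  sim <- simulate_panel(cfg)
  expect_true(all(sim$truth$category == "No difference"))
  expect_true(all(sim$truth$cn_A == 1 & sim$truth$cn_C == 1))
})

test_that("planted exchanges set gainer 2x / loser 0x in the carrier only", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 30L,
                           n_accessions = 4L, seed = 3L)
  cfg <- add_event(cfg, 2L, 1L, 5L, 25L, "exchange", gainer = "C")
  sim <- simulate_panel(cfg)
  tr <- dplyr::filter(sim$truth, accession_id == "acc02", ordinal >= 5,
                      ordinal < 25)
  expect_true(all(tr$cn_C == 2 & tr$cn_A == 0))
  expect_true(all(startsWith(tr$category, "Exchange A")))
  rest <- dplyr::filter(sim$truth, !(accession_id == "acc02" &
                                       ordinal >= 5 & ordinal < 25))
  expect_true(all(rest$category == "No difference"))
  # contradictory overlap is rejected
  cfg_bad <- add_event(cfg, 2L, 1L, 10L, 20L, "deletion", gainer = "C")
  expect_error(simulate_panel(cfg_bad), "contradictory")
})

test_that("truth categories equal classification of the noiseless ratios", {
  cfg <- simulation_config(n_chromosomes = 2L, genes_per_chromosome = 20L,
                           n_accessions = 6L, seed = 8L)
  cfg <- add_event(cfg, 1L, 1L, 0L, 10L, "exchange", gainer = "A")
  cfg <- add_event(cfg, 3L, 2L, 5L, 15L, "duplication", gainer = "C")
  cfg <- add_event(cfg, 4L, 2L, 5L, 15L, "deletion", gainer = "A")
  sim <- simulate_panel(cfg)
  dirs_of <- function(cn) ifelse(cn > 1, "high", ifelse(cn < 1, "low", "null"))
  want <- classify_group(dirs_of(sim$truth$cn_A), dirs_of(sim$truth$cn_C),
                         c("A", "C"))
  expect_equal(sim$truth$category, want)
})

test_that("identical seeds give byte-identical fixture files", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 15L,
                           n_accessions = 3L, seed = 99L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation_files(simulate_panel(cfg), d1)
  p2 <- write_simulation_files(simulate_panel(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = paste("file:", k))
  }
  # and a different seed changes the counts
  cfg2 <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 15L,
                            n_accessions = 3L, seed = 100L)
  expect_false(identical(simulate_panel(cfg2)$counts,
                         simulate_panel(cfg)$counts))
})

test_that("simulated count means track copy number x baseline x library", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 5L,
                           n_accessions = 1L, replicates = 200L,
                           noise_cv = 0.05, seed = 17L)
  sim <- simulate_panel(cfg)
  lam <- sim$true_rpkm[, rep(1, 200)] * (sim$lengths / 1000) *
    (sim$config$library_size / 1e6)
  obs <- rowMeans(sim$counts)
  mu <- rowMeans(lam)
  # 3 SE bound; variance includes Poisson + multiplicative noise
  se <- sqrt((mu + (0.05 * mu)^2) / 200)
  expect_true(all(abs(obs - mu) <= 3.5 * se))
})

test_that("alignment fixtures round-trip through RBH pairing", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 40L,
                           n_accessions = 2L, seed = 5L)
  sim <- simulate_panel(cfg)
  al <- simulate_alignment_tables(sim$groups, decoy_fraction = 0, seed = 5L)
  pairs <- reciprocal_best_pairs(al$hits_ab, al$hits_ba)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(al$true_pairs$gene_a, al$true_pairs$gene_b))

  # a reciprocity-broken pair must vanish from the recovered set
  al2 <- simulate_alignment_tables(sim$groups, n_break = 1L, seed = 6L)
  pairs2 <- reciprocal_best_pairs(al2$hits_ab, al2$hits_ba)
  expect_false(any(pairs2$gene_a %in% al2$broken_pairs$gene_a))
  expect_setequal(paste(pairs2$gene_a, pairs2$gene_b),
                  paste(al2$true_pairs$gene_a, al2$true_pairs$gene_b))

  # decoys with weaker scores never displace true pairs
  al3 <- simulate_alignment_tables(sim$groups, decoy_fraction = 0.3, seed = 7L)
  pairs3 <- reciprocal_best_pairs(al3$hits_ab, al3$hits_ba)
  expect_setequal(paste(pairs3$gene_a, pairs3$gene_b),
                  paste(al3$true_pairs$gene_a, al3$true_pairs$gene_b))
})

test_that("parental controls render single-genome colours; combination blue", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 10L,
                           n_accessions = 2L, noise_model = "none", seed = 9L)
  sim <- simulate_panel(cfg)
  parents <- make_parental_controls(sim)
  combo <- in_silico_combination(list(parents[, 1], parents[, 2]))
  panel <- simulated_panel_rpkm(sim)
  panel <- add_control_samples(panel, cbind(parents, in_silico = combo))
  norm <- normalize_abundance(panel)
  spec <- encode_cmyk(norm, sim$groups)
  pa <- dplyr::filter(spec, sample_id == "parent_A")
  expect_true(all(abs(pa$c - 1) < 1e-12 & pa$m == 0))  # pure cyan
  pc <- dplyr::filter(spec, sample_id == "parent_C")
  expect_true(all(pc$c == 0 & abs(pc$m - 1) < 1e-12))  # pure magenta
  ic <- dplyr::filter(spec, sample_id == "in_silico")
  rgb <- cmyk_to_rgb(ic$c, ic$m, ic$y, ic$k)
  expect_true(all(rgb[, 3] == 1 & abs(rgb[, 1] - rgb[, 2]) < 1e-12))  # blue family
})

test_that("3-genome parents combine to the grey family", {
  cfg <- simulation_config(genomes = c("A", "B", "D"), n_chromosomes = 1L,
                           genes_per_chromosome = 8L, n_accessions = 2L,
                           noise_model = "none", seed = 10L,
                           ordering_genome = "A")
  sim <- simulate_panel(cfg)
  parents <- make_parental_controls(sim)
  combo <- in_silico_combination(lapply(1:3, function(i) parents[, i]))
  panel <- add_control_samples(simulated_panel_rpkm(sim),
                               cbind(parents, in_silico = combo))
  spec <- encode_cmyk(normalize_abundance(panel), sim$groups)
  ic <- dplyr::filter(spec, sample_id == "in_silico")
  rgb <- cmyk_to_rgb(ic$c, ic$m, ic$y, ic$k)
  expect_true(all(abs(rgb[, 1] - rgb[, 2]) < 1e-12 &
                    abs(rgb[, 2] - rgb[, 3]) < 1e-12))
})
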