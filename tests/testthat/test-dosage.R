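test_that("direction test handles identity, clear shifts and near-null cases", {
  r <- direction_test(c(10, 10, 10, 10), 10)
  expect_equal(r$direction, "null")
  expect_equal(r$p_value, 1)
  expect_false(r$degenerate)

  # hand check: x = (20.1, 19.8, 20.3, 20.0), mu = 10
  x <- c(20.1, 19.8, 20.3, 20.0)
  tstat <- (mean(x) - 10) / (sd(x) / 2)
  p_hand <- 2 * pt(-abs(tstat), 3)
  r <- direction_test(x, 10)
  expect_equal(r$direction, "high")
  expect_equal(r$p_value, p_hand)
  expect_lt(r$p_value, 1e-4)

  r <- direction_test(c(9.9, 10.2, 9.7, 10.1), 10)
  expect_equal(r$direction, "null")
  expect_gt(r$p_value, 0.5)
})

test_that("degenerate replicate sets are flagged, never silently passed", {
  # zero variance away from the reference: deleted-copy signature
  r <- direction_test(c(0, 0, 0, 0), 5)
  expect_equal(r$direction, "low")
  expect_equal(r$p_value, 0)
  expect_true(r$degenerate)

  r <- direction_test(7, 5)  # single replicate
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_equal(r$direction, "null")
})

test_that("t machinery matches stats::t.test on 1000 random cases", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    x <- stats::rnorm(n, mean = stats::runif(1, 0, 50),
                      sd = stats::runif(1, 0.01, 5))
    mu <- stats::runif(1, 0, 50)
    ours <- direction_test(x, mu)
    ref <- stats::t.test(x, mu = mu)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the nine-category grid matches the dosage table exactly", {
  arrow <- "\u2192"
  expect_equal(classify_group("high", "high"), "Duplication A and C")
  expect_equal(classify_group("high", "null"), "Duplication A")
  expect_equal(classify_group("null", "high"), "Duplication C")
  expect_equal(classify_group("high", "low"), paste("Exchange C", arrow, "A"))
  expect_equal(classify_group("low", "high"), paste("Exchange A", arrow, "C"))
  expect_equal(classify_group("low", "null"), "Deletion A")
  expect_equal(classify_group("low", "low"), "Deletion A and C")
  expect_equal(classify_group("null", "low"), "Deletion C")
  expect_equal(classify_group("null", "null"), "No difference")

  # total and bijective over the 3x3 grid
  grid <- expand.grid(d1 = c("high", "null", "low"),
                      d2 = c("high", "null", "low"),
                      stringsAsFactors = FALSE)
  cats <- classify_group(grid$d1, grid$d2)
  expect_false(anyNA(cats))
  expect_equal(length(unique(cats)), 9L)
  expect_error(classify_group("up", "down"), "high")
})

test_that("swapping genome labels mirrors the asymmetric categories", {
  dirs <- c("high", "null", "low")
  for (d1 in dirs) for (d2 in dirs) {
    ac <- classify_group(d1, d2, c("A", "C"))
    ca <- classify_group(d2, d1, c("C", "A"))
    expect_equal(ac, ca)
  }
})

test_that("triplet classification extends the pair convention", {
  arrow <- "\u2192"
  expect_equal(classify_triplet(c(A = "high", B = "low", D = "null")),
               paste("Exchange B", arrow, "A"))
  expect_equal(classify_triplet(c(A = "null", B = "null", D = "null")),
               "No difference")
  expect_equal(classify_triplet(c(A = "low", B = "low", D = "low")),
               "Deletion A and B and D")
  expect_equal(classify_triplet(c(A = "high", B = "high", D = "null")),
               "Duplication A and B")
  expect_equal(classify_triplet(c(A = "null", B = "null", D = "low")),
               "Deletion D")
})

test_that("panel classification agrees with scalar direction_test per cell", {
  set.seed(77)
  groups <- toy_groups(15)
  genes <- groups$gene_id
  vals <- matrix(stats::rlnorm(length(genes) * 12, log(20), 0.6),
                 nrow = length(genes), dimnames = list(genes, NULL))
  vals[3, 1:4] <- 0  # a degenerate zero-variance accession
  panel <- toy_panel(vals, n_acc = 3, n_rep = 4)
  calls <- classify_panel(panel, groups, alpha = 0.05)
  long <- tidy(calls)
  pm <- rowMeans(panel$values)
  for (i in sample(nrow(long), 40)) {
    row <- long[i, ]
    gid <- groups$gene_id[groups$group_id == row$group_id &
                            groups$genome == row$genome]
    reps <- panel$values[gid, panel$sample_sheet$accession_id == row$accession_id]
    ref <- direction_test(reps, pm[gid], alpha = 0.05)
    expect_equal(row$p_value, ref$p_value)
    expect_equal(row$direction, ref$direction)
    expect_equal(row$degenerate, ref$degenerate)
  }
})

test_that("an accession equal to the panel mean everywhere is all-null", {
  groups <- toy_groups(5)
  vals <- matrix(7, nrow = 10, ncol = 8,
                 dimnames = list(groups$gene_id, NULL))
  panel <- toy_panel(vals, n_acc = 2, n_rep = 4)
  calls <- classify_panel(panel, groups)
  expect_true(all(calls$category == "No difference"))
  expect_true(all(calls$p_A == 1))
})

test_that("a planted reciprocal exchange is called with the right direction", {
  arrow <- "\u2192"
  cfg <- simulation_config(genomes = c("A", "C"), n_chromosomes = 1L,
                           genes_per_chromosome = 60L, n_accessions = 20L,
                           noise_model = "gaussian", seed = 21L,
                           ordering_genome = "C")
  cfg <- add_event(cfg, 3L, 1L, 20L, 40L, "exchange", gainer = "C")
  sim <- simulate_panel(cfg)
  panel <- simulated_panel_rpkm(sim)
  calls <- classify_panel(panel, sim$groups)
  carrier <- dplyr::filter(tibble::as_tibble(calls), accession_id == "acc03",
                           ordinal >= 20, ordinal < 40)
  expect_gt(mean(carrier$category == paste("Exchange A", arrow, "C")), 0.8)
  other <- dplyr::filter(tibble::as_tibble(calls), accession_id == "acc04",
                         ordinal < 20)
  expect_gt(mean(other$category == "No difference"), 0.8)
})

test_that("BH adjustment and log2 transform are available but off by default", {
  set.seed(31)
  groups <- toy_groups(10)
  vals <- matrix(stats::rlnorm(20 * 16, log(10), 0.4), nrow = 20,
                 dimnames = list(groups$gene_id, NULL))
  panel <- toy_panel(vals, n_acc = 4, n_rep = 4)
  raw <- classify_panel(panel, groups)
  adj <- classify_panel(panel, groups, p_adjust = "BH")
  expect_true(all(adj$p_A >= raw$p_A - 1e-12))
  lg <- classify_panel(panel, groups, transform = "log2")
  expect_s3_class(lg, "dosage_calls")
})
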