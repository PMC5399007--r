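test_that("mutual best hits form pairs; broken reciprocity does not", {
  ab <- hits_tbl("gA1", "gC1", 1e-100, 500)
  ba <- hits_tbl("gC1", "gA1", 1e-100, 500)
  expect_equal(reciprocal_best_pairs(ab, ba),
               tibble::tibble(gene_a = "gA1", gene_b = "gC1"))

  # gA1 -> gC1 best, but gC1 -> gA2 best: no pair
  ba2 <- hits_tbl(c("gC1", "gC1"), c("gA2", "gA1"), c(1e-120, 1e-100),
                  c(600, 500))
  expect_equal(nrow(reciprocal_best_pairs(ab, ba2)), 0L)

  # E-value threshold: hits above 1e-30 are discarded
  weak_ab <- hits_tbl("gA1", "gC1", 1e-10, 500)
  expect_equal(nrow(reciprocal_best_pairs(weak_ab, ba)), 0L)

  expect_equal(nrow(reciprocal_best_pairs(ab[0, ], ba[0, ])), 0L)
})

test_that("tie-breaking and HSP collapsing match the exhaustive oracle", {
  # deliberate bitscore tie between gC1 and gC2 for query gA1: lower
  # E-value, then lexicographic subject id must decide
  ab <- hits_tbl(c("gA1", "gA1", "gA2", "gA2", "gA3"),
                 c("gC1", "gC2", "gC2", "gC3", "gC3"),
                 c(1e-80, 1e-80, 1e-90, 1e-70, 1e-60),
                 c(400, 400, 450, 300, 200))
  ba <- hits_tbl(c("gC1", "gC2", "gC2", "gC3"),
                 c("gA1", "gA1", "gA2", "gA3"),
                 c(1e-80, 1e-75, 1e-74, 1e-60),
                 c(400, 380, 380, 200))
  expect_equal(reciprocal_best_pairs(ab, ba), rbh_oracle(ab, ba))

  # randomized toy tables with integer bitscores to force frequent ties,
  # plus duplicate rows acting as multiple HSPs
  set.seed(42)
  for (rep in 1:25) {
    n <- 6L
    qa <- paste0("a", sample(n, 12, TRUE))
    sb <- paste0("b", sample(n, 12, TRUE))
    habs <- hits_tbl(qa, sb, 10^-sample(25:80, 12, TRUE),
                     sample(5:9, 12, TRUE) * 50)
    qb <- paste0("b", sample(n, 12, TRUE))
    sa <- paste0("a", sample(n, 12, TRUE))
    hbas <- hits_tbl(qb, sa, 10^-sample(25:80, 12, TRUE),
                     sample(5:9, 12, TRUE) * 50)
    expect_equal(reciprocal_best_pairs(habs, hbas), rbh_oracle(habs, hbas))
  }
})

test_that("pair sets are symmetric under swapping the two directions", {
  set.seed(7)
  for (rep in 1:10) {
    habs <- hits_tbl(paste0("a", sample(5, 10, TRUE)),
                     paste0("b", sample(5, 10, TRUE)),
                     10^-sample(31:99, 10, TRUE), sample(4:9, 10, TRUE) * 100)
    hbas <- hits_tbl(paste0("b", sample(5, 10, TRUE)),
                     paste0("a", sample(5, 10, TRUE)),
                     10^-sample(31:99, 10, TRUE), sample(4:9, 10, TRUE) * 100)
    fwd <- reciprocal_best_pairs(habs, hbas)
    rev <- reciprocal_best_pairs(hbas, habs)
    expect_setequal(paste(fwd$gene_a, fwd$gene_b),
                    paste(rev$gene_b, rev$gene_a))
  }
})

test_that("triplets require a consistent triangle", {
  ab <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  ad <- tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("d1", "d2"))
  bd <- tibble::tibble(gene_a = "b1", gene_b = "d1")
  tri <- build_triplets(ab, ad, bd)
  expect_equal(nrow(tri), 1L)
  expect_equal(unlist(tri[1, c("A", "B", "D")], use.names = FALSE),
               c("a1", "b1", "d1"))
  # a2/b2/d2 lack the b-d edge: all three genes dropped and reported
  expect_setequal(attr(tri, "dropped")$gene_id, c("a2", "b2", "d2"))
  expect_equal(attr(tri, "n_dropped"), 3L)
})

test_that("triplet construction equals brute-force triangle enumeration", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 8L
    rnd_pairs <- function(p1, p2) {
      k <- sample(3:n, 1)
      i <- sample(n, k)
      j <- sample(n, k)
      tibble::tibble(gene_a = paste0(p1, i), gene_b = paste0(p2, j)) |>
        dplyr::distinct(gene_a, .keep_all = TRUE) |>
        dplyr::distinct(gene_b, .keep_all = TRUE)
    }
    ab <- rnd_pairs("a", "b"); ad <- rnd_pairs("a", "d"); bd <- rnd_pairs("b", "d")
    tri <- build_triplets(ab, ad, bd)
    # oracle: enumerate all (a,b,d) combinations and test the three edges
    found <- list()
    for (a in unique(c(ab$gene_a, ad$gene_a))) {
      for (b in unique(c(ab$gene_b, bd$gene_a))) {
        for (d in unique(c(ad$gene_b, bd$gene_b))) {
          if (any(ab$gene_a == a & ab$gene_b == b) &&
              any(ad$gene_a == a & ad$gene_b == d) &&
              any(bd$gene_a == b & bd$gene_b == d)) {
            found[[length(found) + 1L]] <- c(a, b, d)
          }
        }
      }
    }
    got <- apply(as.matrix(tri[, c("A", "B", "D")]), 1L, paste, collapse = "|")
    want <- vapply(found, paste, "", collapse = "|")
    expect_setequal(got, want)
  }
})

test_that("a gene may not occur in two groups", {
  pairs <- tibble::tibble(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"))
  expect_error(as_homoeolog_groups(pairs), "more than one homoeologue group")
})

test_that("attach_order sorts by the ordering genome and reports unplaced", {
  groups <- as_homoeolog_groups(
    tibble::tibble(gene_a = c("a1", "a2", "a3"), gene_b = c("c1", "c2", "c3")),
    genomes = c("A", "C"))
  order_table <- tibble::tibble(
    gene_id = c("c1", "c2"), genome = "C", chromosome = "C1",
    ordinal = c(5L, 1L))
  out <- attach_order(groups, order_table, "C")
  # c2 (ordinal 1) before c1 (ordinal 5); group of c3 excluded
  expect_equal(unique(out$ordinal), c(1L, 5L))
  expect_equal(attr(out, "n_unplaced"), 1L)
  expect_error(attach_order(groups, order_table, "B"), "ordering_genome")

  # shuffled 100-group fixture equals an independent sort
  set.seed(3)
  big <- as_homoeolog_groups(
    tibble::tibble(gene_a = paste0("a", 1:100), gene_b = paste0("c", 1:100)),
    genomes = c("A", "C"))
  ords <- sample(0:99)
  ot <- tibble::tibble(gene_id = paste0("c", 1:100), genome = "C",
                       chromosome = sample(c("C1", "C2"), 100, TRUE),
                       ordinal = ords) |> validate_gene_order()
  out <- attach_order(big, ot, "C")
  anchor <- out[out$genome == "C", ]
  perm <- order(anchor$chromosome, anchor$ordinal)
  expect_equal(anchor$gene_id, anchor$gene_id[perm])
})
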