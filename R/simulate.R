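#' Configuration for a simulated allopolyploid panel
#'
#' Describes the generative model for a fully synthetic test panel:
#' homoeologue groups laid out on chromosomes, a shared log-normal
#' baseline expression per group (balanced 1:1 between homoeologues),
#' multiplicative replicate noise, Poisson read-count sampling, and
#' planted copy-number events. Event semantics follow the genome-dosage
#' grid: an exchange sets the gainer member to 2x and the loser to 0x
#' copy number (reciprocal substitution), duplication 2x, deletion 0x,
#' whole-chromosome gain/loss 1.5x/0.5x (one copy gained or lost out of
#' the two carried by a euploid allopolyploid).
#'
#' @param genomes Genome labels, length 2 or 3 (default `c("A", "C")`).
#' @param n_chromosomes Chromosomes per genome.
#' @param genes_per_chromosome Homoeologue groups per chromosome.
#' @param n_accessions Panel size.
#' @param replicates Biological replicates per accession (default 4).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-group baseline abundance, RPKM scale (defaults log(50) and 1: a
#'   typical leaf mRNAseq dynamic range of several orders of magnitude
#'   around tens of RPKM).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   between-replicate noise (default 0.1).
#' @param noise_model `"poisson"` (default; log-normal replicate noise
#'   plus Poisson counting noise), `"gaussian"` (gaussian multiplicative
#'   noise on the abundance scale, no counting noise), or `"none"`
#'   (noiseless expectations).
#' @param events Planted events: a tibble with columns `accession_id`
#'   (or 1-based accession index), `chromosome` (1-based index),
#'   `start_ordinal`, `end_ordinal` (0-based half-open),
#'   `type` (`exchange`, `duplication`, `deletion`,
#'   `whole_chromosome_gain`, `whole_chromosome_loss`), `gainer`,
#'   `loser` (genome labels; `loser` only for exchanges, `gainer` doubles
#'   as the affected genome for the other types).
#' @param gene_length_range Uniform range of gene lengths in bp.
#' @param library_size Aligned reads per sample (default 5e6).
#' @param ordering_genome Genome whose order anchors plots and blocks
#'   (default the first genome).
#' @param seed Integer seed fixing every random draw.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(genomes = c("A", "C"),
                              n_chromosomes = 3L,
                              genes_per_chromosome = 200L,
                              n_accessions = 20L,
                              replicates = 4L,
                              baseline_meanlog = log(50),
                              baseline_sdlog = 1,
                              noise_cv = 0.1,
                              noise_model = c("poisson", "gaussian", "none"),
                              events = NULL,
                              gene_length_range = c(500L, 3000L),
                              library_size = 5e6,
                              ordering_genome = genomes[1L],
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!length(genomes) %in% 2:3) stop("2 or 3 genomes required", call. = FALSE)
  if (is.null(events)) events <- empty_events()
  events <- tibble::as_tibble(events)
  cfg <- list(genomes = genomes, n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              n_accessions = as.integer(n_accessions),
              replicates = as.integer(replicates),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              noise_cv = noise_cv, noise_model = noise_model,
              events = events, gene_length_range = gene_length_range,
              library_size = library_size,
              ordering_genome = ordering_genome, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

empty_events <- function() {
  tibble::tibble(accession_id = character(), chromosome = integer(),
                 start_ordinal = integer(), end_ordinal = integer(),
                 type = character(), gainer = character(),
                 loser = character())
}

#' Plant an event into a simulation configuration
#'
#' @param config A `sim_config`.
#' @param accession Accession id (e.g. `"acc03"`) or 1-based index.
#' @param chromosome 1-based chromosome index.
#' @param start_ordinal,end_ordinal 0-based half-open ordinal span
#'   (ignored for whole-chromosome events).
#' @param type One of `exchange`, `duplication`, `deletion`,
#'   `whole_chromosome_gain`, `whole_chromosome_loss`.
#' @param gainer Genome gaining copies (or, for deletion/loss, the
#'   affected genome).
#' @param loser Genome losing its segment (exchanges only; default the
#'   other genome for two-genome panels).
#' @return The updated `sim_config`.
#' @export
add_event <- function(config, accession, chromosome, start_ordinal = 0L,
                      end_ordinal = NULL, type = "exchange", gainer,
                      loser = NULL) {
  type <- match.arg(type, c("exchange", "duplication", "deletion",
                            "whole_chromosome_gain", "whole_chromosome_loss"))
  if (is.numeric(accession)) accession <- sprintf("acc%02d", accession)
  if (is.null(end_ordinal)) end_ordinal <- config$genes_per_chromosome
  if (startsWith(type, "whole_chromosome")) {
    start_ordinal <- 0L
    end_ordinal <- config$genes_per_chromosome
  }
  if (type == "exchange" && is.null(loser)) {
    others <- setdiff(config$genomes, gainer)
    if (length(others) != 1L) {
      stop("loser must be named for exchanges in 3-genome panels", call. = FALSE)
    }
    loser <- others
  }
  if (start_ordinal < 0L || end_ordinal > config$genes_per_chromosome ||
      end_ordinal <= start_ordinal) {
    stop("event span outside chromosome", call. = FALSE)
  }
  config$events <- dplyr::bind_rows(config$events, tibble::tibble(
    accession_id = accession, chromosome = as.integer(chromosome),
    start_ordinal = as.integer(start_ordinal),
    end_ordinal = as.integer(end_ordinal), type = type, gainer = gainer,
    loser = if (is.null(loser)) NA_character_ else loser))
  config
}

# copy-number multipliers per event type
event_multipliers <- function(type) {
  switch(type,
         exchange = c(gainer = 2, loser = 0),
         duplication = c(gainer = 2, loser = NA),
         deletion = c(gainer = 0, loser = NA),
         whole_chromosome_gain = c(gainer = 1.5, loser = NA),
         whole_chromosome_loss = c(gainer = 0.5, loser = NA))
}

#' Simulate a complete allopolyploid expression panel
#'
#' Generates homoeologue groups, a gene-order table, a sample sheet, a
#' read-count matrix with gene lengths and aligned totals, and the truth
#' table implied by the planted events. Baseline abundance is drawn once
#' per group and shared by all homoeologues (balanced 1:1); expected
#' counts are `copy_number * baseline * replicate_noise * length_kb *
#' library_millions`, Poisson-sampled under the default noise model.
#' Everything is deterministic given the seed.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list of class `he_simulation`: `groups` (ordered long
#'   tibble), `gene_order`, `counts`, `lengths`, `aligned_totals`,
#'   `sample_sheet`, `truth`, `baseline` (named per-group RPKM),
#'   `true_rpkm` (noise-free expectation matrix), `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(cfg) {
  G <- length(cfg$genomes)
  n_grp_chr <- cfg$genes_per_chromosome
  n_chr <- cfg$n_chromosomes
  n_grp <- n_chr * n_grp_chr
  grp_ids <- sprintf("grp%05d", seq_len(n_grp))
  chr_idx <- rep(seq_len(n_chr), each = n_grp_chr)
  ord <- rep(seq_len(n_grp_chr) - 1L, times = n_chr)

  gene_order <- tidyr::expand_grid(genome = cfg$genomes,
                                   i = seq_len(n_grp)) |>
    dplyr::mutate(
      chromosome = paste0(.data$genome, chr_idx[.data$i]),
      ordinal = ord[.data$i],
      gene_id = sprintf("%s%02dg%04d", .data$genome, chr_idx[.data$i],
                        ord[.data$i]),
      length = round(stats::runif(dplyr::n(), cfg$gene_length_range[1L],
                                  cfg$gene_length_range[2L]))
    )
  # homoeologues share one length so RPKM ratios reflect copy number alone
  len_by_i <- gene_order |>
    dplyr::filter(.data$genome == cfg$genomes[1L]) |>
    dplyr::pull(.data$length)
  gene_order$length <- len_by_i[gene_order$i]

  groups <- gene_order |>
    dplyr::mutate(group_id = grp_ids[.data$i]) |>
    dplyr::select("group_id", "genome", "gene_id")
  order_table <- gene_order |>
    dplyr::select("gene_id", "genome", "chromosome", "ordinal")
  groups <- attach_order(groups, order_table, cfg$ordering_genome)

  accs <- sprintf("acc%02d", seq_len(cfg$n_accessions))
  sheet <- tidyr::expand_grid(accession_id = accs,
                              replicate = seq_len(cfg$replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$accession_id, "_r", .data$replicate),
                  assay = "mrnaseq", is_control = FALSE) |>
    dplyr::select("sample_id", "accession_id", "replicate", "assay",
                  "is_control")

  baseline <- stats::setNames(
    stats::rlnorm(n_grp, cfg$baseline_meanlog, cfg$baseline_sdlog), grp_ids)

  # copy number per (gene, accession), default 1
  genes <- gene_order$gene_id
  cn <- matrix(1, nrow = length(genes), ncol = length(accs),
               dimnames = list(genes, accs))
  ev <- cfg$events
  if (nrow(ev)) {
    for (r in seq_len(nrow(ev))) {
      mult <- event_multipliers(ev$type[r])
      sel_g <- gene_order$genome == ev$gainer[r] &
        chr_idx[gene_order$i] == ev$chromosome[r] &
        ord[gene_order$i] >= ev$start_ordinal[r] &
        ord[gene_order$i] < ev$end_ordinal[r]
      prev <- cn[sel_g, ev$accession_id[r]]
      if (any(prev != 1 & prev != mult[["gainer"]])) {
        stop("overlapping contradictory events on one span", call. = FALSE)
      }
      cn[sel_g, ev$accession_id[r]] <- mult[["gainer"]]
      if (ev$type[r] == "exchange") {
        sel_l <- gene_order$genome == ev$loser[r] &
          chr_idx[gene_order$i] == ev$chromosome[r] &
          ord[gene_order$i] >= ev$start_ordinal[r] &
          ord[gene_order$i] < ev$end_ordinal[r]
        prev <- cn[sel_l, ev$accession_id[r]]
        if (any(prev != 1 & prev != 0)) {
          stop("overlapping contradictory events on one span", call. = FALSE)
        }
        cn[sel_l, ev$accession_id[r]] <- 0
      }
    }
  }

  base_gene <- baseline[grp_ids[gene_order$i]]  # per gene, shared in group
  true_rpkm <- cn * base_gene  # gene x accession expectation, RPKM scale

  samples <- sheet$sample_id
  acc_of <- match(sheet$accession_id, accs)
  expect_rpkm <- true_rpkm[, acc_of, drop = FALSE]
  colnames(expect_rpkm) <- samples
  len_kb <- gene_order$length / 1000
  lib_m <- rep(cfg$library_size / 1e6, length(samples))

  noise <- switch(cfg$noise_model,
    none = matrix(1, nrow = length(genes), ncol = length(samples)),
    gaussian = matrix(pmax(stats::rnorm(length(genes) * length(samples), 1,
                                        cfg$noise_cv), 0),
                      nrow = length(genes)),
    poisson = {
      sdl <- sqrt(log(1 + cfg$noise_cv^2))
      matrix(stats::rlnorm(length(genes) * length(samples), -sdl^2 / 2, sdl),
             nrow = length(genes))
    })
  mu <- expect_rpkm * noise
  counts <- switch(cfg$noise_model,
    poisson = {
      lam <- mu * len_kb * rep(lib_m, each = length(genes))
      matrix(stats::rpois(length(lam), lam), nrow = length(genes))
    },
    mu * len_kb * rep(lib_m, each = length(genes))
  )
  dimnames(counts) <- list(genes, samples)

  truth <- truth_table(cfg, grp_ids, chr_idx, ord, accs, cn, gene_order)

  structure(list(
    groups = groups,
    gene_order = order_table,
    counts = counts,
    lengths = stats::setNames(gene_order$length, genes),
    aligned_totals = stats::setNames(rep(cfg$library_size, length(samples)),
                                     samples),
    sample_sheet = sheet,
    truth = truth,
    baseline = baseline,
    true_rpkm = true_rpkm,
    config = cfg
  ), class = "he_simulation")
}

# truth categories implied by the planted copy numbers
truth_table <- function(cfg, grp_ids, chr_idx, ord, accs, cn, gene_order) {
  first <- gene_order$genome == cfg$genomes[1L]
  per_genome <- lapply(cfg$genomes, function(g) {
    cn[gene_order$genome == g, , drop = FALSE]
  })
  names(per_genome) <- cfg$genomes
  out <- tidyr::expand_grid(group = seq_along(grp_ids), accession_id = accs)
  out$group_id <- grp_ids[out$group]
  out$chromosome <- paste0(cfg$ordering_genome, chr_idx[out$group])
  out$ordinal <- ord[out$group]
  ai <- match(out$accession_id, accs)
  dirs <- matrix("null", nrow = nrow(out), ncol = length(cfg$genomes))
  colnames(dirs) <- cfg$genomes
  for (g in cfg$genomes) {
    cng <- per_genome[[g]][cbind(out$group, ai)]
    out[[paste0("cn_", g)]] <- cng
    dirs[cng > 1, g] <- "high"
    dirs[cng < 1, g] <- "low"
  }
  if (length(cfg$genomes) == 2L) {
    out$category <- classify_group(dirs[, 1L], dirs[, 2L], cfg$genomes)
  } else {
    out$category <- apply(dirs, 1L, function(d) classify_triplet(d))
  }
  dplyr::select(out, -"group")
}

#' Build the RPKM panel of a simulation
#'
#' Convenience wrapper: [compute_rpkm()] on the simulated counts,
#' wrapped into an [expression_panel()].
#'
#' @param sim An `he_simulation` from [simulate_panel()].
#' @param assay Panel assay label (default `"mrnaseq"`).
#' @return An [expression_panel()].
#' @export
simulated_panel_rpkm <- function(sim, assay = "mrnaseq") {
  rpkm <- compute_rpkm(sim$counts, sim$lengths, sim$aligned_totals)
  sheet <- sim$sample_sheet
  sheet$assay <- assay
  expression_panel(rpkm, sheet, assay)
}

#' Simulate a DNA-coverage panel matched to a simulation's truth
#'
#' Produces the low-pass resequencing counterpart of a simulated mRNAseq
#' panel: per-gene coverage proportional to the same planted copy
#' numbers, with the chosen noise model, mirroring the accession and
#' replicate structure of the expression panel so the two assay modes
#' traverse identical downstream code paths.
#'
#' @param sim An `he_simulation`.
#' @param depth_rpkm Coverage level (RPKM scale) of a single-copy gene
#'   (default 5).
#' @param replicates Sequenced individuals per accession (default the
#'   simulation's replicate count).
#' @return An [expression_panel()] with `assay = "dnaseq"`.
#' @export
simulate_coverage_panel <- function(sim, depth_rpkm = 5,
                                    replicates = sim$config$replicates) {
  cfg <- sim$config
  genes <- rownames(sim$counts)
  accs <- colnames(sim$true_rpkm)
  # copy number = expectation / baseline
  grp_of_gene <- sim$groups$group_id[match(genes, sim$groups$gene_id)]
  cn <- sweep(sim$true_rpkm, 1L, sim$baseline[grp_of_gene], "/")
  mu <- (cn * depth_rpkm)[, rep(seq_along(accs), each = replicates),
                          drop = FALSE]
  noise <- switch(cfg$noise_model,
    none = matrix(1, nrow = nrow(mu), ncol = ncol(mu)),
    matrix(withr::with_seed(cfg$seed + 1L,
      stats::rlnorm(length(mu), -log(1 + cfg$noise_cv^2) / 2,
                    sqrt(log(1 + cfg$noise_cv^2)))), nrow = nrow(mu)))
  vals <- mu * noise
  sheet <- tidyr::expand_grid(accession_id = accs,
                              replicate = seq_len(replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$accession_id, "_dna",
                                     .data$replicate),
                  assay = "dnaseq", is_control = FALSE) |>
    dplyr::select("sample_id", "accession_id", "replicate", "assay",
                  "is_control")
  colnames(vals) <- sheet$sample_id
  rownames(vals) <- genes
  expression_panel(vals, sheet, "dnaseq")
}

#' Simulate reciprocal alignment tables for homoeologue pairing
#'
#' Emits the two alignment tables (each genome queried against the
#' other) whose reciprocal best hits recover the true pairs: strong
#' mutual hits for every group (E-values well below 1e-30), optional
#' weaker decoy cross-hits, and an optional set of groups whose
#' reciprocity is deliberately broken (the reverse-direction best hit
#' points at a different gene), which must then be absent from RBH
#' output.
#'
#' @param groups Long two-genome homoeologue-group tibble.
#' @param decoy_fraction Fraction of pairs receiving an extra weaker
#'   decoy hit (default 0).
#' @param n_break Number of pairs whose reciprocity is broken.
#' @param seed Seed for decoy placement.
#' @return A list: `hits_ab`, `hits_ba`, `true_pairs` (tibble `gene_a`,
#'   `gene_b` of recoverable pairs), `broken_pairs`.
#' @export
simulate_alignment_tables <- function(groups, decoy_fraction = 0,
                                      n_break = 0L, seed = 1L) {
  genomes <- sort(unique(groups$genome))
  stopifnot(length(genomes) == 2L)
  wide <- groups |>
    dplyr::select("group_id", "genome", "gene_id") |>
    tidyr::pivot_wider(names_from = "genome", values_from = "gene_id")
  a <- wide[[genomes[1L]]]
  b <- wide[[genomes[2L]]]
  n <- length(a)
  withr::with_seed(seed, {
    ev <- 10^-stats::runif(n, 60, 180)
    bs <- round(stats::runif(n, 500, 2000))
    hit_row <- function(q, s, evalue, bitscore) {
      tibble::tibble(query = q, subject = s, pident = 95, length = 500,
                     mismatch = 10, gapopen = 1, qstart = 1, qend = 500,
                     sstart = 1, send = 500, evalue = evalue,
                     bitscore = bitscore)
    }
    ab <- hit_row(a, b, ev, bs)
    ba <- hit_row(b, a, ev, bs)
    if (decoy_fraction > 0 && n > 1L) {
      k <- floor(decoy_fraction * n)
      if (k > 0L) {
        di <- sample(n, k)
        dj <- vapply(di, function(i) sample(setdiff(seq_len(n), i), 1L),
                     integer(1L))
        ab <- dplyr::bind_rows(ab, hit_row(a[di], b[dj], pmin(ev[di] * 1e10, 1e-31),
                                           bs[di] - 100))
        ba <- dplyr::bind_rows(ba, hit_row(b[di], a[dj], pmin(ev[di] * 1e10, 1e-31),
                                           bs[di] - 100))
      }
    }
    broken <- integer(0)
    if (n_break > 0L && n > 1L) {
      broken <- sample(n, min(n_break, n - 1L))
      for (i in broken) {
        j <- if (i < n) i + 1L else 1L
        # b[i]'s best hit now points at a[j], breaking reciprocity for pair i
        ba <- dplyr::bind_rows(ba, hit_row(b[i], a[j], ev[i] / 1e10, bs[i] + 200))
      }
    }
  })
  list(hits_ab = ab, hits_ba = ba,
       true_pairs = tibble::tibble(gene_a = a[setdiff(seq_len(n), broken)],
                                   gene_b = b[setdiff(seq_len(n), broken)]),
       broken_pairs = tibble::tibble(gene_a = a[broken], gene_b = b[broken]))
}

#' Parental single-genome control profiles
#'
#' One pseudo-sample per parent species, expressing only its own genome's
#' homoeologue members at the group baseline and the other members at 0 —
#' the single-genome control rows of a tile plot (pure cyan / magenta /
#' yellow), whose in-silico combination renders the balanced colour.
#'
#' @param sim An `he_simulation`.
#' @return A genes x parents matrix with columns `parent_<genome>`.
#' @export
make_parental_controls <- function(sim) {
  genes <- rownames(sim$counts)
  grp_of_gene <- sim$groups$group_id[match(genes, sim$groups$gene_id)]
  genome_of_gene <- sim$groups$genome[match(genes, sim$groups$gene_id)]
  base <- sim$baseline[grp_of_gene]
  out <- vapply(sim$config$genomes, function(g) {
    ifelse(genome_of_gene == g, base, 0)
  }, numeric(length(genes)))
  rownames(out) <- genes
  colnames(out) <- paste0("parent_", sim$config$genomes)
  out
}

#' Preset simulation scenarios
#'
#' Ready-made configurations mirroring the study designs the simulator
#' emulates: `napus_panel` (2 genomes, replicated variety panel with a
#' handful of segmental exchanges, one telomeric hotspot shared by ~30%
#' of accessions), `juncea_panel` (2 genomes, rarer internal exchanges),
#' `wheat_triplet` (3 genomes, one exchange plus one aneuploid line),
#' `dh_population` (2 genomes, elevated exchange rate as in doubled
#' haploids).
#'
#' @param name Preset name.
#' @param seed Seed.
#' @return A `sim_config`.
#' @export
preset_config <- function(name = c("napus_panel", "juncea_panel",
                                   "wheat_triplet", "dh_population"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
    napus_panel = {
      cfg <- simulation_config(genomes = c("A", "C"), n_chromosomes = 3L,
                               genes_per_chromosome = 200L,
                               n_accessions = 20L, seed = seed,
                               ordering_genome = "C")
      # telomeric hotspot on chromosome 1: ~30% of accessions share it
      for (acc in c(1L, 4L, 7L, 10L, 13L, 16L)) {
        cfg <- add_event(cfg, acc, 1L, 170L, 200L, "exchange", gainer = "A")
      }
      cfg <- add_event(cfg, 2L, 2L, 40L, 80L, "exchange", gainer = "C")
      cfg <- add_event(cfg, 3L, 3L, 0L, 30L, "exchange", gainer = "A")
      cfg <- add_event(cfg, 5L, 2L, 100L, 130L, "duplication", gainer = "A")
      cfg <- add_event(cfg, 6L, 3L, 60L, 90L, "deletion", gainer = "C")
      cfg
    },
    juncea_panel = {
      cfg <- simulation_config(genomes = c("A", "B"), n_chromosomes = 3L,
                               genes_per_chromosome = 200L,
                               n_accessions = 20L, seed = seed,
                               ordering_genome = "A")
      cfg <- add_event(cfg, 3L, 2L, 90L, 115L, "exchange", gainer = "A")
      cfg <- add_event(cfg, 11L, 1L, 50L, 70L, "exchange", gainer = "B")
      cfg
    },
    wheat_triplet = {
      cfg <- simulation_config(genomes = c("A", "B", "D"), n_chromosomes = 2L,
                               genes_per_chromosome = 150L,
                               n_accessions = 12L, seed = seed,
                               ordering_genome = "A")
      cfg <- add_event(cfg, 2L, 1L, 100L, 150L, "exchange", gainer = "A",
                       loser = "B")
      cfg <- add_event(cfg, 4L, 2L, type = "whole_chromosome_gain", gainer = "B")
      cfg <- add_event(cfg, 7L, 2L, type = "whole_chromosome_loss", gainer = "A")
      cfg
    },
    dh_population = {
      cfg <- simulation_config(genomes = c("A", "B"), n_chromosomes = 3L,
                               genes_per_chromosome = 150L,
                               n_accessions = 24L, seed = seed,
                               ordering_genome = "A")
      set.seed(seed)
      for (acc in seq_len(24L)) {
        if (stats::runif(1) < 0.5) {
          chr <- sample(3L, 1L)
          s <- sample(0:120, 1L)
          cfg <- add_event(cfg, acc, chr, s, s + sample(20:30, 1L),
                           "exchange",
                           gainer = sample(c("A", "B"), 1L))
        }
      }
      cfg
    })
}

#' Write a simulation to fixture files
#'
#' Emits exactly the file formats the readers consume: counts, lengths,
#' aligned totals, sample sheet, gene order, groups and truth TSVs.
#' Byte-identical for identical seeds.
#'
#' @param sim An `he_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    totals = file.path(dir, "aligned_totals.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gene_order = file.path(dir, "gene_order.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_matrix(sim$counts, paths[["counts"]])
  readr::write_tsv(tibble::tibble(gene_id = names(sim$lengths),
                                  length = unname(sim$lengths)),
                   paths[["lengths"]])
  readr::write_tsv(tibble::tibble(sample_id = names(sim$aligned_totals),
                                  aligned_total = unname(sim$aligned_totals)),
                   paths[["totals"]])
  readr::write_tsv(sim$sample_sheet, paths[["samples"]])
  readr::write_tsv(sim$gene_order, paths[["gene_order"]])
  write_groups_tsv(sim$groups, paths[["groups"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
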