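#' Assemble a run configuration
#'
#' Collects input paths and thresholds for [run_pipeline()], applying
#' mode-consistent defaults: E-value 1e-30 for pairing, low-abundance
#' threshold 0.4 mean RPKM (mRNAseq) or 0.01 (DNA coverage), t-test
#' alpha 0.01, block calling min_run 10 / max_gap 2.
#'
#' @param counts,lengths,aligned_totals Paths for the count route, or
#' @param rpkm Path to a ready RPKM matrix (skips [compute_rpkm()]).
#' @param sample_sheet,gene_order Paths (required).
#' @param groups Path to a precomputed groups TSV, or
#' @param alignment_ab,alignment_ba Paths to the two reciprocal
#'   alignment tables (then pairing is run).
#' @param genomes Genome labels (pairing route only).
#' @param ordering_genome Genome anchoring plot/block order.
#' @param mode `"mrnaseq"` or `"dnaseq"`.
#' @param max_evalue,min_mean_rpkm,alpha,min_run,max_gap Thresholds
#'   (`min_mean_rpkm = NULL` picks the mode default).
#' @param channel_map Named genome -> channel vector (default cyan,
#'   magenta, yellow in genome sort order).
#' @param seed Seed recorded in the resolved config.
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, lengths = NULL, aligned_totals = NULL,
                       rpkm = NULL, sample_sheet, gene_order,
                       groups = NULL, alignment_ab = NULL,
                       alignment_ba = NULL, genomes = c("A", "C"),
                       ordering_genome = genomes[1L],
                       mode = c("mrnaseq", "dnaseq"),
                       max_evalue = 1e-30, min_mean_rpkm = NULL,
                       alpha = 0.01, min_run = 10L, max_gap = 2L,
                       channel_map = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, max_evalue > 0, min_run >= 1)
  cfg <- list(counts = counts, lengths = lengths,
              aligned_totals = aligned_totals, rpkm = rpkm,
              sample_sheet = sample_sheet, gene_order = gene_order,
              groups = groups, alignment_ab = alignment_ab,
              alignment_ba = alignment_ba, genomes = genomes,
              ordering_genome = ordering_genome, mode = mode,
              max_evalue = max_evalue, min_mean_rpkm = min_mean_rpkm,
              alpha = alpha, min_run = as.integer(min_run),
              max_gap = as.integer(max_gap), channel_map = channel_map,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full homoeologous-exchange pipeline
#'
#' Orchestrates pair -> quantify -> filter -> classify -> plot ->
#' callblocks on file inputs and writes every stage output plus an audit
#' log (genes/groups in and out of every filter) into `out_dir`:
#' `groups.tsv`, `rpkm.tsv`, `calls.tsv`, the over/under/exchange
#' sub-tables, `blocks.tsv`/`blocks.bed`, `frequency.tsv`,
#' `aneuploidy.tsv`, `tdtp.png`, `tdtp_tiles.tsv`, `summary.json` and
#' `config_resolved.yaml`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory stage results
#'   (`groups`, `panel`, `calls`, `blocks`, `frequency`, `aneuploidy`,
#'   `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  order_table <- with_stage("gene_order", read_gene_order(config$gene_order))
  sheet <- with_stage("sample_sheet", read_sample_sheet(config$sample_sheet))

  groups <- with_stage("pair", {
    if (!is.null(config$groups)) {
      g <- read_groups_tsv(config$groups)
      if (!all(c("chromosome", "ordinal") %in% names(g))) {
        g <- attach_order(g, order_table, config$ordering_genome)
      } else {
        attr(g, "ordering_genome") <- config$ordering_genome
      }
      g
    } else if (!is.null(config$alignment_ab)) {
      ab <- read_alignment_table(config$alignment_ab)
      ba <- read_alignment_table(config$alignment_ba)
      pairs <- reciprocal_best_pairs(ab, ba, config$max_evalue)
      log$n_pairs <- nrow(pairs)
      g <- as_homoeolog_groups(pairs, config$genomes)
      attach_order(g, order_table, config$ordering_genome)
    } else {
      stop("config needs either 'groups' or alignment tables")
    }
  })
  log$n_groups_paired <- dplyr::n_distinct(groups$group_id)
  log$n_groups_unplaced <- attr(groups, "n_unplaced")

  panel <- with_stage("quantify", {
    if (!is.null(config$rpkm)) {
      vals <- read_expression_matrix(config$rpkm)
    } else {
      counts <- read_expression_matrix(config$counts)
      lengths <- readr::read_tsv(config$lengths, show_col_types = FALSE)
      totals <- readr::read_tsv(config$aligned_totals, show_col_types = FALSE)
      vals <- compute_rpkm(counts, lengths, totals)
    }
    expression_panel(vals, sheet, config$mode)
  })
  log$n_genes_quantified <- nrow(panel$values)
  log$n_samples <- ncol(panel$values)

  filt <- with_stage("filter", {
    filter_low_expression(panel, groups, config$min_mean_rpkm)
  })
  groups_kept <- filt$retained
  log$low_expression_threshold <- filt$threshold
  log$n_groups_removed_low_expression <-
    dplyr::n_distinct(filt$removed$group_id)
  log$n_groups_retained <- dplyr::n_distinct(groups_kept$group_id)

  calls <- with_stage("classify", {
    classify_panel(panel, groups_kept, alpha = config$alpha)
  })
  readr::write_tsv(tibble::as_tibble(calls), file.path(out_dir, "calls.tsv"))
  sub <- dosage_subtables(calls)
  readr::write_tsv(tibble::as_tibble(sub$over_expressed),
                   file.path(out_dir, "over_expressed.tsv"))
  readr::write_tsv(tibble::as_tibble(sub$under_expressed),
                   file.path(out_dir, "under_expressed.tsv"))
  readr::write_tsv(tibble::as_tibble(sub$exchanges),
                   file.path(out_dir, "exchanges.tsv"))
  log$n_calls <- nrow(calls)
  log$n_exchange_calls <- nrow(sub$exchanges)

  with_stage("plot", {
    norm <- normalize_abundance(panel)
    spec <- encode_cmyk(norm, groups_kept, channel_map = config$channel_map)
    render_tdtp(spec, file.path(out_dir, "tdtp.png"), tile_w = 2L,
                tile_h = 2L)
    write_tdtp_tsv(spec, file.path(out_dir, "tdtp_tiles.tsv"))
  })

  blocks <- with_stage("callblocks", {
    call_blocks(calls, min_run = config$min_run, max_gap = config$max_gap)
  })
  readr::write_tsv(blocks, file.path(out_dir, "blocks.tsv"))
  write_he_blocks_bed(blocks, file.path(out_dir, "blocks.bed"))
  log$n_blocks <- nrow(blocks)

  accs <- unique(sheet$accession_id[!sheet$is_control])
  freq <- with_stage("frequency", he_frequency(blocks, groups_kept, accs))
  readr::write_tsv(freq, file.path(out_dir, "frequency.tsv"))
  aneu <- with_stage("aneuploidy", aneuploidy_screen(calls))
  readr::write_tsv(aneu, file.path(out_dir, "aneuploidy.tsv"))
  log$n_aneuploidy_flags <- nrow(aneu)

  resolved <- config
  resolved$min_mean_rpkm <- filt$threshold
  yaml::write_yaml(unclass(resolved), file.path(out_dir, "config_resolved.yaml"))
  jsonlite::write_json(log, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(groups = groups_kept, panel = panel, calls = calls,
                 blocks = blocks, frequency = freq, aneuploidy = aneu,
                 log = log))
}

#' One-command demo on a generated fixture
#'
#' Simulates a replicated two-genome variety panel with planted
#' exchanges (the `napus_panel` preset), writes its fixture files, and
#' runs the full pipeline on them.
#'
#' @param out_dir Output directory.
#' @param seed Seed for the simulation.
#' @param preset Preset name for [preset_config()].
#' @return Invisibly, the [run_pipeline()] result.
#' @export
run_demo <- function(out_dir, seed = 1L, preset = "napus_panel") {
  cfg <- preset_config(preset, seed = seed)
  sim <- simulate_panel(cfg)
  fixture_dir <- file.path(out_dir, "fixture")
  paths <- write_simulation_files(sim, fixture_dir)
  rc <- run_config(
    counts = paths[["counts"]], lengths = paths[["lengths"]],
    aligned_totals = paths[["totals"]], sample_sheet = paths[["samples"]],
    gene_order = paths[["gene_order"]], groups = paths[["groups"]],
    genomes = cfg$genomes, ordering_genome = cfg$ordering_genome,
    seed = seed
  )
  run_pipeline(rc, out_dir)
}
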