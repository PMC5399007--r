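#' Call contiguous homoeologous-exchange blocks
#'
#' Segments each accession's per-group dosage calls into maximal runs of
#' concordant exchange calls along each chromosome (run-length smoothing
#' over the categorical calls — the simplest auditable rule). Two
#' concordant genes belong to the same run when at most `max_gap`
#' non-concordant genes lie between them; a run is reported as a block
#' when it contains at least `min_run` concordant genes. Blocks never
#' span chromosomes. Block coordinates are 0-based half-open ordinal
#' spans on the ordering genome; `support` is the fraction of genes in
#' the span carrying the block's call.
#'
#' @param calls A `dosage_calls` tibble from [classify_panel()], ordered
#'   by (chromosome, ordinal) within each accession (as produced);
#'   unordered input is an error.
#' @param min_run Minimum concordant genes per block (default 10).
#' @param max_gap Maximum interruptions tolerated between concordant
#'   genes (default 2).
#' @return A tibble of blocks: `accession_id`, `chromosome`,
#'   `start_ordinal`, `end_ordinal`, `direction`, `n_genes`, `support`.
#' @export
call_blocks <- function(calls, min_run = 10L, max_gap = 2L) {
  need <- c("accession_id", "chromosome", "ordinal", "category")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- tibble::as_tibble(calls)[, need]
  ordered <- df |>
    dplyr::group_by(.data$accession_id, .data$chromosome) |>
    dplyr::summarise(ok = !is.unsorted(.data$ordinal), .groups = "drop")
  if (!all(ordered$ok)) {
    stop("calls must be ordered by (chromosome, ordinal) within accession",
         call. = FALSE)
  }
  df |>
    dplyr::group_by(.data$accession_id, .data$chromosome) |>
    dplyr::group_modify(~ scan_blocks(.x, min_run, max_gap)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$accession_id, .data$chromosome, .data$start_ordinal)
}

# Run scan over one accession x chromosome call sequence.
scan_blocks <- function(d, min_run, max_gap) {
  out <- list()
  dirs <- unique(d$category[startsWith(d$category, "Exchange")])
  for (dir in dirs) {
    idx <- which(d$category == dir)
    if (length(idx) == 0L) next
    # split concordant indices where more than max_gap other genes intervene
    brk <- which(diff(idx) - 1L > max_gap)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(idx))
    for (j in seq_along(starts)) {
      members <- idx[starts[j]:ends[j]]
      if (length(members) < min_run) next
      span <- members[1L]:members[length(members)]
      out[[length(out) + 1L]] <- tibble::tibble(
        start_ordinal = d$ordinal[members[1L]],
        end_ordinal = d$ordinal[members[length(members)]] + 1L,
        direction = dir,
        n_genes = length(members),
        support = length(members) / length(span)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start_ordinal = integer(), end_ordinal = integer(),
                          direction = character(), n_genes = integer(),
                          support = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Panel-wide homoeologous-exchange frequency per position
#'
#' For every homoeologue-group position (ordering-genome chromosome and
#' ordinal), counts the accessions whose exchange blocks cover it, split
#' by exchange direction, and reports the covering fraction of the panel.
#' Positions covered by a block touching either chromosome end (ordinal 0
#' or the last ordinal — the gene-order proxies for telomeres) are
#' flagged `telomeric`. The attribute `direction_bias` summarizes, per
#' ordered genome pair, the total block-gene counts gaining each genome.
#'
#' @param blocks Blocks from [call_blocks()] over the full panel.
#' @param groups Ordered homoeologue-group tibble (defines the position
#'   grid).
#' @param panel_accessions Character vector of all panel accessions (the
#'   denominator for fractions).
#' @return A tibble: `chromosome`, `ordinal`, `group_id`, `direction`,
#'   `count`, `fraction`, `telomeric`; one row per position per observed
#'   direction (direction `NA`, count 0 when no blocks exist at all).
#' @export
he_frequency <- function(blocks, groups, panel_accessions) {
  grid <- groups |>
    dplyr::distinct(.data$chromosome, .data$ordinal, .data$group_id) |>
    dplyr::arrange(.data$chromosome, .data$ordinal)
  chrom_last <- grid |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(last_ordinal = max(.data$ordinal), .groups = "drop")
  n_acc <- length(unique(panel_accessions))
  if (nrow(blocks) == 0L) {
    out <- grid |>
      dplyr::mutate(direction = NA_character_, count = 0L, fraction = 0,
                    telomeric = FALSE)
    attr(out, "direction_bias") <- tibble::tibble(direction = character(),
                                                  block_genes = integer())
    return(out)
  }
  blk <- blocks |>
    dplyr::left_join(chrom_last, by = "chromosome") |>
    dplyr::mutate(touches_end = .data$start_ordinal == 0L |
                    .data$end_ordinal - 1L >= .data$last_ordinal)
  cover <- blk |>
    dplyr::mutate(ordinal = purrr::map2(.data$start_ordinal,
                                        .data$end_ordinal - 1L, seq.int)) |>
    tidyr::unnest("ordinal") |>
    dplyr::select("accession_id", "chromosome", "direction",
                  telomeric = "touches_end", "ordinal") |>
    dplyr::distinct()
  counts <- cover |>
    dplyr::group_by(.data$chromosome, .data$ordinal, .data$direction) |>
    dplyr::summarise(count = dplyr::n_distinct(.data$accession_id),
                     telomeric = any(.data$telomeric), .groups = "drop")
  out <- tidyr::expand_grid(grid,
                            direction = sort(unique(blocks$direction))) |>
    dplyr::left_join(counts, by = c("chromosome", "ordinal", "direction")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  telomeric = dplyr::coalesce(.data$telomeric, FALSE),
                  fraction = .data$count / n_acc) |>
    dplyr::select("chromosome", "ordinal", "group_id", "direction", "count",
                  "fraction", "telomeric") |>
    dplyr::arrange(.data$chromosome, .data$ordinal, .data$direction)
  bias <- blocks |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(block_genes = sum(.data$n_genes), .groups = "drop")
  attr(out, "direction_bias") <- bias
  out
}

#' Screen for whole-chromosome aneuploidy
#'
#' Flags a chromosome-scale gain or loss of one subgenome copy in an
#' accession when at least `min_fraction` of the chromosome's homoeologue
#' groups carry the same single-genome duplication or deletion category.
#'
#' @param calls A `dosage_calls` tibble from [classify_panel()].
#' @param min_fraction Fraction of a chromosome's groups that must agree
#'   (default 0.8).
#' @return A tibble: `accession_id`, `chromosome`, `genome`, `event`
#'   (`"gain"`/`"loss"`), `fraction`, `n_groups`.
#' @export
aneuploidy_screen <- function(calls, min_fraction = 0.8) {
  genomes <- attr(calls, "genomes")
  if (is.null(genomes)) {
    stop("calls must carry a 'genomes' attribute (from classify_panel)",
         call. = FALSE)
  }
  per_chr <- tibble::as_tibble(calls) |>
    dplyr::group_by(.data$accession_id, .data$chromosome)
  out <- list()
  for (g in genomes) {
    dup_lab <- paste0("Duplication ", g)
    del_lab <- paste0("Deletion ", g)
    fr <- per_chr |>
      dplyr::summarise(
        n_groups = dplyr::n(),
        gain = mean(.data$category == dup_lab),
        loss = mean(.data$category == del_lab),
        .groups = "drop"
      )
    gains <- fr |>
      dplyr::filter(.data$gain >= min_fraction) |>
      dplyr::transmute(.data$accession_id, .data$chromosome, genome = g,
                       event = "gain", fraction = .data$gain, .data$n_groups)
    losses <- fr |>
      dplyr::filter(.data$loss >= min_fraction) |>
      dplyr::transmute(.data$accession_id, .data$chromosome, genome = g,
                       event = "loss", fraction = .data$loss, .data$n_groups)
    out[[g]] <- dplyr::bind_rows(gains, losses)
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$accession_id, .data$chromosome, .data$genome)
}
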