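#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy dosage calls into one row per direction test
#'
#' Unpivots the per-genome columns of a `dosage_calls` table back into
#' long form: one row per (group, accession, genome) with the test's
#' mean, reference mean, p-value, direction and degenerate flag.
#'
#' @param x A `dosage_calls` tibble from [classify_panel()].
#' @param ... Unused.
#' @return A long tibble.
#' @method tidy dosage_calls
#' @export
tidy.dosage_calls <- function(x, ...) {
  genomes <- attr(x, "genomes")
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = dplyr::matches(paste0("^(mean|panel_mean|p|direction|degenerate)_(",
                                   paste(genomes, collapse = "|"), ")$")),
      names_to = c(".value", "genome"),
      names_pattern = "^(mean|panel_mean|p|direction|degenerate)_(.+)$"
    ) |>
    dplyr::rename(accession_mean = "mean", p_value = "p")
}

#' Summarize a dosage-call table
#'
#' @param x A `dosage_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble: numbers of groups, accessions and calls,
#'   the alpha used, the fraction of non-"No difference" calls, and the
#'   count of exchange calls.
#' @method glance dosage_calls
#' @export
glance.dosage_calls <- function(x, ...) {
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$group_id),
    n_accessions = dplyr::n_distinct(x$accession_id),
    n_calls = nrow(x),
    alpha = attr(x, "alpha"),
    frac_changed = mean(x$category != "No difference"),
    n_exchange_calls = sum(startsWith(x$category, "Exchange"))
  )
}

#' Plot per-accession dosage categories along the genome
#'
#' Tile map of dosage categories (x = gene order, y = accession),
#' facetted by chromosome — a categorical companion to the continuous
#' CMYK tile plot.
#'
#' @param object A `dosage_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dosage_calls
#' @export
autoplot.dosage_calls <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ordinal, y = .data$accession_id,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_brewer(palette = "Set1", na.value = "grey90") +
    ggplot2::labs(x = "gene order (ordinal)", y = NULL, fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Plot panel-wide exchange frequency along the genome
#'
#' @param object An `he_frequency` table (tibble from [he_frequency()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_he_frequency <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ordinal, y = .data$fraction,
                                       colour = .data$direction)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "gene order (ordinal)",
                  y = "fraction of accessions with HE") +
    ggplot2::theme_minimal()
}
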