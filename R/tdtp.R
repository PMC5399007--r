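#' Normalize abundance to [0, 1] across the plotted population
#'
#' Each member gene is scaled independently across all plotted samples by
#' dividing by its maximum: the sample with the highest abundance gets 1
#' (darkest colour), zeros stay 0 (a deleted copy stays white), and the
#' rendition is purely relative within each homoeologue — scaling a
#' gene's RPKM by any constant leaves its colours unchanged. A
#' percentile-capped variant (`method = "quantile"`) divides by an upper
#' quantile and clips to 1, to resist single-sample outliers.
#'
#' @param values Genes x samples abundance matrix, or an
#'   [expression_panel()] (all columns, controls included, are plotted).
#' @param method `"max"` (default) or `"quantile"`.
#' @param cap_quantile Upper quantile used when `method = "quantile"`
#'   (default 0.99).
#' @return A matrix of the same shape with values in [0, 1].
#' @export
normalize_abundance <- function(values, method = c("max", "quantile"),
                                cap_quantile = 0.99) {
  method <- match.arg(method)
  if (inherits(values, "expression_panel")) values <- values$values
  ref <- switch(method,
    max = apply(values, 1L, max),
    quantile = apply(values, 1L, stats::quantile, probs = cap_quantile,
                     names = FALSE)
  )
  ref[ref <= 0] <- 1  # all-zero genes map to all-zero rows
  out <- pmin(values / ref, 1)
  out
}

#' Encode normalized subgenome abundance as CMYK tiles
#'
#' Binds each genome to one CMYK channel (default: first genome to cyan,
#' second to magenta, third to yellow — so balanced pairs render blue and
#' balanced triplets render grey) and builds the per-tile channel table
#' for a Transcriptome Display Tile Plot: one tile per (group, sample),
#' channel value = that genome's normalized abundance, unmapped channels
#' and K fixed at 0.
#'
#' @param normalized Genes x samples matrix in [0, 1] from
#'   [normalize_abundance()].
#' @param groups Ordered long homoeologue-group tibble (with `chromosome`
#'   and `ordinal` from [attach_order()]).
#' @param channel_map Named character vector genome -> channel, e.g.
#'   `c(A = "cyan", C = "magenta")`; must be injective. Default assigns
#'   cyan/magenta/yellow in genome sort order.
#' @param sample_order Optional character vector of sample columns to
#'   plot, in row order (default: all columns of `normalized`).
#' @return A `tdtp_spec` tibble: `group_id`, `chromosome`, `ordinal`,
#'   `sample_id`, `c`, `m`, `y`, `k`; attributes `channel_map`,
#'   `column_order` (group/chromosome/ordinal tibble), `row_order`.
#' @export
encode_cmyk <- function(normalized, groups, channel_map = NULL,
                        sample_order = NULL) {
  genomes <- sort(unique(groups$genome))
  if (is.null(channel_map)) {
    channel_map <- stats::setNames(c("cyan", "magenta", "yellow")[seq_along(genomes)],
                                   genomes)
  }
  if (anyDuplicated(channel_map) || !all(channel_map %in% c("cyan", "magenta", "yellow"))) {
    stop("channel_map must map each genome to a distinct channel among cyan/magenta/yellow",
         call. = FALSE)
  }
  if (!all(genomes %in% names(channel_map))) {
    stop("channel_map lacks genome(s): ",
         paste(setdiff(genomes, names(channel_map)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("chromosome", "ordinal") %in% names(groups))) {
    stop("groups need chromosome/ordinal; run attach_order() first", call. = FALSE)
  }
  if (is.null(sample_order)) sample_order <- colnames(normalized)
  long <- groups |>
    dplyr::mutate(channel = unname(channel_map[.data$genome])) |>
    dplyr::select("group_id", "chromosome", "ordinal", "gene_id", "channel")
  tiles <- tidyr::expand_grid(
    dplyr::distinct(long, .data$group_id, .data$chromosome, .data$ordinal),
    sample_id = sample_order
  )
  vals <- long |>
    dplyr::inner_join(
      tibble::tibble(
        gene_id = rep(rownames(normalized), times = length(sample_order)),
        sample_id = rep(sample_order, each = nrow(normalized)),
        value = as.vector(normalized[, sample_order, drop = FALSE])
      ),
      by = "gene_id"
    ) |>
    tidyr::pivot_wider(id_cols = c("group_id", "sample_id"),
                       names_from = "channel", values_from = "value")
  for (ch in c("cyan", "magenta", "yellow")) {
    if (!ch %in% names(vals)) vals[[ch]] <- 0
  }
  spec <- tiles |>
    dplyr::inner_join(vals, by = c("group_id", "sample_id")) |>
    dplyr::rename(c = "cyan", m = "magenta", y = "yellow") |>
    dplyr::mutate(k = 0) |>
    dplyr::arrange(.data$chromosome, .data$ordinal,
                   match(.data$sample_id, sample_order))
  class(spec) <- c("tdtp_spec", class(spec))
  attr(spec, "channel_map") <- channel_map
  attr(spec, "column_order") <- dplyr::distinct(spec, .data$group_id,
                                                .data$chromosome, .data$ordinal)
  attr(spec, "row_order") <- sample_order
  spec
}

#' Convert CMYK channel values to RGB
#'
#' Standard subtractive conversion: `r = (1-c)(1-k)`, `g = (1-m)(1-k)`,
#' `b = (1-y)(1-k)`. Full cyan+magenta gives blue (the balanced-pair
#' colour); full cyan+magenta+yellow gives black, and equal mid-level
#' channels give the grey family (the balanced-triplet colours).
#'
#' @param c,m,y,k Channel values in [0, 1]; vectorized.
#' @return A numeric matrix with columns `r`, `g`, `b` in [0, 1].
#' @export
cmyk_to_rgb <- function(c, m, y, k = 0) {
  ch <- cbind(c = c, m = m, y = y, k = k)
  if (anyNA(ch) || any(ch < 0) || any(ch > 1)) {
    stop("CMYK channels must lie in [0, 1]", call. = FALSE)
  }
  cbind(r = (1 - ch[, "c"]) * (1 - ch[, "k"]),
        g = (1 - ch[, "m"]) * (1 - ch[, "k"]),
        b = (1 - ch[, "y"]) * (1 - ch[, "k"]))
}

# Pixel raster (H x W x 3 array) for a tile-plot spec. Used by both the
# PNG and SVG writers so the two formats agree exactly.
tdtp_raster <- function(spec, tile_w = 1L, tile_h = 1L, gap = 2L,
                        gap_colour = c(1, 1, 1), markers = NULL) {
  cols <- attr(spec, "column_order")
  rows <- attr(spec, "row_order")
  chrom <- cols$chromosome
  chrom_breaks <- which(chrom[-1L] != chrom[-length(chrom)])
  n_col <- nrow(cols)
  n_row <- length(rows)
  # x offset (pixels) of each tile column, inserting a gap at chromosome ends
  x0 <- (seq_len(n_col) - 1L) * tile_w +
    gap * findInterval(seq_len(n_col) - 1L, chrom_breaks)
  width <- x0[n_col] + tile_w
  height <- n_row * tile_h
  img <- array(rep(gap_colour, each = height * width), dim = c(height, width, 3L))
  rgb <- cmyk_to_rgb(spec$c, spec$m, spec$y, spec$k)
  ci <- match(spec$group_id, cols$group_id)
  ri <- match(spec$sample_id, rows)
  for (i in seq_len(nrow(spec))) {
    ys <- (ri[i] - 1L) * tile_h + seq_len(tile_h)
    xs <- x0[ci[i]] + seq_len(tile_w)
    img[ys, xs, 1L] <- rgb[i, "r"]
    img[ys, xs, 2L] <- rgb[i, "g"]
    img[ys, xs, 3L] <- rgb[i, "b"]
  }
  if (!is.null(markers) && nrow(markers) > 0L) {
    mi <- match(markers$group_id, cols$group_id)
    mi <- mi[!is.na(mi)]
    for (j in mi) {  # 1-px black marker line at the column's left edge
      x <- x0[j]
      if (x < 1L) x <- 1L
      img[, x, ] <- 0
    }
  }
  img
}

#' Render a Transcriptome Display Tile Plot
#'
#' Draws one tile per (homoeologue group, sample): columns are groups in
#' genome order with a visible gap at chromosome boundaries, rows are
#' samples in the supplied order (replicates adjacent per accession).
#' Output is deterministic: identical specs and options give identical
#' pixels (PNG) or bytes (SVG). Optional gene markers draw a 1-px black
#' vertical line at the marked group's position.
#'
#' @param spec A `tdtp_spec` from [encode_cmyk()].
#' @param path Output path ending in `.png` or `.svg`.
#' @param tile_w,tile_h Tile size in pixels (defaults 1 x 1).
#' @param gap Chromosome gap width in pixels (default 2).
#' @param markers Optional tibble with a `group_id` column (and
#'   optionally `label`) of positions to mark.
#' @return The path, invisibly.
#' @export
render_tdtp <- function(spec, path, tile_w = 1L, tile_h = 1L, gap = 2L,
                        markers = NULL) {
  if (nrow(spec) == 0L) stop("empty tile-plot spec", call. = FALSE)
  img <- tdtp_raster(spec, tile_w = tile_w, tile_h = tile_h, gap = gap,
                     markers = markers)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, target = path)
  } else if (ext == "svg") {
    write_raster_svg(img, path)
  } else {
    stop("unsupported image format: .", ext, " (use .png or .svg)", call. = FALSE)
  }
  invisible(path)
}

# Minimal deterministic SVG writer: one <rect> per pixel run per row.
write_raster_svg <- function(img, path) {
  h <- dim(img)[1L]
  w <- dim(img)[2L]
  hex <- grDevices::rgb(img[, , 1L], img[, , 2L], img[, , 3L])
  dim(hex) <- c(h, w)
  lines <- character(0)
  lines <- c(lines, sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" shape-rendering="crispEdges">',
    w, h))
  for (r in seq_len(h)) {
    row <- hex[r, ]
    runs <- rle(row)
    x <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
    keep <- runs$values != "#FFFFFF"  # white background left implicit
    if (any(keep)) {
      lines <- c(lines, sprintf(
        '<rect x="%d" y="%d" width="%d" height="1" fill="%s"/>',
        x[keep], r - 1L, runs$lengths[keep], runs$values[keep]))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-tile CMYK sidecar table
#'
#' @param spec A `tdtp_spec`.
#' @param path Output TSV path.
#' @export
write_tdtp_tsv <- function(spec, path) {
  readr::write_tsv(tibble::as_tibble(spec), path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tile-plot spec with ggplot2
#'
#' Convenience ggplot rendering of a `tdtp_spec` (the pixel-exact writer
#' is [render_tdtp()]): tiles coloured by their CMYK-derived RGB, columns
#' facetted by chromosome, rows in sample order.
#'
#' @param object A `tdtp_spec`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tdtp_spec
#' @export
autoplot.tdtp_spec <- function(object, ...) {
  rgb <- cmyk_to_rgb(object$c, object$m, object$y, object$k)
  df <- tibble::as_tibble(object)
  df$fill <- grDevices::rgb(rgb[, "r"], rgb[, "g"], rgb[, "b"])
  df$sample_id <- factor(df$sample_id, levels = rev(attr(object, "row_order")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ordinal, y = .data$sample_id,
                                   fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "gene order (ordinal)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}
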