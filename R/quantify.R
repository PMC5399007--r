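#' Expression panel container
#'
#' Bundles a genes-by-samples abundance matrix (RPKM for mRNAseq, coverage
#' RPKM for low-pass DNA resequencing) with its sample sheet. Columns must
#' match the sample sheet exactly and values must be non-negative.
#'
#' @param values Numeric genes x samples matrix (rownames = gene ids,
#'   colnames = sample ids).
#' @param sample_sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @param assay `"mrnaseq"` or `"dnaseq"`; governs default thresholds.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, sample_sheet,
                             assay = c("mrnaseq", "dnaseq")) {
  assay <- match.arg(assay)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    stop("values matrix must have gene rownames and sample colnames", call. = FALSE)
  }
  if (!setequal(colnames(values), sample_sheet$sample_id) ||
      ncol(values) != nrow(sample_sheet)) {
    stop("panel columns do not match the sample sheet", call. = FALSE)
  }
  values <- values[, sample_sheet$sample_id, drop = FALSE]
  if (any(values < 0)) stop("panel values must be non-negative", call. = FALSE)
  structure(
    list(values = values, sample_sheet = sample_sheet, assay = assay),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("<expression_panel> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$assay, "), ",
      dplyr::n_distinct(x$sample_sheet$accession_id[!x$sample_sheet$is_control]),
      " accessions\n", sep = "")
  invisible(x)
}

# Sample ids of the analysis population (controls excluded).
panel_samples <- function(panel) {
  panel$sample_sheet$sample_id[!panel$sample_sheet$is_control]
}

#' Compute RPKM from raw counts
#'
#' RPKM = reads per kilobase of gene model per million aligned reads:
#' `count / (length/1000) / (aligned_total/1e6)`. The aligned totals are
#' supplied by the caller (they are per-million *aligned* reads, which the
#' count matrix alone cannot reproduce); a column-sum fallback is available
#' behind `use_column_sums` for data without mapping statistics.
#'
#' @param counts Integer (or numeric) genes x samples matrix.
#' @param lengths Gene lengths in bp: named numeric vector or a tibble
#'   with columns `gene_id`, `length`.
#' @param aligned_totals Aligned reads per sample: named numeric vector or
#'   a tibble with columns `sample_id`, `aligned_total`. All must be > 0.
#' @param use_column_sums If `TRUE` and `aligned_totals` is `NULL`, use
#'   `colSums(counts)` as library sizes.
#' @return A numeric RPKM matrix with the same dimnames as `counts`.
#' @export
compute_rpkm <- function(counts, lengths, aligned_totals = NULL,
                         use_column_sums = FALSE) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$gene_id)
  }
  if (is.null(aligned_totals)) {
    if (!use_column_sums) {
      stop("aligned_totals is required (or set use_column_sums = TRUE)",
           call. = FALSE)
    }
    aligned_totals <- colSums(counts)
  }
  if (is.data.frame(aligned_totals)) {
    aligned_totals <- stats::setNames(aligned_totals$aligned_total,
                                      aligned_totals$sample_id)
  }
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) {
    stop("gene(s) without length: ", paste(utils::head(miss, 5L), collapse = ", "),
         call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  if (any(len < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  miss_s <- setdiff(colnames(counts), names(aligned_totals))
  if (length(miss_s)) {
    stop("sample(s) without aligned totals: ", paste(miss_s, collapse = ", "),
         call. = FALSE)
  }
  tot <- aligned_totals[colnames(counts)]
  if (any(tot <= 0)) stop("aligned totals must be > 0", call. = FALSE)
  counts / ((len / 1000) %o% (tot / 1e6))
}

#' Remove homoeologue groups with low abundance
#'
#' A member gene fails when its mean abundance across the analysis panel
#' (all non-control samples, replicates included) is below the threshold;
#' the whole group is removed if any member fails, so no one-sided pairs
#' survive that could mimic exchanges. Defaults: 0.4 RPKM for mRNAseq,
#' 0.01 RPKM for DNA-coverage panels.
#'
#' @param panel An [expression_panel()].
#' @param groups Long homoeologue-group tibble.
#' @param min_mean_rpkm Threshold; `NULL` picks the assay default.
#' @return A list with tibbles `retained` and `removed` (the latter with a
#'   `failing_members` column), plus `member_means` for auditing.
#' @export
filter_low_expression <- function(panel, groups, min_mean_rpkm = NULL) {
  if (is.null(min_mean_rpkm)) {
    min_mean_rpkm <- if (panel$assay == "dnaseq") 0.01 else 0.4
  }
  use <- panel_samples(panel)
  means <- rowMeans(panel$values[, use, drop = FALSE])
  miss <- setdiff(groups$gene_id, names(means))
  if (length(miss)) {
    stop("group member(s) absent from panel: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  member <- groups |>
    dplyr::mutate(mean_rpkm = unname(means[.data$gene_id]),
                  fails = .data$mean_rpkm < min_mean_rpkm)
  status <- member |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(removed = any(.data$fails),
                     failing_members = paste(.data$gene_id[.data$fails],
                                             collapse = ","),
                     .groups = "drop")
  removed_ids <- status$group_id[status$removed]
  retained <- dplyr::filter(groups, !.data$group_id %in% removed_ids)
  removed <- groups |>
    dplyr::filter(.data$group_id %in% removed_ids) |>
    dplyr::left_join(dplyr::select(status, "group_id", "failing_members"),
                     by = "group_id")
  for (a in c("ordering_genome", "n_unplaced", "unplaced")) {
    attr(retained, a) <- attr(groups, a)
  }
  list(retained = retained, removed = removed,
       member_means = dplyr::select(member, "group_id", "genome", "gene_id",
                                    "mean_rpkm"),
       threshold = min_mean_rpkm)
}

#' In-silico combination of parental samples
#'
#' Combines parent-species abundance profiles into a synthetic
#' allopolyploid control: the per-gene weighted mean of the parental
#' values (each parent first averaged over its own columns). Used for the
#' control rows of tile plots, where the combination of single-genome
#' parents should render the balanced colour.
#'
#' @param parents A list of genes x samples matrices (or single-column
#'   matrices / named vectors) sharing an identical gene universe.
#' @param weights Non-negative weights, one per parent; default equal.
#' @return A named numeric vector: the combined per-gene abundance.
#' @export
in_silico_combination <- function(parents, weights = NULL) {
  stopifnot(length(parents) >= 1L)
  parents <- lapply(parents, function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 1L, dimnames = list(names(p), NULL))
    p
  })
  genes <- rownames(parents[[1L]])
  for (p in parents[-1L]) {
    miss <- c(setdiff(genes, rownames(p)), setdiff(rownames(p), genes))
    if (length(miss)) {
      stop("parental panels differ in gene universe; missing: ",
           paste(utils::head(unique(miss), 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(parents))
  if (length(weights) != length(parents) || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative, one per parent, not all zero", call. = FALSE)
  }
  w <- weights / sum(weights)
  prof <- vapply(parents, function(p) rowMeans(p[genes, , drop = FALSE]),
                 numeric(length(genes)))
  stats::setNames(as.numeric(prof %*% w), genes)
}

#' Append control columns to an expression panel
#'
#' @param panel An [expression_panel()].
#' @param controls A genes x controls matrix (same gene universe as the
#'   panel) of control profiles, e.g. parents and their in-silico
#'   combination.
#' @return The panel with control columns appended and flagged
#'   `is_control` in the sample sheet.
#' @export
add_control_samples <- function(panel, controls) {
  if (!identical(sort(rownames(controls)), sort(rownames(panel$values)))) {
    stop("control profiles must cover exactly the panel gene universe",
         call. = FALSE)
  }
  controls <- controls[rownames(panel$values), , drop = FALSE]
  sheet <- dplyr::bind_rows(
    panel$sample_sheet,
    tibble::tibble(sample_id = colnames(controls),
                   accession_id = colnames(controls),
                   replicate = 1L, assay = panel$assay, is_control = TRUE)
  )
  expression_panel(cbind(panel$values, controls), sheet, panel$assay)
}
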