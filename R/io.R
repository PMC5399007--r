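#' Read a tabular alignment file (BLAST outfmt-6 style)
#'
#' Parses the standard 12-column tab-delimited alignment format
#' (query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore) produced by `blastn -outfmt 6` and
#' compatible aligners. Every row must carry all twelve fields with
#' numeric E-value and bitscore; malformed rows abort with their row
#' number rather than being silently dropped.
#'
#' @param path Path to a tab-delimited alignment file.
#' @param dialect Input dialect; currently only `"outfmt6"`.
#' @return A tibble with one row per alignment hit and columns
#'   `query`, `subject`, `pident`, `length`, `mismatch`, `gapopen`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_alignment_table <- function(path, dialect = "outfmt6") {
  dialect <- match.arg(dialect, "outfmt6")
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), cols))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("alignment format error at row ", bad, ": expected 12 columns, got ",
         nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    stop("alignment format error at row ", bad,
         ": non-numeric value in a numeric column", call. = FALSE)
  }
  out <- tibble::tibble(query = m[, 1L], subject = m[, 2L])
  for (i in seq_len(10L)) out[[cols[i + 2L]]] <- num[, i]
  out
}

#' Read a genes-by-samples expression (or coverage) matrix
#'
#' Expects delimited text with gene identifiers in the first column and a
#' header row of sample identifiers. Values must be non-negative numbers;
#' duplicated gene rows and (by default) missing values are rejected.
#'
#' @param path Path to a TSV matrix file.
#' @param na_action `"error"` (default) aborts on missing values;
#'   `"zero"` imputes 0. Silent imputation hides quantification failures,
#'   so it is opt-in.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression_matrix <- function(path, na_action = c("error", "zero")) {
  na_action <- match.arg(na_action)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs a gene_id column plus at least one sample", call. = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("duplicated gene_id in expression matrix: ", dup, call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gene_ids
  if (anyNA(vals)) {
    if (na_action == "error") {
      idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", gene_ids[idx[1L]], "', sample '",
           colnames(vals)[idx[2L]], "' (use na_action = \"zero\" to impute 0)",
           call. = FALSE)
    }
    vals[is.na(vals)] <- 0
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at gene '", rownames(vals)[idx[1L]], "', sample '",
         colnames(vals)[idx[2L]], "'", call. = FALSE)
  }
  vals
}

#' Write a genes-by-samples matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips values at full
#' double precision.
#'
#' @param values Numeric matrix with rownames (gene ids) and colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(values, path) {
  df <- tibble::tibble(gene_id = rownames(values))
  for (s in colnames(values)) df[[s]] <- values[, s]
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet maps sequencing samples to accessions and biological
#' replicates: columns `sample_id`, `accession_id`, `replicate`, `assay`
#' (one of `mrnaseq`, `dnaseq`), and optionally `is_control` (logical,
#' default `FALSE`) marking parental / in-silico control columns that are
#' excluded from panel means and filtering.
#'
#' @param path Path to a TSV sample sheet.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "accession_id", "replicate", "assay")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sheet <- tibble::as_tibble(sheet)
  if (!"is_control" %in% names(sheet)) sheet$is_control <- FALSE
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1L], call. = FALSE)
  }
  if (!all(sheet$assay %in% c("mrnaseq", "dnaseq"))) {
    stop("assay must be 'mrnaseq' or 'dnaseq'", call. = FALSE)
  }
  if (any(sheet$replicate < 1)) stop("replicate indices must be >= 1", call. = FALSE)
  dup <- sheet |>
    dplyr::count(.data$accession_id, .data$replicate, .data$assay) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("replicate indices within accession '", dup$accession_id[1L],
         "' are not distinct", call. = FALSE)
  }
  sheet
}

#' Read a gene-order table
#'
#' Places every gene on a chromosome at an ordinal (0-based rank along the
#' chromosome). Columns: `gene_id`, `genome`, `chromosome`, `ordinal`, and
#' optionally `start`/`end` in base pairs (pass-through only; the tile-plot
#' layout uses ranks, not physical coordinates). After loading, ordinals
#' within each chromosome are re-ranked to a gap-free 0..n-1 sequence,
#' preserving their relative order.
#'
#' @param path Path to a TSV gene-order table.
#' @return A tibble sorted by (genome, chromosome, ordinal).
#' @export
read_gene_order <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  validate_gene_order(df)
}

#' @rdname read_gene_order
#' @param order_table A data frame to validate/normalize in place.
#' @export
validate_gene_order <- function(order_table) {
  need <- c("gene_id", "genome", "chromosome", "ordinal")
  miss <- setdiff(need, names(order_table))
  if (length(miss)) stop("gene-order table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- tibble::as_tibble(order_table)
  if (anyDuplicated(out$gene_id)) {
    stop("duplicated gene_id in gene-order table: ",
         out$gene_id[duplicated(out$gene_id)][1L], call. = FALSE)
  }
  key <- paste(out$genome, out$chromosome, out$ordinal)
  if (anyDuplicated(key)) {
    stop("duplicated (genome, chromosome, ordinal) in gene-order table",
         call. = FALSE)
  }
  out |>
    dplyr::arrange(.data$genome, .data$chromosome, .data$ordinal) |>
    dplyr::group_by(.data$genome, .data$chromosome) |>
    dplyr::mutate(ordinal = seq_along(.data$ordinal) - 1L) |>
    dplyr::ungroup()
}

#' Write homoeologous-exchange blocks as BED
#'
#' Emits 0-based half-open intervals, sorted by chromosome then start. When
#' blocks carry only ordinal coordinates (gene ranks, the pipeline default)
#' the track header flags `coords=ordinal`; with `start`/`end` columns in bp
#' those are used instead. The BED name field encodes
#' `accession|direction`.
#'
#' @param blocks A tibble of HE blocks from [call_blocks()].
#' @param path Output path.
#' @param track_name Track name for the header line.
#' @export
write_he_blocks_bed <- function(blocks, path, track_name = "he_blocks") {
  use_bp <- all(c("start", "end") %in% names(blocks)) && nrow(blocks) > 0 &&
    !anyNA(blocks$start) && !anyNA(blocks$end)
  coords <- if (use_bp) "bp" else "ordinal"
  header <- sprintf('track name=%s description="homoeologous exchange blocks" coords=%s',
                    track_name, coords)
  if (nrow(blocks) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  need <- c("chromosome", "start_ordinal", "end_ordinal", "accession_id", "direction")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stop("blocks lack coordinate column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  s <- if (use_bp) blocks$start else blocks$start_ordinal
  e <- if (use_bp) blocks$end else blocks$end_ordinal
  if (anyNA(s) || anyNA(e)) stop("block without coordinates", call. = FALSE)
  bed <- tibble::tibble(
    chrom = blocks$chromosome,
    start = as.integer(s),
    end = as.integer(e),
    name = paste(blocks$accession_id, blocks$direction, sep = "|"),
    score = round(1000 * blocks$support),
    strand = "."
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$name)
  body <- do.call(paste, c(as.list(bed), sep = "\t"))
  writeLines(c(header, body), path, useBytes = FALSE)
  invisible(path)
}

#' Read / write homoeologue group tables
#'
#' Groups are stored long: one row per member gene with columns `group_id`,
#' `genome`, `gene_id`, plus `chromosome` and `ordinal` once an ordering
#' genome has been attached (see [attach_order()]).
#'
#' @param path TSV path.
#' @return A tibble of group members.
#' @export
read_groups_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("group_id", "genome", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("groups table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_groups_tsv
#' @param groups A tibble of group members.
#' @export
write_groups_tsv <- function(groups, path) {
  readr::write_tsv(groups, path)
  invisible(path)
}
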