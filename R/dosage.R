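# Arrow used in the printed exchange category labels ("Exchange C -> A"
# is printed with a true arrow glyph).
HE_ARROW <- "\u2192"

exchange_label <- function(loser, gainer) {
  paste0("Exchange ", loser, " ", HE_ARROW, " ", gainer)
}

#' One-sample direction test of replicate expression against the panel mean
#'
#' Two-sided one-sample t-test of an accession's replicate RPKM values for
#' one gene against the scalar panel mean. The direction is `high` or
#' `low` (by the sign of the mean difference) when p < alpha, else `null`.
#'
#' Degenerate inputs are flagged, never silently passed: with zero
#' replicate variance the p-value is 1 when the replicate mean equals the
#' panel mean exactly (no evidence of change) and 0 otherwise (RPKM ties
#' at 0 are routine for deleted copies and must still be called); with
#' fewer than two replicates no test is possible and the p-value is `NA`
#' with direction `null`.
#'
#' @param replicate_values Numeric replicate RPKM values (one accession,
#'   one gene).
#' @param panel_mean Scalar reference mean across the panel.
#' @param alpha Significance threshold (default 0.01).
#' @return A one-row tibble: `direction`, `p_value`, `accession_mean`,
#'   `panel_mean`, `n`, `degenerate`.
#' @export
direction_test <- function(replicate_values, panel_mean, alpha = 0.01) {
  x <- unname(as.numeric(replicate_values))
  n <- length(x)
  m <- mean(x)
  panel_mean <- unname(panel_mean)
  if (n < 2L) {
    return(tibble::tibble(direction = "null", p_value = NA_real_,
                          accession_mean = m, panel_mean = panel_mean,
                          n = n, degenerate = TRUE))
  }
  s2 <- stats::var(x)
  degenerate <- FALSE
  if (s2 == 0) {
    if (m == panel_mean) {
      p <- 1
    } else {
      p <- 0
      degenerate <- TRUE
    }
  } else {
    tstat <- (m - panel_mean) / sqrt(s2 / n)
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  direction <- if (!is.na(p) && p < alpha) {
    if (m > panel_mean) "high" else "low"
  } else "null"
  tibble::tibble(direction = direction, p_value = p, accession_mean = m,
                 panel_mean = panel_mean, n = n, degenerate = degenerate)
}

#' Classify a homoeologue pair into the nine genome-dosage categories
#'
#' Maps the per-genome direction calls of a two-genome group onto the
#' nine-category genome-dosage grid: simultaneous high/high is duplication
#' of both copies, high with low is an exchange written
#' "Exchange loser -> gainer" (the low genome's segment was replaced by a
#' duplicate of the high genome's), single-genome high/low with the other
#' unchanged is duplication/deletion of that copy, and null/null is no
#' difference.
#'
#' @param dir_first,dir_second Directions (`"high"`, `"null"`, `"low"`)
#'   for the first and second genome. Vectorized.
#' @param genomes Two genome labels, e.g. `c("A", "C")`.
#' @return Character vector of category labels.
#' @export
classify_group <- function(dir_first, dir_second, genomes = c("A", "C")) {
  stopifnot(length(genomes) == 2L)
  g1 <- genomes[1L]
  g2 <- genomes[2L]
  ok <- c("high", "null", "low")
  if (!all(dir_first %in% ok) || !all(dir_second %in% ok)) {
    stop("directions must be 'high', 'null' or 'low'", call. = FALSE)
  }
  both <- paste(sort(c(g1, g2)), collapse = " and ")  # canonical label order
  grid <- c(
    "high.high" = paste0("Duplication ", both),
    "high.null" = paste0("Duplication ", g1),
    "null.high" = paste0("Duplication ", g2),
    "high.low"  = exchange_label(g2, g1),
    "low.high"  = exchange_label(g1, g2),
    "low.null"  = paste0("Deletion ", g1),
    "low.low"   = paste0("Deletion ", both),
    "null.low"  = paste0("Deletion ", g2),
    "null.null" = "No difference"
  )
  unname(grid[paste(dir_first, dir_second, sep = ".")])
}

#' Classify a homoeologue triplet from per-genome directions
#'
#' Extends the two-genome grid to three subgenomes. All-null is
#' "No difference". When both gaining (high) and losing (low) genomes are
#' present the call is an exchange, written "Exchange losers -> gainers"
#' following the convention that the high genome gained the low genome's
#' segment. With only highs (plus nulls) the call is a duplication of the
#' high genomes; with only lows, a deletion of the low genomes.
#'
#' @param directions Named character vector of directions, one per genome
#'   (names are the genome labels, e.g. `c(A = "high", B = "low",
#'   D = "null")`).
#' @return A single category label.
#' @export
classify_triplet <- function(directions) {
  stopifnot(length(directions) == 3L, !is.null(names(directions)))
  highs <- sort(names(directions)[directions == "high"])
  lows <- sort(names(directions)[directions == "low"])
  if (length(highs) == 0L && length(lows) == 0L) return("No difference")
  if (length(highs) > 0L && length(lows) > 0L) {
    return(exchange_label(paste(lows, collapse = " and "),
                          paste(highs, collapse = " and ")))
  }
  if (length(highs) > 0L) {
    return(paste0("Duplication ", paste(highs, collapse = " and ")))
  }
  paste0("Deletion ", paste(lows, collapse = " and "))
}

# Vectorized per-(gene, accession) one-sample t machinery. Returns a long
# tibble over gene x accession with mean, p, direction, degenerate.
# Consistent by construction with direction_test(); the equivalence is
# asserted in the test suite.
panel_direction_tests <- function(values, sample_sheet, alpha = 0.01,
                                  exclude_self = FALSE, panel_means = NULL,
                                  transform = c("identity", "log2")) {
  transform <- match.arg(transform)
  sheet <- sample_sheet[!sample_sheet$is_control, , drop = FALSE]
  x <- values[, sheet$sample_id, drop = FALSE]
  if (transform == "log2") x <- log2(x + 1)
  accs <- unique(sheet$accession_id)
  # indicator: samples x accessions
  ind <- vapply(accs, function(a) as.numeric(sheet$accession_id == a),
                numeric(nrow(sheet)))
  n <- colSums(ind)
  sums <- x %*% ind
  means <- sweep(sums, 2L, n, "/")
  sqsums <- (x^2) %*% ind
  ss <- sqsums - sweep(means^2, 2L, n, "*")
  ss[ss < 0] <- 0  # guard tiny negative rounding residue
  s2 <- sweep(ss, 2L, pmax(n - 1, 1), "/")
  if (is.null(panel_means)) {
    tot <- rowSums(x)
    if (exclude_self) {
      pm <- (tot - sums) / rep(ncol(x) - n, each = nrow(x))
    } else {
      pm <- matrix(tot / ncol(x), nrow = nrow(x), ncol = length(accs))
    }
  } else {
    pm <- matrix(panel_means[rownames(x)], nrow = nrow(x), ncol = length(accs))
  }
  dimnames(pm) <- dimnames(means)
  se <- sqrt(sweep(s2, 2L, n, "/"))
  tstat <- (means - pm) / se
  p <- 2 * stats::pt(-abs(tstat), df = rep(n - 1, each = nrow(x)))
  zerovar <- s2 == 0
  eq <- means == pm
  p[zerovar & eq] <- 1
  p[zerovar & !eq] <- 0
  degen <- zerovar & !eq
  few <- rep(n < 2, each = nrow(x))
  p[few] <- NA_real_
  degen[few] <- TRUE
  dir <- matrix("null", nrow = nrow(x), ncol = length(accs))
  sig <- !is.na(p) & p < alpha
  dir[sig & means > pm] <- "high"
  dir[sig & means < pm] <- "low"
  tibble::tibble(
    gene_id = rep(rownames(x), times = length(accs)),
    accession_id = rep(accs, each = nrow(x)),
    accession_mean = as.vector(means),
    panel_mean = as.vector(pm),
    p_value = as.vector(p),
    direction = as.vector(dir),
    degenerate = as.vector(degen)
  )
}

#' Classify every homoeologue group in every accession
#'
#' Runs the replicate t-test for each member gene of each group in each
#' accession against the panel mean and maps the per-genome directions to
#' a genome-dosage category: the nine-category grid for pairs, its
#' three-genome extension for triplets.
#'
#' @param panel An [expression_panel()] (already low-expression filtered).
#' @param groups Long homoeologue-group tibble with order attached.
#' @param alpha Significance threshold for each t-test (default 0.01; raw
#'   p-values, no multiple-testing correction, matching the method's
#'   definition — BH correction is available via `p_adjust`).
#' @param exclude_self If `TRUE`, the reference mean for an accession
#'   excludes that accession's own samples. Default `FALSE`: the
#'   reference is the mean of all samples, which makes the test slightly
#'   conservative (the tested replicates are part of the reference).
#' @param panel_means Optional named vector of per-gene reference means,
#'   overriding the mean computed from the panel (e.g. a known generative
#'   mean when calibrating on simulated data).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param transform `"identity"` (default; RPKM tested untransformed) or
#'   `"log2"` for log2(x+1).
#' @return A `dosage_calls` tibble: one row per (group, accession) with
#'   `category` plus per-genome columns `mean_<g>`, `panel_mean_<g>`,
#'   `p_<g>`, `direction_<g>`, `degenerate_<g>`. Attributes: `genomes`,
#'   `alpha`, `ordering_genome`.
#' @export
classify_panel <- function(panel, groups, alpha = 0.01, exclude_self = FALSE,
                           panel_means = NULL, p_adjust = c("none", "BH"),
                           transform = c("identity", "log2")) {
  p_adjust <- match.arg(p_adjust)
  genomes <- sort(unique(groups$genome))
  if (!length(genomes) %in% 2:3) {
    stop("groups must span two or three genomes", call. = FALSE)
  }
  miss <- setdiff(groups$gene_id, rownames(panel$values))
  if (length(miss)) {
    stop("group member(s) absent from panel: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  vals <- panel$values[unique(groups$gene_id), , drop = FALSE]
  tests <- panel_direction_tests(vals, panel$sample_sheet, alpha = alpha,
                                 exclude_self = exclude_self,
                                 panel_means = panel_means,
                                 transform = transform)
  if (p_adjust == "BH") {
    tests$p_value <- stats::p.adjust(tests$p_value, method = "BH")
    sig <- !is.na(tests$p_value) & tests$p_value < alpha
    tests$direction <- ifelse(!sig, "null",
                              ifelse(tests$accession_mean > tests$panel_mean,
                                     "high", "low"))
  }
  member_cols <- c("group_id", "genome", "gene_id")
  if ("chromosome" %in% names(groups)) {
    member_cols <- c(member_cols, "chromosome", "ordinal")
  }
  long <- groups |>
    dplyr::select(dplyr::all_of(member_cols)) |>
    dplyr::inner_join(tests, by = "gene_id", relationship = "many-to-many")
  wide <- long |>
    tidyr::pivot_wider(
      id_cols = dplyr::any_of(c("group_id", "chromosome", "ordinal",
                                "accession_id")),
      names_from = "genome",
      values_from = c("accession_mean", "panel_mean", "p_value", "direction",
                      "degenerate"),
      names_glue = "{.value}_{genome}"
    )
  names(wide) <- sub("^accession_mean_", "mean_", names(wide))
  names(wide) <- sub("^p_value_", "p_", names(wide))
  dir_cols <- paste0("direction_", genomes)
  if (length(genomes) == 2L) {
    wide$category <- classify_group(wide[[dir_cols[1L]]], wide[[dir_cols[2L]]],
                                    genomes)
  } else {
    dm <- as.matrix(wide[, dir_cols])
    colnames(dm) <- genomes
    wide$category <- apply(dm, 1L, function(d) classify_triplet(d))
  }
  if ("chromosome" %in% names(wide)) {
    wide <- dplyr::arrange(wide, .data$accession_id, .data$chromosome,
                           .data$ordinal)
  }
  out <- dplyr::relocate(wide, "category", .after = "accession_id")
  class(out) <- c("dosage_calls", class(out))
  attr(out, "genomes") <- genomes
  attr(out, "alpha") <- alpha
  attr(out, "ordering_genome") <- attr(groups, "ordering_genome")
  out
}

#' Split dosage calls into the over/under/exchange sub-tables
#'
#' Returns the three genome-ordered tables reported alongside the calls:
#' groups over-expressed in one or both genomes (duplications),
#' under-expressed (deletions), and over-expressed in one genome with the
#' other under-expressed (exchanges).
#'
#' @param calls A `dosage_calls` tibble from [classify_panel()].
#' @return A list of tibbles: `over_expressed`, `under_expressed`,
#'   `exchanges`.
#' @export
dosage_subtables <- function(calls) {
  list(
    over_expressed = dplyr::filter(calls, startsWith(.data$category, "Duplication")),
    under_expressed = dplyr::filter(calls, startsWith(.data$category, "Deletion")),
    exchanges = dplyr::filter(calls, startsWith(.data$category, "Exchange"))
  )
}
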