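#' Reciprocal-best-hit homoeologue pairing
#'
#' Builds homoeologous gene pairs from two alignment tables (genome 1
#' queried against genome 2 and vice versa), keeping only mutual best
#' hits. Hits with E-value above `max_evalue` are discarded first
#' (default 1e-30, the standard stringency for cross-subgenome CDS
#' alignments). Where a query-subject pair has several HSPs only the
#' highest-bitscore one is kept; the best hit per query is then the
#' highest bitscore, with ties broken by lower E-value and finally by
#' lexicographically smallest subject id, so the result is deterministic.
#'
#' @param hits_ab Alignment hits with genome-1 genes as queries
#'   (tibble from [read_alignment_table()]).
#' @param hits_ba Alignment hits with genome-2 genes as queries.
#' @param max_evalue E-value threshold; hits above it are discarded.
#' @return A tibble with columns `gene_a`, `gene_b`, one row per
#'   reciprocal best pair; each gene occurs in at most one pair.
#' @export
reciprocal_best_pairs <- function(hits_ab, hits_ba, max_evalue = 1e-30) {
  best_a <- best_hits(hits_ab, max_evalue)
  best_b <- best_hits(hits_ba, max_evalue)
  if (nrow(best_a) == 0L || nrow(best_b) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  pairs <- dplyr::inner_join(
    dplyr::rename(best_a, gene_a = "query", gene_b = "subject"),
    dplyr::rename(best_b, gene_b = "query", gene_a = "subject"),
    by = c("gene_a", "gene_b")
  )
  pairs |>
    dplyr::select("gene_a", "gene_b") |>
    dplyr::arrange(.data$gene_a)
}

# Best surviving hit per query: collapse HSPs to the strongest per
# (query, subject), then rank by bitscore desc, evalue asc, subject asc.
best_hits <- function(hits, max_evalue) {
  hits <- dplyr::filter(hits, .data$evalue <= max_evalue)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(query = character(), subject = character()))
  }
  hits |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject) |>
    dplyr::distinct(.data$query, .data$subject, .keep_all = TRUE) |>
    dplyr::distinct(.data$query, .keep_all = TRUE) |>
    dplyr::select("query", "subject")
}

#' Build homoeologous triplets from three pairwise RBH lists
#'
#' A triplet (a, b, d) over genomes 1, 2, 3 is emitted iff all three
#' pairwise reciprocal best pairs (a,b), (a,d) and (b,d) are present — a
#' consistent triangle, the most conservative reading of triplet
#' construction. Genes participating in incomplete triangles are dropped
#' and counted in the `dropped` attribute.
#'
#' @param pairs_ab,pairs_ad,pairs_bd Pair tibbles from
#'   [reciprocal_best_pairs()] over genomes (1,2), (1,3), (2,3).
#' @param genomes Character vector of three genome labels, e.g.
#'   `c("A","B","D")`.
#' @return A tibble with one row per triplet and one gene column per
#'   genome; attribute `dropped` holds a tibble of genes in broken
#'   triangles and `n_dropped` their count.
#' @export
build_triplets <- function(pairs_ab, pairs_ad, pairs_bd,
                           genomes = c("A", "B", "D")) {
  stopifnot(length(genomes) == 3L)
  ab <- dplyr::rename(pairs_ab, a = "gene_a", b = "gene_b")
  ad <- dplyr::rename(pairs_ad, a = "gene_a", d = "gene_b")
  bd <- dplyr::rename(pairs_bd, b = "gene_a", d = "gene_b")
  tri <- ab |>
    dplyr::inner_join(ad, by = "a") |>
    dplyr::inner_join(bd, by = c("b", "d")) |>
    dplyr::arrange(.data$a)
  in_triangle <- c(tri$a, tri$b, tri$d)
  all_genes <- tibble::tibble(
    gene_id = c(ab$a, ab$b, ad$a, ad$d, bd$b, bd$d),
    genome = c(rep(genomes[c(1, 2)], each = nrow(ab)),
               rep(genomes[c(1, 3)], each = nrow(ad)),
               rep(genomes[c(2, 3)], each = nrow(bd)))
  ) |> dplyr::distinct()
  dropped <- dplyr::filter(all_genes, !.data$gene_id %in% in_triangle)
  out <- tibble::tibble(a = tri$a, b = tri$b, d = tri$d)
  names(out) <- genomes
  attr(out, "dropped") <- dropped
  attr(out, "n_dropped") <- nrow(dropped)
  out
}

#' Turn pair or triplet tables into a long homoeologue-group table
#'
#' @param members A pair tibble (`gene_a`, `gene_b`) or a triplet tibble
#'   (one column per genome, as from [build_triplets()]).
#' @param genomes Genome labels in column order (pairs only; triplet
#'   tables already carry genome column names).
#' @return A long tibble: `group_id`, `genome`, `gene_id`.
#' @export
as_homoeolog_groups <- function(members, genomes = c("A", "C")) {
  if (all(c("gene_a", "gene_b") %in% names(members))) {
    stopifnot(length(genomes) == 2L)
    wide <- tibble::tibble(members$gene_a, members$gene_b)
    names(wide) <- genomes
  } else {
    wide <- tibble::as_tibble(members)
    genomes <- names(wide)
  }
  wide$group_id <- sprintf("grp%05d", seq_len(nrow(wide)))
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(genomes),
                              names_to = "genome", values_to = "gene_id")
  if (anyDuplicated(long$gene_id)) {
    stop("a gene occurs in more than one homoeologue group: ",
         long$gene_id[duplicated(long$gene_id)][1L], call. = FALSE)
  }
  dplyr::select(long, "group_id", "genome", "gene_id")
}

#' Attach genome order to homoeologue groups
#'
#' Assigns each group the chromosome and ordinal of its member in the
#' ordering genome (tile plots are drawn "in genome order" of one member)
#' and sorts groups by (chromosome, ordinal). Groups whose ordering-genome
#' member is absent from the order table are excluded and counted in the
#' `n_unplaced` attribute.
#'
#' @param groups Long group tibble (`group_id`, `genome`, `gene_id`).
#' @param order_table Gene-order tibble (see [read_gene_order()]).
#' @param ordering_genome Which genome's order to use, e.g. `"C"`.
#' @return The long group tibble with `chromosome` and `ordinal` columns
#'   added (identical within a group), sorted in genome order;
#'   attributes `ordering_genome`, `n_unplaced`, `unplaced`.
#' @export
attach_order <- function(groups, order_table, ordering_genome) {
  if (!ordering_genome %in% groups$genome) {
    stop("ordering_genome '", ordering_genome,
         "' is not among the group member genomes", call. = FALSE)
  }
  anchors <- groups |>
    dplyr::filter(.data$genome == ordering_genome) |>
    dplyr::inner_join(
      dplyr::select(order_table, "gene_id", "chromosome", "ordinal"),
      by = "gene_id"
    ) |>
    dplyr::select("group_id", "chromosome", "ordinal")
  placed <- unique(anchors$group_id)
  unplaced <- setdiff(unique(groups$group_id), placed)
  out <- groups |>
    dplyr::filter(.data$group_id %in% placed) |>
    dplyr::select("group_id", "genome", "gene_id") |>
    dplyr::inner_join(anchors, by = "group_id") |>
    dplyr::arrange(.data$chromosome, .data$ordinal, .data$genome)
  attr(out, "ordering_genome") <- ordering_genome
  attr(out, "n_unplaced") <- length(unplaced)
  attr(out, "unplaced") <- unplaced
  out
}
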