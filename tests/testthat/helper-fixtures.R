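# Shared fixture builders. Everything is generated in code; no files on disk.

# A 12-column outfmt-6 line for one hit.
hit_line <- function(q, s, evalue, bitscore) {
  paste(q, s, "98.2", "500", "2", "1", "1", "500", "1", "500",
        format(evalue), format(bitscore), sep = "\t")
}

write_hits_file <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                                .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# Hit tibble built directly (bypassing the reader) for pairing tests.
hits_tbl <- function(query, subject, evalue, bitscore) {
  tibble::tibble(query = query, subject = subject, pident = 98, length = 500,
                 mismatch = 2, gapopen = 1, qstart = 1, qend = 500,
                 sstart = 1, send = 500, evalue = evalue, bitscore = bitscore)
}

# Independent best-hit oracle: for each query take the best surviving hit
# by (bitscore desc, evalue asc, subject asc) after collapsing HSPs, then
# intersect the two directions.
rbh_oracle <- function(hits_ab, hits_ba, max_evalue = 1e-30) {
  best <- function(h) {
    h <- h[h$evalue <= max_evalue, , drop = FALSE]
    out <- list()
    for (q in unique(h$query)) {
      hq <- h[h$query == q, , drop = FALSE]
      # collapse HSPs per subject
      coll <- do.call(rbind, lapply(split(hq, hq$subject), function(d) {
        d <- d[order(-d$bitscore, d$evalue), , drop = FALSE]
        d[1L, c("subject", "evalue", "bitscore")]
      }))
      coll <- coll[order(-coll$bitscore, coll$evalue, coll$subject), ,
                   drop = FALSE]
      out[[q]] <- coll$subject[1L]
    }
    out
  }
  ba <- best(hits_ba)
  ab <- best(hits_ab)
  pairs <- list()
  for (a in names(ab)) {
    b <- ab[[a]]
    if (!is.null(ba[[b]]) && identical(ba[[b]], a)) {
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) return(tibble::tibble(gene_a = character(),
                                            gene_b = character()))
  m <- do.call(rbind, pairs)
  tibble::tibble(gene_a = m[, 1L], gene_b = m[, 2L]) |>
    dplyr::arrange(gene_a)
}

# Small panel built directly from a value matrix: n_acc accessions x n_rep
# replicates; column order acc01_r1, acc01_r2, ...
toy_panel <- function(values, n_acc, n_rep, assay = "mrnaseq") {
  accs <- sprintf("acc%02d", seq_len(n_acc))
  sheet <- tidyr::expand_grid(accession_id = accs,
                              replicate = seq_len(n_rep)) |>
    dplyr::mutate(sample_id = paste0(accession_id, "_r", replicate),
                  assay = assay, is_control = FALSE) |>
    dplyr::select(sample_id, accession_id, replicate, assay, is_control)
  colnames(values) <- sheet$sample_id
  expression_panel(values, sheet, assay)
}

# Two-genome group table (one group per gene index) laid on one chromosome.
toy_groups <- function(n, genomes = c("A", "C"), chromosome = "C1") {
  long <- tidyr::expand_grid(i = seq_len(n), genome = genomes) |>
    dplyr::mutate(group_id = sprintf("grp%05d", i),
                  gene_id = paste0(genome, "_g", i),
                  chromosome = chromosome, ordinal = i - 1L) |>
    dplyr::select(group_id, genome, gene_id, chromosome, ordinal)
  attr(long, "ordering_genome") <- genomes[1L]
  long
}

# Independent block-scan oracle: walks the call sequence collecting
# concordant indices one by one, closing the run when the gap exceeds
# max_gap; structured differently from the implementation's split-based
# scan.
block_oracle <- function(categories, ordinals, min_run, max_gap) {
  dirs <- unique(categories[startsWith(categories, "Exchange")])
  out <- list()
  for (dir in dirs) {
    run <- integer(0)
    close_run <- function(run) {
      if (length(run) >= min_run) {
        span <- run[1L]:run[length(run)]
        out[[length(out) + 1L]] <<- data.frame(
          start_ordinal = ordinals[run[1L]],
          end_ordinal = ordinals[run[length(run)]] + 1L,
          direction = dir, n_genes = length(run),
          support = length(run) / length(span))
      }
    }
    for (i in seq_along(categories)) {
      if (categories[i] == dir) {
        if (length(run) && (i - run[length(run)] - 1L) > max_gap) {
          close_run(run)
          run <- integer(0)
        }
        run <- c(run, i)
      }
    }
    close_run(run)
  }
  if (!length(out)) {
    return(tibble::tibble(start_ordinal = integer(), end_ordinal = integer(),
                          direction = character(), n_genes = integer(),
                          support = numeric()))
  }
  tibble::as_tibble(do.call(rbind, out)) |>
    dplyr::arrange(start_ordinal, direction)
}
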