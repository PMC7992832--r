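#' @importFrom stats setNames median
NULL

# A-site window in CDS-local nt coordinates: [3, L) when the stop codon is a
# legitimate A-site (default), [3, L-3) when it is excluded.
asite_window <- function(cds_length_nt, window_end = "stop") {
  if (window_end == "stop") c(3L, cds_length_nt)
  else c(3L, cds_length_nt - 3L)
}

#' Objective value T of the integer program for one gene and offset
#'
#' For a gene's (size, frame) 5'-end count map, `score_offset` returns the
#' number of reads whose implied A-site nucleotide `p + delta` falls between
#' the second codon and the stop codon of the CDS — the objective the offset
#' engine maximises subject to `0 <= delta <= S` and `delta mod 3 == 0`.
#'
#' @param gene_counts Data frame or list with `pos` (CDS-local 5'-end
#'   positions) and `count` columns, restricted to one (gene, size, frame).
#' @param cds_length_nt CDS length in nt (multiple of 3).
#' @param S Fragment size in nt.
#' @param delta Candidate offset; must satisfy the constraints.
#' @param window_end See [job_config()].
#' @return Integer objective value.
#' @export
score_offset <- function(gene_counts, cds_length_nt, S, delta,
                         window_end = "stop") {
  if (delta %% 3L != 0L || delta < 0L || delta > S)
    asite_stop("offset ", delta, " violates 0 <= delta <= ", S,
               " and delta mod 3 == 0")
  win <- asite_window(cds_length_nt, window_end)
  a <- gene_counts$pos + delta
  sum(gene_counts$count[a >= win[1] & a < win[2]])
}

#' Per-gene argmax offsets
#'
#' Enumerates every feasible offset (multiples of 3 in `[0, S]`) and returns
#' the set attaining the maximal objective. The integer program is small
#' enough that exhaustive enumeration is exact.
#'
#' @inheritParams score_offset
#' @return Integer vector of argmax offsets (empty when the gene has no
#'   reads at this (size, frame)).
#' @export
best_offsets_for_gene <- function(gene_counts, cds_length_nt, S,
                                  window_end = "stop") {
  if (is.null(gene_counts) || !length(gene_counts$pos) ||
      sum(gene_counts$count) == 0L) return(integer(0))
  deltas <- feasible_offsets(S)
  scores <- vapply(deltas, function(d)
    score_offset(gene_counts, cds_length_nt, S, d, window_end), integer(1))
  if (max(scores) == 0L) return(integer(0))
  deltas[scores == max(scores)]
}

#' Genes eligible to vote at a (size, frame)
#'
#' A gene is eligible when its read count at the given (size, frame),
#' divided by its codon count, reaches `min_reads_per_codon` — the filter
#' that removes genes whose small sample would bias the offset vote.
#'
#' @param tensor A `count_tensor`.
#' @param S,F Fragment size and frame.
#' @param config A [job_config()].
#' @return Character vector of eligible gene ids.
#' @export
filter_eligible_genes <- function(tensor, S, F, config) {
  sub <- tensor$counts[.(unique(tensor$counts$gene), as.integer(S),
                         as.integer(F)), nomatch = NULL]
  if (!nrow(sub)) return(character(0))
  tot <- sub[, .(reads = sum(count)), by = gene]
  codons <- tensor$cds_length[tot$gene] / 3
  tot$gene[tot$reads / codons >= config$min_reads_per_codon &
           tot$reads > 0L]
}

#' Metagene start-region ratio at an offset
#'
#' Aggregates A-site positions `p + delta` of all eligible genes at a
#' (size, frame) into codon indices and returns the ratio of the mean summed
#' read count in codons 2, 3 and 4 to the summed count in codon 1. A clean
#' initiation signature (few A-sites called at the start codon itself) gives
#' a large ratio; the uniqueness rule requires at least
#' `min_metagene_ratio`. Returns `Inf` when codon 1 is empty but codons 2-4
#' are not, and 0 when all four are empty.
#'
#' @inheritParams filter_eligible_genes
#' @param delta Offset at which to aggregate (the modal offset in practice).
#' @param genes Gene ids to aggregate over (defaults to the eligible set).
#' @return Non-negative real (possibly `Inf`).
#' @export
metagene_ratio <- function(tensor, S, F, delta, config,
                           genes = filter_eligible_genes(tensor, S, F, config)) {
  if (!length(genes)) return(0)
  sub <- tensor$counts[.(genes, as.integer(S), as.integer(F)), nomatch = NULL]
  if (!nrow(sub)) return(0)
  codon <- (sub$pos + delta) %/% 3L + 1L        # 1-based codon index
  c1 <- sum(sub$count[codon == 1L])
  c234 <- vapply(2:4, function(k) sum(sub$count[codon == k]), numeric(1))
  num <- mean(c234)
  if (c1 == 0) { if (num > 0) Inf else 0 } else num / c1
}

#' Cross-gene offset decision for one (size, frame)
#'
#' Implements the voting scheme: eligible genes each vote for their argmax
#' offset (genes whose argmax is tied abstain); the modal offset is called
#' `unique` when the vote fraction reaches `min_vote_fraction`, at least
#' `min_genes` genes voted, and the metagene ratio at the modal offset
#' reaches `min_metagene_ratio`. Otherwise the two top vote-getters are
#' reported as `ambiguous` (when at least two distinct offsets received
#' votes and the gene floor is met), else the cell is `insufficient`.
#'
#' @inheritParams filter_eligible_genes
#' @return An `offset_decision`: list with `size`, `frame`, `status`
#'   (`unique`/`ambiguous`/`insufficient`), `offsets` (length 1, 2 or 0),
#'   `n_genes_eligible`, `n_genes_voting`, `vote_fraction`,
#'   `metagene_ratio`.
#' @export
decide_offset <- function(tensor, S, F, config) {
  eligible <- filter_eligible_genes(tensor, S, F, config)
  decision <- function(status, offsets, n_vote, vf, mr)
    structure(list(size = as.integer(S), frame = as.integer(F),
                   status = status, offsets = as.integer(offsets),
                   n_genes_eligible = length(eligible),
                   n_genes_voting = n_vote,
                   vote_fraction = vf, metagene_ratio = mr),
              class = "offset_decision")
  if (!length(eligible))
    return(decision("insufficient", integer(0), 0L, NA_real_, NA_real_))

  votes <- integer(0)
  for (g in eligible) {
    gc <- tensor$counts[.(g, as.integer(S), as.integer(F)), nomatch = NULL]
    best <- best_offsets_for_gene(gc, tensor$cds_length[[g]], S,
                                  config$window_end)
    if (length(best) == 1L) votes <- c(votes, best)   # tied genes abstain
  }
  n_vote <- length(votes)
  if (n_vote == 0L)
    return(decision("insufficient", integer(0), 0L, NA_real_, NA_real_))

  tal <- sort(table(votes), decreasing = TRUE)
  cand <- as.integer(names(tal))
  # deterministic order: descending votes, ties by smaller offset
  ord <- order(-as.integer(tal), cand)
  cand <- cand[ord]; tal <- as.integer(tal)[ord]
  modal <- cand[1]
  vf <- tal[1] / n_vote
  mr <- metagene_ratio(tensor, S, F, modal, config, genes = eligible)

  if (vf >= config$min_vote_fraction && n_vote >= config$min_genes &&
      mr >= config$min_metagene_ratio)
    return(decision("unique", modal, n_vote, vf, mr))
  if (length(cand) >= 2L && n_vote >= config$min_genes)
    return(decision("ambiguous", cand[1:2], n_vote, vf, mr))
  decision("insufficient", integer(0), n_vote, vf, mr)
}

#' Per-gene vote tallies for diagnostics
#'
#' The unthresholded vote distribution behind [decide_offset()]: how many
#' eligible genes voted for each offset at each (size, frame).
#'
#' @param tensor A `count_tensor`.
#' @param config A [job_config()].
#' @return data.frame with columns `size`, `frame`, `offset`, `votes`.
#' @export
offset_vote_distribution <- function(tensor, config) {
  out <- list()
  for (S in seq.int(config$size_min, config$size_max)) for (F in 0:2) {
    eligible <- filter_eligible_genes(tensor, S, F, config)
    votes <- integer(0)
    for (g in eligible) {
      gc <- tensor$counts[.(g, as.integer(S), as.integer(F)), nomatch = NULL]
      best <- best_offsets_for_gene(gc, tensor$cds_length[[g]], S,
                                    config$window_end)
      if (length(best) == 1L) votes <- c(votes, best)
    }
    if (length(votes)) {
      tal <- table(votes)
      out[[length(out) + 1L]] <- data.frame(
        size = S, frame = F, offset = as.integer(names(tal)),
        votes = as.integer(tal))
    }
  }
  if (!length(out))
    return(data.frame(size = integer(0), frame = integer(0),
                      offset = integer(0), votes = integer(0)))
  do.call(rbind, out)
}

#' Compute the full A-site offset table
#'
#' Runs [decide_offset()] for every (size, frame) cell of the configured
#' grid. The result is deterministic for a given tensor and configuration.
#'
#' @param tensor A `count_tensor`.
#' @param config A [job_config()].
#' @return An `offset_table`: data.frame with one row per (size, frame) and
#'   columns `size`, `frame`, `status`, `offset` (unique offset or first
#'   ambiguous candidate, NA if insufficient), `offset2` (second ambiguous
#'   candidate or NA), `n_genes_eligible`, `n_genes_voting`,
#'   `vote_fraction`, `metagene_ratio`.
#' @export
compute_offset_table <- function(tensor, config) {
  rows <- list()
  for (S in seq.int(config$size_min, config$size_max)) for (F in 0:2) {
    d <- decide_offset(tensor, S, F, config)
    rows[[length(rows) + 1L]] <- data.frame(
      size = d$size, frame = d$frame, status = d$status,
      offset = if (length(d$offsets) >= 1L) d$offsets[1] else NA_integer_,
      offset2 = if (length(d$offsets) >= 2L) d$offsets[2] else NA_integer_,
      n_genes_eligible = d$n_genes_eligible,
      n_genes_voting = d$n_genes_voting,
      vote_fraction = d$vote_fraction,
      metagene_ratio = d$metagene_ratio)
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("offset_table", "data.frame")
  tab
}

#' @export
print.offset_table <- function(x, ...) {
  n <- table(factor(x$status, c("unique", "ambiguous", "insufficient")))
  cat(sprintf("offset_table: %d (size,frame) cells — %d unique, %d ambiguous, %d insufficient\n",
              nrow(x), n[["unique"]], n[["ambiguous"]], n[["insufficient"]]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Offset-table I/O: the user-facing TSV has one row per size with frame
# columns (unique -> "15", ambiguous -> "15/18", insufficient -> "NA"); a
# companion diagnostics TSV carries the vote statistics per cell.
# ---------------------------------------------------------------------------

#' Write an offset table (and its diagnostics) as TSV
#'
#' @param table An `offset_table`.
#' @param path Output TSV (`size`, `frame0`, `frame1`, `frame2`; ambiguous
#'   cells hold `d1/d2`, insufficient cells `NA`).
#' @param diagnostics_path Optional companion TSV of per-cell vote
#'   statistics; defaults to `<path minus extension>_diagnostics.tsv`.
#' @export
write_offset_table <- function(table, path, diagnostics_path = NULL) {
  stopifnot(inherits(table, "offset_table"))
  cell <- function(S, F) {
    r <- table[table$size == S & table$frame == F, ]
    switch(r$status,
           unique = as.character(r$offset),
           ambiguous = paste0(r$offset, "/", r$offset2),
           insufficient = "NA")
  }
  sizes <- sort(unique(table$size))
  lines <- c("size\tframe0\tframe1\tframe2",
             vapply(sizes, function(S)
               paste(S, cell(S, 0), cell(S, 1), cell(S, 2), sep = "\t"), ""))
  writeLines(lines, path)
  if (is.null(diagnostics_path))
    diagnostics_path <- paste0(sub("\\.tsv$", "", path), "_diagnostics.tsv")
  utils::write.table(
    as.data.frame(table)[order(table$size, table$frame), ],
    diagnostics_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an offset table TSV
#'
#' Parses the dialect written by [write_offset_table()]. Diagnostics columns
#' are restored from the companion file when present, otherwise NA.
#'
#' @param path Offset-table TSV.
#' @return An `offset_table`.
#' @export
read_offset_table <- function(path) {
  if (!file.exists(path)) asite_stop("offset table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!identical(names(df), c("size", "frame0", "frame1", "frame2")))
    asite_stop("offset table ", path, ": expected columns size, frame0, ",
               "frame1, frame2")
  rows <- list()
  for (i in seq_len(nrow(df))) for (F in 0:2) {
    cellv <- df[i, paste0("frame", F)]
    if (is.na(cellv) || cellv == "NA") {
      status <- "insufficient"; o1 <- NA_integer_; o2 <- NA_integer_
    } else if (grepl("/", cellv, fixed = TRUE)) {
      parts <- as.integer(strsplit(cellv, "/", fixed = TRUE)[[1]])
      status <- "ambiguous"; o1 <- parts[1]; o2 <- parts[2]
    } else {
      status <- "unique"; o1 <- as.integer(cellv); o2 <- NA_integer_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      size = as.integer(df$size[i]), frame = F, status = status,
      offset = o1, offset2 = o2,
      n_genes_eligible = NA_integer_, n_genes_voting = NA_integer_,
      vote_fraction = NA_real_, metagene_ratio = NA_real_)
  }
  tab <- do.call(rbind, rows)
  bad <- !is.na(tab$offset) &
    (tab$offset %% 3L != 0L | tab$offset < 0L | tab$offset > tab$size)
  if (any(bad))
    asite_stop("offset table ", path, ": offsets must be multiples of 3 in ",
               "[0, size]")
  class(tab) <- c("offset_table", "data.frame")
  tab
}
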