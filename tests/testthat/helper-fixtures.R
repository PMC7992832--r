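# Shared fixtures: direct tensor construction, an independent brute-force
# oracle for the offset objective, and constructed vote sets with a forced
# per-gene argmax.

options(asiteIP.log_level = "ERROR")

# Build a count_tensor straight from (gene, size, pos, count) rows; frame is
# derived from pos. cds_length is a named integer vector over all genes.
make_tensor <- function(df, cds_length, config) {
  df$frame <- ((df$pos %% 3) + 3) %% 3
  asiteIP:::new_count_tensor(
    data.table::data.table(gene = df$gene, size = as.integer(df$size),
                           frame = as.integer(df$frame),
                           pos = as.integer(df$pos),
                           count = as.integer(df$count)),
    cds_length, config)
}

# Independent oracle: plain-loop enumeration of the objective over all
# feasible offsets. Deliberately avoids every package helper.
oracle_score <- function(pos, count, L, S, delta, window_end = "stop") {
  hi <- if (window_end == "stop") L else L - 3
  tot <- 0L
  for (i in seq_along(pos)) {
    a <- pos[i] + delta
    if (a >= 3 && a < hi) tot <- tot + count[i]
  }
  tot
}

oracle_best_offsets <- function(pos, count, L, S, window_end = "stop") {
  if (sum(count) == 0) return(integer(0))
  deltas <- seq(0, S - (S %% 3), by = 3)
  sc <- integer(length(deltas))
  for (j in seq_along(deltas))
    sc[j] <- oracle_score(pos, count, L, S, deltas[j], window_end)
  if (max(sc) == 0) return(integer(0))
  as.integer(deltas[sc == max(sc)])
}

# Straight-line reference for a whole offset table: eligibility, votes,
# thresholds, re-implemented with simple loops over a plain data.frame.
oracle_offset_table <- function(rows, cds_length, config) {
  out <- list()
  for (S in config$size_min:config$size_max) for (F in 0:2) {
    votes <- integer(0); eligible <- character(0)
    for (g in names(cds_length)) {
      sel <- rows$gene == g & rows$size == S &
        ((rows$pos %% 3) + 3) %% 3 == F
      n <- sum(rows$count[sel])
      if (n == 0 || n / (cds_length[[g]] / 3) < config$min_reads_per_codon)
        next
      eligible <- c(eligible, g)
      best <- oracle_best_offsets(rows$pos[sel], rows$count[sel],
                                  cds_length[[g]], S, config$window_end)
      if (length(best) == 1) votes <- c(votes, best)
    }
    status <- "insufficient"; o1 <- NA_integer_; o2 <- NA_integer_
    if (length(votes) > 0) {
      tal <- table(votes)
      cand <- as.integer(names(tal)); nv <- as.integer(tal)
      ord <- order(-nv, cand); cand <- cand[ord]; nv <- nv[ord]
      vf <- nv[1] / length(votes)
      # metagene ratio at the modal offset over eligible genes
      c1 <- 0; c234 <- c(0, 0, 0)
      for (g in eligible) {
        sel <- rows$gene == g & rows$size == S &
          ((rows$pos %% 3) + 3) %% 3 == F
        codon <- (rows$pos[sel] + cand[1]) %/% 3 + 1
        c1 <- c1 + sum(rows$count[sel][codon == 1])
        for (k in 2:4) c234[k - 1] <- c234[k - 1] +
            sum(rows$count[sel][codon == k])
      }
      mr <- if (c1 == 0) { if (mean(c234) > 0) Inf else 0 } else mean(c234) / c1
      if (vf >= config$min_vote_fraction && length(votes) >= config$min_genes &&
          mr >= config$min_metagene_ratio) {
        status <- "unique"; o1 <- cand[1]
      } else if (length(cand) >= 2 && length(votes) >= config$min_genes) {
        status <- "ambiguous"; o1 <- cand[1]; o2 <- cand[2]
      }
    }
    out[[length(out) + 1]] <- data.frame(size = S, frame = F, status = status,
                                         offset = o1, offset2 = o2)
  }
  do.call(rbind, out)
}

# Random small tensor rows for fuzzing: <= 5 genes, <= 30 codons each.
random_tensor_rows <- function(n_genes = sample(1:5, 1),
                               sizes = 20:35, extra_nt = 35) {
  cds_length <- integer(0)
  rows <- list()
  for (i in seq_len(n_genes)) {
    g <- paste0("g", i)
    L <- 3L * sample(3:30, 1)
    cds_length[[g]] <- L
    n <- sample(1:40, 1)
    pos <- sample(seq(-extra_nt, L + extra_nt - 1), n, replace = TRUE)
    S <- sizes[sample.int(length(sizes), n, replace = TRUE)]
    rows[[i]] <- data.frame(gene = g, size = S, pos = pos,
                            count = sample(1:5, n, replace = TRUE))
  }
  rows <- do.call(rbind, rows)
  rows <- stats::aggregate(count ~ gene + size + pos, rows, sum)
  list(rows = rows, cds_length = cds_length)
}

# A gene whose argmax offset is forced to `delta`: a codon-2 read (beats
# delta-3) and a stop-codon read (beats delta+3) plus filler mid-CDS reads
# for eligibility. All at one (size, frame-0) cell.
vote_gene_rows <- function(gene, delta, L = 30L, S = 28L,
                           n_codon2 = 4L, n_stop = 4L, n_mid = 4L,
                           mid_local_nt = 15L) {
  data.frame(gene = gene,
             size = S,
             pos = c(3L - delta, L - 3L - delta, mid_local_nt - delta),
             count = c(n_codon2, n_stop, n_mid))
}

# 100-gene vote set: k genes vote offset 15, the rest vote 18, with
# geometries keeping the metagene ratio at the modal offset comfortably
# above threshold for every k in [50, 100].
mixed_vote_tensor <- function(k, n_genes = 100L, L = 30L, S = 28L, config) {
  rows <- list()
  for (i in seq_len(n_genes)) {
    g <- sprintf("g%03d", i)
    rows[[i]] <- if (i <= k)
      data.frame(gene = g, size = S,
                 pos = c(3L - 15L, L - 3L - 15L, 0L),
                 count = c(20L, 2L, 8L))            # argmax 15
    else
      data.frame(gene = g, size = S,
                 pos = c(3L - 18L, L - 3L - 18L, 15L - 18L),
                 count = c(1L, 1L, 8L))             # argmax 18
  }
  cds_length <- stats::setNames(rep(L, n_genes), sprintf("g%03d", seq_len(n_genes)))
  make_tensor(do.call(rbind, rows), cds_length, config)
}

# Minimal GFF3 writer for annotation fixtures. `features` is a data.frame
# with columns seqid, type, start, end, strand, attributes.
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                     features$seqid, features$type, features$start,
                     features$end, features$strand,
                     ifelse(features$type == "CDS", "0", "."),
                     features$attributes))
  writeLines(lines, path)
  path
}
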