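# ---------------------------------------------------------------------------
# Applying an offset table to 5'-end counts.
#
# Three profile sets are produced from the same tensor:
#   nt       : A-site nt position p + delta (offset used unmodified)
#   frame0   : p + delta - F, which maps frame-1/2 reads onto frame 0 by
#              reducing their offset by 1 and 2 respectively; every assigned
#              position is a multiple of 3
#   codon    : frame0 positions binned by codon (index = pos %/% 3)
# Internal indices are 0-based; file output is 1-based.
# ---------------------------------------------------------------------------

# resolve the offset used for each (size, frame) cell under a policy
resolve_offsets <- function(table, policy = c("drop_ambiguous", "use_first")) {
  policy <- match.arg(policy)
  delta <- ifelse(table$status == "unique", table$offset,
                  ifelse(table$status == "ambiguous" & policy == "use_first",
                         table$offset, NA_integer_))
  data.frame(size = table$size, frame = table$frame, delta = delta,
             status = table$status)
}

apply_offsets_impl <- function(tensor, table, policy, frame0) {
  stopifnot(inherits(tensor, "count_tensor"), inherits(table, "offset_table"))
  counts <- tensor$counts
  grid_needed <- unique(counts[, .(size, frame)])
  have <- paste(table$size, table$frame)
  missing <- !(paste(grid_needed$size, grid_needed$frame) %in% have)
  if (any(missing))
    asite_stop("offset table does not cover (size, frame) cells present in ",
               "the counts: ",
               paste(grid_needed$size[missing], grid_needed$frame[missing],
                     sep = "/", collapse = ", "))
  res <- resolve_offsets(table, policy)
  m <- merge(as.data.frame(counts), res, by = c("size", "frame"))

  usable <- !is.na(m$delta)
  dropped_no_offset <- sum(m$count[!usable])
  m <- m[usable, , drop = FALSE]
  eff <- if (frame0) m$delta - m$frame else m$delta
  target <- m$pos + eff
  L <- tensor$cds_length[m$gene]
  inside <- target >= 0L & target < L
  dropped_out_of_cds <- sum(m$count[!inside])
  m <- m[inside, , drop = FALSE]; target <- target[inside]

  profiles <- lapply(stats::setNames(nm = sort(names(tensor$cds_length))),
                     function(g) integer(tensor$cds_length[[g]]))
  if (nrow(m)) {
    agg <- stats::aggregate(m$count, by = list(gene = m$gene, pos = target),
                            FUN = sum)
    for (g in unique(agg$gene)) {
      sel <- agg$gene == g
      profiles[[g]][agg$pos[sel] + 1L] <- agg$x[sel]
    }
  }
  structure(list(resolution = "nucleotide", profiles = profiles,
                 assigned = sum(vapply(profiles, sum, integer(1))),
                 dropped_no_offset = dropped_no_offset,
                 dropped_out_of_cds = dropped_out_of_cds,
                 policy = policy),
            class = "density_profiles")
}

#' A-site density profiles at nucleotide resolution
#'
#' Each read at 5'-end position `p` in a (size, frame) cell with a usable
#' offset `delta` contributes one count at nt position `p + delta` of its
#' gene; positions outside the CDS are dropped and counted. Cells whose
#' offset is ambiguous are dropped under the default `drop_ambiguous` policy
#' (the recommended treatment of reads with uncertain A-site offsets) or
#' assigned with the top candidate under `use_first`; insufficient cells are
#' always dropped.
#'
#' @param tensor A `count_tensor`.
#' @param table An `offset_table` covering the tensor's (size, frame) cells.
#' @param policy `"drop_ambiguous"` (default) or `"use_first"`.
#' @return A `density_profiles` object: named list of per-gene integer
#'   vectors plus drop counters.
#' @export
apply_offsets_nt <- function(tensor, table,
                             policy = c("drop_ambiguous", "use_first"))
  apply_offsets_impl(tensor, table, match.arg(policy), frame0 = FALSE)

#' A-site density profiles mapped to frame 0
#'
#' As [apply_offsets_nt()], but a frame-F read uses the effective offset
#' `delta - F` (the offset is reduced by 1 for frame-1 reads and by 2 for
#' frame-2 reads), so every assigned nucleotide position is a multiple of 3.
#'
#' @inheritParams apply_offsets_nt
#' @export
apply_offsets_frame0 <- function(tensor, table,
                                 policy = c("drop_ambiguous", "use_first"))
  apply_offsets_impl(tensor, table, match.arg(policy), frame0 = TRUE)

#' A-site density profiles at codon resolution
#'
#' Frame-0 nucleotide profiles binned by codon: codon index
#' `pos %/% 3` (0-based internally; written 1-based), each codon summing its
#' three frame-0 nt positions.
#'
#' @inheritParams apply_offsets_nt
#' @export
apply_offsets_codon <- function(tensor, table,
                                policy = c("drop_ambiguous", "use_first")) {
  nt <- apply_offsets_frame0(tensor, table, match.arg(policy))
  profiles <- lapply(nt$profiles, function(v) {
    as.integer(rowsum(v, (seq_along(v) - 1L) %/% 3L))
  })
  nt$profiles <- profiles
  nt$resolution <- "codon"
  nt
}

#' @export
print.density_profiles <- function(x, ...) {
  cat(sprintf("density_profiles (%s resolution): %d genes, %d reads assigned (%d dropped: %d no-offset, %d outside CDS)\n",
              x$resolution, length(x$profiles), x$assigned,
              x$dropped_no_offset + x$dropped_out_of_cds,
              x$dropped_no_offset, x$dropped_out_of_cds))
  invisible(x)
}

#' Write density profiles in the tab dialect
#'
#' One line per gene: gene name, its length (nt or codons), then the read
#' count at every position, tab-separated. Genes are sorted by id, making
#' the output deterministic.
#'
#' @param profiles A `density_profiles` object.
#' @param path Output path.
#' @export
write_profile_tab <- function(profiles, path) {
  stopifnot(inherits(profiles, "density_profiles"))
  ids <- sort(names(profiles$profiles))
  lines <- vapply(ids, function(g) {
    v <- profiles$profiles[[g]]
    paste(c(g, length(v), v), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile tab file
#'
#' Inverse of [write_profile_tab()]; the resolution is not stored in the
#' file and must be supplied.
#'
#' @param path Profile tab file.
#' @param resolution `"nucleotide"` or `"codon"`.
#' @return A `density_profiles` object.
#' @export
read_profile_tab <- function(path, resolution = c("nucleotide", "codon")) {
  resolution <- match.arg(resolution)
  lines <- readLines(path, warn = FALSE)
  profiles <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      asite_stop("line ", i, " of ", path, ": too few fields")
    len <- as.integer(f[2])
    v <- as.integer(f[-(1:2)])
    if (length(v) != len)
      asite_stop("line ", i, " of ", path, ": declared length ", len,
                 " but ", length(v), " counts")
    profiles[[f[1]]] <- v
  }
  structure(list(resolution = resolution, profiles = profiles,
                 assigned = sum(vapply(profiles, sum, integer(1))),
                 dropped_no_offset = NA_integer_,
                 dropped_out_of_cds = NA_integer_,
                 policy = NA_character_),
            class = "density_profiles")
}

#' Raw 5'-end vs A-site per-codon comparison for one gene
#'
#' Returns paired per-codon arrays over the first `first_n_codons` codons of
#' one gene: the raw read density obtained by binning 5'-end positions
#' directly into codons, and the A-site density after applying the offset
#' table (codon resolution). On data with an initiation pause the A-site
#' array peaks at codon 2 while the raw array peaks upstream.
#'
#' @param gene_id Gene to export.
#' @param tensor A `count_tensor`.
#' @param table An `offset_table`.
#' @param first_n_codons Number of leading codons to return (default 30).
#' @param policy Ambiguity policy, as in [apply_offsets_nt()].
#' @return data.frame with columns `codon` (1-based), `raw`, `asite`.
#' @export
export_raw_vs_asite <- function(gene_id, tensor, table, first_n_codons = 30L,
                                policy = c("drop_ambiguous", "use_first")) {
  policy <- match.arg(policy)
  if (!gene_id %in% names(tensor$cds_length))
    asite_stop("gene ", gene_id, " not in tensor")
  L <- tensor$cds_length[[gene_id]]
  n <- min(as.integer(first_n_codons), L %/% 3L)
  raw <- integer(n)
  sub <- tensor$counts[gene == gene_id & pos >= 0L & pos < L]
  if (nrow(sub)) {
    cod <- sub$pos %/% 3L + 1L
    agg <- rowsum(sub$count, cod)
    idx <- as.integer(rownames(agg))
    keep <- idx <= n
    raw[idx[keep]] <- agg[keep, 1]
  }
  codon_prof <- apply_offsets_codon(tensor, table, policy)$profiles[[gene_id]]
  data.frame(codon = seq_len(n), raw = raw,
             asite = codon_prof[seq_len(n)])
}
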