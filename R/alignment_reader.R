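#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBam asBam
#'   countBam
#' @importFrom GenomicAlignments cigarWidthAlongQuerySpace
#'   cigarWidthAlongReferenceSpace
#' @import data.table
NULL

# Convert a SAM file to a temporary (sorted, indexed) BAM so that both input
# flavours go through the same reader. BAM paths are returned unchanged.
as_bam_path <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  } else path
}

#' Count read 5' ends in CDS-local coordinates
#'
#' Streams a SAM or BAM file of ribosome-protected-fragment alignments and
#' accumulates, per gene and per (fragment size, reading frame), the number
#' of read 5' ends at each CDS-local nucleotide position within
#' `[-extra_nt, cds_length_nt + extra_nt)`.
#'
#' Retention rules: an alignment is counted iff it is mapped, primary and
#' not supplementary; its strand matches the gene's strand (genome mode) or
#' is forward (transcriptome mode); its aligned query length S (soft clips
#' excluded) lies in `[size_min, size_max]`; its 5' end (the rightmost
#' reference coordinate for minus-strand alignments) maps into exactly one
#' gene's CDS-or-flank window. Reads whose 5' end falls in an intron, or in
#' the windows of two or more same-strand genes, are dropped and counted.
#' The reading frame is `F = p mod 3` of the local 5'-end position `p`
#' (non-negative residue).
#'
#' @param alignments Path to a SAM or BAM file.
#' @param annotation An `annotation_set`.
#' @param config A [job_config()].
#' @return A `count_tensor`: a list with `counts` (data.table with columns
#'   `gene`, `size`, `frame`, `pos`, `count`), `cds_length` (named integer
#'   vector over all annotation genes), `config`, and `stats` (per-rule drop
#'   counters summing with the retained count to the number of alignment
#'   records in the file).
#' @export
build_count_tensor <- function(alignments, annotation, config) {
  stopifnot(inherits(annotation, "annotation_set"),
            inherits(config, "job_config"))
  if (!file.exists(alignments))
    asite_stop("alignment file not found: ", alignments)
  bam <- as_bam_path(alignments)

  n_total <- Rsamtools::countBam(bam)$records
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "strand", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_primary <- length(res$pos)

  stats <- list(total = n_total,
                not_primary_or_unmapped = n_total - n_primary,
                size_out_of_range = 0L, unassigned_reference = 0L,
                strand_incompatible = 0L, outside_window = 0L,
                multi_gene_overlap = 0L, retained = 0L)

  if (n_primary == 0L) asite_stop("no primary mapped alignments in ", alignments)

  size <- GenomicAlignments::cigarWidthAlongQuerySpace(
    res$cigar, after.soft.clipping = TRUE)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  strand <- as.character(res$strand)
  pos0 <- res$pos - 1L                     # SAM 1-based -> 0-based
  p5 <- ifelse(strand == "+", pos0, pos0 + refw - 1L)
  rname <- as.character(res$rname)

  ok_size <- size >= config$size_min & size <= config$size_max
  stats$size_out_of_range <- sum(!ok_size)

  refs_known <- vapply(annotation$records, `[[`, "", "reference_name")
  ok_ref <- rname %in% refs_known
  if (any(!ok_ref & ok_size)) {
    stats$unassigned_reference <- sum(!ok_ref & ok_size)
    asite_log("WARNING", stats$unassigned_reference,
              " read(s) on references absent from the annotation")
  }
  cand <- which(ok_size & ok_ref)

  # strand compatibility per candidate read is gene-specific; collect
  # (read, gene, local pos) hits over all strand-compatible windows
  hits_read <- integer(0); hits_gene <- character(0); hits_pos <- integer(0)
  for (g in gene_ids(annotation)) {
    rec <- annotation$records[[g]]
    want_strand <- if (config$mode == "transcriptome") "+" else rec$strand
    sel <- cand[rname[cand] == rec$reference_name &
                strand[cand] == want_strand]
    if (!length(sel)) next
    loc <- ref_to_cds_local(rec, p5[sel], config$extra_nt)
    inwin <- !is.na(loc)
    if (any(inwin)) {
      hits_read <- c(hits_read, sel[inwin])
      hits_gene <- c(hits_gene, rep(g, sum(inwin)))
      hits_pos <- c(hits_pos, loc[inwin])
    }
  }

  # strand-incompatible: candidate reads on a known reference that hit no
  # same-strand window but would hit an opposite-strand gene's window
  unhit <- setdiff(cand, unique(hits_read))
  if (length(unhit)) {
    opp <- logical(length(unhit))
    for (g in gene_ids(annotation)) {
      rec <- annotation$records[[g]]
      want_strand <- if (config$mode == "transcriptome") "+" else rec$strand
      sel <- which(rname[unhit] == rec$reference_name &
                   strand[unhit] != want_strand)
      if (length(sel))
        opp[sel] <- opp[sel] |
          !is.na(ref_to_cds_local(rec, p5[unhit[sel]], config$extra_nt))
    }
    stats$strand_incompatible <- sum(opp)
    stats$outside_window <- length(unhit) - sum(opp)
  }

  dup <- hits_read %in% hits_read[duplicated(hits_read)]
  stats$multi_gene_overlap <- length(unique(hits_read[dup]))
  keep <- !dup
  stats$retained <- sum(keep)
  if (stats$retained == 0L)
    asite_stop("zero reads retained from ", alignments,
               " under the current configuration")

  dt <- data.table::data.table(gene = hits_gene[keep],
                               size = size[hits_read[keep]],
                               pos = hits_pos[keep])
  dt[, frame := pos %% 3L]
  counts <- dt[, .(count = .N), by = .(gene, size, frame, pos)]
  data.table::setkey(counts, gene, size, frame, pos)

  asite_log("INFO", "alignments: ", n_total, " records, ", stats$retained,
            " retained (", stats$not_primary_or_unmapped,
            " non-primary/unmapped, ", stats$size_out_of_range,
            " size out of range, ", stats$unassigned_reference,
            " unknown reference, ", stats$strand_incompatible,
            " strand-incompatible, ", stats$outside_window,
            " outside all windows, ", stats$multi_gene_overlap,
            " multi-gene overlap)")

  new_count_tensor(counts, cds_lengths(annotation), config, stats)
}

#' Construct a count tensor from explicit counts
#'
#' Programmatic constructor for workflows that already hold 5'-end counts
#' (e.g. constructed vote sets or external pipelines). The reading frame is
#' derived from the position; counts must be non-negative and sizes within
#' the configured range.
#'
#' @param counts data.frame with columns `gene`, `size`, `pos` (CDS-local
#'   5'-end position) and `count`.
#' @param cds_length Named integer vector of CDS lengths (nt) covering every
#'   gene.
#' @param config A [job_config()].
#' @return A `count_tensor`.
#' @export
count_tensor <- function(counts, cds_length, config) {
  stopifnot(all(c("gene", "size", "pos", "count") %in% names(counts)),
            inherits(config, "job_config"))
  if (any(counts$count < 0)) asite_stop("counts must be non-negative")
  if (any(counts$size < config$size_min | counts$size > config$size_max))
    asite_stop("sizes outside the configured [size_min, size_max] range")
  if (!all(counts$gene %in% names(cds_length)))
    asite_stop("cds_length missing for some genes")
  dt <- data.table::as.data.table(counts)
  dt[, frame := ((pos %% 3L) + 3L) %% 3L]
  agg <- dt[, .(count = sum(count)), by = .(gene, size, frame, pos)]
  new_count_tensor(agg, cds_length, config,
                   stats = list(total = sum(counts$count),
                                retained = sum(counts$count)))
}

new_count_tensor <- function(counts, cds_length, config, stats = list()) {
  counts <- data.table::as.data.table(counts)
  for (col in c("size", "frame", "pos", "count"))
    counts[[col]] <- as.integer(counts[[col]])
  data.table::setkey(counts, gene, size, frame, pos)
  structure(list(counts = counts, cds_length = cds_length,
                 config = config, stats = stats),
            class = "count_tensor")
}

#' @export
print.count_tensor <- function(x, ...) {
  cat(sprintf("count_tensor: %d genes with reads, %d (size,frame,pos) cells, %d reads\n",
              length(unique(x$counts$gene)), nrow(x$counts),
              sum(x$counts$count)))
  invisible(x)
}

#' Marginal read totals per (size, frame)
#'
#' @param tensor A `count_tensor`.
#' @return A data.frame with columns `size`, `frame`, `reads`; the totals sum
#'   to the number of retained reads.
#' @export
fragment_size_distribution <- function(tensor) {
  stopifnot(inherits(tensor, "count_tensor"))
  out <- tensor$counts[, .(reads = sum(count)), by = .(size, frame)]
  data.table::setorder(out, size, frame)
  as.data.frame(out)
}
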