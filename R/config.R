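#' Job configuration for offset and profile jobs
#'
#' Bundles the tunable parameters of an A-site offset or profile job and
#' validates them. All thresholds default to the method's canonical values:
#' genes must average at least one read per codon at a given (size, frame) to
#' be eligible, at least 70\% of voting genes must agree on the modal offset,
#' at least ten genes must vote, and the mean read count over codons 2--4 must
#' be at least five times the count in codon 1.
#'
#' @param size_min,size_max Fragment size range in nt (inclusive).
#' @param extra_nt Number of nt beyond the CDS over which read 5' ends are
#'   still assigned to a gene (and within which overlap with another gene is
#'   avoided). Defaults to `size_max`: an elongating ribosome whose A-site is
#'   at codon 2 leaves a 5' end up to S - 3 nt upstream of the start codon, so
#'   the flank must cover the largest fragment size for those reads to inform
#'   the offset.
#' @param min_reads_per_codon Gene-eligibility floor: reads at (size, frame)
#'   divided by the gene's codon count must reach this value (default 1).
#' @param min_vote_fraction Minimum fraction of voting genes sharing the modal
#'   offset for a unique call (default 0.7). Must be strictly greater than
#'   0.5; values at or below 0.5 are rejected.
#' @param min_genes Minimum number of voting genes for any decision
#'   (default 10).
#' @param min_metagene_ratio Minimum ratio of the mean read count in codons
#'   2--4 to the count in codon 1, evaluated at the modal offset across
#'   eligible genes (default 5).
#' @param mode Alignment mode, `"genome"` or `"transcriptome"`.
#' @param window_end `"stop"` (default) counts the stop codon as a legitimate
#'   A-site position (window nt 3 .. CDS end); `"sense"` excludes it.
#' @return A validated `job_config` object (a list).
#' @export
job_config <- function(size_min = 20L, size_max = 35L,
                       extra_nt = NULL,
                       min_reads_per_codon = 1,
                       min_vote_fraction = 0.7,
                       min_genes = 10L,
                       min_metagene_ratio = 5,
                       mode = c("genome", "transcriptome"),
                       window_end = c("stop", "sense")) {
  mode <- match.arg(mode)
  window_end <- match.arg(window_end)
  size_min <- as.integer(size_min); size_max <- as.integer(size_max)
  if (is.null(extra_nt)) extra_nt <- size_max
  extra_nt <- as.integer(extra_nt)
  min_genes <- as.integer(min_genes)

  if (!(size_min > 0L && size_min <= size_max))
    asite_stop("invalid size range: need 0 < size_min <= size_max, got [",
               size_min, ", ", size_max, "]")
  if (!(min_vote_fraction > 0.5 && min_vote_fraction <= 1))
    asite_stop("min_vote_fraction must lie in (0.5, 1]; got ",
               min_vote_fraction)
  if (extra_nt < 0L) asite_stop("extra_nt must be >= 0")
  if (min_genes < 1L) asite_stop("min_genes must be >= 1")
  if (!(min_metagene_ratio > 0)) asite_stop("min_metagene_ratio must be > 0")
  if (min_reads_per_codon < 0) asite_stop("min_reads_per_codon must be >= 0")

  structure(list(size_min = size_min, size_max = size_max,
                 extra_nt = extra_nt,
                 min_reads_per_codon = min_reads_per_codon,
                 min_vote_fraction = min_vote_fraction,
                 min_genes = min_genes,
                 min_metagene_ratio = min_metagene_ratio,
                 mode = mode, window_end = window_end),
            class = "job_config")
}

#' @export
print.job_config <- function(x, ...) {
  cat("A-site job configuration\n")
  cat(sprintf("  fragment sizes     : %d-%d nt\n", x$size_min, x$size_max))
  cat(sprintf("  flank (extra nt)   : %d\n", x$extra_nt))
  cat(sprintf("  min reads/codon    : %g\n", x$min_reads_per_codon))
  cat(sprintf("  min vote fraction  : %g\n", x$min_vote_fraction))
  cat(sprintf("  min voting genes   : %d\n", x$min_genes))
  cat(sprintf("  min metagene ratio : %g\n", x$min_metagene_ratio))
  cat(sprintf("  mode               : %s\n", x$mode))
  cat(sprintf("  A-site window end  : %s\n", x$window_end))
  invisible(x)
}

# feasible offsets for a fragment of size S: multiples of 3 in [0, S]
feasible_offsets <- function(S) seq.int(0L, 3L * (as.integer(S) %/% 3L), by = 3L)
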