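#' @import ggplot2
#' @importFrom jsonlite write_json toJSON
#' @importFrom tools md5sum
NULL

#' Eligible-gene counts per (size, frame)
#'
#' The number of genes passing the reads-per-codon eligibility filter in
#' every cell of the configured (size, frame) grid — the "number of genes
#' for various fragment size and frame combinations" diagnostic.
#'
#' @param tensor A `count_tensor`.
#' @param config A [job_config()].
#' @return data.frame with columns `size`, `frame`, `n_genes`.
#' @export
genes_per_cell <- function(tensor, config) {
  grid <- expand.grid(frame = 0:2,
                      size = seq.int(config$size_min, config$size_max))
  n <- mapply(function(S, F) length(filter_eligible_genes(tensor, S, F, config)),
              grid$size, grid$frame)
  data.frame(size = grid$size, frame = grid$frame, n_genes = as.integer(n))
}

#' Assemble a job report
#'
#' Collects everything needed to reproduce and audit a job: the
#' configuration echo, md5 digests of the input files, the per-rule read
#' drop counters, the size/frame distribution, the unthresholded offset
#' vote distribution and the eligible-genes table.
#'
#' @param config A [job_config()].
#' @param inputs Named character vector of input file paths.
#' @param tensor A `count_tensor`.
#' @param extra Optional named list merged into the report (e.g. output
#'   paths).
#' @return A `job_report` list.
#' @export
make_job_report <- function(config, inputs, tensor, extra = list()) {
  digests <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_, "")
  rep <- list(config = unclass(config),
              inputs = as.list(stats::setNames(digests, names(inputs))),
              input_paths = as.list(inputs),
              read_counters = tensor$stats,
              size_distribution = fragment_size_distribution(tensor),
              offset_votes = offset_vote_distribution(tensor, config),
              genes_per_cell = genes_per_cell(tensor, config),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  rep <- utils::modifyList(rep, extra)
  class(rep) <- "job_report"
  rep
}

#' Write report files and static plots
#'
#' Writes `report.json` (configuration echo, input digests, counters),
#' `size_distribution.tsv`, `offset_votes.tsv` and `genes_per_cell.tsv`,
#' plus static PNG plots of the size distribution per frame and of the
#' offset vote distribution. Every number shown in a plot is also present
#' in one of the TSVs; the plots are views, never the only record.
#'
#' @param report A `job_report` from [make_job_report()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(report, outdir) {
  stopifnot(inherits(report, "job_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wtsv(report$size_distribution, "size_distribution.tsv")
  wtsv(report$offset_votes, "offset_votes.tsv")
  wtsv(report$genes_per_cell, "genes_per_cell.tsv")

  jr <- report
  jr$size_distribution <- NULL; jr$offset_votes <- NULL
  jr$genes_per_cell <- NULL
  jp <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(jr), jp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, jp)

  if (nrow(report$size_distribution)) {
    sd <- report$size_distribution
    sd$frame <- factor(sd$frame)
    g1 <- ggplot(sd, aes(x = size, y = reads, colour = frame,
                         group = frame)) +
      geom_point() +
      { if (length(unique(sd$size)) > 1L) geom_line() } +
      labs(x = "fragment size (nt)", y = "reads",
           title = "Fragment size distribution by frame") +
      theme_minimal()
    p1 <- file.path(outdir, "size_distribution.png")
    ggsave(p1, g1, width = 6, height = 4, dpi = 120)
    files <- c(files, p1)
  }
  if (nrow(report$offset_votes)) {
    ov <- report$offset_votes
    ov$frame <- factor(ov$frame)
    g2 <- ggplot(ov, aes(x = offset, y = votes, fill = frame)) +
      geom_col(position = "dodge") +
      facet_wrap(~size) +
      labs(x = "A-site offset (nt)", y = "gene votes",
           title = "Offset distribution among genes") +
      theme_minimal()
    p2 <- file.path(outdir, "offset_votes.png")
    ggsave(p2, g2, width = 7, height = 5, dpi = 120)
    files <- c(files, p2)
  }
  invisible(files)
}
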