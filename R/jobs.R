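# ---------------------------------------------------------------------------
# High-level job runners mirroring the two job types (offset, profile) plus
# simulation, motif evaluation and annotation conversion. These back the
# `asite-ip` command-line script in inst/cli/ and are the programmatic entry
# points. Each writes a run.log and a report.json into the output directory.
# ---------------------------------------------------------------------------

with_run_log <- function(outdir, expr) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  old <- options(asiteIP.log_file = file.path(outdir, "run.log"))
  on.exit(options(old))
  force(expr)
}

load_annotation_for_job <- function(annotation_path, mode, filter_path = NULL,
                                    filter_mode = "include") {
  ann <- read_annotation(annotation_path, mode)
  if (!is.null(filter_path))
    ann <- apply_gene_filter(ann, filter_path, filter_mode)
  ann
}

#' Run an offset job
#'
#' Reads alignments and annotation, accumulates the 5'-end count tensor,
#' computes the A-site offset table, and writes `offset_table.tsv`,
#' `offset_table_diagnostics.tsv`, the diagnostics bundle (TSVs, plots,
#' `report.json`) and `run.log` into `output_dir`.
#'
#' @param alignments SAM or BAM path.
#' @param annotation_path GFF3 or TAB CDS annotation path.
#' @param output_dir Output directory.
#' @param config A [job_config()].
#' @param fasta Optional FASTA path (recorded in the report digests; the
#'   offset computation itself does not use sequence).
#' @param filter_path,filter_mode Optional gene filter
#'   (see [apply_gene_filter()]).
#' @return Invisibly, list with `offset_table`, `tensor` and `report`.
#' @export
run_offset_job <- function(alignments, annotation_path, output_dir,
                           config = job_config(), fasta = NULL,
                           filter_path = NULL, filter_mode = "include") {
  with_run_log(output_dir, {
    asite_log("INFO", "offset job started")
    ann <- load_annotation_for_job(annotation_path, config$mode,
                                   filter_path, filter_mode)
    tensor <- build_count_tensor(alignments, ann, config)
    table <- compute_offset_table(tensor, config)
    tpath <- file.path(output_dir, "offset_table.tsv")
    write_offset_table(table, tpath)
    inputs <- c(alignments = alignments, annotation = annotation_path)
    if (!is.null(fasta)) inputs <- c(inputs, fasta = fasta)
    if (!is.null(filter_path)) inputs <- c(inputs, filter = filter_path)
    report <- make_job_report(config, inputs, tensor,
                              extra = list(offset_table = tpath))
    render_report(report, output_dir)
    asite_log("INFO", "offset job finished: ", sum(table$status == "unique"),
              "/", nrow(table), " cells unique")
    invisible(list(offset_table = table, tensor = tensor, report = report))
  })
}

#' Run a profile job
#'
#' Applies a custom offset table to the counts and writes the three A-site
#' density profile sets — `profiles_nt.tab` (per nucleotide),
#' `profiles_frame0_nt.tab` (per nucleotide mapped to frame 0) and
#' `profiles_codon.tab` (per codon) — together with a drop-statistics JSON
#' sidecar, the diagnostics bundle and `run.log`.
#'
#' @inheritParams run_offset_job
#' @param offsets Path to an offset table TSV (dialect of
#'   [write_offset_table()]).
#' @param policy Treatment of (size, frame) cells with ambiguous offsets:
#'   `"drop_ambiguous"` (default, recommended) or `"use_first"`.
#' @return Invisibly, list with the three `density_profiles` objects and
#'   the report.
#' @export
run_profile_job <- function(alignments, annotation_path, offsets, output_dir,
                            config = job_config(), fasta = NULL,
                            filter_path = NULL, filter_mode = "include",
                            policy = c("drop_ambiguous", "use_first")) {
  policy <- match.arg(policy)
  with_run_log(output_dir, {
    asite_log("INFO", "profile job started (ambiguity policy: ", policy, ")")
    ann <- load_annotation_for_job(annotation_path, config$mode,
                                   filter_path, filter_mode)
    table <- read_offset_table(offsets)
    tensor <- build_count_tensor(alignments, ann, config)
    prof_nt <- apply_offsets_nt(tensor, table, policy)
    prof_f0 <- apply_offsets_frame0(tensor, table, policy)
    prof_cod <- apply_offsets_codon(tensor, table, policy)
    write_profile_tab(prof_nt, file.path(output_dir, "profiles_nt.tab"))
    write_profile_tab(prof_f0, file.path(output_dir, "profiles_frame0_nt.tab"))
    write_profile_tab(prof_cod, file.path(output_dir, "profiles_codon.tab"))
    drops <- list(policy = policy,
                  nt = prof_nt[c("assigned", "dropped_no_offset",
                                 "dropped_out_of_cds")],
                  frame0 = prof_f0[c("assigned", "dropped_no_offset",
                                     "dropped_out_of_cds")],
                  codon = prof_cod[c("assigned", "dropped_no_offset",
                                     "dropped_out_of_cds")])
    jsonlite::write_json(drops, file.path(output_dir, "drop_statistics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    inputs <- c(alignments = alignments, annotation = annotation_path,
                offsets = offsets)
    if (!is.null(fasta)) inputs <- c(inputs, fasta = fasta)
    report <- make_job_report(config, inputs, tensor)
    render_report(report, output_dir)
    asite_log("INFO", "profile job finished: ", prof_nt$assigned,
              " reads assigned at nt resolution")
    invisible(list(nt = prof_nt, frame0 = prof_f0, codon = prof_cod,
                   report = report))
  })
}

#' Convert a GFF3 annotation to the TAB CDS dialect
#'
#' @param gff_path Input GFF3.
#' @param out_path Output TAB annotation path.
#' @param mode Alignment mode the annotation targets.
#' @return Invisibly, `out_path`.
#' @export
convert_annotation <- function(gff_path, out_path,
                               mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  ann <- parse_gff(gff_path, mode)
  write_cds_table(ann, out_path)
  asite_log("INFO", "converted ", length(ann), " genes to ", out_path)
  invisible(out_path)
}

#' Run a simulation job
#'
#' Writes a complete synthetic dataset (FASTA, TAB annotation, SAM, truth
#' TSV) into `output_dir`; see [simulate_dataset()].
#'
#' @param spec_json Path to a JSON file of [synthetic_spec()] arguments
#'   (`true_offset_map` as an array of `{size, frame, offset}` objects;
#'   `stall_motifs` as an array of `{motif, enrichment, per_gene}` objects),
#'   or `NULL` for the default spec.
#' @param output_dir Output directory.
#' @param mode `"genome"` or `"transcriptome"`.
#' @param seed Overrides the spec's seed when non-NULL.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
run_simulate_job <- function(spec_json = NULL, output_dir,
                             mode = c("genome", "transcriptome"),
                             seed = NULL) {
  mode <- match.arg(mode)
  args <- if (!is.null(spec_json))
    jsonlite::fromJSON(spec_json, simplifyDataFrame = TRUE) else list()
  if (!is.null(args$stall_motifs) && is.data.frame(args$stall_motifs))
    args$stall_motifs <- split(args$stall_motifs,
                               seq_len(nrow(args$stall_motifs)))
  if (!is.null(seed)) args$seed <- as.integer(seed)
  spec <- do.call(synthetic_spec, args)
  with_run_log(output_dir, {
    asite_log("INFO", "simulating ", spec$n_genes, " genes (seed ",
              spec$seed, ", mode ", mode, ")")
    res <- simulate_dataset(spec, output_dir, mode)
    asite_log("INFO", "wrote ", nrow(res$truth$reads), " reads to ",
              res$paths$sam)
    invisible(res)
  })
}

#' Run a motif evaluation job
#'
#' Compares two offset tables at a stall motif (see
#' [evaluate_motif_offsets()]) and writes `motif_instances.tsv` and
#' `motif_summary.json` into `output_dir`.
#'
#' @inheritParams run_offset_job
#' @param offsets_a,offsets_b Paths to the two offset-table TSVs.
#' @param fasta Reference FASTA (required: motif search translates CDSs).
#' @param motif Amino-acid triplet (default "PPG").
#' @param min_density Floor on the pairwise-maximum density (default 1).
#' @return Invisibly, the [evaluate_motif_offsets()] result.
#' @export
run_motif_eval_job <- function(alignments, annotation_path, fasta,
                               offsets_a, offsets_b, output_dir,
                               config = job_config(), motif = "PPG",
                               min_density = 1) {
  with_run_log(output_dir, {
    asite_log("INFO", "motif evaluation started (", motif, ")")
    ann <- load_annotation_for_job(annotation_path, config$mode)
    tensor <- build_count_tensor(alignments, ann, config)
    res <- evaluate_motif_offsets(tensor, read_offset_table(offsets_a),
                                  read_offset_table(offsets_b),
                                  fasta, ann, motif = motif,
                                  min_density = min_density)
    utils::write.table(res$instances,
                       file.path(output_dir, "motif_instances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res[c("fraction_a_higher", "n", "signed_rank_p")],
                         file.path(output_dir, "motif_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    asite_log("INFO", sprintf(
      "motif evaluation finished: fraction A higher = %.3f (n = %d, p = %.3g)",
      res$fraction_a_higher, res$n, res$signed_rank_p))
    invisible(res)
  })
}
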