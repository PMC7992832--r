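# position (codon index, 1-based, of the THIRD residue) of every occurrence
# of an amino-acid triplet in a protein string; overlapping occurrences are
# all reported (scan every position)
find_triplet_positions <- function(aa, motif) {
  n <- nchar(aa)
  if (n < 3L) return(integer(0))
  starts <- which(vapply(seq_len(n - 2L), function(i)
    substr(aa, i, i + 2L) == motif, logical(1)))
  starts + 2L
}

#' Locate tripeptide motif instances in annotated CDSs
#'
#' Translates each gene's CDS with the standard genetic code and reports
#' every (possibly overlapping) occurrence of the amino-acid triplet. The
#' returned codon index is that of the motif's third residue — the codon
#' the ribosomal A-site occupies while a Pro-Pro-X stall is resolved, which
#' makes these motifs a positional ground truth for comparing offset
#' assignments. Genes whose CDS contains an internal stop codon are skipped
#' with a warning.
#'
#' @param seqs Reference sequences: a [Biostrings::DNAStringSet] or a FASTA
#'   path.
#' @param annotation An `annotation_set`.
#' @param motif Amino-acid triplet, e.g. `"PPG"`.
#' @return data.frame with columns `gene_id`, `codon_index` (1-based, third
#'   residue; always >= 3), `motif`, ordered by gene then position.
#' @export
find_motif_instances <- function(seqs, annotation, motif) {
  stopifnot(is.character(motif), nchar(motif) == 3L)
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- list()
  for (g in sort(gene_ids(annotation))) {
    rec <- annotation$records[[g]]
    cds <- extract_cds_seq(rec, seqs)
    aa <- as.character(Biostrings::translate(cds, if.fuzzy.codon = "X"))
    body <- substr(aa, 1L, nchar(aa) - 1L)    # final codon is the stop
    if (grepl("*", body, fixed = TRUE)) {
      asite_warn("gene ", g, " skipped: internal stop codon in CDS")
      next
    }
    at <- find_triplet_positions(body, motif)
    if (length(at))
      out[[g]] <- data.frame(gene_id = g, codon_index = at, motif = motif)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), codon_index = integer(0),
                      motif = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ribosome density at motif instances
#'
#' Looks up the codon-resolution density at each instance's third-residue
#' codon. Instances in genes with zero total coverage are excluded (and
#' logged), since they carry no signal under any offset assignment.
#'
#' @param codon_profiles A `density_profiles` object at codon resolution.
#' @param instances data.frame from [find_motif_instances()].
#' @return Numeric vector of densities, one per retained instance, with the
#'   retained rows of `instances` attached as attribute `"instances"`.
#' @export
density_at_instances <- function(codon_profiles, instances) {
  stopifnot(inherits(codon_profiles, "density_profiles"),
            codon_profiles$resolution == "codon")
  covered <- vapply(codon_profiles$profiles, function(v) sum(v) > 0, logical(1))
  keep <- instances$gene_id %in% names(covered)[covered]
  if (any(!keep))
    asite_log("INFO", sum(!keep),
              " motif instance(s) in zero-coverage genes excluded")
  inst <- instances[keep, , drop = FALSE]
  dens <- vapply(seq_len(nrow(inst)), function(i) {
    v <- codon_profiles$profiles[[inst$gene_id[i]]]
    k <- inst$codon_index[i]
    if (k <= length(v)) as.numeric(v[k]) else NA_real_
  }, numeric(1))
  ok <- !is.na(dens)
  structure(dens[ok], instances = inst[ok, , drop = FALSE])
}

#' Paired comparison of two offset assignments at motif instances
#'
#' Given paired densities at the same motif instances under two competing
#' offset tables, reports the fraction of instances where assignment A
#' yields the higher density (ties count for neither side) and a two-sided
#' Wilcoxon signed-rank p-value on the paired differences. When all pairs
#' are tied the test is degenerate and p = 1 is returned.
#'
#' @param densities_a,densities_b Equal-length paired numeric vectors.
#' @return List with `fraction_a_higher`, `n`, and `signed_rank_p`.
#' @export
paired_offset_comparison <- function(densities_a, densities_b) {
  if (length(densities_a) != length(densities_b))
    asite_stop("paired density vectors must have equal length")
  n <- length(densities_a)
  if (n < 1L) asite_stop("need at least one instance pair")
  frac <- sum(densities_a > densities_b) / n
  d <- densities_a - densities_b
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(densities_a, densities_b,
                                        paired = TRUE, exact = FALSE)$p.value)
  list(fraction_a_higher = frac, n = n, signed_rank_p = p)
}

#' Compare two offset tables at a stall motif
#'
#' End-to-end motif evaluation: locates `motif` instances, builds codon
#' profiles under each offset table, pairs the densities at the third
#' residue, applies a `min_density` floor on the pairwise maximum (a
#' reproducible surrogate for restricting to the strongest instances), and
#' runs [paired_offset_comparison()].
#'
#' @param tensor A `count_tensor`.
#' @param table_a,table_b Two `offset_table`s to compare.
#' @param seqs Reference sequences (`DNAStringSet` or FASTA path).
#' @param annotation An `annotation_set`.
#' @param motif Amino-acid triplet.
#' @param min_density Instances whose density is below this under both
#'   tables are excluded (default 1 read).
#' @param policy Ambiguity policy for profile building.
#' @return List with the summary of [paired_offset_comparison()] plus the
#'   per-instance table (`instances` with `density_a`, `density_b`).
#' @export
evaluate_motif_offsets <- function(tensor, table_a, table_b, seqs, annotation,
                                   motif = "PPG", min_density = 1,
                                   policy = c("drop_ambiguous", "use_first")) {
  policy <- match.arg(policy)
  inst <- find_motif_instances(seqs, annotation, motif)
  if (!nrow(inst)) asite_stop("no instances of motif ", motif, " found")
  prof_a <- apply_offsets_codon(tensor, table_a, policy)
  prof_b <- apply_offsets_codon(tensor, table_b, policy)
  da <- density_at_instances(prof_a, inst)
  db <- density_at_instances(prof_b, inst)
  ia <- attr(da, "instances"); ib <- attr(db, "instances")
  key_a <- paste(ia$gene_id, ia$codon_index)
  key_b <- paste(ib$gene_id, ib$codon_index)
  common <- intersect(key_a, key_b)
  a <- as.numeric(da)[match(common, key_a)]
  b <- as.numeric(db)[match(common, key_b)]
  keep <- pmax(a, b) >= min_density
  if (!any(keep))
    asite_stop("no motif instance reaches min_density = ", min_density)
  cmp <- paired_offset_comparison(a[keep], b[keep])
  inst_out <- ia[match(common, key_a)[keep], c("gene_id", "codon_index", "motif")]
  inst_out$density_a <- a[keep]; inst_out$density_b <- b[keep]
  rownames(inst_out) <- NULL
  c(cmp, list(instances = inst_out))
}

#' Shift every decided offset in a table by a fixed amount
#'
#' Utility for misassignment experiments: adds `shift_nt` (a multiple of 3)
#' to each unique/ambiguous offset, clamping within `[0, size]`.
#'
#' @param table An `offset_table`.
#' @param shift_nt Shift in nt (multiple of 3).
#' @return The shifted `offset_table`.
#' @export
shift_offset_table <- function(table, shift_nt = 3L) {
  stopifnot(shift_nt %% 3L == 0L)
  clamp <- function(o, S) pmin(pmax(o + shift_nt, 0L), (S %/% 3L) * 3L)
  table$offset <- ifelse(is.na(table$offset), NA_integer_,
                         clamp(table$offset, table$size))
  table$offset2 <- ifelse(is.na(table$offset2), NA_integer_,
                          clamp(table$offset2, table$size))
  table
}
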