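# ---------------------------------------------------------------------------
# Ground-truth Ribo-Seq simulator.
#
# The generator emulates steady-state elongation: ribosome A-sites are drawn
# only from codon 2 through the stop codon of each CDS, codon 2 may carry an
# initiation-pause multiplier, and selected tripeptide motifs may carry a
# stall multiplier on their third codon. Fragment sizes follow a discrete
# distribution; a fragment of size S whose 5' end lies in frame F is placed
# at p = a - (delta(S,F) - F), where a is the A-site start, matching the
# frame-0 convention in which frame-1/2 offsets act reduced by 1 and 2.
# ---------------------------------------------------------------------------

.sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.default_offset_map <- function() {
  data.frame(size = rep(c(28L, 29L, 30L, 31L), each = 3),
             frame = rep(0:2, 4),
             offset = rep(c(15L, 15L, 18L, 18L), each = 3))
}

#' Specification of a synthetic ribosome-profiling dataset
#'
#' Defines the study conditions of the simulator. Defaults describe a small
#' but realistic steady-state experiment: 30 genes of 60 codons, the
#' canonical yeast offset geometry (15 nt for 28-29 nt fragments, 18 nt for
#' 30-31 nt fragments, in every frame), 10 reads per codon per (size, frame)
#' class, and no noise.
#'
#' @param n_genes Number of genes.
#' @param codons_per_gene Integer range (length 1 or 2) of codons per gene,
#'   including start and stop codons.
#' @param true_offset_map data.frame with columns `size`, `frame`, `offset`;
#'   offsets must be multiples of 3 in `[0, size]`.
#' @param size_distribution Named numeric vector of probabilities over the
#'   fragment sizes in `true_offset_map` (default uniform).
#' @param frame_probs Probabilities of a read's 5' end lying in frame
#'   0/1/2 (default uniform).
#' @param reads_per_codon Expected per-codon read depth within each
#'   (size, frame) class (default 10).
#' @param initiation_pause_factor Multiplier on the codon-2 A-site
#'   probability, emulating the pause while the start codon occupies the
#'   P-site (default 1 = no pause).
#' @param stall_motifs Optional list of lists with elements `motif`
#'   (amino-acid triplet, e.g. "PPG"), `enrichment` (A-site density
#'   multiplier on the third codon, >= 1) and `per_gene` (instances seeded
#'   per gene, default 1).
#' @param noise_fraction Fraction of reads with uniformly random in-CDS 5'
#'   ends (default 0).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 30L,
                           codons_per_gene = 60L,
                           true_offset_map = .default_offset_map(),
                           size_distribution = NULL,
                           frame_probs = c(1, 1, 1) / 3,
                           reads_per_codon = 10,
                           initiation_pause_factor = 1,
                           stall_motifs = NULL,
                           noise_fraction = 0,
                           seed = 1L) {
  true_offset_map <- as.data.frame(true_offset_map)
  stopifnot(all(c("size", "frame", "offset") %in% names(true_offset_map)))
  with(true_offset_map, {
    if (any(offset %% 3 != 0 | offset < 0 | offset > size))
      asite_stop("true offsets must be multiples of 3 in [0, size]")
  })
  if (anyDuplicated(true_offset_map[c("size", "frame")]))
    asite_stop("duplicate (size, frame) in true_offset_map")
  sizes <- sort(unique(true_offset_map$size))
  if (is.null(size_distribution))
    size_distribution <- stats::setNames(rep(1 / length(sizes), length(sizes)),
                                         sizes)
  if (abs(sum(size_distribution) - 1) > 1e-8)
    asite_stop("size_distribution must sum to 1")
  if (!setequal(names(size_distribution), as.character(sizes)))
    asite_stop("size_distribution names must match the offset map sizes")
  if (length(frame_probs) != 3L || abs(sum(frame_probs) - 1) > 1e-8)
    asite_stop("frame_probs must be 3 probabilities summing to 1")
  if (!is.null(stall_motifs)) {
    for (m in stall_motifs) {
      stopifnot(is.character(m$motif), nchar(m$motif) == 3L)
      if (is.null(m$enrichment) || m$enrichment < 1)
        asite_stop("stall motif enrichment must be >= 1")
    }
  }
  if (noise_fraction < 0 || noise_fraction > 1)
    asite_stop("noise_fraction must lie in [0, 1]")
  if (length(codons_per_gene) == 1L) codons_per_gene <- rep(codons_per_gene, 2)
  if (codons_per_gene[1] < 4L)
    asite_stop("genes need at least 4 codons (start, two sense, stop)")
  structure(list(n_genes = as.integer(n_genes),
                 codons_per_gene = as.integer(codons_per_gene),
                 true_offset_map = true_offset_map,
                 size_distribution = size_distribution,
                 frame_probs = frame_probs,
                 reads_per_codon = reads_per_codon,
                 initiation_pause_factor = initiation_pause_factor,
                 stall_motifs = stall_motifs,
                 noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# reverse-translate one amino acid to an arbitrary codon (first in table)
.aa_to_codon <- local({
  tab <- NULL
  function(aa) {
    if (is.null(tab)) {
      cods <- .sense_codons()
      aas <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(cods), no.init.codon = TRUE))
      tab <<- stats::setNames(cods, aas)[!duplicated(aas)]
    }
    out <- tab[strsplit(aa, "")[[1]]]
    if (anyNA(out)) asite_stop("cannot encode amino acid(s) in '", aa, "'")
    unname(out)
  }
})

#' Generate a synthetic reference and its annotation
#'
#' Builds one reference sequence per gene: 50 nt of random flank, the CDS
#' (ATG start, random sense codons, TAA stop), and 50 nt of trailing flank.
#' In genome mode genes alternate between the + and - strand (the minus
#' reference carries the reverse complement), exercising both coordinate
#' paths; in transcriptome mode all records are single-segment "+". Stall
#' motifs from the spec are seeded at random interior positions, `per_gene`
#' instances per gene. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param mode `"genome"` or `"transcriptome"`.
#' @return List with `seqs` (a [Biostrings::DNAStringSet] of references) and
#'   `annotation` (an `annotation_set`).
#' @export
make_transcriptome <- function(spec, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  set.seed(spec$seed)
  flank <- 50L
  sense <- .sense_codons()
  records <- list()
  seqs <- character(spec$n_genes)
  refnames <- character(spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    gid <- sprintf("gene%03d", i)
    n_cod <- if (spec$codons_per_gene[1] == spec$codons_per_gene[2])
      spec$codons_per_gene[1]
    else sample(spec$codons_per_gene[1]:spec$codons_per_gene[2], 1L)
    body <- sample(sense, n_cod - 2L, replace = TRUE)
    # seed stall motifs at interior positions (codons 3 .. n-4), first codon
    # of the triplet; instances kept non-overlapping
    if (!is.null(spec$stall_motifs)) {
      slots <- 3:(n_cod - 5L)
      for (m in spec$stall_motifs) {
        per <- m$per_gene %||% 1L
        placed <- integer(0)
        cods <- .aa_to_codon(m$motif)
        tries <- 0L
        while (length(placed) < per && tries < 100L) {
          tries <- tries + 1L
          at <- slots[sample.int(length(slots), 1L)]
          if (any(abs(at - placed) < 3L)) next
          body[(at - 1L):(at + 1L)] <- cods   # body[k] is codon k+1 of CDS
          placed <- c(placed, at)
        }
      }
    }
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    mrna <- paste0(
      paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE), collapse = ""),
      cds,
      paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE), collapse = ""))
    refnames[i] <- if (mode == "genome") sprintf("ref%03d", i) else gid
    strand <- if (mode == "genome" && i %% 2L == 0L) "-" else "+"
    seqs[i] <- if (strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(mrna)))
    else mrna
    records[[gid]] <- cds_record(gid, refnames[i], strand,
                                 cbind(flank, flank + nchar(cds)))
  }
  seqset <- Biostrings::DNAStringSet(stats::setNames(seqs, refnames))
  list(seqs = seqset, annotation = annotation_set(records, mode))
}

#' Simulate ribosome footprints with known offsets
#'
#' Draws A-site codons per gene from codon 2 through the stop codon (with
#' initiation-pause and stall-motif multipliers), fragment sizes and frames
#' from the spec's distributions, places each 5' end at
#' `A-site start - (offset - frame)`, and writes a valid SAM file (with
#' `@SQ` headers and correct flags and sequences on both strands). A
#' `noise_fraction` of reads instead get uniform in-CDS 5' ends.
#'
#' @param spec A [synthetic_spec()].
#' @param transcriptome Result of [make_transcriptome()] (its `seqs` and
#'   `annotation`).
#' @param sam_path Output SAM path.
#' @return Invisibly, a `synthetic_truth` list: `reads` (data.frame with
#'   gene, a_codon, size, frame, offset, p5_local, noise flag),
#'   `true_offset_map`, and `seed`.
#' @export
simulate_footprints <- function(spec, transcriptome, sam_path) {
  annotation <- transcriptome$annotation
  seqs <- transcriptome$seqs
  set.seed(spec$seed + 1L)
  map <- spec$true_offset_map
  map_key <- paste(map$size, map$frame)
  sizes <- as.integer(names(spec$size_distribution))
  n_cells <- nrow(map)

  all_reads <- list()
  for (g in gene_ids(annotation)) {
    rec <- annotation$records[[g]]
    n_cod <- rec$cds_length_nt %/% 3L
    w <- rep(1, n_cod - 1L)               # A-site codons 2..n_cod
    w[1] <- w[1] * spec$initiation_pause_factor
    if (!is.null(spec$stall_motifs)) {
      aa <- as.character(Biostrings::translate(extract_cds_seq(rec, seqs)))
      for (m in spec$stall_motifs) {
        at <- find_triplet_positions(aa, m$motif)   # codon of 3rd residue
        at <- at[at >= 2L & at <= n_cod]
        w[at - 1L] <- w[at - 1L] * m$enrichment
      }
    }
    n_reads <- stats::rpois(1L, spec$reads_per_codon * n_cod * n_cells)
    if (n_reads == 0L) next
    a_codon <- sample(2:n_cod, n_reads, replace = TRUE, prob = w)
    S <- sizes[sample.int(length(sizes), n_reads, replace = TRUE,
                          prob = spec$size_distribution[as.character(sizes)])]
    F <- sample(0:2, n_reads, replace = TRUE, prob = spec$frame_probs)
    delta <- map$offset[match(paste(S, F), map_key)]
    if (anyNA(delta))
      asite_stop("true_offset_map has no entry for a sampled (size, frame)")
    p5 <- (a_codon - 1L) * 3L - (delta - F)
    noise <- stats::runif(n_reads) < spec$noise_fraction
    if (any(noise)) {
      p5[noise] <- sample.int(rec$cds_length_nt, sum(noise),
                              replace = TRUE) - 1L
      F[noise] <- p5[noise] %% 3L
      delta[noise] <- NA_integer_
      a_codon[noise] <- NA_integer_
    }
    all_reads[[g]] <- data.frame(gene = g, a_codon = a_codon, size = S,
                                 frame = F, offset = delta, p5_local = p5,
                                 noise = noise)
  }
  reads <- do.call(rbind, all_reads)
  rownames(reads) <- NULL
  write_sam(reads, annotation, seqs, sam_path)
  invisible(structure(list(reads = reads,
                           true_offset_map = map,
                           seed = spec$seed),
                      class = "synthetic_truth"))
}

# Emit a SAM file for simulated reads. Plain single-exon alignments: CIGAR
# "<S>M", flag 0 or 16, MAPQ 255, sequence taken from the reference (reverse
# complemented on the minus strand).
write_sam <- function(reads, annotation, seqs, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), Biostrings::width(seqs)))
  body <- character(nrow(reads))
  for (g in unique(reads$gene)) {
    rec <- annotation$records[[g]]
    idx <- which(reads$gene == g)
    p <- reads$p5_local[idx]; S <- reads$size[idx]
    if (rec$strand == "+") {
      seg0 <- rec$segments[1, 1]
      pos1 <- seg0 + p + 1L                  # SAM 1-based leftmost
      flag <- 0L
      sq <- as.character(Biostrings::extractAt(
        seqs[[rec$reference_name]],
        IRanges::IRanges(start = pos1, width = S)))
    } else {
      segend <- rec$segments[1, 2]
      pos1 <- segend - p - S + 1L
      flag <- 16L
      sq <- as.character(Biostrings::reverseComplement(Biostrings::extractAt(
        seqs[[rec$reference_name]],
        IRanges::IRanges(start = pos1, width = S))))
    }
    body[idx] <- sprintf("read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                         idx, flag, rec$reference_name, pos1, S, sq)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a complete synthetic dataset to a directory
#'
#' Convenience wrapper over [make_transcriptome()] and
#' [simulate_footprints()]: writes `reference.fa`, `annotation.tab`,
#' `reads.sam` and `truth.tsv` (per-read ground truth plus the true offset
#' map and seed in the header comments).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param mode `"genome"` or `"transcriptome"`.
#' @return Invisibly, list with `paths` (named list: `fasta`, `annotation`,
#'   `sam`, `truth`), plus the in-memory `annotation`, `seqs` and `truth`.
#' @export
simulate_dataset <- function(spec, dir, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- make_transcriptome(spec, mode)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                annotation = file.path(dir, "annotation.tab"),
                sam = file.path(dir, "reads.sam"),
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(tx$seqs, paths$fasta)
  write_cds_table(tx$annotation, paths$annotation)
  truth <- simulate_footprints(spec, tx, paths$sam)
  hdr <- c(sprintf("# seed=%d", truth$seed),
           sprintf("# true_offset size=%d frame=%d offset=%d",
                   truth$true_offset_map$size, truth$true_offset_map$frame,
                   truth$true_offset_map$offset))
  con <- file(paths$truth, "w")
  writeLines(hdr, con)
  utils::write.table(truth$reads, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(list(paths = paths, annotation = tx$annotation, seqs = tx$seqs,
                 truth = truth))
}

# Build a count_tensor directly from a synthetic_truth object (no SAM round
# trip); used where a test targets downstream machinery rather than
# alignment ingestion.
truth_to_tensor <- function(truth, annotation, config) {
  r <- truth$reads
  keep <- r$size >= config$size_min & r$size <= config$size_max &
    r$p5_local >= -config$extra_nt &
    r$p5_local < cds_lengths(annotation)[r$gene] + config$extra_nt
  r <- r[keep, , drop = FALSE]
  dt <- data.table::data.table(gene = r$gene, size = r$size,
                               pos = r$p5_local)
  dt[, frame := pos %% 3L]
  counts <- dt[, .(count = .N), by = .(gene, size, frame, pos)]
  new_count_tensor(counts, cds_lengths(annotation), config,
                   stats = list(total = nrow(truth$reads),
                                retained = sum(keep)))
}
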