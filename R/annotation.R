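#' @importFrom rtracklayer import
#' @importFrom S4Vectors mcols
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#'   subseq translate
NULL

# ---------------------------------------------------------------------------
# CdsRecord / annotation_set
#
# A CdsRecord stores one gene's CDS geometry: reference name, strand, and the
# ordered CDS segments as a 2-column (start, end) matrix, 0-based half-open,
# in 5'->3' order along the mRNA (for "-" genes the first segment is the one
# with the highest reference coordinates). Local coordinate 0 is the first nt
# of the start codon on both strands, so all downstream arithmetic is
# strand-agnostic. The CDS includes the stop codon.
# ---------------------------------------------------------------------------

cds_record <- function(gene_id, reference_name, strand, segments) {
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (any(segments[, 2] <= segments[, 1]))
    asite_stop("gene ", gene_id, ": empty or inverted CDS segment")
  if (!strand %in% c("+", "-"))
    asite_stop("gene ", gene_id, ": strand must be '+' or '-'")
  # order 5'->3' along the mRNA
  ord <- order(segments[, 1], decreasing = (strand == "-"))
  segments <- segments[ord, , drop = FALSE]
  # non-overlap / strict ordering along the strand
  by_coord <- segments[order(segments[, 1]), , drop = FALSE]
  if (nrow(by_coord) > 1 &&
      any(by_coord[-1, 1] < by_coord[-nrow(by_coord), 2]))
    asite_stop("gene ", gene_id, ": overlapping CDS segments")
  len <- sum(segments[, 2] - segments[, 1])
  structure(list(gene_id = gene_id, reference_name = reference_name,
                 strand = strand, segments = segments,
                 cds_length_nt = as.integer(len)),
            class = "cds_record")
}

record_is_valid <- function(rec) {
  rec$cds_length_nt %% 3L == 0L && rec$cds_length_nt >= 9L
}

annotation_set <- function(records, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  ids <- vapply(records, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    asite_stop("duplicate gene_id in annotation: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(records) <- ids
  if (mode == "transcriptome") {
    bad <- vapply(records, function(r)
      nrow(r$segments) != 1L || r$strand != "+", logical(1))
    if (any(bad))
      asite_stop("transcriptome mode requires single-segment '+' records; ",
                 "offending genes: ", paste(ids[bad], collapse = ", "))
  }
  structure(list(records = records, mode = mode), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes (%s mode)\n",
              length(x$records), x$mode))
  lens <- vapply(x$records, `[[`, integer(1), "cds_length_nt")
  if (length(lens))
    cat(sprintf("  CDS length (nt): min %d / median %g / max %d\n",
                min(lens), stats::median(lens), max(lens)))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$records)

gene_ids <- function(annotation) names(annotation$records)

cds_lengths <- function(annotation)
  vapply(annotation$records, `[[`, integer(1), "cds_length_nt")

# ---------------------------------------------------------------------------
# Coordinate mapping (vectorised over positions)
# ---------------------------------------------------------------------------

# CDS-local position l (0-based, 0 = first nt of start codon) -> reference
# coordinate. l may extend beyond the CDS: negative values run into the 5'
# flank, values >= cds_length_nt into the 3' flank, linearly beyond the
# terminal segments.
cds_local_to_ref <- function(rec, l) {
  widths <- rec$segments[, 2] - rec$segments[, 1]
  cum0 <- cumsum(c(0L, widths))              # local start of each segment
  L <- rec$cds_length_nt
  seg <- findInterval(l, cum0, left.open = FALSE)   # 1..nseg for in-CDS
  seg[l < 0] <- 0L
  seg[l >= L] <- length(widths) + 1L
  out <- integer(length(l))
  plus <- rec$strand == "+"
  inside <- seg >= 1L & seg <= length(widths)
  if (any(inside)) {
    off <- l[inside] - cum0[seg[inside]]
    out[inside] <- if (plus) rec$segments[seg[inside], 1] + off
                   else      rec$segments[seg[inside], 2] - 1L - off
  }
  up <- seg == 0L
  if (any(up)) out[up] <- if (plus) rec$segments[1, 1] + l[up]
                          else      rec$segments[1, 2] - 1L - l[up]
  dn <- seg == length(widths) + 1L
  if (any(dn)) {
    nlast <- nrow(rec$segments)
    out[dn] <- if (plus) rec$segments[nlast, 2] + (l[dn] - L)
               else      rec$segments[nlast, 1] - 1L - (l[dn] - L)
  }
  out
}

# Reference coordinate -> CDS-local position, or NA when the coordinate falls
# in an intron or beyond the +/- extra_nt flank.
ref_to_cds_local <- function(rec, refpos, extra_nt = 0L) {
  L <- rec$cds_length_nt
  widths <- rec$segments[, 2] - rec$segments[, 1]
  cum0 <- cumsum(c(0L, widths))
  out <- rep(NA_integer_, length(refpos))
  for (k in seq_len(nrow(rec$segments))) {
    s <- rec$segments[k, 1]; e <- rec$segments[k, 2]
    hit <- refpos >= s & refpos < e
    if (any(hit)) {
      out[hit] <- if (rec$strand == "+") cum0[k] + (refpos[hit] - s)
                  else                   cum0[k] + (e - 1L - refpos[hit])
    }
  }
  if (extra_nt > 0L) {
    if (rec$strand == "+") {
      s1 <- rec$segments[1, 1]; eN <- rec$segments[nrow(rec$segments), 2]
      up <- is.na(out) & refpos < s1 & refpos >= s1 - extra_nt
      out[up] <- refpos[up] - s1
      dn <- is.na(out) & refpos >= eN & refpos < eN + extra_nt
      out[dn] <- L + (refpos[dn] - eN)
    } else {
      e1 <- rec$segments[1, 2]; sN <- rec$segments[nrow(rec$segments), 1]
      up <- is.na(out) & refpos >= e1 & refpos < e1 + extra_nt
      out[up] <- e1 - 1L - refpos[up]
      dn <- is.na(out) & refpos < sN & refpos >= sN - extra_nt
      out[dn] <- L + (sN - 1L - refpos[dn])
    }
  }
  out
}

# Extract the CDS nucleotide sequence (5'->3' mRNA sense) for one record from
# a DNAStringSet of reference sequences.
extract_cds_seq <- function(rec, seqs) {
  if (!rec$reference_name %in% names(seqs))
    asite_stop("reference ", rec$reference_name, " absent from sequences")
  ref <- seqs[[rec$reference_name]]
  parts <- lapply(seq_len(nrow(rec$segments)), function(k) {
    piece <- subseq(ref, start = rec$segments[k, 1] + 1L,
                    end = rec$segments[k, 2])
    if (rec$strand == "-") reverseComplement(piece) else piece
  })
  do.call(Biostrings::xscat, parts)
}

# ---------------------------------------------------------------------------
# Parsers
# ---------------------------------------------------------------------------

#' Parse a GFF3 annotation into CDS records
#'
#' Reads CDS features from a GFF3 file, groups them per gene (taking the
#' first-encountered mRNA when a gene has several isoforms), converts the
#' 1-based inclusive GFF coordinates to the package's 0-based half-open
#' convention, and validates each gene: the summed CDS length must be a
#' multiple of 3 (the CDS is taken to include the stop codon) and at least
#' 9 nt. Genes failing validation are skipped with a warning rather than
#' truncated, since silent truncation would shift reading frames.
#'
#' @param path Path to a GFF3 file.
#' @param mode `"genome"` or `"transcriptome"`. Transcriptome-mode records
#'   must be single-segment and on the "+" strand.
#' @return An `annotation_set`.
#' @export
parse_gff <- function(path, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) asite_stop("GFF file not found: ", path)
  # structural pre-check so malformed lines are reported with their number
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  body_end <- if (length(fasta_at)) fasta_at[1] - 1L else length(lines)
  for (i in seq_len(body_end)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L)
      asite_stop("malformed GFF line ", i, ": expected 9 tab-separated ",
                 "columns in ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)

  # map mRNA/transcript id -> owning gene id (first mRNA per gene wins)
  tx2gene <- character(0)
  is_tx <- typ %in% c("mRNA", "transcript")
  if (any(is_tx)) {
    txid <- as.character(md$ID[is_tx])
    par <- md$Parent[is_tx]
    txgene <- vapply(seq_along(txid), function(j) {
      p <- par[[j]]
      if (length(p)) as.character(p[[1]]) else txid[j]
    }, "")
    tx2gene <- stats::setNames(txgene, txid)
  }

  is_cds <- typ == "CDS"
  if (!any(is_cds)) asite_stop("no CDS features in ", path)
  cds <- gr[is_cds]
  cmd <- S4Vectors::mcols(cds)
  parent_of <- function(j) {
    p <- cmd$Parent[[j]]
    if (length(p)) return(as.character(p[[1]]))
    for (fld in c("gene_id", "ID", "Name"))
      if (!is.null(cmd[[fld]]) && !is.na(cmd[[fld]][j]))
        return(as.character(cmd[[fld]][j]))
    asite_stop("CDS feature without Parent/gene_id/ID attribute in ", path)
  }
  parents <- vapply(seq_along(cds), parent_of, "")

  # resolve each CDS's parent to a gene; keep only the first tx per gene
  genes <- ifelse(parents %in% names(tx2gene),
                  unname(tx2gene[parents]), parents)
  first_tx <- tapply(parents, genes, function(p) p[1])
  keep <- parents == unname(first_tx[genes])
  n_iso_dropped <- length(unique(parents[!keep]))
  if (n_iso_dropped > 0)
    asite_warn(n_iso_dropped, " additional isoform(s) ignored; only the ",
               "first-encountered mRNA per gene is used")
  cds <- cds[keep]; genes <- genes[keep]

  records <- list()
  for (g in unique(genes)) {
    sel <- which(genes == g)
    strand <- as.character(BiocGenerics::strand(cds[sel]))[1]
    segs <- cbind(BiocGenerics::start(cds[sel]) - 1L,   # 1-based -> 0-based
                  BiocGenerics::end(cds[sel]))          # inclusive -> half-open
    rec <- cds_record(g, as.character(GenomicRanges::seqnames(cds[sel]))[1],
                      strand, segs)
    if (!record_is_valid(rec)) {
      asite_warn("gene ", g, " skipped: CDS length ", rec$cds_length_nt,
                 " nt is not a multiple of 3 (or < 9 nt)")
      next
    }
    records[[g]] <- rec
  }
  if (!length(records)) asite_stop("no valid CDS records parsed from ", path)
  annotation_set(records, mode)
}

#' Parse a TAB-based CDS annotation table
#'
#' Reads the package's TAB annotation dialect (see [write_cds_table()]):
#' a header line `#gene_id<TAB>reference<TAB>strand<TAB>segments<TAB>cds_length`
#' followed by one gene per line, with `segments` a comma-separated list of
#' 0-based half-open `start-end` pairs in 5'->3' (strand) order.
#'
#' @inheritParams parse_gff
#' @param path Path to a TAB annotation file.
#' @return An `annotation_set`.
#' @export
parse_cds_table <- function(path, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) asite_stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5L)
      asite_stop("line ", i, " of ", path, ": expected 5 tab-separated ",
                 "columns, found ", length(fields))
    gid <- fields[1]
    if (gid %in% names(records))
      asite_stop("duplicate gene_id '", gid, "' at line ", i, " of ", path)
    segs <- do.call(rbind, lapply(
      strsplit(fields[4], ",", fixed = TRUE)[[1]],
      function(s) {
        se <- suppressWarnings(as.integer(strsplit(s, "-", fixed = TRUE)[[1]]))
        if (length(se) != 2L || anyNA(se))
          asite_stop("line ", i, " of ", path, ": bad segment '", s, "'")
        se
      }))
    rec <- cds_record(gid, fields[2], fields[3], segs)
    if (rec$cds_length_nt != as.integer(fields[5]))
      asite_stop("line ", i, " of ", path, ": cds_length ", fields[5],
                 " does not match segment sum ", rec$cds_length_nt)
    if (!record_is_valid(rec)) {
      asite_warn("gene ", gid, " skipped: CDS length ", rec$cds_length_nt,
                 " nt is not a multiple of 3 (or < 9 nt)")
      next
    }
    records[[gid]] <- rec
  }
  if (!length(records)) asite_stop("no valid CDS records parsed from ", path)
  annotation_set(records, mode)
}

#' Parse either annotation format by extension
#'
#' Dispatches to [parse_gff()] for `.gff`/`.gff3` files and to
#' [parse_cds_table()] otherwise.
#' @inheritParams parse_gff
#' @export
read_annotation <- function(path, mode = c("genome", "transcriptome")) {
  mode <- match.arg(mode)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) parse_gff(path, mode)
  else parse_cds_table(path, mode)
}

#' Write an annotation set as a TAB-based CDS table
#'
#' Writes the canonical TAB dialect: header
#' `#gene_id<TAB>reference<TAB>strand<TAB>segments<TAB>cds_length`, one gene
#' per line sorted by `gene_id`, with segments as comma-separated
#' `start-end` pairs (0-based half-open, 5'->3' order). The round trip
#' through [parse_cds_table()] restores the annotation exactly.
#'
#' @param annotation An `annotation_set`.
#' @param path Output path.
#' @export
write_cds_table <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  ids <- sort(gene_ids(annotation))
  lines <- c("#gene_id\treference\tstrand\tsegments\tcds_length",
             vapply(ids, function(g) {
               r <- annotation$records[[g]]
               segs <- paste(sprintf("%d-%d", r$segments[, 1],
                                     r$segments[, 2]), collapse = ",")
               paste(g, r$reference_name, r$strand, segs, r$cds_length_nt,
                     sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Keep or remove genes listed in a filter file
#'
#' @param annotation An `annotation_set`.
#' @param filter_path Text file with one gene_id per line (blank lines and
#'   `#` comments ignored).
#' @param filter_mode `"include"` keeps only listed genes; `"exclude"`
#'   removes them. Ids not present in the annotation are reported with a
#'   warning, never fatal; an include filter that leaves no genes is an
#'   error.
#' @return The filtered `annotation_set`.
#' @export
apply_gene_filter <- function(annotation, filter_path,
                              filter_mode = c("include", "exclude")) {
  filter_mode <- match.arg(filter_mode)
  if (!file.exists(filter_path))
    asite_stop("filter file not found: ", filter_path)
  ids <- readLines(filter_path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[ids != "" & !startsWith(ids, "#")]
  unknown <- setdiff(ids, gene_ids(annotation))
  if (length(unknown))
    asite_warn(length(unknown), " filter id(s) not in annotation: ",
               paste(utils::head(unknown, 5), collapse = ", "),
               if (length(unknown) > 5) ", ..." else "")
  keep <- if (filter_mode == "include") intersect(gene_ids(annotation), ids)
          else setdiff(gene_ids(annotation), ids)
  if (filter_mode == "include" && !length(keep))
    asite_stop("include filter leaves zero genes")
  annotation_set(annotation$records[keep], annotation$mode)
}
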