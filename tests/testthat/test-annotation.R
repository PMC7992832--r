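test_that("GFF coordinates convert to 0-based half-open records", {
  gff <- write_gff3(data.frame(
    seqid = "chr1", type = c("gene", "mRNA", "CDS"),
    start = c(1, 1, 1), end = c(300, 300, 300), strand = "+",
    attributes = c("ID=g1", "ID=g1.t1;Parent=g1", "ID=g1.c1;Parent=g1.t1")),
    tempfile(fileext = ".gff3"))
  ann <- parse_gff(gff, "genome")
  rec <- ann$records[["g1"]]
  expect_identical(unname(rec$segments[1, ]), c(0L, 300L))
  expect_identical(rec$cds_length_nt, 300L)
  expect_identical(rec$strand, "+")
})

test_that("multi-segment genes are summed and non-mod-3 genes skipped with a warning", {
  # 1..100 + 201..300 sums to 200 nt (not a multiple of 3) -> skipped;
  # 1..99 + 202..300 sums to 198 nt -> valid two-segment record
  gff_bad <- write_gff3(data.frame(
    seqid = "chr1", type = c("CDS", "CDS"),
    start = c(1, 201), end = c(100, 300), strand = "+",
    attributes = "Parent=g1"), tempfile(fileext = ".gff3"))
  expect_warning(expect_error(parse_gff(gff_bad, "genome"), "no valid"),
                 "not a multiple of 3")

  gff_ok <- write_gff3(data.frame(
    seqid = "chr1", type = c("CDS", "CDS"),
    start = c(1, 202), end = c(99, 300), strand = "+",
    attributes = "Parent=g1"), tempfile(fileext = ".gff3"))
  ann <- parse_gff(gff_ok, "genome")
  rec <- ann$records[["g1"]]
  expect_identical(nrow(rec$segments), 2L)
  expect_identical(rec$cds_length_nt, 198L)
  expect_identical(sum(rec$segments[, 2] - rec$segments[, 1]),
                   rec$cds_length_nt)
})

test_that("minus-strand local coordinates run 5'->3' along the mRNA", {
  gff <- write_gff3(data.frame(
    seqid = "chr1", type = "CDS", start = 101, end = 400, strand = "-",
    attributes = "Parent=gneg"), tempfile(fileext = ".gff3"))
  rec <- parse_gff(gff, "genome")$records[["gneg"]]
  # local 0 is the first nt of the start codon = reference position 399
  expect_identical(asiteIP:::cds_local_to_ref(rec, 0L), 399L)
  expect_identical(asiteIP:::ref_to_cds_local(rec, 399L), 0L)
  # extracted first codon equals the reverse complement of reference 398..400
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 450, replace = TRUE), collapse = "")))
  cds <- asiteIP:::extract_cds_seq(rec, ref)
  rc <- Biostrings::reverseComplement(
    Biostrings::subseq(ref[["chr1"]], 398, 400))
  expect_identical(as.character(Biostrings::subseq(cds, 1, 3)),
                   as.character(rc))
  expect_identical(length(cds), rec$cds_length_nt)
})

test_that("local<->reference mapping is a bijection onto the segment union", {
  rec <- asiteIP:::cds_record("g", "chr", "-",
                              rbind(c(200, 230), c(100, 160), c(10, 40)))
  L <- rec$cds_length_nt
  refs <- asiteIP:::cds_local_to_ref(rec, 0:(L - 1L))
  expect_identical(length(unique(refs)), as.integer(L))
  expect_setequal(refs, c(200:229, 100:159, 10:39))
  back <- asiteIP:::ref_to_cds_local(rec, refs)
  expect_identical(back, 0:(L - 1L))
  # intron positions map to NA even with a flank
  expect_true(is.na(asiteIP:::ref_to_cds_local(rec, 180L, extra_nt = 5L)))
})

test_that("TAB round trip is the identity on an annotation set", {
  gff <- write_gff3(data.frame(
    seqid = c("chr1", "chr1", "chr2"), type = "CDS",
    start = c(1, 202, 501), end = c(99, 300, 800),
    strand = c("+", "+", "-"),
    attributes = c("Parent=gA", "Parent=gA", "Parent=gB")),
    tempfile(fileext = ".gff3"))
  ann <- parse_gff(gff, "genome")
  tab <- tempfile(fileext = ".tab")
  write_cds_table(ann, tab)
  ann2 <- parse_cds_table(tab, "genome")
  expect_identical(gene_ids <- sort(names(ann$records)),
                   sort(names(ann2$records)))
  for (g in gene_ids)
    expect_identical(ann$records[[g]][c("reference_name", "strand",
                                        "cds_length_nt")],
                     ann2$records[[g]][c("reference_name", "strand",
                                         "cds_length_nt")])
  expect_identical(ann$records[["gA"]]$segments, ann2$records[["gA"]]$segments)
  # second round trip is byte-identical
  tab2 <- tempfile(fileext = ".tab")
  write_cds_table(ann2, tab2)
  expect_identical(readLines(tab), readLines(tab2))
})

test_that("TAB parser reports malformed lines and duplicate genes", {
  p <- tempfile()
  writeLines(c("#gene_id\treference\tstrand\tsegments\tcds_length",
               "g1\tchr1\t+\t0-300"), p)   # 4 columns
  expect_error(parse_cds_table(p, "genome"), "line 2")
  writeLines(c("g1\tchr1\t+\t0-300\t300",
               "g1\tchr1\t+\t0-300\t300"), p)
  expect_error(parse_cds_table(p, "genome"), "duplicate gene_id 'g1'")
})

test_that("malformed GFF lines are reported with their line number", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tCDS\t1\t300\t.\t+\t0;Parent=g1"), p)
  expect_error(parse_gff(p, "genome"), "line 2")
})

test_that("gene filter keeps/removes listed genes and tolerates unknown ids", {
  recs <- list(asiteIP:::cds_record("g1", "c", "+", cbind(0, 30)),
               asiteIP:::cds_record("g2", "c", "+", cbind(100, 130)))
  ann <- asiteIP:::annotation_set(recs, "genome")
  f <- tempfile()
  writeLines("g1", f)
  expect_identical(names(apply_gene_filter(ann, f, "include")$records), "g1")
  expect_identical(names(apply_gene_filter(ann, f, "exclude")$records), "g2")
  writeLines(character(0), f)
  expect_identical(names(apply_gene_filter(ann, f, "exclude")$records),
                   c("g1", "g2"))
  writeLines(c("g1", "ghost"), f)
  expect_warning(out <- apply_gene_filter(ann, f, "include"), "ghost")
  expect_identical(names(out$records), "g1")
  writeLines("ghost", f)
  expect_warning(expect_error(apply_gene_filter(ann, f, "include"),
                              "zero genes"), "ghost")
})

test_that("transcriptome mode enforces single-segment forward records", {
  recs <- list(asiteIP:::cds_record("g1", "tx1", "-", cbind(0, 30)))
  expect_error(asiteIP:::annotation_set(recs, "transcriptome"),
               "transcriptome mode")
})

test_that("isoforms beyond the first mRNA per gene are ignored with a warning", {
  gff <- write_gff3(data.frame(
    seqid = "chr1",
    type = c("gene", "mRNA", "CDS", "mRNA", "CDS"),
    start = c(1, 1, 1, 1, 1), end = c(300, 300, 300, 150, 150),
    strand = "+",
    attributes = c("ID=g1", "ID=t1;Parent=g1", "Parent=t1",
                   "ID=t2;Parent=g1", "Parent=t2")),
    tempfile(fileext = ".gff3"))
  expect_warning(ann <- parse_gff(gff, "genome"), "isoform")
  expect_identical(ann$records[["g1"]]$cds_length_nt, 300L)
})
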