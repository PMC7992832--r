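# Hand-built SAM fixture over three genes on one chromosome:
#   g1: +, CDS [100,130)          g2: -, CDS [300,330)
#   g3: +, two exons [400,430)+[460,490)
#   g4: +, CDS [120,150)  (overlaps g1's window)
sam_annotation <- function(with_g4 = FALSE) {
  recs <- list(
    asiteIP:::cds_record("g1", "chr1", "+", cbind(100, 130)),
    asiteIP:::cds_record("g2", "chr1", "-", cbind(300, 330)),
    asiteIP:::cds_record("g3", "chr1", "+", rbind(c(400, 430), c(460, 490))))
  if (with_g4)
    recs <- c(recs, list(asiteIP:::cds_record("g4", "chr1", "+",
                                              cbind(120, 150))))
  asiteIP:::annotation_set(recs, "genome")
}

write_test_sam <- function(body) {
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
               sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                       sprintf("r%02d", seq_along(body$flag)), body$flag,
                       body$rname, body$pos, body$cigar)), p)
  p
}

test_that("5'-end counting handles strands, flanks, clips and splices", {
  ann <- sam_annotation()
  body <- data.frame(
    flag = c(0L, 16L, 0L, 0L, 0L, 256L, 4L, 0L),
    rname = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "*", "chr1"),
    pos = c(101L,      # r01: + read, 5' end local 0 of g1
            303L,      # r02: - read 28M, rightmost ref 329 = local 0 of g2
            99L,       # r03: + read, 5' end local -2 of g1
            101L,      # r04: 2S26M -> S = 26, 5' end local 0 of g1
            435L,      # r05: 5' end in g3's intron
            101L,      # r06: secondary -> excluded
            0L,        # r07: unmapped -> excluded
            311L),     # r08: + read inside g2 (- gene) -> strand-incompatible
    cigar = c("28M", "28M", "28M", "2S26M", "10M50N18M", "28M", "*", "28M"))
  sam <- write_test_sam(body)

  cfg0 <- job_config(size_min = 20, size_max = 35, extra_nt = 0)
  t0 <- suppressMessages(build_count_tensor(sam, ann, cfg0))
  cnt <- as.data.frame(t0$counts)
  g1_28 <- cnt[cnt$gene == "g1" & cnt$size == 28, ]
  expect_identical(unname(unlist(g1_28[c("frame", "pos", "count")])),
                   c(0L, 0L, 1L))
  # minus-strand 5' end is the rightmost reference coordinate
  expect_identical(cnt[cnt$gene == "g2", ]$pos, 0L)
  expect_identical(cnt[cnt$gene == "g2", ]$frame, 0L)
  # soft clips excluded from fragment size
  expect_identical(cnt[cnt$gene == "g1" & cnt$size == 26, ]$pos, 0L)
  # flank read dropped at extra_nt = 0 ...
  expect_false(any(cnt$pos < 0))
  # ... intron read dropped, strand-incompatible counted
  expect_identical(t0$stats$outside_window, 2L)   # r03 flank + r05 intron
  expect_identical(t0$stats$strand_incompatible, 1L)
  expect_identical(t0$stats$not_primary_or_unmapped, 2L)
  # conservation: every record lands in exactly one counter
  with(t0$stats, expect_identical(
    total, retained + not_primary_or_unmapped + size_out_of_range +
      unassigned_reference + strand_incompatible + outside_window +
      multi_gene_overlap))

  # with extra_nt = 3 the flank read is counted at p = -2, frame 1
  cfg3 <- job_config(size_min = 20, size_max = 35, extra_nt = 3)
  t3 <- suppressMessages(build_count_tensor(sam, ann, cfg3))
  c3 <- as.data.frame(t3$counts)
  flank_row <- c3[c3$pos == -2L, ]
  expect_identical(nrow(flank_row), 1L)
  expect_identical(flank_row$gene, "g1")
  expect_identical(flank_row$frame, 1L)
  expect_identical(flank_row$count, 1L)
})

test_that("reads claimed by two same-strand windows are dropped", {
  ann <- sam_annotation(with_g4 = TRUE)
  body <- data.frame(flag = 0L, rname = "chr1",
                     pos = c(126L, 101L),   # local 25 of g1 AND 5 of g4; local 0 of g1
                     cigar = "28M")
  sam <- write_test_sam(body)
  cfg <- job_config(size_min = 20, size_max = 35, extra_nt = 0)
  tt <- suppressMessages(build_count_tensor(sam, ann, cfg))
  expect_identical(tt$stats$multi_gene_overlap, 1L)
  expect_identical(tt$stats$retained, 1L)
  expect_identical(as.data.frame(tt$counts)$gene, "g1")
})

test_that("ingestion is deterministic under read reordering", {
  ann <- sam_annotation()
  body <- data.frame(flag = 0L, rname = "chr1",
                     pos = c(101L, 104L, 110L, 101L, 107L), cigar = "28M")
  s1 <- write_test_sam(body)
  s2 <- write_test_sam(body[c(4, 2, 5, 1, 3), , drop = FALSE])
  cfg <- job_config(size_min = 20, size_max = 35, extra_nt = 0)
  t1 <- suppressMessages(build_count_tensor(s1, ann, cfg))
  t2 <- suppressMessages(build_count_tensor(s2, ann, cfg))
  expect_identical(as.data.frame(t1$counts), as.data.frame(t2$counts))
})

test_that("size/frame marginals conserve the retained read count", {
  ann <- sam_annotation()
  body <- data.frame(flag = 0L, rname = "chr1",
                     pos = c(101L, 101L, 101L, 105L), cigar = c(rep("28M", 3), "29M"))
  sam <- write_test_sam(body)
  cfg <- job_config(size_min = 20, size_max = 35, extra_nt = 0)
  tt <- suppressMessages(build_count_tensor(sam, ann, cfg))
  dist <- fragment_size_distribution(tt)
  expect_identical(sum(dist$reads), tt$stats$retained)
  expect_identical(dist$reads[dist$size == 28 & dist$frame == 0], 3L)
  expect_identical(dist$reads[dist$size == 29 & dist$frame == 1], 1L)
  # frame consistency invariant on every stored cell
  expect_true(all(tt$counts$frame == ((tt$counts$pos %% 3) + 3) %% 3))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(job_config(min_vote_fraction = 0.5), "0.5")
  expect_error(job_config(size_min = 30, size_max = 20), "size range")
  expect_error(job_config(extra_nt = -1), "extra_nt")
  expect_error(job_config(min_genes = 0), "min_genes")
})
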