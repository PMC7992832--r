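cfg <- job_config(size_min = 28, size_max = 28)

test_that("the objective counts reads landing between codon 2 and the stop codon", {
  gc0 <- data.frame(pos = integer(0), count = integer(0))
  for (d in seq(0, 27, by = 3))
    expect_identical(score_offset(gc0, 300L, 28L, d), 0L)
  # read at p = -15: delta 15 puts the A-site at nt 0 (codon 1, excluded);
  # delta 18 puts it at nt 3 (codon 2, counted)
  gc <- data.frame(pos = -15L, count = 1L)
  expect_identical(score_offset(gc, 300L, 28L, 15L), 0L)
  expect_identical(score_offset(gc, 300L, 28L, 18L), 1L)
  gc3 <- data.frame(pos = c(0L, 3L, 6L), count = c(1L, 1L, 1L))
  expect_identical(score_offset(gc3, 300L, 28L, 15L), 3L)
  # stop codon counts under the default window, not under "sense"
  gstop <- data.frame(pos = 300L - 3L - 15L, count = 1L)
  expect_identical(score_offset(gstop, 300L, 28L, 15L, "stop"), 1L)
  expect_identical(score_offset(gstop, 300L, 28L, 15L, "sense"), 0L)
  expect_error(score_offset(gc, 300L, 28L, 16L), "violates")
  expect_error(score_offset(gc, 300L, 28L, 30L), "violates")
})

test_that("per-gene argmax matches brute force and reports ties", {
  rows <- vote_gene_rows("g", 15L, L = 30L)
  gc <- data.frame(pos = rows$pos, count = rows$count)
  expect_identical(best_offsets_for_gene(gc, 30L, 28L), 15L)
  # symmetric construction: reads only mid-CDS score equally at several deltas
  gtie <- data.frame(pos = c(0L, 3L), count = c(1L, 1L))
  best <- best_offsets_for_gene(gtie, 300L, 28L)
  expect_true(length(best) > 1L)
  expect_identical(best, oracle_best_offsets(gtie$pos, gtie$count, 300L, 28L))
  expect_identical(best_offsets_for_gene(
    data.frame(pos = 0L, count = 0L), 30L, 28L), integer(0))
})

test_that("gene eligibility flips exactly at the reads-per-codon floor", {
  L <- 300L  # 100 codons
  mk <- function(n) make_tensor(
    data.frame(gene = "g", size = 28L, pos = seq(0, by = 3, length.out = n),
               count = 1L),
    c(g = L), cfg)
  expect_identical(filter_eligible_genes(mk(99L), 28, 0, cfg), character(0))
  expect_identical(filter_eligible_genes(mk(100L), 28, 0, cfg), "g")
  cfg0 <- job_config(size_min = 28, size_max = 28, min_reads_per_codon = 0)
  expect_identical(filter_eligible_genes(mk(1L), 28, 0, cfg0), "g")
})

test_that("metagene ratio follows the codon 2-4 vs codon 1 rule", {
  # codon-1 total 10, codons 2/3/4 = 60/40/50 at delta 15 -> mean 50 / 10 = 5
  rows <- data.frame(gene = "g", size = 28L,
                     pos = c(-15L, -12L, -9L, -6L),
                     count = c(10L, 60L, 40L, 50L))
  tt <- make_tensor(rows, c(g = 300L),
                    job_config(size_min = 28, size_max = 28,
                               min_reads_per_codon = 0))
  cfg0 <- job_config(size_min = 28, size_max = 28, min_reads_per_codon = 0)
  expect_equal(metagene_ratio(tt, 28, 0, 15L, cfg0), 5.0)
  # empty codon 1 with signal downstream passes any finite threshold
  rows2 <- rows[-1, ]
  tt2 <- make_tensor(rows2, c(g = 300L), cfg0)
  expect_identical(metagene_ratio(tt2, 28, 0, 15L, cfg0), Inf)
  # no reads at all -> 0
  expect_identical(metagene_ratio(tt2, 28, 1, 15L, cfg0), 0)
})

test_that("vote fraction threshold flips unique <-> ambiguous at exactly 70%", {
  d14 <- decide_offset(mixed_vote_tensor(14L, n_genes = 20L, config = cfg),
                       28, 0, cfg)            # 14/20 = 70%
  expect_identical(d14$status, "unique")
  expect_identical(d14$offsets, 15L)
  expect_equal(d14$vote_fraction, 0.7)
  d13 <- decide_offset(mixed_vote_tensor(13L, n_genes = 20L, config = cfg),
                       28, 0, cfg)            # 13/20 = 65%
  expect_identical(d13$status, "ambiguous")
  expect_identical(d13$offsets, c(15L, 18L))
})

test_that("the ten-gene floor separates decided from insufficient", {
  mk <- function(n) {
    rows <- do.call(rbind, lapply(seq_len(n), function(i)
      vote_gene_rows(sprintf("g%02d", i), 15L)))
    make_tensor(rows, stats::setNames(rep(30L, n), sprintf("g%02d", seq_len(n))),
                cfg)
  }
  expect_identical(decide_offset(mk(9L), 28, 0, cfg)$status, "insufficient")
  d10 <- decide_offset(mk(10L), 28, 0, cfg)
  expect_identical(d10$status, "unique")
  expect_identical(d10$n_genes_voting, 10L)
  # empty cell
  dempty <- decide_offset(mk(10L), 28, 2, cfg)
  expect_identical(dempty$status, "insufficient")
  expect_identical(dempty$offsets, integer(0))
})

test_that("uniqueness requires the five-fold metagene ratio", {
  # ten genes voting 15; codon-1 vs codons-2..4 totals tuned around ratio 5
  mk <- function(extra_c1) {
    rows <- do.call(rbind, lapply(1:10, function(i) {
      r <- data.frame(gene = sprintf("g%02d", i), size = 28L,
                      pos = c(-15L, -12L, -9L, -6L, 30L - 18L),
                      count = c(1L, 6L, 4L, 5L, 2L))
      if (i == 1L && extra_c1 > 0L)
        r$count[1] <- r$count[1] + extra_c1
      r
    }))
    make_tensor(rows, stats::setNames(rep(30L, 10), sprintf("g%02d", 1:10)),
                cfg)
  }
  d5 <- decide_offset(mk(0L), 28, 0, cfg)     # ratio (150/3)/10 = 5 exactly
  expect_identical(d5$status, "unique")
  expect_equal(d5$metagene_ratio, 5.0)
  d49 <- decide_offset(mk(1L), 28, 0, cfg)    # ratio 50/11 < 5
  expect_false(d49$status == "unique")
  expect_lt(d49$metagene_ratio, 5)
})

test_that("raising thresholds only demotes statuses (monotonicity)", {
  set.seed(404)
  rank_of <- c(insufficient = 0L, ambiguous = 1L, unique = 2L)
  for (rep in 1:10) {
    rt <- random_tensor_rows(sizes = 28L)
    base <- job_config(size_min = 28, size_max = 28, min_genes = 1,
                       min_vote_fraction = 0.51, min_metagene_ratio = 1e-9)
    tt <- make_tensor(rt$rows, rt$cds_length, base)
    d0 <- decide_offset(tt, 28, 0, base)
    stricter_vote <- job_config(size_min = 28, size_max = 28, min_genes = 1,
                                min_vote_fraction = 0.99,
                                min_metagene_ratio = 1e-9)
    d1 <- decide_offset(tt, 28, 0, stricter_vote)
    expect_lte(rank_of[[d1$status]], rank_of[[d0$status]])
    if (d0$status == "unique" && d1$status != "unique")
      expect_identical(d1$status, "ambiguous")   # vote threshold never skips to insufficient when 2+ candidates
    stricter_genes <- job_config(size_min = 28, size_max = 28,
                                 min_genes = 1000,
                                 min_vote_fraction = 0.51,
                                 min_metagene_ratio = 1e-9)
    d2 <- decide_offset(tt, 28, 0, stricter_genes)
    expect_identical(d2$status, "insufficient")
  }
})

test_that("every reported offset satisfies the integer-program constraints", {
  set.seed(99)
  for (rep in 1:20) {
    rt <- random_tensor_rows()
    c20 <- job_config(size_min = 20, size_max = 35, min_genes = 1,
                      min_vote_fraction = 0.51, min_metagene_ratio = 1e-9)
    tt <- make_tensor(rt$rows, rt$cds_length, c20)
    tab <- compute_offset_table(tt, c20)
    off <- c(tab$offset, tab$offset2)
    sz <- c(tab$size, tab$size)
    ok <- is.na(off) | (off %% 3 == 0 & off >= 0 & off <= sz)
    expect_true(all(ok))
  }
})

test_that("offset table TSV round-trips statuses and values", {
  rows <- do.call(rbind, lapply(1:12, function(i)
    vote_gene_rows(sprintf("g%02d", i), if (i <= 6) 15L else 18L)))
  tt <- make_tensor(rows, stats::setNames(rep(30L, 12), sprintf("g%02d", 1:12)),
                    cfg)
  tab <- compute_offset_table(tt, cfg)
  expect_identical(tab$status[tab$frame == 0], "ambiguous")
  p <- tempfile(fileext = ".tsv")
  write_offset_table(tab, p)
  back <- read_offset_table(p)
  expect_identical(back$status, tab$status)
  expect_identical(back$offset, tab$offset)
  expect_identical(back$offset2, tab$offset2)
  expect_true(file.exists(sub("\\.tsv$", "_diagnostics.tsv", p)))
  expect_error(read_offset_table(tempfile()), "not found")
})

test_that("vote distribution mirrors the decision tallies", {
  n <- 20L
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    vote_gene_rows(sprintf("g%02d", i), if (i <= 14) 15L else 18L)))
  tt <- make_tensor(rows, stats::setNames(rep(30L, n), sprintf("g%02d", seq_len(n))),
                    cfg)
  vd <- offset_vote_distribution(tt, cfg)
  v0 <- vd[vd$frame == 0, ]
  expect_identical(v0$votes[v0$offset == 15], 14L)
  expect_identical(v0$votes[v0$offset == 18], 6L)
  expect_identical(sum(v0$votes), decide_offset(tt, 28, 0, cfg)$n_genes_voting)
})
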