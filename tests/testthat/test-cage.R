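make_tags <- function(chrom, start, end, strand, condition) {
  df <- gintervals(chrom, start, end, strand)
  df$condition <- condition
  df
}

test_that("single-linkage clustering merges overlapping stranded tag spans", {
  tags <- make_tags("chr1", c(100, 115, 200), c(120, 140, 220), "+", "Veh")
  cl <- cluster_cage(tags, 10, 10)
  expect_equal(cl$start, c(100L, 200L))
  expect_equal(cl$end, c(140L, 220L))
  # same spans on opposite strands stay apart
  tags2 <- rbind(make_tags("chr1", 100, 120, "+", "Veh"),
                 make_tags("chr1", 100, 120, "-", "VPA"))
  expect_equal(nrow(cluster_cage(tags2, 1, 1)), 2)
  expect_error(cluster_cage(make_tags("chr1", 1, 5, ".", "Veh"), 1, 1),
               "stranded")
  # TPM recomputes from counts and totals; counts bounded by totals
  tags3 <- rbind(make_tags("chr1", c(0, 5), c(21, 26), "+", "Veh"),
                 make_tags("chr1", 10, 31, "+", "VPA"))
  cl3 <- cluster_cage(tags3, 2, 1)
  expect_equal(cl3$count_veh, 2L)
  expect_equal(cl3$count_vpa, 1L)
  expect_equal(cl3$tpm_veh, 2 * 1e6 / 2)
  expect_equal(cl3$peak_position, 0L)  # modal tie broken leftmost
})

test_that("clustering matches the transitive-closure oracle on random tags", {
  set.seed(19)
  n <- 500
  start <- sample.int(20000, n, replace = TRUE)
  tags <- make_tags(sample(c("chr1", "chr2"), n, TRUE), start, start + 21,
                    sample(c("+", "-"), n, TRUE),
                    sample(c("Veh", "VPA"), n, TRUE))
  cl <- cluster_cage(tags, sum(tags$condition == "Veh"),
                     sum(tags$condition == "VPA"))
  # per strand/chrom component counts
  n_comp <- 0
  for (ch in unique(tags$chrom)) for (s in c("+", "-")) {
    sub <- tags[tags$chrom == ch & tags$strand == s, ]
    if (nrow(sub)) n_comp <- n_comp + length(unique(oracle_components(sub)))
  }
  expect_equal(nrow(cl), n_comp)
  expect_equal(sum(cl$count_veh) + sum(cl$count_vpa), n)
})

test_that("TPM filter keeps clusters passing in either sample, inclusive", {
  cl <- data.frame(tpm_veh = c(9, 9, 10, 0), tpm_vpa = c(11, 9, 0, 20))
  kept <- filter_tpm(cl)
  expect_equal(nrow(kept), 3)
  expect_false(any(kept$tpm_veh == 9 & kept$tpm_vpa == 9))
})

test_that("differential TSS status via Fisher + BH", {
  cl <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                   strand = "+", count_veh = c(10L, 50L),
                   count_vpa = c(100L, 50L))
  out <- classify_tss(cl, 1e6, 1e6)
  expect_equal(out$status, c("induced", "non_induced"))
  p_oracle <- stats::fisher.test(matrix(c(100, 1e6 - 100, 10, 1e6 - 10), 2,
                                        byrow = TRUE),
                                 alternative = "greater")$p.value
  expect_equal(out$p_up[1], p_oracle, tolerance = 1e-9)
  expect_true(all(out$status %in% c("induced", "downregulated", "non_induced")))
})

test_that("promoter overlap respects orientation and the coding-start bound", {
  f <- withr::local_tempfile()
  # gene on +: spans 10000-20000, CDS from 10500; gene on -: 40000-50000, CDS ends 49500
  writeLines(c(
    "chr1\t10000\t20000\tgp\t0\t+\t10500\t19800\t0\t1\t10000,\t0,",
    "chr1\t40000\t50000\tgm\t0\t-\t40200\t49500\t0\t1\t10000,\t0,"), f)
  genes <- read_bed12(f)
  prom <- promoter_regions(genes)
  expect_equal(prom$start[1], 9000L)
  expect_equal(prom$end[1], 10500L)
  expect_equal(prom$start[2], 49500L)  # first coding base 49499 excluded
  expect_equal(prom$end[2], 50999L + 1L)

  cl <- rbind(make_tags("chr1", 9990, 10020, "+", "x"),     # at + TSS
              make_tags("chr1", 7000, 7500, "+", "x"),      # 2 kb upstream
              make_tags("chr1", 50400, 50600, "-", "x"),    # upstream of - TSS
              make_tags("chr1", 9990, 10020, "-", "x"))     # wrong strand
  cl$status <- c("induced", "non_induced", "induced", "non_induced")
  ov <- promoter_overlap(cl, genes)
  expect_equal(ov$flags, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ov$by_status$fraction[ov$by_status$status == "induced"], 1)
})

test_that("exon-1 tag ratio counts 5' ends in transcript orientation", {
  f <- withr::local_tempfile()
  # + gene: exon1 0-100, exon2 500-1000; - gene: exon "1" is the rightmost block
  writeLines(c(
    "chr1\t0\t1000\tgp\t0\t+\t0\t0\t0\t2\t100,500,\t0,500,",
    "chr2\t0\t1000\tgm\t0\t-\t0\t0\t0\t2\t100,500,\t0,500,"), f)
  genes <- read_bed12(f)
  tags <- rbind(
    make_tags("chr1", c(10, 20, 30, 40, 50, 60, 70, 80), c(31, 41, 51, 61, 71, 81, 91, 101), "+", "Veh"),
    make_tags("chr1", c(600, 700), c(621, 721), "+", "Veh"),
    make_tags("chr2", rep(600, 10), rep(621, 10), "-", "Veh"),
    make_tags("chr1", c(10, 20), c(31, 41), "+", "VPA"))
  r <- exon1_ratio(genes, tags)
  expect_equal(r$ratio[r$gene == "gp" & r$condition == "Veh"], 0.8)
  expect_equal(r$ratio[r$gene == "gm"], 1)   # block 500-1000 is exon 1 on minus
  expect_false(any(r$condition == "VPA"))    # below the 10-tag floor
  # all tags intronic
  tags2 <- make_tags("chr1", 200 + 10 * (0:11), 221 + 10 * (0:11), "+", "Veh")
  r2 <- exon1_ratio(genes, tags2)
  expect_equal(r2$ratio[r2$gene == "gp"], 0)
})

test_that("TSS profile is flat on uniform tags, centered on planted enrichment, drops spikes", {
  set.seed(23)
  f <- withr::local_tempfile()
  writeLines(sprintf("chr1\t%d\t%d\tg%d\t0\t%s\t0\t0\t0\t1\t2000,\t0,",
                     seq(20000, 380000, by = 20000),
                     seq(22000, 382000, by = 20000),
                     1:19, rep(c("+", "-"), length.out = 19)), f)
  genes <- read_bed12(f)
  lib <- tag_library(list(chr1 = sample.int(400000, 150000, TRUE) - 1L))
  prof <- tss_profile(lib, genes, flank = 5000)
  expect_equal(length(prof$mean_tpm), 20)
  expect_lt(stats::sd(prof$mean_tpm) / mean(prof$mean_tpm), 0.05)
  expect_error(tss_profile(lib, genes, flank = 5300), "multiple")

  # planted enrichment at every TSS: center bins dominate
  extra <- unlist(lapply(genes$tss, function(t) t + sample(-250:249, 300, TRUE)))
  lib2 <- tag_library(list(chr1 = sort(c(lib$positions$chr1, extra))))
  prof2 <- tss_profile(lib2, genes, flank = 5000)
  center <- which(prof2$bin_offsets %in% c(-500, 0))
  expect_true(all(rank(-prof2$mean_tpm)[center] <= 2))

  # a single promoter with a 100x spike bin is excluded in pass 2
  spike <- genes$tss[5] + sample(1000:1499, 40000, TRUE)
  lib3 <- tag_library(list(chr1 = sort(c(lib$positions$chr1, spike))))
  prof3 <- tss_profile(lib3, genes, flank = 5000)
  expect_equal(prof3$n_promoters_retained, 18)
})
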