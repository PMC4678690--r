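test_that("genome generation is deterministic with calibrated mappable coverage", {
  cfg <- small_config(seed = 3)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(g1$mappability, g2$mappability)
  cov <- sum(g1$mappability$end - g1$mappability$start) / sum(g1$chrom_sizes)
  # 3000 independent 100-bp blocks at 0.9: binomial SE ~ 0.0055
  expect_lt(abs(cov - cfg$mappable_fraction), 0.02)
  full <- make_genome(small_config(seed = 3, mappable_fraction = 1))
  expect_equal(sum(full$mappability$end - full$mappability$start),
               sum(full$chrom_sizes))
})

test_that("annotation: class mix, non-overlapping genes, embedded motif instances", {
  cfg <- small_config(seed = 6)
  ann <- make_annotation(cfg, make_genome(cfg))
  # repeat class mix within the multinomial 99% envelope
  tab <- table(ann$repeats$repeat_class)
  for (k in names(cfg$repeat_mix)) {
    p <- cfg$repeat_mix[[k]]
    se <- sqrt(p * (1 - p) / cfg$n_repeats)
    expect_lt(abs(tab[[k]] / cfg$n_repeats - p), 2.58 * se + 0.01)
  }
  # genes pairwise non-overlapping
  genes <- ann$genes
  ord <- order(genes$chrom, genes$start)
  same <- genes$chrom[ord][-1] == genes$chrom[ord][-nrow(genes)]
  expect_true(all(genes$start[ord][-1][same] >= genes$end[ord][-nrow(genes)][same]))
  # enhancers intergenic
  expect_false(any(dhssremodel:::overlaps_any(ann$truth$enhancers, genes)))
  # every motif-carrying SINE contains the exact consensus and scans at rel 1
  m <- pfm_to_pwm(read_jaspar(system.file("extdata", "synthetic_forkhead.jaspar",
                                          package = "dhssremodel"))[[1]])
  ms <- ann$truth$motif_sines
  expect_gt(nrow(ms), 0)
  seqs <- region_sequences(ann$genome$seqs, ms)
  expect_true(all(grepl(cfg$motif_consensus, seqs, fixed = TRUE)))
  hits <- scan_region(seqs[1], m)
  expect_true(any(hits$rel_score == 1))
})

test_that("DHSS tag intensities realize the planted fold structure", {
  cfg <- small_config(seed = 9)
  g <- make_genome(cfg, sequence = FALSE)
  ann <- make_annotation(cfg, g)
  dh <- simulate_dhss(cfg, ann$truth, g$mappability)
  expect_s3_class(dh$veh, "tag_library")
  planted <- ann$truth$planted_regions
  # expected fraction of tags inside planted regions from the intensity integral
  mw <- function(iv) sum(pmin(iv$end, 1e9) - iv$start)  # widths (mappable approx by region)
  map_in <- vapply(seq_len(nrow(planted)), function(i) {
    m <- dhssremodel:::intersect_intervals(g$mappability, planted[i, , drop = FALSE])
    if (nrow(m)) sum(m$end - m$start) else 0
  }, 0)
  total_map <- sum(g$mappability$end - g$mappability$start)
  w_bg <- total_map
  w_reg_veh <- sum(map_in * (cfg$region_fold - 1))
  frac_expected <- (sum(map_in) * cfg$region_fold) /
    (w_bg + w_reg_veh)
  pos <- dh$veh$positions$chr1
  in_reg <- sum(count_tags(dh$veh, "chr1", planted$start, planted$end))
  frac_obs <- in_reg / dh$veh$n_total
  se <- sqrt(frac_expected * (1 - frac_expected) / dh$veh$n_total)
  expect_lt(abs(frac_obs - frac_expected), 3 * se + 0.01)
  # induced regions: VPA/veh density ratio near the extra fold
  ind <- planted[planted$label == "vpa_induced", , drop = FALSE]
  n_v <- sum(count_tags(dh$veh, "chr1", ind$start, ind$end))
  n_p <- sum(count_tags(dh$vpa, "chr1", ind$start, ind$end))
  # correct for the differing library normalizations
  w_reg_vpa <- sum(map_in * (cfg$region_fold - 1)) +
    sum(map_in[planted$label == "vpa_induced"] *
          cfg$region_fold * (cfg$induced_extra_fold - 1))
  norm_ratio <- (w_bg + w_reg_vpa) / (w_bg + w_reg_veh)
  ratio <- (n_p / n_v) * norm_ratio
  expect_lt(abs(ratio - cfg$induced_extra_fold), 1.0)
  # determinism
  dh2 <- simulate_dhss(cfg, ann$truth, g$mappability)
  expect_identical(dh$vpa$positions, dh2$vpa$positions)
})

test_that("CAGE generator: planted fold change, sharp vs broad widths, determinism", {
  cfg <- small_config(seed = 13)
  g <- make_genome(cfg, sequence = FALSE)
  ann <- make_annotation(cfg, g)
  cage <- simulate_cage(cfg, ann$truth, ann$genes)
  genes <- ann$genes
  up <- genes[genes$name %in% ann$truth$up_promoters, , drop = FALSE]
  expect_gt(nrow(up), 0)
  cnt <- function(tags, gs) {
    vapply(seq_len(nrow(gs)), function(i) {
      p5 <- dhssremodel:::cage_five_prime(tags)
      sum(tags$chrom == gs$chrom[i] & abs(p5 - gs$tss[i]) <= 400)
    }, 0)
  }
  r <- sum(cnt(cage$vpa, up)) / sum(cnt(cage$veh, up))
  # VPA/veh ratio at up promoters ~ cage_fold, shrunk by the VPA library's
  # larger promoter weight total
  w_up <- sum(genes$name %in% ann$truth$up_promoters) * cfg$cage_fold +
    sum(!genes$name %in% ann$truth$up_promoters)
  w_dn <- sum(genes$name %in% ann$truth$down_promoters) * cfg$cage_fold +
    sum(!genes$name %in% ann$truth$down_promoters)
  expected <- cfg$cage_fold * w_dn / w_up
  expect_lt(abs(r - expected) / expected, 0.2)
  # sharp promoters give tighter clusters than broad ones
  sharp <- genes[genes$shape == "sharp" & !genes$name %in%
                   c(ann$truth$up_promoters, ann$truth$down_promoters), ]
  broad <- genes[genes$shape == "broad" & !genes$name %in%
                   c(ann$truth$up_promoters, ann$truth$down_promoters), ]
  spread <- function(gs) {
    mean(vapply(seq_len(nrow(gs)), function(i) {
      p5 <- dhssremodel:::cage_five_prime(cage$veh)
      sel <- cage$veh$chrom == gs$chrom[i] & abs(p5 - gs$tss[i]) <= 400
      stats::sd(p5[sel])
    }, 0), na.rm = TRUE)
  }
  expect_lt(spread(sharp), spread(broad))
  cage2 <- simulate_cage(cfg, ann$truth, ann$genes)
  expect_identical(cage$vpa, cage2$vpa)
})

test_that("bundle writing is deterministic and readable back", {
  cfg <- small_config(seed = 17)
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  b1 <- simulate_bundle(cfg, d1)
  b2 <- simulate_bundle(cfg, d2)
  files <- list.files(d1)
  expect_true(all(c("genome.fa", "chrom.sizes", "mappability.bed",
                    "dhss_veh.bed", "dhss_vpa.bed", "cage_veh.bed",
                    "cage_vpa.bed", "genes.bed12", "repeats.tsv",
                    "enhancers.bed", "foxa2.bed", "motifs.jaspar",
                    "qpcr.tsv", "truth.json") %in% files))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # BED12 round-trip preserves the gene models
  genes2 <- read_bed12(file.path(d1, "genes.bed12"))
  expect_equal(genes2$tss, b1$genes$tss)
  expect_equal(genes2$cds_start, b1$genes$cds_start)
  expect_equal(genes2$exon_starts[[5]], b1$genes$exon_starts[[5]])
  # tag BED round-trips into identical libraries
  lib <- read_tag_bed(file.path(d1, "dhss_veh.bed"), "Veh")
  expect_equal(lib$n_total, b1$dhss$veh$n_total)
  expect_equal(lib$positions$chr1, b1$dhss$veh$positions$chr1)
})
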