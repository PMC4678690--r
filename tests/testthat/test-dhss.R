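test_that("effective length counts mappable positions exactly", {
  win <- gintervals("chr1", 0, 10000)
  expect_equal(effective_length(win, NULL), 10000L)
  half <- gintervals("chr1", 0, 5000)
  expect_equal(effective_length(win, half), 5000L)

  set.seed(4)
  blocks <- sort(sample(seq(0, 9900, by = 100), 40))
  map <- merge_intervals(gintervals("chr1", blocks, blocks + sample(20:90, 40, TRUE)))
  q <- gintervals("chr1", sample(0:8000, 50, TRUE), 10000)
  q$end <- q$start + sample(100:1500, 50, TRUE)
  got <- effective_length(q, map)
  mappable <- unique(unlist(mapply(seq, map$start, map$end - 1, SIMPLIFY = FALSE)))
  want <- vapply(seq_len(nrow(q)), function(i) {
    sum(mappable >= q$start[i] & mappable < q$end[i])
  }, 0L)
  expect_equal(got, want)
  # query on a chromosome absent from the track has zero effective length
  expect_equal(effective_length(gintervals("chr2", 0, 100), map), 0L)
})

test_that("window enumeration tiles the genome with unique big-window containment", {
  w <- enumerate_windows(c(chr1 = 20000L))
  expect_equal(sort(unique(w$big_start)), c(0L, 9600L, 19200L))
  expect_true(all(w$start %% 400 == 0))
  expect_true(all(w$start >= w$big_start & w$end <= w$big_end))
  # small window at 9200 still belongs to the first big window
  expect_equal(w$big_start[w$start == 9200], 0L)
  # and 9600 to the second
  expect_equal(w$big_start[w$start == 9600], 9600L)
  # truncated windows shorter than the step are dropped
  w2 <- enumerate_windows(c(chrA = 1250L))
  expect_equal(max(w2$end), 1250L)       # [800, 1250) kept at width 450
  expect_true(all(w2$end - w2$start >= 400))
  w3 <- enumerate_windows(c(chrB = 1100L))
  expect_equal(max(w3$end), 900L)        # [800, 1100) dropped at width 300
  expect_equal(nrow(enumerate_windows(c(tiny = 350L))), 0)

  # containment is unique under the default tiling
  g <- scan_geometry()
  for (s in seq(0, 50000, by = g$small_step)) {
    n_contain <- sum(vapply(seq(0, 48000, by = g$big_step), function(b) {
      s >= b && s + g$small_window <= b + g$big_window
    }, TRUE))
    expect_equal(n_contain, 1)
  }
})

test_that("combined z-score follows the pooled normalization formula", {
  # centered case
  expect_equal(combined_z(10, 10, 10, 10, 3, 3, 1e5, 1e5), 0)
  # hand-derived value at r = 1
  z <- combined_z(30, 30, 10, 10, sqrt(9.5), sqrt(9.5), 2e5, 2e5)
  expect_equal(z, 40 / sqrt(2 * 9.5), tolerance = 1e-12)
  expect_equal(z, 9.17663, tolerance = 1e-4)
  # degenerate sigma is flagged, not zeroed
  expect_true(is.na(combined_z(5, 5, 5, 5, 0, 0, 1e5, 1e5)))
  expect_error(combined_z(1, 1, 1, 1, 1, 1, 0, 1e5), "positive")
  # with r = 1 and the treated condition empty, reduces to the
  # single-condition binomial z-score
  z1 <- combined_z(25, 0, 10, 0, 3, 0, 1e5, 1e5)
  expect_equal(z1, (25 - 10) / 3)
})

test_that("scan is deterministic, seed changes z_rand only, planted spike wins", {
  cfg <- small_config(seed = 2, n_dhss_regions = 0)
  g <- make_genome(cfg, sequence = FALSE)
  ann <- make_annotation(cfg, g)
  dh <- simulate_dhss(cfg, ann$truth, g$mappability)

  s1 <- scan_windows(dh$veh, dh$vpa, g$chrom_sizes, g$mappability, seed = 5)
  s2 <- scan_windows(dh$veh, dh$vpa, g$chrom_sizes, g$mappability, seed = 5)
  expect_identical(s1, s2)
  s3 <- scan_windows(dh$veh, dh$vpa, g$chrom_sizes, g$mappability, seed = 6)
  expect_equal(s1$z_norm, s3$z_norm)
  expect_false(identical(s1$z_rand, s3$z_rand))

  # plant a 20x-enriched 500 bp region into both libraries
  spike <- 150200L:150699L
  veh2 <- tag_library(list(chr1 = c(dh$veh$positions$chr1,
                                    rep(spike, length.out = 400))), "Veh")
  vpa2 <- tag_library(list(chr1 = c(dh$vpa$positions$chr1,
                                    rep(spike, length.out = 400))), "VPA")
  s4 <- scan_windows(veh2, vpa2, g$chrom_sizes, g$mappability, seed = 5)
  top <- s4[which.max(s4$z_norm), ]
  expect_true(top$start < 150700 && top$end > 150200)
})

test_that("cutoff calibration finds the smallest qualifying grid point", {
  # perfect separation: z_norm all 10, z_rand all below 2
  stats <- data.frame(z_norm = rep(10, 100), z_rand = runif(100, 0, 2))
  cal <- calibrate_cutoff(stats)
  expect_true(cal$z_cutoff <= 2 + 0.1)
  expect_equal(cal$n_called, 100L)
  expect_lte(cal$fdr, 0.05)
  # null-like stats where the rand tail dominates everywhere: no cutoff
  stats2 <- data.frame(z_norm = rep(1, 50), z_rand = rep(5, 50))
  cal2 <- calibrate_cutoff(stats2)
  expect_true(is.na(cal2$z_cutoff))
  expect_error(calibrate_cutoff(data.frame(z_norm = numeric(), z_rand = numeric())),
               "no finite")
})

test_that("significant-window merging matches connected components", {
  stats <- data.frame(chrom = "chr1",
                      start = c(0L, 400L, 2000L, 2400L, 4000L),
                      end = c(500L, 900L, 2500L, 2900L, 4500L),
                      z_norm = c(6, 7, 2, 8, 9))
  m <- merge_significant(stats, 5)
  expect_equal(m$start, c(0L, 2400L, 4000L))
  expect_equal(m$end, c(900L, 2900L, 4500L))
  expect_equal(m$max_z, c(7, 8, 9))
  expect_equal(nrow(merge_significant(stats, 100)), 0)

  set.seed(12)
  for (i in 1:20) {
    x <- random_intervals(30)
    x$z_norm <- runif(30, 4, 10)
    m <- merge_significant(x, 5)
    sig <- x[x$z_norm >= 5, ]
    expect_equal(nrow(m), length(unique(oracle_components(sig))))
  }
})

test_that("differential classification recovers planted condition-specific signal", {
  set.seed(31)
  # background libraries of 1e5 tags, one region 10x enriched in VPA only
  bg_v <- sort(sample.int(1e6, 1e5) - 1L)
  bg_p <- sort(sample.int(1e6, 1e5) - 1L)
  region <- gintervals("chr1", 500000, 500500)
  extra <- sample(500000:500499, 450, replace = TRUE)
  veh <- tag_library(list(chr1 = bg_v), "Veh")
  vpa <- tag_library(list(chr1 = sort(c(bg_p, extra))), "VPA")
  flat <- gintervals("chr1", 100000, 100500)
  cl <- classify_differential(rbind(region, flat), veh, vpa)
  expect_equal(cl$status, c("vpa_induced", "shared"))
  expect_true(all(cl$n_veh <= veh$n_total & cl$n_vpa <= vpa$n_total))
  # induced clusters have a higher VPA rate
  ind <- cl[cl$status == "vpa_induced", ]
  expect_true(all(ind$n_vpa / vpa$n_total > ind$n_veh / veh$n_total))
  # statuses partition the set
  expect_equal(sum(table(cl$status)), nrow(cl))
})
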