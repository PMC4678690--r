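#' Two-scale scan geometry
#'
#' The genome is scanned in big windows (10 kb, consecutive windows
#' overlapping by 400 bp, i.e. step 9600) each tiled with small windows
#' (500 bp, overlapping by 100 bp, step 400). Under this phase-0 tiling every
#' small window is fully contained in exactly one big window.
#'
#' @param big_window,big_step,small_window,small_step window sizes and steps
#'   in bases.
#' @return list of class `scan_geometry`.
#' @export
scan_geometry <- function(big_window = 10000L, big_step = 9600L,
                          small_window = 500L, small_step = 400L) {
  stopifnot(big_step > 0, small_step > 0, small_window < big_window,
            big_step <= big_window, small_step <= small_window)
  structure(list(big_window = as.integer(big_window),
                 big_step = as.integer(big_step),
                 small_window = as.integer(small_window),
                 small_step = as.integer(small_step)),
            class = "scan_geometry")
}

#' Effective (uniquely mappable) length of intervals
#'
#' With a mappability track: the number of uniquely mappable positions inside
#' each interval, the repeat-corrected length used as `L` and `l` in the
#' binomial window model. Without a track the raw length is returned.
#'
#' @param intervals interval `data.frame`.
#' @param mappability merged interval `data.frame` of mappable positions, or
#'   `NULL`.
#' @return integer vector of effective lengths.
#' @export
effective_length <- function(intervals, mappability = NULL) {
  if (is.null(mappability)) return(intervals$end - intervals$start)
  out <- integer(nrow(intervals))
  by_chrom <- split(seq_len(nrow(mappability)), mappability$chrom)
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    mi <- by_chrom[[ch]]
    if (is.null(mi)) next
    ord <- mi[order(mappability$start[mi])]
    s <- mappability$start[ord]
    e <- mappability$end[ord]
    cumw <- cumsum(e - s)
    # mappable positions strictly before x
    cov_before <- function(x) {
      j <- findInterval(x, s)
      ifelse(j == 0, 0,
             cumw[pmax(j, 1)] - pmax(0, e[pmax(j, 1)] - pmax(x, s[pmax(j, 1)])))
    }
    out[qi] <- as.integer(cov_before(intervals$end[qi]) - cov_before(intervals$start[qi]))
  }
  out
}

#' Enumerate scan windows over the genome
#'
#' Big windows start at multiples of `big_step`, small windows at multiples
#' of `small_step`; each small window is paired with the unique big window
#' containing it. Windows running past the chromosome end are truncated
#' there, and truncated small windows shorter than `small_step` are dropped.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param geometry a [scan_geometry()].
#' @return `data.frame` with columns `chrom`, `start`, `end` (small window)
#'   and `big_start`, `big_end`.
#' @export
enumerate_windows <- function(chrom_sizes, geometry = scan_geometry()) {
  out <- vector("list", length(chrom_sizes))
  for (i in seq_along(chrom_sizes)) {
    ch <- names(chrom_sizes)[i]
    len <- chrom_sizes[[i]]
    if (len < geometry$small_window) next
    s <- seq.int(0L, len - 1L, by = geometry$small_step)
    e <- pmin(s + geometry$small_window, len)
    keep <- (e - s) >= geometry$small_step
    s <- s[keep]; e <- e[keep]
    if (!length(s)) next
    bs <- geometry$big_step * (s %/% geometry$big_step)
    be <- pmin(bs + geometry$big_window, len)
    contained <- s >= bs & e <= be
    out[[i]] <- data.frame(chrom = ch, start = s[contained], end = e[contained],
                           big_start = bs[contained], big_end = be[contained],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      big_start = integer(), big_end = integer())
  }
  rownames(res) <- NULL
  res
}

#' Combined normalized z-score
#'
#' Pools the two conditions after scaling the treated counts by the library
#' size ratio `r = N_tot_veh / N_tot_vpa`:
#' `n_norm = n_veh + r n_vpa`, `E_norm = E_veh + r E_vpa`,
#' `sigma_norm = sqrt(sigma_veh^2 + r^2 sigma_vpa^2)`, and
#' `z = (n_norm - E_norm) / sigma_norm`. Returns `NA` where
#' `sigma_norm == 0` (no evidence in the window).
#'
#' @param n_veh,n_vpa small-window counts (vectorized).
#' @param e_veh,e_vpa,sigma_veh,sigma_vpa per-condition binomial moments.
#' @param n_tot_veh,n_tot_vpa library totals, both positive.
#' @return numeric vector of z-scores, `NA` where undefined.
#' @export
combined_z <- function(n_veh, n_vpa, e_veh, e_vpa, sigma_veh, sigma_vpa,
                       n_tot_veh, n_tot_vpa) {
  if (n_tot_veh <= 0 || n_tot_vpa <= 0) stop("library totals must be positive")
  stopifnot(all(sigma_veh >= 0), all(sigma_vpa >= 0))
  r <- n_tot_veh / n_tot_vpa
  sigma_norm <- sqrt(sigma_veh^2 + sigma_vpa^2 * r^2)
  z <- (n_veh + n_vpa * r - (e_veh + e_vpa * r)) / sigma_norm
  z[sigma_norm == 0] <- NA_real_
  z
}

#' Scan tag libraries with the two-scale window statistic
#'
#' For every small window: per condition, `N` = big-window count, `n` =
#' small-window count, binomial moments at `p = l_eff / L_eff`, then the
#' combined normalized z-score. Simultaneously a random count is drawn per
#' condition from `Binomial(N, p)` with the seeded generator and combined
#' identically into `z_rand`, the matched null draw that calibrates the
#' empirical FDR cutoff. Windows with an undefined z (zero effective length
#' or `sigma_norm == 0`) are excluded.
#'
#' @param veh,vpa [tag_library()] objects for the two conditions.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param mappability optional merged mappability track for effective-length
#'   correction (`NULL` = raw lengths).
#' @param geometry a [scan_geometry()].
#' @param seed integer seed for the random draws.
#' @return `data.frame` of window statistics: coordinates, `l_eff`, `L_eff`,
#'   `n_veh`, `n_vpa`, `N_veh`, `N_vpa`, `z_norm`, `z_rand`.
#' @export
scan_windows <- function(veh, vpa, chrom_sizes, mappability = NULL,
                         geometry = scan_geometry(), seed = 1L) {
  stopifnot(inherits(veh, "tag_library"), inherits(vpa, "tag_library"))
  if (veh$n_total == 0 || vpa$n_total == 0) stop("tag libraries must be non-empty")
  win <- enumerate_windows(chrom_sizes, geometry)
  if (nrow(win) == 0) return(cbind(win, data.frame(l_eff = integer(), L_eff = integer())))
  big <- data.frame(chrom = win$chrom, start = win$big_start, end = win$big_end)
  win$l_eff <- effective_length(win[c("chrom", "start", "end")], mappability)
  win$L_eff <- effective_length(big, mappability)
  win$n_veh <- count_tags_intervals(veh, win)
  win$n_vpa <- count_tags_intervals(vpa, win)
  win$N_veh <- count_tags_intervals(veh, big)
  win$N_vpa <- count_tags_intervals(vpa, big)

  ok <- win$l_eff > 0 & win$L_eff > 0 & win$l_eff <= win$L_eff
  win <- win[ok, , drop = FALSE]
  p <- win$l_eff / win$L_eff
  mom_veh <- binomial_moments(win$N_veh, p)
  mom_vpa <- binomial_moments(win$N_vpa, p)
  win$z_norm <- combined_z(win$n_veh, win$n_vpa, mom_veh$E, mom_vpa$E,
                           mom_veh$sigma, mom_vpa$sigma,
                           veh$n_total, vpa$n_total)
  rnd <- withr::with_seed(seed, list(
    veh = stats::rbinom(nrow(win), win$N_veh, p),
    vpa = stats::rbinom(nrow(win), win$N_vpa, p)
  ))
  win$z_rand <- combined_z(rnd$veh, rnd$vpa, mom_veh$E, mom_vpa$E,
                           mom_veh$sigma, mom_vpa$sigma,
                           veh$n_total, vpa$n_total)
  win <- win[!is.na(win$z_norm), , drop = FALSE]
  rownames(win) <- NULL
  win$strand <- NULL
  win
}

#' Calibrate the z-score cutoff at a target empirical FDR
#'
#' Estimates `FDR(c) = #\{z_rand >= c\} / max(1, #\{z_norm >= c\})` on a
#' grid from the smallest to the largest observed z (step `grid_step`) and
#' returns the smallest cutoff meeting the target. Returns `NA` when no grid
#' point qualifies.
#'
#' @param stats window table from [scan_windows()].
#' @param target_fdr target false discovery rate (default 0.05).
#' @param grid_step cutoff grid resolution (default 0.1).
#' @return list with `z_cutoff` (or `NA`), and the estimated `fdr`,
#'   `n_called`, `n_rand_exceed` at the cutoff.
#' @export
calibrate_cutoff <- function(stats, target_fdr = 0.05, grid_step = 0.1) {
  z_norm <- stats$z_norm[is.finite(stats$z_norm)]
  z_rand <- stats$z_rand[is.finite(stats$z_rand)]
  if (!length(z_norm)) stop("no finite window statistics to calibrate on")
  zs_norm <- sort(z_norm)
  zs_rand <- sort(z_rand)
  lo <- min(c(z_norm, z_rand))
  hi <- max(c(z_norm, z_rand))
  grid <- unique(c(seq(lo, hi, by = grid_step), hi))
  n_norm_ge <- length(zs_norm) - findInterval(grid - 1e-12, zs_norm)
  n_rand_ge <- length(zs_rand) - findInterval(grid - 1e-12, zs_rand)
  fdr <- n_rand_ge / pmax(1, n_norm_ge)
  ok <- which(fdr <= target_fdr)
  if (!length(ok)) {
    return(list(z_cutoff = NA_real_, fdr = NA_real_, n_called = 0L,
                n_rand_exceed = 0L))
  }
  i <- ok[1]
  list(z_cutoff = grid[i], fdr = fdr[i], n_called = n_norm_ge[i],
       n_rand_exceed = n_rand_ge[i])
}

#' Merge significant windows into DHSS clusters
#'
#' Overlapping small windows with `z_norm >= z_cutoff` are merged into
#' clusters; each cluster records the maximal window z.
#'
#' @param stats window table from [scan_windows()].
#' @param z_cutoff finite z-score cutoff (e.g. from [calibrate_cutoff()]).
#' @return interval `data.frame` with a `max_z` column.
#' @export
merge_significant <- function(stats, z_cutoff) {
  if (!is.finite(z_cutoff)) stop("z_cutoff must be finite")
  sig <- stats[!is.na(stats$z_norm) & stats$z_norm >= z_cutoff, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- empty_intervals()
    out$max_z <- numeric()
    return(out)
  }
  mg <- merge_with_groups(sig[c("chrom", "start", "end")])
  out <- mg$merged
  grp <- factor(mg$group, levels = seq_len(nrow(out)))
  out$max_z <- as.numeric(tapply(sig$z_norm, grp, max))
  out
}

# Shared differential machinery for DHSS clusters and CAGE TSS clusters:
# per region, one-tailed Fisher tests of the count-vs-rest table in both
# directions, BH within each direction, and a three-way status.
differential_status <- function(n_a, n_b, n_tot_a, n_tot_b, alpha = 0.05,
                                labels = c("vpa_induced", "vehicle_specific", "shared")) {
  k <- length(n_a)
  p_a <- vapply(seq_len(k), function(i) {
    fisher_one_tailed(n_a[i], n_tot_a - n_a[i], n_b[i], n_tot_b - n_b[i], "greater")
  }, 0)
  p_b <- vapply(seq_len(k), function(i) {
    fisher_one_tailed(n_b[i], n_tot_b - n_b[i], n_a[i], n_tot_a - n_a[i], "greater")
  }, 0)
  q_a <- bh_adjust(p_a)
  q_b <- bh_adjust(p_b)
  status <- rep(labels[3], k)
  status[q_a < alpha] <- labels[1]
  status[q_a >= alpha & q_b < alpha] <- labels[2]
  data.frame(p_up = p_a, q_up = q_a, p_down = p_b, q_down = q_b,
             status = status, stringsAsFactors = FALSE)
}

#' Classify DHSS clusters as induced, vehicle-specific or shared
#'
#' Tag counts are recounted over each merged cluster span (overlapping
#' windows would double count) and each cluster's table
#' `[[n_vpa, N_tot_vpa - n_vpa], [n_veh, N_tot_veh - n_veh]]` is tested
#' one-tailed in both directions; BH correction is applied per direction
#' across all clusters. Status is `vpa_induced` when the VPA-direction q
#' falls below `alpha`, `vehicle_specific` when only the vehicle direction
#' does, otherwise `shared`.
#'
#' @param clusters interval `data.frame` from [merge_significant()].
#' @param veh,vpa the two [tag_library()]s.
#' @param alpha BH q-value threshold (default 0.05).
#' @return cluster table with counts, `status`, and per-direction p/q
#'   columns (`p_vpa`, `q_vpa`, `p_veh`, `q_veh`).
#' @export
classify_differential <- function(clusters, veh, vpa, alpha = 0.05) {
  out <- clusters
  out$n_veh <- count_tags_intervals(veh, clusters)
  out$n_vpa <- count_tags_intervals(vpa, clusters)
  if (nrow(out) == 0) {
    out$status <- character()
    return(out)
  }
  d <- differential_status(out$n_vpa, out$n_veh, vpa$n_total, veh$n_total, alpha)
  out$status <- d$status
  out$p_vpa <- d$p_up; out$q_vpa <- d$q_up
  out$p_veh <- d$p_down; out$q_veh <- d$q_down
  out
}

#' Full DHSS cluster calling pipeline
#'
#' Scan, calibrate the cutoff at the target empirical FDR, merge significant
#' windows, and classify clusters differentially. If calibration finds no
#' qualifying cutoff the fallback cutoff is used only when `calibrate =
#' FALSE`; otherwise no clusters are called.
#'
#' @param veh,vpa [tag_library()]s.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param mappability optional merged mappability track.
#' @param geometry a [scan_geometry()].
#' @param target_fdr calibration target (default 0.05).
#' @param alpha BH threshold for differential classification.
#' @param seed seed for the calibration draws.
#' @param calibrate if `FALSE`, skip calibration and use `fallback_cutoff`.
#' @param fallback_cutoff cutoff used when calibration is disabled
#'   (default 5.5).
#' @return list with `windows`, `z_cutoff`, `calibration`, and the
#'   classified `clusters` table.
#' @export
call_dhss <- function(veh, vpa, chrom_sizes, mappability = NULL,
                      geometry = scan_geometry(), target_fdr = 0.05,
                      alpha = 0.05, seed = 1L, calibrate = TRUE,
                      fallback_cutoff = 5.5) {
  win <- scan_windows(veh, vpa, chrom_sizes, mappability, geometry, seed)
  cal <- NULL
  if (calibrate) {
    cal <- calibrate_cutoff(win, target_fdr)
    z_cutoff <- cal$z_cutoff
  } else {
    z_cutoff <- fallback_cutoff
  }
  if (!is.finite(z_cutoff)) {
    clusters <- classify_differential(merge_significant(win, Inf), veh, vpa, alpha)
  } else {
    clusters <- classify_differential(merge_significant(win, z_cutoff), veh, vpa, alpha)
  }
  list(windows = win, z_cutoff = z_cutoff, calibration = cal, clusters = clusters)
}
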