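# Independent brute-force oracles and shared fixtures. Each oracle is a
# deliberately naive reimplementation used only to validate the package's
# optimized code paths.

# linear-scan tag count
oracle_count <- function(pos, start, end) sum(pos >= start & pos < end)

# exhaustive pairwise nearest distance (gap; 0 on overlap; NA if no target)
oracle_nearest <- function(q, targets) {
  sel <- targets$chrom == q$chrom
  if (!any(sel)) return(NA_integer_)
  d <- mapply(function(s, e) {
    if (s < q$end && e > q$start) 0L else max(s - q$end, q$start - e)
  }, targets$start[sel], targets$end[sel])
  as.integer(min(d))
}

# connected components of the strict-overlap graph (transitive closure)
oracle_components <- function(df) {
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && df$chrom[i] == df$chrom[j] &&
          df$start[i] < df$end[j] && df$end[i] > df$start[j] &&
          comp[i] != comp[j]) {
        comp[pmax(comp[i], comp[j]) == comp] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# direct-space hypergeometric enumeration for small tables
oracle_fisher_greater <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; col2 <- b + d; N <- a + b + c + d
  xs <- max(0, row1 - col2):min(row1, col1)
  probs <- choose(col1, xs) * choose(col2, row1 - xs) / choose(N, row1)
  sum(probs[xs >= a])
}

# term-by-term binomial upper tail
oracle_binom_greater <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
}

# per-window rescoring of a motif scan, forward strand
oracle_scan_strand <- function(seq, motif) {
  bases <- strsplit(seq, "")[[1]]
  w <- motif$width
  out <- rep(NA_real_, max(0L, nchar(seq) - w + 1L))
  for (i in seq_along(out)) {
    win <- bases[i:(i + w - 1L)]
    idx <- match(win, c("A", "C", "G", "T"))
    if (anyNA(idx)) next
    s <- sum(motif$weights[cbind(idx, seq_len(w))])
    out[i] <- (s - motif$min_score) / (motif$max_score - motif$min_score)
  }
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                             max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# reduced-scale simulation config for fast module tests
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_len = 600000L, n_genes = 15L,
               n_repeats = 300L, n_dhss_regions = 30L, n_tags_dhss = 30000L,
               n_tags_cage = 20000L, n_enhancers = 30L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# default-scale bundle, built once per test run and shared
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function() {
  if (is.null(.bundle_cache$bundle)) {
    dir <- file.path(tempdir(), "dhssremodel-default-bundle")
    .bundle_cache$bundle <- simulate_bundle(sim_config(seed = 20260901L), dir)
  }
  .bundle_cache$bundle
}
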