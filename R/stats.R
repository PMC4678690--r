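## Statistical primitives used across the pipeline. All implemented
## self-contained (log space where margins can be large) and cross-checked
## against independent oracles in the test suite.

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability of the table `[[a, b], [c, d]]` (rows =
#' group, columns = outcome), evaluated in log space so that margins in the
#' millions (e.g. genome-wide repeat counts) remain stable.
#' `direction = "greater"` tests enrichment of outcome 1 in row 1, i.e.
#' `P(X >= a)` with `X` hypergeometric at the observed margins.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param direction `"greater"` or `"less"`.
#' @return p-value in `[0, 1]`; degenerate margins give 1.
#' @export
fisher_one_tailed <- function(a, b, c, d, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  row1 <- a + b; col1 <- a + c; col2 <- b + d
  if (row1 == 0 || col1 + col2 == 0 || col1 == 0 || col2 + row1 == 0) return(1)
  lo <- max(0, row1 - col2)
  hi <- min(row1, col1)
  if (lo > hi) return(1)
  x <- lo:hi
  logp <- stats::dhyper(x, col1, col2, row1, log = TRUE)
  keep <- if (direction == "greater") x >= a else x <= a
  min(1, exp(logsumexp(logp[keep])))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, returned in
#' the input order and clamped to `[0, 1]`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q[order(ord)]
}

#' One-tailed Wilcoxon rank-sum test (x stochastically greater)
#'
#' Exact enumeration of all rank assignments when the pooled sample has at
#' most `exact_max` observations and no ties; otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max pooled-size threshold for the exact branch (default 12).
#' @return one-tailed p-value for the alternative that `x` tends larger.
#' @export
wilcoxon_greater <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(pooled) > 0
  if (n <= exact_max && !ties) {
    sums <- colSums(utils::combn(n, nx))
    return(mean(sums >= w_obs))
  }
  u <- w_obs - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  stats::pnorm((u - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_eff) * D` with effective size `n_x n_y / (n_x + n_y)`.
#'
#' @param x,y non-empty numeric samples.
#' @return list with elements `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), 0)
  fy <- vapply(pts, function(t) mean(y <= t), 0)
  D <- max(abs(fx - fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(n_eff) * D
  if (lambda == 0) return(list(D = 0, p = 1))
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(D = D, p = min(1, max(0, p)))
}

#' Welch's two-tailed t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom; the
#' pooled-variance alternative is available via `var_equal = TRUE` (the
#' equal/unequal choice is left explicit because figure-level usage of the
#' "two-tailed t test" does not pin it down).
#'
#' @param x,y numeric samples with at least 2 points each.
#' @param var_equal use the pooled-variance statistic instead.
#' @return two-tailed p-value.
#' @export
welch_t_two_tailed <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 points per group")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mean(x) - mean(y)) / se
  2 * stats::pt(-abs(tstat), df)
}

#' Upper-tail binomial test
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, computed through the log-space
#' regularized tail so extreme p-values keep full precision.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return p-value.
#' @export
binomial_test_greater <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Binomial mean and standard deviation
#'
#' The window-model moments: `E = N p`, `sigma = sqrt(N p (1 - p))` with
#' `p = l/L` the ratio of effective small- to big-window length.
#'
#' @param n_trials number of trials `N` (vectorized).
#' @param p success probability (vectorized).
#' @return list with vectors `E` and `sigma`.
#' @export
binomial_moments <- function(n_trials, p) {
  stopifnot(all(n_trials >= 0), all(p >= 0 & p <= 1))
  list(E = n_trials * p, sigma = sqrt(n_trials * p * (1 - p)))
}

#' qPCR accessibility statistic
#'
#' Delta-Ct = Ct(digested DNA) - Ct(undigested DNA); larger values mean the
#' locus was more available to DNase I digestion.
#'
#' @param ct_digested,ct_undigested finite non-negative cycle thresholds.
#' @return numeric delta-Ct (vectorized).
#' @export
delta_ct <- function(ct_digested, ct_undigested) {
  stopifnot(all(is.finite(ct_digested)), all(is.finite(ct_undigested)),
            all(ct_digested >= 0), all(ct_undigested >= 0))
  ct_digested - ct_undigested
}

#' Read qPCR measurements
#'
#' Tab-separated with columns primer_id, condition, ct_digested,
#' ct_undigested (header optional).
#'
#' @param path path to the table.
#' @return `data.frame` with the four columns plus a computed `delta_ct`.
#' @export
read_qpcr <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("primer", first, ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           col.names = c("primer_id", "condition",
                                         "ct_digested", "ct_undigested"),
                           stringsAsFactors = FALSE)
  tab$delta_ct <- delta_ct(tab$ct_digested, tab$ct_undigested)
  tab
}

#' Per-primer-category qPCR comparison
#'
#' Summarizes delta-Ct by condition and compares the two conditions with a
#' two-tailed Welch t test, overall and per primer category when primer ids
#' carry a `category:primer` prefix.
#'
#' @param qpcr table from [read_qpcr()].
#' @param cond_a,cond_b condition labels to compare (defaults: the first two
#'   observed).
#' @return `data.frame` with category, per-condition mean delta-Ct, n, and p.
#' @export
qpcr_stats <- function(qpcr, cond_a = NULL, cond_b = NULL) {
  conds <- unique(qpcr$condition)
  if (is.null(cond_a)) cond_a <- conds[1]
  if (is.null(cond_b)) cond_b <- conds[2]
  cat_of <- ifelse(grepl(":", qpcr$primer_id, fixed = TRUE),
                   sub(":.*$", "", qpcr$primer_id), "all")
  cats <- unique(c(cat_of, "all"))
  rows <- lapply(cats, function(cc) {
    sel <- if (cc == "all") rep(TRUE, nrow(qpcr)) else cat_of == cc
    xa <- qpcr$delta_ct[sel & qpcr$condition == cond_a]
    xb <- qpcr$delta_ct[sel & qpcr$condition == cond_b]
    p <- if (length(xa) >= 2 && length(xb) >= 2) welch_t_two_tailed(xa, xb) else NA_real_
    data.frame(category = cc,
               mean_delta_ct_a = mean(xa), n_a = length(xa),
               mean_delta_ct_b = mean(xb), n_b = length(xb),
               p_welch = p)
  })
  out <- do.call(rbind, rows)
  names(out)[c(2, 4)] <- paste0("mean_delta_ct_", c(cond_a, cond_b))
  out
}
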