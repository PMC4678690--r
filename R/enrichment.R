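#' Assign each region to its longest-overlap repeat
#'
#' When a region overlaps several repeats the one sharing the greatest
#' number of bases wins; ties break deterministically toward the longer
#' repeat, then the leftmost start.
#'
#' @param regions interval `data.frame`.
#' @param repeats repeat table from [read_repeats()].
#' @return `data.frame` with one row per region: `repeat_class`, `family`,
#'   `name`, `overlap` (bases; class is `NA` when nothing overlaps).
#' @export
assign_repeat <- function(regions, repeats) {
  n <- nrow(regions)
  out <- data.frame(repeat_class = rep(NA_character_, n),
                    family = NA_character_, name = NA_character_,
                    overlap = 0L, stringsAsFactors = FALSE)
  pairs <- overlap_pairs(regions, repeats)
  if (!nrow(pairs)) return(out)
  ov <- pmin(regions$end[pairs$a_idx], repeats$end[pairs$b_idx]) -
    pmax(regions$start[pairs$a_idx], repeats$start[pairs$b_idx])
  rep_len_ <- repeats$end[pairs$b_idx] - repeats$start[pairs$b_idx]
  ord <- order(pairs$a_idx, -ov, -rep_len_, repeats$start[pairs$b_idx])
  first <- ord[!duplicated(pairs$a_idx[ord])]
  ai <- pairs$a_idx[first]
  bi <- pairs$b_idx[first]
  out$repeat_class[ai] <- repeats$repeat_class[bi]
  out$family[ai] <- repeats$family[bi]
  out$name[ai] <- repeats$name[bi]
  out$overlap[ai] <- ov[first]
  out
}

#' Does each region overlap any repeat of a given class?
#'
#' Independent of the longest-overlap winner: `TRUE` whenever at least one
#' overlapping repeat has the wanted class.
#'
#' @param regions interval `data.frame`.
#' @param repeats repeat table.
#' @param wanted_class class to look for (e.g. `"SINE"`).
#' @return logical vector per region.
#' @export
any_overlap_class <- function(regions, repeats, wanted_class) {
  overlaps_any(regions, repeats[repeats$repeat_class == wanted_class, , drop = FALSE])
}

#' Genomic category of regions relative to gene models
#'
#' Fixed precedence: `promoter` when the region overlaps any promoter
#' region (same definition as [promoter_regions()]; strand ignored for
#' unstranded queries), else `gene_body` when it overlaps any gene span,
#' else `intergenic`.
#'
#' @param regions interval `data.frame`.
#' @param genes gene table from [read_bed12()].
#' @return character vector of categories.
#' @export
genomic_category <- function(regions, genes) {
  prom <- promoter_regions(genes)
  in_prom <- overlaps_any(regions, prom, same_strand = TRUE)
  in_gene <- overlaps_any(regions, genes[c("chrom", "start", "end", "strand")])
  ifelse(in_prom, "promoter", ifelse(in_gene, "gene_body", "intergenic"))
}

#' Bin query regions by distance to the nearest target
#'
#' Proximal: gap < 1 kb; semi-distal: 1 kb <= gap <= 1 Mb; distal:
#' gap > 1 Mb; `no_target` counts queries on chromosomes without targets.
#' The four counts partition the query set.
#'
#' @param queries,targets interval `data.frame`s.
#' @param proximal_max,distal_min bin edges in bases.
#' @return list with the four counts and the raw `distances` vector.
#' @export
distance_bins <- function(queries, targets, proximal_max = 1000L,
                          distal_min = 1000000L) {
  d <- nearest_distance(queries, targets)
  list(proximal = sum(!is.na(d) & d < proximal_max),
       semi_distal = sum(!is.na(d) & d >= proximal_max & d <= distal_min),
       distal = sum(!is.na(d) & d > distal_min),
       no_target = sum(is.na(d)),
       distances = d)
}

#' Overlap enrichment of one region set against a background
#'
#' One-tailed Fisher's exact test of the table
#' `[[a_hits, a_total - a_hits], [bg_hits, bg_total - bg_hits]]` plus the
#' odds ratio (Haldane 0.5 correction when any cell is zero).
#'
#' @param set_a_hits,set_a_total hits and size of the focal set.
#' @param bg_hits,bg_total hits and size of the background set.
#' @return list with `odds_ratio` and `p`.
#' @export
overlap_fisher <- function(set_a_hits, set_a_total, bg_hits, bg_total) {
  stopifnot(set_a_hits <= set_a_total, bg_hits <= bg_total)
  a <- set_a_hits; b <- set_a_total - set_a_hits
  c_ <- bg_hits; d <- bg_total - bg_hits
  cells <- c(a, b, c_, d)
  h <- if (any(cells == 0)) 0.5 else 0
  list(odds_ratio = ((a + h) * (d + h)) / ((b + h) * (c_ + h)),
       p = fisher_one_tailed(a, b, c_, d, "greater"))
}

#' Binomial test of enhancer overlap
#'
#' `k` = number of queries overlapping at least one (merged) enhancer.
#' The null probability that a uniformly placed interval of the mean query
#' length overlaps the enhancer set is computed analytically per chromosome
#' as `min(chrom_len, coverage + n_enh (mean_len - 1)) / genome_len`, summed
#' and capped at 1; the upper-tail binomial p-value follows.
#'
#' @param queries interval `data.frame`.
#' @param enhancers interval `data.frame` (merged internally).
#' @param chrom_sizes named chromosome lengths.
#' @return list with `k`, `n`, `p0`, `p`.
#' @export
enhancer_binomial <- function(queries, enhancers, chrom_sizes) {
  if (nrow(enhancers) == 0) {
    return(list(k = 0L, n = nrow(queries), p0 = 0, p = 1))
  }
  enh <- merge_intervals(enhancers)
  k <- sum(overlaps_any(queries, enh))
  n <- nrow(queries)
  mean_len <- mean(queries$end - queries$start)
  total <- sum(chrom_sizes)
  mass <- 0
  for (ch in unique(enh$chrom)) {
    if (!ch %in% names(chrom_sizes)) next
    sel <- enh$chrom == ch
    cov <- sum(enh$end[sel] - enh$start[sel])
    mass <- mass + min(chrom_sizes[[ch]], cov + sum(sel) * (mean_len - 1))
  }
  p0 <- min(1, mass / total)
  list(k = k, n = n, p0 = p0, p = binomial_test_greater(k, n, p0))
}

#' KS test of nearest-target distances against uniform placement
#'
#' Compares the observed nearest-distance distribution of the queries with
#' that of `n_random` uniformly placed intervals whose lengths are resampled
#' from the query length distribution (seeded). Small D / large p means the
#' queries sit no closer to the targets than chance placement.
#'
#' @param queries,targets interval `data.frame`s.
#' @param chrom_sizes named chromosome lengths.
#' @param n_random number of random intervals (default 1000).
#' @param seed RNG seed.
#' @return list with `D` and `p` (plus the two distance samples).
#' @export
distance_ks_vs_random <- function(queries, targets, chrom_sizes,
                                  n_random = 1000L, seed = 1L) {
  stopifnot(nrow(targets) > 0, nrow(queries) > 0)
  d_obs <- nearest_distance(queries, targets)
  d_obs <- d_obs[!is.na(d_obs)]
  rand <- withr::with_seed(seed, {
    lens <- sample(queries$end - queries$start, n_random, replace = TRUE)
    chrom <- sample(names(chrom_sizes), n_random, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    max_start <- pmax(0L, chrom_sizes[chrom] - lens)
    start <- floor(stats::runif(n_random) * (max_start + 1))
    gintervals(chrom, start, start + lens)
  })
  d_rand <- nearest_distance(rand, targets)
  d_rand <- d_rand[!is.na(d_rand)]
  ks <- ks_two_sample(d_obs, d_rand)
  list(D = ks$D, p = ks$p, d_obs = d_obs, d_rand = d_rand)
}
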