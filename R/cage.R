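#' Read CAGE tags from a BED6 file
#'
#' CAGE tags keep their mapped span and strand (the 5' end is the `start`
#' on `+` and `end - 1` on `-`).
#'
#' @param path BED6 file.
#' @param condition condition label attached to every tag.
#' @return interval `data.frame` with `strand` and `condition` columns.
#' @export
read_cage_bed <- function(path, condition = "sample") {
  df <- read_bed(path, stranded = TRUE)
  if (nrow(df) && any(df$strand == ".")) stop("CAGE tags must be stranded")
  df$condition <- condition
  df
}

cage_five_prime <- function(tags) {
  ifelse(tags$strand == "-", tags$end - 1L, tags$start)
}

#' Single-linkage TSS clusters from CAGE tags
#'
#' Tags are merged transitively whenever their spans overlap on the same
#' chromosome and strand (single linkage, no gap tolerance). Each cluster
#' records per-condition tag counts, TPM (counts per million mapped tags)
#' and the peak position (modal 5'-end; leftmost on ties).
#'
#' @param tags stranded tag table, e.g. `rbind` of two [read_cage_bed()]
#'   results.
#' @param n_tot_veh,n_tot_vpa library-wide mapped-tag totals used for TPM.
#' @param cond_veh,cond_vpa the condition labels in `tags$condition`.
#' @return cluster `data.frame` with `count_veh`, `count_vpa`, `tpm_veh`,
#'   `tpm_vpa`, `peak_position`.
#' @export
cluster_cage <- function(tags, n_tot_veh, n_tot_vpa,
                         cond_veh = "Veh", cond_vpa = "VPA") {
  if (nrow(tags) && any(!tags$strand %in% c("+", "-"))) {
    stop("CAGE tags must be stranded")
  }
  stopifnot(n_tot_veh > 0, n_tot_vpa > 0)
  if (nrow(tags) == 0) {
    out <- empty_intervals()
    out[c("count_veh", "count_vpa", "tpm_veh", "tpm_vpa", "peak_position")] <-
      list(integer(), integer(), numeric(), numeric(), integer())
    return(out)
  }
  parts <- split(seq_len(nrow(tags)), list(tags$chrom, tags$strand), drop = TRUE)
  clusters <- list()
  for (idx in parts) {
    sub <- tags[idx, , drop = FALSE]
    mg <- merge_with_groups(sub[c("chrom", "start", "end")])
    cl <- mg$merged
    cl$strand <- sub$strand[1]
    p5 <- cage_five_prime(sub)
    is_veh <- sub$condition == cond_veh
    grp <- factor(mg$group, levels = seq_len(nrow(cl)))
    cl$count_veh <- as.integer(tapply(is_veh, grp, sum))
    cl$count_vpa <- as.integer(tapply(!is_veh, grp, sum))
    cl$peak_position <- as.integer(tapply(p5, grp, function(p) {
      tab <- table(p)
      as.integer(names(tab)[which.max(tab)])
    }))
    clusters[[length(clusters) + 1L]] <- cl
  }
  out <- do.call(rbind, clusters)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$tpm_veh <- out$count_veh * 1e6 / n_tot_veh
  out$tpm_vpa <- out$count_vpa * 1e6 / n_tot_vpa
  out
}

#' Retain TSS clusters expressed above a TPM floor
#'
#' Keeps clusters with at least `min_tpm` tags per million in either or both
#' samples.
#'
#' @param clusters table from [cluster_cage()].
#' @param min_tpm threshold (default 10).
#' @return filtered cluster table.
#' @export
filter_tpm <- function(clusters, min_tpm = 10) {
  keep <- clusters$tpm_veh >= min_tpm | clusters$tpm_vpa >= min_tpm
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential status of TSS clusters
#'
#' The same one-tailed Fisher + per-direction BH construction as the DHSS
#' cluster classification, applied to CAGE counts. Status is `induced`
#' (up in VPA), `downregulated`, or `non_induced`.
#'
#' @param clusters filtered table from [filter_tpm()].
#' @param n_tot_veh,n_tot_vpa library totals.
#' @param alpha BH q threshold (default 0.05).
#' @return cluster table with `status`, `p_up`, `q_up`, `p_down`, `q_down`.
#' @export
classify_tss <- function(clusters, n_tot_veh, n_tot_vpa, alpha = 0.05) {
  out <- clusters
  if (nrow(out) == 0) {
    out$status <- character()
    return(out)
  }
  d <- differential_status(out$count_vpa, out$count_veh, n_tot_vpa, n_tot_veh,
                           alpha, labels = c("induced", "downregulated", "non_induced"))
  cbind(out, d)
}

#' Overlap of TSS clusters with promoter regions
#'
#' Flags each cluster that intersects a promoter region on the same strand
#' and summarizes the overlap fraction per status group, with a one-tailed
#' Fisher test of the induced group against the rest.
#'
#' @param clusters TSS cluster table (with `status` for the group summary;
#'   optional).
#' @param genes gene table from [read_bed12()].
#' @param upstream promoter upstream extent passed to [promoter_regions()].
#' @return list with `flags` (logical per cluster), `by_status` summary
#'   `data.frame`, and `p_induced_vs_rest` (NA when no status column).
#' @export
promoter_overlap <- function(clusters, genes, upstream = 1000L) {
  prom <- promoter_regions(genes, upstream)
  flags <- overlaps_any(clusters, prom, same_strand = TRUE)
  by_status <- NULL
  p <- NA_real_
  if (!is.null(clusters$status) && nrow(clusters)) {
    agg <- tapply(flags, clusters$status, function(f) c(sum(f), length(f)))
    by_status <- data.frame(
      status = names(agg),
      n_overlap = vapply(agg, `[`, 0, 1),
      n_total = vapply(agg, `[`, 0, 2)
    )
    by_status$fraction <- by_status$n_overlap / by_status$n_total
    ind <- clusters$status == "induced"
    if (any(ind) && any(!ind)) {
      p <- fisher_one_tailed(sum(flags[ind]), sum(!flags[ind]),
                             sum(flags[!ind]), sum(!flags[!ind]), "greater")
    }
    rownames(by_status) <- NULL
  }
  list(flags = flags, by_status = by_status, p_induced_vs_rest = p)
}

#' First-exon CAGE tag ratio per gene
#'
#' For every gene with at least `min_tags` CAGE tags (5'-end within the gene
#' span, same strand), the fraction of those tags whose 5' end lies in the
#' first exon (transcript orientation). Computed per condition, for the
#' downstream two-tailed t comparison of exon-1 specificity.
#'
#' @param genes gene table from [read_bed12()].
#' @param tags CAGE tag table with `condition`.
#' @param min_tags minimum gene-level tag count (default 10).
#' @return `data.frame` with `gene`, `condition`, `n_tags`, `ratio`.
#' @export
exon1_ratio <- function(genes, tags, min_tags = 10L) {
  rows <- list()
  p5 <- cage_five_prime(tags)
  for (i in seq_len(nrow(genes))) {
    ex_s <- genes$exon_starts[[i]]
    ex_e <- genes$exon_ends[[i]]
    if (!length(ex_s)) {
      warning("gene without exons skipped: ", genes$name[i])
      next
    }
    first <- if (genes$strand[i] == "-") length(ex_s) else 1L
    in_gene <- tags$chrom == genes$chrom[i] & tags$strand == genes$strand[i] &
      p5 >= genes$start[i] & p5 < genes$end[i]
    for (cond in unique(tags$condition)) {
      sel <- in_gene & tags$condition == cond
      n <- sum(sel)
      if (n < min_tags) next
      in_ex1 <- sum(p5[sel] >= ex_s[first] & p5[sel] < ex_e[first])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes$name[i], condition = cond, n_tags = n,
        ratio = in_ex1 / n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), condition = character(),
                      n_tags = integer(), ratio = numeric()))
  }
  do.call(rbind, rows)
}

#' Average DHSS tag profile around TSSs
#'
#' DHSS-tag TPM in 500-bp bins spanning +/- `flank` around each promoter
#' TSS, orientation-flipped for minus-strand genes. Promoters on chrM are
#' excluded; a first pass computes cross-promoter bin means and a second
#' pass drops any promoter containing a bin above 10x that bin's first-pass
#' mean, the outlier rule that keeps a handful of extreme loci from
#' dominating the average.
#'
#' @param dhss a [tag_library()].
#' @param genes gene table (TSS and strand are used).
#' @param flank half-width in bases, a multiple of `bin` (default 5000).
#' @param bin bin width (default 500).
#' @param outlier_fold exclusion multiplier (default 10).
#' @return list with `bin_offsets` (bin start offsets relative to the TSS,
#'   oriented), `mean_tpm`, and `n_promoters_retained`.
#' @export
tss_profile <- function(dhss, genes, flank = 5000L, bin = 500L,
                        outlier_fold = 10) {
  if (flank %% bin != 0) stop("flank must be a multiple of the bin width")
  genes <- genes[genes$chrom != "chrM", , drop = FALSE]
  if (nrow(genes) == 0) stop("no promoters to profile")
  offsets <- seq.int(-flank, flank - bin, by = bin)
  nb <- length(offsets)
  mat <- matrix(0, nrow = nrow(genes), ncol = nb)
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    if (genes$strand[i] == "-") {
      starts <- tss - offsets - bin + 1L
    } else {
      starts <- tss + offsets
    }
    starts <- pmax(starts, 0L)
    cnt <- count_tags(dhss, genes$chrom[i], starts, starts + bin)
    mat[i, ] <- cnt * 1e6 / dhss$n_total
  }
  pass1 <- colMeans(mat)
  thresh <- outlier_fold * pass1
  drop <- apply(mat, 1, function(row) any(thresh > 0 & row > thresh))
  kept <- mat[!drop, , drop = FALSE]
  list(bin_offsets = offsets,
       mean_tpm = if (nrow(kept)) colMeans(kept) else rep(NA_real_, nb),
       n_promoters_retained = nrow(kept))
}
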