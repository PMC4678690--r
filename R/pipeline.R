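write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a synthetic bundle directory to pipeline input paths
#'
#' @param dir directory written by [simulate_bundle()].
#' @return named list of paths for [run_all()].
#' @export
bundle_paths <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(veh_tags = p("dhss_veh.bed"), vpa_tags = p("dhss_vpa.bed"),
       chrom_sizes = p("chrom.sizes"), mappability = p("mappability.bed"),
       cage_veh = p("cage_veh.bed"), cage_vpa = p("cage_vpa.bed"),
       genes = p("genes.bed12"), repeats = p("repeats.tsv"),
       enhancers = p("enhancers.bed"), foxa2 = p("foxa2.bed"),
       fasta = p("genome.fa"), motifs = p("motifs.jaspar"),
       qpcr = p("qpcr.tsv"))
}

have_input <- function(paths, key) {
  !is.null(paths[[key]]) && file.exists(paths[[key]])
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end and writes the summary tables:
#' `dhss_clusters.bed`, `dhss_venn.tsv`, `tss_clusters.bed`,
#' `tss_promoter_overlap.tsv`, `exon1_ratios.tsv`, `distance_bins.tsv`,
#' `repeat_assignment.tsv`, `motif_comparison.tsv`, `overlap_tests.tsv`,
#' `tss_profile.tsv`, `qpcr_stats.tsv`, plus `run_log.txt` recording the
#' package version, seed and parameter values. Analyses whose optional
#' inputs (mappability, enhancers, Foxa2 peaks, FASTA/motifs, qPCR) are
#' missing are skipped with a warning; the run continues. Reruns with
#' identical inputs, parameters and seed are byte-identical.
#'
#' @param paths named list of input paths (see [bundle_paths()] for keys).
#' @param out_dir output directory.
#' @param seed seed for the calibration draws and randomized null models.
#' @param target_fdr empirical-FDR calibration target (default 0.05).
#' @param alpha BH q threshold for differential calls (default 0.05).
#' @param min_tpm TSS cluster expression floor (default 10 TPM).
#' @param motif_threshold relative motif score cutoff (default 0.8).
#' @param flank TSS profile half-width (default 5000).
#' @param n_random random intervals for the distance KS null (default 1000).
#' @param geometry a [scan_geometry()].
#' @return invisibly, a list with the main result objects.
#' @export
run_all <- function(paths, out_dir, seed = 1L, target_fdr = 0.05,
                    alpha = 0.05, min_tpm = 10, motif_threshold = 0.8,
                    flank = 5000L, n_random = 1000L,
                    geometry = scan_geometry()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(out_dir, f)
  log_lines <- c(
    paste0("dhssremodel ", as.character(utils::packageVersion("dhssremodel"))),
    paste0("seed=", seed), paste0("target_fdr=", target_fdr),
    paste0("alpha=", alpha), paste0("min_tpm=", min_tpm),
    paste0("motif_threshold=", motif_threshold), paste0("flank=", flank))
  note <- function(msg) log_lines <<- c(log_lines, msg)

  ## DHSS calling
  veh <- read_tag_bed(paths$veh_tags, "Veh")
  vpa <- read_tag_bed(paths$vpa_tags, "VPA")
  sizes <- read_chrom_sizes(paths$chrom_sizes)
  mapp <- NULL
  if (have_input(paths, "mappability")) {
    mapp <- read_mappability(paths$mappability)
  } else {
    warning("no mappability track; using raw window lengths")
    note("WARN mappability absent, raw lengths used")
  }
  dhss <- call_dhss(veh, vpa, sizes, mapp, geometry, target_fdr, alpha, seed)
  cl <- dhss$clusters
  note(paste0("z_cutoff=", dhss$z_cutoff, " clusters=", nrow(cl)))
  writeLines(paste(cl$chrom, cl$start, cl$end, cl$status,
                   round(cl$max_z * 10), ".", cl$n_veh, cl$n_vpa,
                   signif(cl$p_vpa, 6), signif(cl$q_vpa, 6), sep = "\t"),
             o("dhss_clusters.bed"))
  venn <- as.data.frame(table(factor(cl$status,
                                     levels = c("vpa_induced", "vehicle_specific", "shared"))))
  names(venn) <- c("status", "count")
  write_tsv(venn, o("dhss_venn.tsv"),
            paste0("DHSS cluster differential status; z_cutoff=", dhss$z_cutoff))
  induced_dhss <- cl[cl$status == "vpa_induced", , drop = FALSE]
  noninduced_dhss <- cl[cl$status != "vpa_induced", , drop = FALSE]

  ## CAGE TSS clusters
  genes <- read_bed12(paths$genes)
  cage_veh <- read_cage_bed(paths$cage_veh, "Veh")
  cage_vpa <- read_cage_bed(paths$cage_vpa, "VPA")
  cage_all <- rbind(cage_veh, cage_vpa)
  tss <- cluster_cage(cage_all, nrow(cage_veh), nrow(cage_vpa))
  tss <- filter_tpm(tss, min_tpm)
  tss <- classify_tss(tss, nrow(cage_veh), nrow(cage_vpa), alpha)
  writeLines(paste(tss$chrom, tss$start, tss$end, tss$status, 0, tss$strand,
                   tss$count_veh, tss$count_vpa,
                   signif(tss$tpm_veh, 6), signif(tss$tpm_vpa, 6),
                   signif(tss$q_up, 6), signif(tss$q_down, 6), sep = "\t"),
             o("tss_clusters.bed"))

  ## promoter overlap of TSS clusters
  prom_ov <- promoter_overlap(tss, genes)
  write_tsv(prom_ov$by_status, o("tss_promoter_overlap.tsv"),
            paste0("one-tailed Fisher induced vs rest p=",
                   signif(prom_ov$p_induced_vs_rest, 6)))

  ## exon-1 tag ratios
  ratios <- exon1_ratio(genes, cage_all)
  rv <- ratios$ratio[ratios$condition == "Veh"]
  rp <- ratios$ratio[ratios$condition == "VPA"]
  p_ex1 <- if (length(rv) >= 2 && length(rp) >= 2) welch_t_two_tailed(rp, rv) else NA
  write_tsv(ratios, o("exon1_ratios.tsv"),
            paste0("two-tailed Welch t (VPA vs Veh ratios) p=", signif(p_ex1, 6)))

  ## distance bins TSS -> DHSS
  bin_rows <- list()
  for (qname in c("induced_tss", "non_induced_tss")) {
    q <- if (qname == "induced_tss") tss[tss$status == "induced", , drop = FALSE]
         else tss[tss$status != "induced", , drop = FALSE]
    for (tname in c("induced_dhss", "non_induced_dhss")) {
      tgt <- if (tname == "induced_dhss") induced_dhss else noninduced_dhss
      if (nrow(q) == 0 || nrow(tgt) == 0) next
      b <- distance_bins(q, tgt)
      bin_rows[[paste(qname, tname)]] <- data.frame(
        query = qname, target = tname, proximal = b$proximal,
        semi_distal = b$semi_distal, distal = b$distal,
        no_target = b$no_target)
    }
  }
  write_tsv(do.call(rbind, bin_rows), o("distance_bins.tsv"),
            "bins: proximal < 1 kb, semi-distal 1 kb - 1 Mb, distal > 1 Mb")

  ## repeat assignment and SINE genomic distribution
  repeats <- read_repeats(paths$repeats)
  asg <- assign_repeat(cl, repeats)
  sine_any <- any_overlap_class(cl, repeats, "SINE")
  grp <- ifelse(cl$status == "vpa_induced", "induced", "non_induced")
  rep_rows <- list()
  for (g in unique(grp)) {
    tab <- table(factor(asg$repeat_class[grp == g],
                        levels = c("SINE", "LINE", "LTR", "DNA", "Other")),
                 useNA = "no")
    for (k in names(tab)) {
      rep_rows[[paste(g, k)]] <- data.frame(analysis = "longest_overlap",
                                            group = g, key = k,
                                            value = as.integer(tab[[k]]))
    }
    rep_rows[[paste(g, "none")]] <- data.frame(
      analysis = "longest_overlap", group = g, key = "none",
      value = sum(is.na(asg$repeat_class[grp == g])))
    rep_rows[[paste(g, "any_sine")]] <- data.frame(
      analysis = "any_overlap", group = g, key = "SINE",
      value = sum(sine_any[grp == g]))
  }
  cat_groups <- list(
    sine_dhss_induced = cl[grp == "induced" & sine_any, , drop = FALSE],
    sine_dhss_non_induced = cl[grp == "non_induced" & sine_any, , drop = FALSE],
    all_sines = repeats[repeats$repeat_class == "SINE", , drop = FALSE])
  for (g in names(cat_groups)) {
    if (nrow(cat_groups[[g]]) == 0) next
    cats <- table(factor(genomic_category(cat_groups[[g]], genes),
                         levels = c("promoter", "gene_body", "intergenic")))
    for (k in names(cats)) {
      rep_rows[[paste(g, k)]] <- data.frame(analysis = "sine_genomic_category",
                                            group = g, key = k,
                                            value = as.integer(cats[[k]]))
    }
  }
  write_tsv(do.call(rbind, rep_rows), o("repeat_assignment.tsv"))

  ## motif over-representation
  if (have_input(paths, "fasta") && have_input(paths, "motifs")) {
    genome <- Biostrings::readDNAStringSet(paths$fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    motifs <- lapply(read_jaspar(paths$motifs), pfm_to_pwm,
                     threshold_rel = motif_threshold)
    a <- cl[grp == "induced" & sine_any, , drop = FALSE]
    b <- cl[!(grp == "induced" & sine_any), , drop = FALSE]
    if (nrow(a) && nrow(b)) {
      cmp <- compare_groups(a, b, genome, motifs)
      write_tsv(cmp$summary, o("motif_comparison.tsv"),
                c(paste0("group A: induced SINE-overlapping DHSS (n=", nrow(a), ")"),
                  paste0("group B: all other DHSS (n=", nrow(b), ")")))
    } else {
      warning("motif comparison skipped: empty region group")
      note("WARN motif comparison skipped (empty group)")
    }
  } else {
    warning("motif comparison skipped: missing FASTA or motif input")
    note("WARN motif comparison skipped (missing input)")
  }

  ## enhancer and Foxa2 overlap tests
  test_rows <- list()
  if (have_input(paths, "enhancers")) {
    enh <- read_bed(paths$enhancers)
    for (g in c("all", "induced", "non_induced")) {
      q <- switch(g, all = cl, induced = induced_dhss,
                  non_induced = noninduced_dhss)
      if (nrow(q) == 0) next
      eb <- enhancer_binomial(q, enh, sizes)
      test_rows[[paste0("enh_", g)]] <- data.frame(
        test = "enhancer_binomial", group = g,
        statistic = eb$k / eb$n, p = eb$p)
    }
    if (nrow(cl)) {
      ks <- distance_ks_vs_random(cl, enh, sizes, n_random, seed)
      test_rows$enh_ks <- data.frame(test = "enhancer_distance_ks",
                                     group = "all", statistic = ks$D, p = ks$p)
    }
  } else {
    warning("enhancer tests skipped: no enhancer input")
    note("WARN enhancer tests skipped")
  }
  if (have_input(paths, "foxa2")) {
    foxa2 <- read_bed(paths$foxa2)
    a <- cl[grp == "induced" & sine_any, , drop = FALSE]
    sines <- repeats[repeats$repeat_class == "SINE", , drop = FALSE]
    if (nrow(a) && nrow(sines)) {
      fo <- overlap_fisher(sum(overlaps_any(a, foxa2)), nrow(a),
                           sum(overlaps_any(sines, foxa2)), nrow(sines))
      test_rows$foxa2 <- data.frame(test = "foxa2_overlap_fisher",
                                    group = "induced_sine_dhss_vs_all_sines",
                                    statistic = fo$odds_ratio, p = fo$p)
    }
  } else {
    warning("Foxa2 overlap test skipped: no Foxa2 input")
    note("WARN Foxa2 test skipped")
  }
  tests <- if (length(test_rows)) do.call(rbind, test_rows) else
    data.frame(test = character(), group = character(),
               statistic = numeric(), p = numeric())
  write_tsv(tests, o("overlap_tests.tsv"))

  ## DHSS profile around TSSs
  prof_veh <- tss_profile(veh, genes, flank)
  prof_vpa <- tss_profile(vpa, genes, flank)
  write_tsv(data.frame(bin_offset = prof_veh$bin_offsets,
                       mean_tpm_veh = prof_veh$mean_tpm,
                       mean_tpm_vpa = prof_vpa$mean_tpm),
            o("tss_profile.tsv"),
            paste0("promoters retained: veh=", prof_veh$n_promoters_retained,
                   " vpa=", prof_vpa$n_promoters_retained))

  ## qPCR validation statistics
  if (have_input(paths, "qpcr")) {
    qp <- qpcr_stats(read_qpcr(paths$qpcr), "Veh", "VPA")
    write_tsv(qp, o("qpcr_stats.tsv"))
  } else {
    warning("qPCR table skipped: no qPCR input")
    note("WARN qPCR skipped")
  }

  writeLines(log_lines, o("run_log.txt"))
  invisible(list(dhss = dhss, clusters = cl, tss = tss,
                 tables = list.files(out_dir, full.names = TRUE)))
}
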