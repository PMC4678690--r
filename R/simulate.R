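#' Configuration of the synthetic study
#'
#' Defines the toy genome and the planted structure emulating the downstream
#' form of paired DNase-hypersensitivity and CAGE tag libraries from a
#' vehicle and a VPA condition: locally enriched accessible regions (a
#' subset further enriched in VPA only), promoter-concentrated CAGE tags
#' with sharp/broad shapes and condition-specific fold changes, a
#' RepeatMasker-like repeat annotation with motif instances embedded in a
#' fraction of SINEs, intergenic enhancers, and a partial mappability track.
#'
#' @param seed master seed; every generator derives its stream from it.
#' @param n_chroms,chrom_len genome shape (default 3 x 2 Mb).
#' @param n_genes number of gene models (default 120).
#' @param n_repeats repeat count (default 3000) with `repeat_mix` class
#'   proportions.
#' @param repeat_mix named class proportions (SINE/LINE/LTR/DNA).
#' @param motif_fraction_sine fraction of SINEs carrying an embedded motif
#'   consensus (default 0.3).
#' @param motif_consensus consensus written into motif-carrying SINEs.
#' @param n_dhss_regions planted accessible regions (default 300) of width
#'   `region_width`.
#' @param induced_fraction fraction of planted regions with additional
#'   VPA-only enrichment (default 0.25).
#' @param base_rate background tags per kb per library (default 5).
#' @param region_fold accessibility fold over background in planted regions,
#'   both conditions (default 10).
#' @param induced_extra_fold additional VPA-only fold in induced regions
#'   (default 5).
#' @param n_tags_dhss,n_tags_cage per-library expected tag totals.
#' @param cage_up_fraction,cage_down_fraction fractions of promoters up- or
#'   down-regulated in VPA (default 0.1 each).
#' @param cage_fold promoter fold change (default 8).
#' @param mappable_fraction fraction of the genome uniquely mappable
#'   (default 0.9), modeled as 100-bp blocks dropped independently.
#' @param n_enhancers intergenic enhancer regions (default 150).
#' @param region_width planted region width in bases (default 500).
#' @param tag_len CAGE tag span (default 21).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_len = 2000000L,
                       n_genes = 120L, n_repeats = 3000L,
                       repeat_mix = c(SINE = 0.55, LINE = 0.25, LTR = 0.15, DNA = 0.05),
                       motif_fraction_sine = 0.3,
                       motif_consensus = "TGTTTACTTA",
                       n_dhss_regions = 300L, induced_fraction = 0.25,
                       base_rate = 5, region_fold = 10, induced_extra_fold = 5,
                       n_tags_dhss = 200000L, n_tags_cage = 100000L,
                       cage_up_fraction = 0.1, cage_down_fraction = 0.1,
                       cage_fold = 8, mappable_fraction = 0.9,
                       n_enhancers = 150L, region_width = 500L,
                       tag_len = 21L) {
  cfg <- list(seed = as.integer(seed) %% 2147483000L, n_chroms = n_chroms,
              chrom_len = chrom_len, n_genes = n_genes, n_repeats = n_repeats,
              repeat_mix = repeat_mix,
              motif_fraction_sine = motif_fraction_sine,
              motif_consensus = motif_consensus,
              n_dhss_regions = n_dhss_regions,
              induced_fraction = induced_fraction, base_rate = base_rate,
              region_fold = region_fold,
              induced_extra_fold = induced_extra_fold,
              n_tags_dhss = n_tags_dhss, n_tags_cage = n_tags_cage,
              cage_up_fraction = cage_up_fraction,
              cage_down_fraction = cage_down_fraction,
              cage_fold = cage_fold, mappable_fraction = mappable_fraction,
              n_enhancers = n_enhancers, region_width = region_width,
              tag_len = tag_len)
  fr <- c(cfg$motif_fraction_sine, cfg$induced_fraction, cfg$cage_up_fraction,
          cfg$cage_down_fraction, cfg$mappable_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$cage_up_fraction + cfg$cage_down_fraction <= 1,
            cfg$n_tags_dhss > 0, cfg$n_tags_cage > 0, cfg$chrom_len > 0,
            abs(sum(cfg$repeat_mix) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

sim_chrom_sizes <- function(config) {
  stats::setNames(rep(config$chrom_len, config$n_chroms),
                  paste0("chr", seq_len(config$n_chroms)))
}

#' Generate the synthetic genome
#'
#' I.i.d. uniform ACGT sequence plus a mappability track built by dropping
#' 100-bp blocks independently at rate `1 - mappable_fraction`. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @param sequence generate the actual sequence? (`FALSE` skips it for runs
#'   that only need coordinates, e.g. caller calibration studies.)
#' @return list with `seqs` (named character or `NULL`), `chrom_sizes`,
#'   `mappability` (merged interval `data.frame`).
#' @export
make_genome <- function(config, sequence = TRUE) {
  sizes <- sim_chrom_sizes(config)
  block <- 100L
  withr::with_seed(config$seed, {
    seqs <- NULL
    if (sequence) {
      seqs <- vapply(names(sizes), function(ch) {
        paste(sample(c("A", "C", "G", "T"), sizes[[ch]], replace = TRUE),
              collapse = "")
      }, "")
    }
    map <- list()
    for (ch in names(sizes)) {
      n_blocks <- ceiling(sizes[[ch]] / block)
      keep <- stats::runif(n_blocks) < config$mappable_fraction
      r <- rle(keep)
      ends_b <- cumsum(r$lengths)
      starts_b <- ends_b - r$lengths
      sel <- r$values
      if (!any(sel)) next
      map[[ch]] <- gintervals(ch, starts_b[sel] * block,
                              pmin(ends_b[sel] * block, sizes[[ch]]))
    }
  })
  mappability <- if (length(map)) do.call(rbind, map) else empty_intervals()
  rownames(mappability) <- NULL
  list(seqs = seqs, chrom_sizes = sizes, mappability = mappability)
}

# Greedy non-overlapping placement of n intervals with given widths.
# `occupied` intervals are avoided too. Errors after bounded retries.
place_nonoverlapping <- function(n, widths, chrom_sizes, occupied = NULL,
                                 max_tries = 50L) {
  placed <- if (is.null(occupied)) empty_intervals() else occupied[c("chrom", "start", "end", "strand")]
  out <- empty_intervals()
  need <- n
  tries <- 0L
  probs <- chrom_sizes / sum(chrom_sizes)
  while (need > 0) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " non-overlapping regions; reduce counts or widths")
    }
    w <- rep_len(widths, need)
    ch <- sample(names(chrom_sizes), need, replace = TRUE, prob = probs)
    start <- floor(stats::runif(need) * (chrom_sizes[ch] - w))
    cand <- gintervals(ch, start, start + w)
    ok <- !overlaps_any(cand, placed)
    # also reject candidates overlapping each other within the batch
    if (any(ok)) {
      cand_ok <- cand[ok, , drop = FALSE]
      mg <- merge_with_groups(cand_ok)
      keep_first <- !duplicated(mg$group)
      cand_ok <- cand_ok[keep_first, , drop = FALSE]
      out <- rbind(out, cand_ok)
      placed <- rbind(placed, cand_ok)
      need <- n - nrow(out)
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate gene models, repeats, enhancers and the truth ledger
#'
#' Places non-overlapping gene models (3-8 exons, ~90% coding), repeats with
#' the configured class mix, intergenic enhancers and the planted accessible
#' regions; embeds the motif consensus into a fraction of SINEs (when the
#' genome carries sequence); assigns sharp/broad promoter shapes and samples
#' the up-/down-regulated promoter sets. Everything is recorded in the
#' returned truth ledger.
#'
#' @param config a [sim_config()].
#' @param genome result of [make_genome()].
#' @return list with `genes`, `repeats`, `enhancers`, `truth`, and the
#'   (possibly motif-edited) `genome`.
#' @export
make_annotation <- function(config, genome) {
  sizes <- genome$chrom_sizes
  withr::with_seed(config$seed + 1L, {
    ## gene models
    gene_len <- sample(3000:20000, config$n_genes, replace = TRUE)
    genes <- place_nonoverlapping(config$n_genes, gene_len, sizes)
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$name <- sprintf("gene%03d", seq_len(nrow(genes)))
    exon_starts <- vector("list", nrow(genes))
    exon_ends <- vector("list", nrow(genes))
    thick_start <- integer(nrow(genes))
    thick_end <- integer(nrow(genes))
    coding <- stats::runif(nrow(genes)) < 0.9
    for (i in seq_len(nrow(genes))) {
      len <- genes$end[i] - genes$start[i]
      k <- sample(3:8, 1)
      cuts <- sort(sample(seq(150L, len - 150L, by = 50L), 2L * (k - 1L)))
      bnd <- c(0L, cuts, len)
      es <- genes$start[i] + bnd[seq(1, length(bnd) - 1, by = 2)]
      ee <- genes$start[i] + bnd[seq(2, length(bnd), by = 2)]
      exon_starts[[i]] <- es
      exon_ends[[i]] <- ee
      if (coding[i]) {
        if (genes$strand[i] == "-") {
          thick_start[i] <- es[1] + 30L
          thick_end[i] <- ee[length(ee)] - 30L
        } else {
          thick_start[i] <- es[1] + 30L
          thick_end[i] <- ee[length(ee)] - 30L
        }
      } else {
        thick_start[i] <- genes$start[i]
        thick_end[i] <- genes$start[i]
      }
    }
    genes$thick_start <- thick_start
    genes$thick_end <- thick_end
    genes$cds_start <- ifelse(coding,
                              ifelse(genes$strand == "-", thick_end - 1L, thick_start),
                              NA_integer_)
    genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
    genes$exon_starts <- I(exon_starts)
    genes$exon_ends <- I(exon_ends)
    genes$shape <- sample(c("sharp", "broad"), nrow(genes), replace = TRUE)

    ## repeats: uniform, may overlap anything
    cls <- sample(names(config$repeat_mix), config$n_repeats, replace = TRUE,
                  prob = config$repeat_mix)
    width <- c(SINE = 150L, LINE = 600L, LTR = 400L, DNA = 300L)[cls] +
      sample(-30:30, config$n_repeats, replace = TRUE)
    ch <- sample(names(sizes), config$n_repeats, replace = TRUE,
                 prob = sizes / sum(sizes))
    start <- floor(stats::runif(config$n_repeats) * (sizes[ch] - width))
    repeats <- gintervals(ch, start, start + width)
    repeats$name <- sprintf("%s%04d", cls, seq_len(config$n_repeats))
    repeats$repeat_class <- cls
    repeats$family <- ifelse(cls == "SINE",
                             sample(c("B1", "B2"), config$n_repeats, replace = TRUE,
                                    prob = c(0.7, 0.3)),
                             paste0(cls, "1"))
    repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL

    ## intergenic enhancers
    enhancers <- place_nonoverlapping(config$n_enhancers, 300L, sizes,
                                      occupied = genes)

    ## planted accessible regions
    planted <- if (config$n_dhss_regions > 0) {
      place_nonoverlapping(config$n_dhss_regions, config$region_width, sizes)
    } else empty_intervals()
    planted$label <- rep("shared", nrow(planted))
    if (nrow(planted)) {
      n_ind <- round(config$induced_fraction * nrow(planted))
      planted$label[sample(nrow(planted), n_ind)] <- "vpa_induced"
    }

    ## motif embedding into SINEs
    sine_idx <- which(repeats$repeat_class == "SINE")
    n_motif <- round(config$motif_fraction_sine * length(sine_idx))
    motif_sines <- sort(sample(sine_idx, n_motif))
    if (!is.null(genome$seqs) && length(motif_sines)) {
      cons <- config$motif_consensus
      for (i in motif_sines) {
        w <- repeats$end[i] - repeats$start[i]
        off <- sample.int(w - nchar(cons) - 1L, 1)
        at <- repeats$start[i] + off
        substr(genome$seqs[[repeats$chrom[i]]], at + 1L,
               at + nchar(cons)) <- cons
      }
    }

    ## condition-specific promoter sets
    n_up <- round(config$cage_up_fraction * nrow(genes))
    n_down <- round(config$cage_down_fraction * nrow(genes))
    reg <- sample(nrow(genes), n_up + n_down)
    up <- genes$name[reg[seq_len(n_up)]]
    down <- genes$name[reg[n_up + seq_len(n_down)]]
  })
  truth <- list(planted_regions = planted,
                up_promoters = up, down_promoters = down,
                motif_sines = repeats[motif_sines, , drop = FALSE],
                enhancers = enhancers)
  list(genes = genes, repeats = repeats, enhancers = enhancers,
       truth = truth, genome = genome)
}

# Uniform positions over the coverage of a disjoint interval set.
sample_covered_positions <- function(intervals, k) {
  if (k == 0 || nrow(intervals) == 0) return(integer(0))
  w <- intervals$end - intervals$start
  cum <- cumsum(w)
  u <- sample.int(cum[length(cum)], k, replace = TRUE)
  j <- findInterval(u - 1L, cum) + 1L
  intervals$start[j] + (u - (cum[j] - w[j])) - 1L
}

intersect_intervals <- function(a, b) {
  pairs <- overlap_pairs(a, b)
  if (!nrow(pairs)) return(empty_intervals())
  gintervals(a$chrom[pairs$a_idx],
             pmax(a$start[pairs$a_idx], b$start[pairs$b_idx]),
             pmin(a$end[pairs$a_idx], b$end[pairs$b_idx]))
}

#' Simulate the two DHSS tag libraries
#'
#' Tag 5'-end positions are drawn from a piecewise-constant intensity:
#' background `base_rate` per kb everywhere mappable, `region_fold` times
#' that inside planted regions (both conditions), and an additional
#' `induced_extra_fold` inside induced regions in the VPA library only.
#' Unmappable positions never emit tags. Library totals are Poisson around
#' `n_tags_dhss`.
#'
#' @param config a [sim_config()].
#' @param truth truth ledger from [make_annotation()].
#' @param mappability merged mappability track.
#' @return list with `veh` and `vpa` [tag_library()]s.
#' @export
simulate_dhss <- function(config, truth, mappability) {
  planted <- truth$planted_regions
  # mappable sub-intervals of each planted region
  region_maps <- lapply(seq_len(nrow(planted)), function(i) {
    intersect_intervals(mappability, planted[i, , drop = FALSE])
  })
  map_by_chrom <- split(mappability, mappability$chrom)
  bg_w <- vapply(map_by_chrom, function(m) sum(m$end - m$start), 0)
  region_mw <- vapply(region_maps, function(m) {
    if (nrow(m)) sum(m$end - m$start) else 0
  }, 0)
  libs <- withr::with_seed(config$seed + 2L, {
    lapply(c(veh = "Veh", vpa = "VPA"), function(cond) {
      fold <- rep(config$region_fold, nrow(planted))
      if (cond == "VPA" && nrow(planted)) {
        fold[planted$label == "vpa_induced"] <-
          config$region_fold * config$induced_extra_fold
      }
      w <- c(bg_w, region_mw * (fold - 1))
      n_lib <- stats::rpois(1, config$n_tags_dhss)
      counts <- as.integer(stats::rmultinom(1, n_lib, w))
      pos <- vector("list", length(w))
      chrom <- vector("list", length(w))
      for (i in seq_along(bg_w)) {
        pos[[i]] <- sample_covered_positions(map_by_chrom[[i]], counts[i])
        chrom[[i]] <- rep(names(bg_w)[i], counts[i])
      }
      for (r in seq_along(region_mw)) {
        i <- length(bg_w) + r
        pos[[i]] <- sample_covered_positions(region_maps[[r]], counts[i])
        chrom[[i]] <- rep(planted$chrom[r], counts[i])
      }
      tag_library(split(unlist(pos), unlist(chrom)), cond)
    })
  })
  libs
}

#' Simulate the two CAGE tag libraries
#'
#' 90% of each library's tags land at promoters -- 5' ends Normal(TSS, 20 bp)
#' for sharp promoters, Uniform(TSS +/- 150) for broad -- and 10% are
#' uniform background. Up-regulated promoters receive `cage_fold` more VPA
#' tags; down-regulated promoters the symmetric vehicle excess. Tags span
#' `tag_len` bases on the gene strand.
#'
#' @param config a [sim_config()].
#' @param truth truth ledger.
#' @param genes gene table from [make_annotation()].
#' @return list with `veh` and `vpa` stranded tag `data.frame`s (CAGE
#'   format) and the library totals `n_veh`, `n_vpa`.
#' @export
simulate_cage <- function(config, truth, genes) {
  sizes <- sim_chrom_sizes(config)
  tlen <- config$tag_len
  res <- withr::with_seed(config$seed + 3L, {
    lapply(c(veh = "Veh", vpa = "VPA"), function(cond) {
      w <- rep(1, nrow(genes))
      if (cond == "VPA") {
        w[genes$name %in% truth$up_promoters] <- config$cage_fold
      } else {
        w[genes$name %in% truth$down_promoters] <- config$cage_fold
      }
      n_lib <- stats::rpois(1, config$n_tags_cage)
      k_prom <- stats::rbinom(1, n_lib, 0.9)
      counts <- as.integer(stats::rmultinom(1, k_prom, w))
      chrom <- character(0); p5 <- integer(0); strand <- character(0)
      for (i in seq_len(nrow(genes))) {
        if (counts[i] == 0) next
        tss <- genes$tss[i]
        p <- if (genes$shape[i] == "sharp") {
          as.integer(round(stats::rnorm(counts[i], tss, 20)))
        } else {
          tss + sample(-150:150, counts[i], replace = TRUE)
        }
        chrom <- c(chrom, rep(genes$chrom[i], counts[i]))
        p5 <- c(p5, p)
        strand <- c(strand, rep(genes$strand[i], counts[i]))
      }
      n_bg <- n_lib - k_prom
      bg_ch <- sample(names(sizes), n_bg, replace = TRUE,
                      prob = sizes / sum(sizes))
      bg_p <- floor(stats::runif(n_bg) * sizes[bg_ch])
      chrom <- c(chrom, bg_ch)
      p5 <- c(p5, as.integer(bg_p))
      strand <- c(strand, sample(c("+", "-"), n_bg, replace = TRUE))
      # clamp 5' ends so full tag spans fit the chromosome
      p5 <- pmax(pmin(p5, sizes[chrom] - tlen), tlen - 1L)
      start <- ifelse(strand == "-", p5 - tlen + 1L, p5)
      tags <- gintervals(chrom, start, start + tlen, strand)
      tags$condition <- cond
      tags
    })
  })
  list(veh = res$veh, vpa = res$vpa,
       n_veh = nrow(res$veh), n_vpa = nrow(res$vpa))
}

write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$name[i], 0,
          genes$strand[i], genes$thick_start[i], genes$thick_end[i], "0",
          length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

write_repeats <- function(repeats, path) {
  writeLines(c("chrom\tstart\tend\tname\trepeat_class\tfamily",
               paste(repeats$chrom, repeats$start, repeats$end, repeats$name,
                     repeats$repeat_class, repeats$family, sep = "\t")),
             path)
  invisible(path)
}

write_tag_bed <- function(lib, path) {
  chrom <- rep(names(lib$positions), lengths(lib$positions))
  pos <- unlist(lib$positions, use.names = FALSE)
  if (!length(pos)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(paste(chrom, pos, pos + 1L, sep = "\t"), path)
  invisible(path)
}

# Synthetic transcription-factor binding peaks: most motif-carrying SINEs
# get a peak over the embedded instance, plus unrelated background peaks,
# so overlap-enrichment analyses have a known positive signal.
synthetic_foxa2 <- function(config, truth) {
  sizes <- sim_chrom_sizes(config)
  withr::with_seed(config$seed + 5L, {
    ms <- truth$motif_sines
    sel <- if (nrow(ms)) sort(sample(nrow(ms), round(0.6 * nrow(ms)))) else integer()
    peaks <- if (length(sel)) {
      gintervals(ms$chrom[sel], pmax(0L, ms$start[sel] - 50L),
                 ms$end[sel] + 50L)
    } else empty_intervals()
    n_bg <- 100L
    ch <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes / sum(sizes))
    start <- floor(stats::runif(n_bg) * (sizes[ch] - 200L))
    peaks <- rbind(peaks, gintervals(ch, start, start + 200L))
  })
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

synthetic_qpcr <- function(config) {
  withr::with_seed(config$seed + 4L, {
    cats <- c(induced_dhss = 3.0, tss_proximal = 2.5, random = 0.8)
    rows <- list()
    for (cat in names(cats)) {
      for (cond in c("Veh", "VPA")) {
        shift <- if (cond == "VPA") cats[[cat]] else cats[[cat]] * 0.4
        undig <- stats::rnorm(8, 20, 0.2)
        dig <- undig + stats::rnorm(8, shift, 0.3)
        rows[[paste(cat, cond)]] <- data.frame(
          primer_id = sprintf("%s:p%02d", cat, 1:8),
          condition = cond,
          ct_digested = round(dig, 3),
          ct_undigested = round(undig, 3))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate and write the full synthetic input bundle
#'
#' Runs the genome, annotation, DHSS and CAGE generators and writes every
#' file the pipeline consumes: `genome.fa`, `chrom.sizes`,
#' `mappability.bed`, `dhss_veh.bed`/`dhss_vpa.bed` (tag 5' ends),
#' `cage_veh.bed`/`cage_vpa.bed`, `genes.bed12`, `repeats.tsv`,
#' `enhancers.bed`, `motifs.jaspar` (the package's synthetic forkhead-like
#' fixtures), `qpcr.tsv` (synthetic), and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(config, sequence = TRUE)
  ann <- make_annotation(config, genome)
  genome <- ann$genome
  dhss <- simulate_dhss(config, ann$truth, genome$mappability)
  cage <- simulate_cage(config, ann$truth, ann$genes)

  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), p("genome.fa"))
  writeLines(paste(names(genome$chrom_sizes), genome$chrom_sizes, sep = "\t"),
             p("chrom.sizes"))
  write_bed(genome$mappability, p("mappability.bed"))
  write_tag_bed(dhss$veh, p("dhss_veh.bed"))
  write_tag_bed(dhss$vpa, p("dhss_vpa.bed"))
  write_bed(cage$veh, p("cage_veh.bed"))
  write_bed(cage$vpa, p("cage_vpa.bed"))
  write_bed12(ann$genes, p("genes.bed12"))
  write_repeats(ann$repeats, p("repeats.tsv"))
  write_bed(ann$enhancers, p("enhancers.bed"))
  file.copy(system.file("extdata", "synthetic_forkhead.jaspar",
                        package = "dhssremodel"),
            p("motifs.jaspar"), overwrite = TRUE)
  write_bed(synthetic_foxa2(config, ann$truth), p("foxa2.bed"))
  qpcr <- synthetic_qpcr(config)
  utils::write.table(qpcr, p("qpcr.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_json <- list(
    planted_regions = ann$truth$planted_regions[c("chrom", "start", "end", "label")],
    up_promoters = ann$truth$up_promoters,
    down_promoters = ann$truth$down_promoters,
    motif_sines = ann$truth$motif_sines[c("chrom", "start", "end", "name")],
    enhancers = ann$truth$enhancers[c("chrom", "start", "end")]
  )
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(config = config, genome = genome, genes = ann$genes,
                 repeats = ann$repeats, enhancers = ann$enhancers,
                 truth = ann$truth, dhss = dhss, cage = cage, qpcr = qpcr,
                 dir = out_dir))
}
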