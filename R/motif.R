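#' Read JASPAR-format position frequency matrices
#'
#' Accepts both dialects: a `>ID NAME` header followed by four plain
#' whitespace-separated count rows, or rows labelled `A [ ... ]` etc.
#' Rows are taken in A, C, G, T order (labels win when present).
#'
#' @param path PFM text file, possibly with several matrices.
#' @return list of PFMs, each a list with `id`, `name`, `counts`
#'   (4 x W matrix, rownames ACGT).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- which(startsWith(lines, ">"))
  if (!length(headers)) stop("no JASPAR header ('>') lines found in ", path)
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4) {
      stop("JASPAR parse error: expected 4 count rows, got ", length(block))
    }
    hdr <- strsplit(sub("^>", "", lines[headers[i]]), "\\s+")[[1]]
    labelled <- grepl("^[ACGT]\\s*\\[", block)
    rows <- lapply(seq_along(block), function(j) {
      txt <- block[j]
      base <- if (labelled[j]) sub("^([ACGT]).*", "\\1", txt) else c("A", "C", "G", "T")[j]
      nums <- as.numeric(strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]$", "", txt)),
                                  "\\s+")[[1]])
      if (anyNA(nums)) stop("JASPAR parse error: non-numeric counts in row '", txt, "'")
      list(base = base, counts = nums)
    })
    w <- lengths(lapply(rows, `[[`, "counts"))
    if (length(unique(w)) != 1) stop("JASPAR parse error: row length mismatch")
    counts <- matrix(0, 4, w[1], dimnames = list(c("A", "C", "G", "T"), NULL))
    for (r in rows) counts[r$base, ] <- r$counts
    if (any(colSums(counts) <= 0)) stop("JASPAR parse error: empty matrix column")
    out[[i]] <- list(id = hdr[1],
                     name = if (length(hdr) > 1) hdr[2] else hdr[1],
                     counts = counts)
  }
  out
}

#' Convert a PFM to a log-odds scoring matrix
#'
#' Column probabilities use a background-split pseudocount,
#' `p = (count + pseudocount * bg) / (colsum + pseudocount)`, and weights are
#' `log2(p / bg)`. Score bounds are the summed per-column extremes; the
#' relative score `(score - min) / (max - min)` is the "% similarity" scale
#' thresholded at `threshold_rel`.
#'
#' @param pfm one element of [read_jaspar()].
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background base composition (default uniform).
#' @param threshold_rel relative-score cutoff stored on the motif
#'   (default 0.8).
#' @return list of class `scored_motif` with `id`, `name`, `weights`,
#'   `min_score`, `max_score`, `threshold_rel`, `width`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4),
                       threshold_rel = 0.8) {
  counts <- pfm$counts
  stopifnot(nrow(counts) == 4, threshold_rel >= 0, threshold_rel <= 1)
  background <- background / sum(background)
  p <- sweep(counts + pseudocount * background, 2,
             colSums(counts) + pseudocount, "/")
  w <- log2(p / background)
  structure(list(id = pfm$id, name = pfm$name, weights = w,
                 min_score = sum(apply(w, 2, min)),
                 max_score = sum(apply(w, 2, max)),
                 threshold_rel = threshold_rel,
                 width = ncol(w)),
            class = "scored_motif")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Relative scores of every window of motif width on one strand of `seq`
# (character). Windows containing non-ACGT letters score NA.
scan_scores <- function(seq, motif) {
  w <- motif$width
  L <- nchar(seq)
  if (L < w) return(numeric(0))
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))
  nwin <- L - w + 1L
  s <- numeric(nwin)
  bad <- logical(nwin)
  for (j in seq_len(w)) {
    cj <- code[j:(nwin + j - 1L)]
    bad <- bad | is.na(cj)
    s <- s + ifelse(is.na(cj), 0, motif$weights[cbind(cj, j)])
  }
  rel <- (s - motif$min_score) / (motif$max_score - motif$min_score)
  rel[bad] <- NA_real_
  rel
}

#' Scan a sequence for motif matches on both strands
#'
#' Every window of motif width on both strands is scored; windows containing
#' `N` are skipped; hits at or above the motif's relative-score threshold are
#' returned. Positions are 0-based offsets of the match window on the
#' forward sequence.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param motif a [pfm_to_pwm()] result.
#' @param threshold_rel optional override of the motif's stored threshold.
#' @return `data.frame` with `position`, `strand`, `rel_score`.
#' @export
scan_region <- function(sequence, motif, threshold_rel = NULL) {
  if (motif$max_score <= motif$min_score) {
    stop("degenerate motif: max score equals min score")
  }
  thr <- if (is.null(threshold_rel)) motif$threshold_rel else threshold_rel
  fwd <- scan_scores(sequence, motif)
  rev_ <- scan_scores(revcomp(sequence), motif)
  L <- nchar(sequence)
  hits_f <- which(!is.na(fwd) & fwd >= thr)
  hits_r <- which(!is.na(rev_) & rev_ >= thr)
  out <- data.frame(
    position = c(hits_f - 1L, L - motif$width - (hits_r - 1L)),
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    rel_score = c(fwd[hits_f], rev_[hits_r])
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Extract region sequences from a genome
#'
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @param regions interval `data.frame`.
#' @return character vector of region sequences.
#' @export
region_sequences <- function(genome, regions) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    if (!ch %in% names(genome)) stop("region outside FASTA bounds: ", ch)
    if (regions$end[i] > nchar(genome[[ch]])) {
      stop(sprintf("region outside FASTA bounds: %s:%d-%d",
                   ch, regions$start[i], regions$end[i]))
    }
    out[i] <- substr(genome[[ch]], regions$start[i] + 1L, regions$end[i])
  }
  out
}

#' Motif over-representation between two region groups
#'
#' Per region, the number of motif hits at the relative-score threshold;
#' per motif, a one-tailed Wilcoxon rank-sum test that group A regions
#' carry more matches than group B.
#'
#' @param regions_a,regions_b interval `data.frame`s (e.g. induced
#'   SINE-overlapping DHSS vs all other DHSS).
#' @param genome named character vector / `DNAStringSet`.
#' @param motifs list of [pfm_to_pwm()] motifs.
#' @return list with `summary` `data.frame` (motif, mean counts, p) and the
#'   per-region `counts_a`, `counts_b` matrices (regions x motifs).
#' @export
compare_groups <- function(regions_a, regions_b, genome, motifs) {
  seq_a <- region_sequences(genome, regions_a)
  seq_b <- region_sequences(genome, regions_b)
  count_hits <- function(seqs, motif) {
    vapply(seqs, function(s) nrow(scan_region(s, motif)), 0L, USE.NAMES = FALSE)
  }
  ids <- vapply(motifs, `[[`, "", "id")
  counts_a <- sapply(motifs, function(m) count_hits(seq_a, m))
  counts_b <- sapply(motifs, function(m) count_hits(seq_b, m))
  counts_a <- matrix(counts_a, nrow = length(seq_a), dimnames = list(NULL, ids))
  counts_b <- matrix(counts_b, nrow = length(seq_b), dimnames = list(NULL, ids))
  summary <- data.frame(
    motif_id = ids,
    name = vapply(motifs, `[[`, "", "name"),
    mean_hits_a = colMeans(counts_a),
    mean_hits_b = colMeans(counts_b),
    p_wilcoxon = vapply(seq_along(motifs), function(j) {
      wilcoxon_greater(counts_a[, j], counts_b[, j])
    }, 0)
  )
  rownames(summary) <- NULL
  list(summary = summary, counts_a = counts_a, counts_b = counts_b)
}
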