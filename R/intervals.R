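#' Construct a table of genomic intervals
#'
#' The universal coordinate carrier of the package: a plain `data.frame` with
#' columns `chrom`, `start`, `end`, `strand`, using 0-based half-open
#' coordinates (BED convention) throughout. `strand` is one of `"+"`, `"-"`
#' or `"."` (unstranded).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions; must satisfy
#'   `start < end`.
#' @param strand strand characters, recycled; default unstranded.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
gintervals <- function(chrom = character(), start = integer(),
                       end = integer(), strand = ".") {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) stop("interval coordinates must not be NA")
  if (any(df$chrom == "" | is.na(df$chrom))) stop("chromosome names must be non-empty")
  if (any(df$start < 0)) stop("interval start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("invalid interval at row %d: start (%d) >= end (%d)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

empty_intervals <- function() {
  gintervals(character(), integer(), integer())
}

#' Read a BED file into an interval table
#'
#' Parses BED3/BED6 (and wider; extra columns ignored beyond name/score/strand)
#' into the package's 0-based half-open interval `data.frame`. Chromosome
#' names are matched verbatim downstream -- no "chr" prefix normalization is
#' applied.
#'
#' @param path path to an existing BED file.
#' @param stranded if `TRUE`, require and keep column 6 as the strand;
#'   otherwise intervals are loaded unstranded even if a strand column exists.
#' @return interval `data.frame` (with a `name` column when present in the
#'   file).
#' @export
read_bed <- function(path, stranded = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns", which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end or negative start", bad[1]))
  }
  strand <- rep(".", length(chrom))
  if (stranded) {
    if (any(nf < 6)) {
      stop(sprintf("BED parse error at line %d: strand requested but fewer than 6 columns",
                   which(nf < 6)[1]))
    }
    strand <- vapply(fields, `[[`, "", 6L)
    if (!all(strand %in% c("+", "-", "."))) {
      stop(sprintf("BED parse error at line %d: invalid strand",
                   which(!strand %in% c("+", "-", "."))[1]))
    }
  }
  df <- gintervals(chrom, start, end, strand)
  if (all(nf >= 4)) df$name <- vapply(fields, `[[`, "", 4L)
  df
}

#' Write an interval table as BED
#'
#' Emits BED3 for unstranded input and BED6 (name `.`, score 0 unless a
#' `name`/`score` column is present) whenever any interval carries a strand.
#' `read_bed(write_bed(x))` round-trips the coordinates exactly.
#'
#' @param intervals interval `data.frame`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  any_strand <- nrow(intervals) > 0 && any(intervals$strand != ".")
  if (any_strand || !is.null(intervals$name)) {
    name <- if (is.null(intervals$name)) "." else intervals$name
    score <- if (is.null(intervals$score)) 0L else intervals$score
    out <- paste(intervals$chrom, intervals$start, intervals$end,
                 name, score, intervals$strand, sep = "\t")
  } else {
    out <- paste(intervals$chrom, intervals$start, intervals$end, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file with chromosome name and length.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  if (any(tab$size <= 0)) stop("chromosome sizes must be positive")
  stats::setNames(tab$size, tab$chrom)
}

#' Overlap length of two intervals
#'
#' Number of shared bases between two 0-based half-open intervals; 0 when
#' they abut, are disjoint, or lie on different chromosomes. This is the
#' primitive behind the longest-overlap repeat assignment rule.
#'
#' @param a,b single-row interval `data.frame`s (or lists with `chrom`,
#'   `start`, `end`).
#' @return integer number of overlapping bases.
#' @export
overlap_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  max(0L, as.integer(min(a$end, b$end) - max(a$start, b$start)))
}

#' Merge overlapping intervals
#'
#' Collapses strictly overlapping intervals (shared bases; abutting half-open
#' intervals stay separate) into their union, per chromosome. Strand is
#' ignored; callers that need per-strand merging split beforehand.
#'
#' @param intervals interval `data.frame`.
#' @return sorted, non-overlapping interval `data.frame`.
#' @export
merge_intervals <- function(intervals) {
  merged <- merge_with_groups(intervals)
  merged$merged
}

# Merge overlapping intervals and report, for every input row, the index of
# the merged interval it belongs to. Workhorse for DHSS cluster merging and
# CAGE single-linkage clustering, where per-cluster aggregates are needed.
merge_with_groups <- function(intervals) {
  validate_intervals(intervals)
  n <- nrow(intervals)
  if (n == 0) {
    return(list(merged = empty_intervals(), group = integer()))
  }
  ord <- order(intervals$chrom, intervals$start, intervals$end)
  chrom <- intervals$chrom[ord]
  start <- intervals$start[ord]
  end <- intervals$end[ord]
  group <- integer(n)
  g <- 0L
  out_chrom <- character(0)
  out_start <- integer(0)
  out_end <- integer(0)
  cur_end <- -1L
  cur_chrom <- ""
  for (i in seq_len(n)) {
    if (chrom[i] != cur_chrom || start[i] >= cur_end) {
      g <- g + 1L
      out_chrom[g] <- chrom[i]
      out_start[g] <- start[i]
      out_end[g] <- end[i]
      cur_chrom <- chrom[i]
      cur_end <- end[i]
    } else {
      if (end[i] > cur_end) cur_end <- end[i]
      out_end[g] <- cur_end
    }
    group[ord[i]] <- g
  }
  list(merged = gintervals(out_chrom, out_start, out_end), group = group)
}

#' Distance to the nearest interval in a target set
#'
#' Gap in bases between each query and the closest target on the same
#' chromosome; 0 for overlapping or abutting pairs, `NA` when the query's
#' chromosome carries no target.
#'
#' @param queries interval `data.frame`.
#' @param targets interval `data.frame` (need not be disjoint).
#' @return integer vector of distances, one per query row.
#' @export
nearest_distance <- function(queries, targets) {
  validate_intervals(queries)
  validate_intervals(targets)
  res <- rep(NA_integer_, nrow(queries))
  if (nrow(targets) == 0 || nrow(queries) == 0) return(res)
  by_chrom <- split(seq_len(nrow(targets)), targets$chrom)
  for (ch in names(by_chrom)) {
    qi <- which(queries$chrom == ch)
    if (!length(qi)) next
    ti <- by_chrom[[ch]]
    ord <- ti[order(targets$start[ti])]
    ts <- targets$start[ord]
    te_cm <- cummax(targets$end[ord])
    for (k in qi) {
      qs <- queries$start[k]
      qe <- queries$end[k]
      j <- findInterval(qe - 1L, ts)  # targets with start < qe
      d <- Inf
      if (j > 0) {
        m <- te_cm[j]
        if (m > qs) { res[k] <- 0L; next }
        d <- qs - m
      }
      if (j < length(ts)) d <- min(d, ts[j + 1L] - qe)
      res[k] <- as.integer(d)
    }
  }
  res
}

# All strictly-overlapping (query, subject) index pairs between two interval
# tables, chromosome-aware. IRanges does the interval tree work.
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(a_idx = integer(), b_idx = integer()))
  }
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ia] + 1L, a$end[ia]),
      IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    )
    out[[ch]] <- data.frame(a_idx = ia[S4Vectors::queryHits(hits)],
                            b_idx = ib[S4Vectors::subjectHits(hits)])
  }
  if (!length(out)) return(data.frame(a_idx = integer(), b_idx = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# TRUE for each row of `a` that overlaps at least one row of `b`, optionally
# requiring strand compatibility ("." matches anything).
overlaps_any <- function(a, b, same_strand = FALSE) {
  hit <- logical(nrow(a))
  pairs <- overlap_pairs(a, b)
  if (nrow(pairs) && same_strand) {
    sa <- a$strand[pairs$a_idx]
    sb <- b$strand[pairs$b_idx]
    pairs <- pairs[sa == "." | sb == "." | sa == sb, , drop = FALSE]
  }
  hit[unique(pairs$a_idx)] <- TRUE
  hit
}
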