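#' Read gene models from a BED12 file
#'
#' Gene models carry the transcript span, strand, TSS, translation start
#' (from the thickStart/thickEnd columns; `NA` for non-coding models where
#' thickStart == thickEnd) and exon blocks. All coordinates 0-based
#' half-open.
#'
#' @param path BED12 file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `tss`, `cds_start` (genomic 0-based position of the first coding
#'   base, `NA` if non-coding) and list-columns `exon_starts`, `exon_ends`
#'   (genomic coordinates, left to right).
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(cbind(empty_intervals(),
                 data.frame(name = character(), tss = integer(),
                            cds_start = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12)) {
    stop(sprintf("BED12 parse error at line %d: fewer than 12 columns",
                 which(lengths(fields) < 12)[1]))
  }
  g <- function(i) vapply(fields, `[[`, "", i)
  chrom <- g(1); start <- as.integer(g(2)); end <- as.integer(g(3))
  name <- g(4); strand <- g(6)
  thick_start <- as.integer(g(7)); thick_end <- as.integer(g(8))
  n_blocks <- as.integer(g(10))
  sizes <- lapply(strsplit(g(11), ",", fixed = TRUE), as.integer)
  offs <- lapply(strsplit(g(12), ",", fixed = TRUE), as.integer)
  if (any(lengths(sizes) != n_blocks) || any(lengths(offs) != n_blocks)) {
    stop("BED12 parse error: block count does not match block lists")
  }
  exon_starts <- mapply(function(s, o) s + o, start, offs, SIMPLIFY = FALSE)
  exon_ends <- mapply(function(es, sz) es + sz, exon_starts, sizes, SIMPLIFY = FALSE)
  coding <- thick_start < thick_end
  # first coding base in genomic coordinates: thickStart on +, thickEnd-1 on -
  cds_start <- ifelse(coding, ifelse(strand == "-", thick_end - 1L, thick_start),
                      NA_integer_)
  df <- gintervals(chrom, start, end, strand)
  df$name <- name
  df$tss <- ifelse(strand == "-", end - 1L, start)
  df$cds_start <- as.integer(cds_start)
  df$exon_starts <- I(exon_starts)
  df$exon_ends <- I(exon_ends)
  df
}

#' Promoter regions of gene models
#'
#' A promoter runs from 1 kb upstream of the TSS to the start of the coding
#' region (excluding the first coding base), in transcript orientation. For
#' non-coding models (no translation start) the surrogate
#' `[tss - 1000, tss + 500)` is used and flagged via the `is_coding` column.
#'
#' @param genes gene table from [read_bed12()].
#' @param upstream bases upstream of the TSS (default 1000).
#' @param noncoding_downstream downstream extent of the non-coding surrogate
#'   (default 500).
#' @return interval `data.frame` with `name` and `is_coding` columns; strand
#'   copied from the gene.
#' @export
promoter_regions <- function(genes, upstream = 1000L, noncoding_downstream = 500L) {
  n <- nrow(genes)
  if (n == 0) return(cbind(empty_intervals(), data.frame(name = character(), is_coding = logical())))
  coding <- !is.na(genes$cds_start)
  start <- integer(n); end <- integer(n)
  plus <- genes$strand != "-"
  # plus strand: [tss - upstream, cds_start); minus: [cds_start + 1, tss + upstream + 1)
  start[plus] <- genes$tss[plus] - upstream
  end[plus] <- ifelse(coding[plus], genes$cds_start[plus], genes$tss[plus] + noncoding_downstream)
  end[!plus] <- genes$tss[!plus] + upstream + 1L
  start[!plus] <- ifelse(coding[!plus], genes$cds_start[!plus] + 1L,
                         genes$tss[!plus] - noncoding_downstream + 1L)
  # guard degenerate models whose translation start precedes the TSS
  end[plus] <- pmax(end[plus], genes$tss[plus] + 1L)
  start[!plus] <- pmin(start[!plus], genes$tss[!plus])
  start <- pmax(start, 0L)
  df <- gintervals(genes$chrom, start, end, genes$strand)
  df$name <- genes$name
  df$is_coding <- coding
  df
}

#' Read a repeat annotation table
#'
#' Tab-separated with columns chrom, start, end, name, repeat_class, family
#' (BED-like, 0-based half-open; the RepeatMasker-derived dialect used by the
#' synthetic generator). Classes outside {SINE, LINE, LTR, DNA} are mapped to
#' "Other".
#'
#' @param path path to the table (header optional, detected on `chrom`).
#' @return interval `data.frame` with `name`, `repeat_class`, `family`.
#' @export
read_repeats <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[1], "chrom")) lines <- lines[-1]
  if (!length(lines)) {
    return(cbind(empty_intervals(),
                 data.frame(name = character(), repeat_class = character(),
                            family = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6)) {
    stop(sprintf("repeat table parse error at line %d: fewer than 6 columns",
                 which(lengths(fields) < 6)[1]))
  }
  g <- function(i) vapply(fields, `[[`, "", i)
  df <- gintervals(g(1), as.integer(g(2)), as.integer(g(3)))
  df$name <- g(4)
  cls <- g(5)
  cls[!cls %in% c("SINE", "LINE", "LTR", "DNA")] <- "Other"
  df$repeat_class <- cls
  df$family <- g(6)
  df
}

#' Read a mappability track
#'
#' BED intervals marking uniquely mappable positions; merged and sorted on
#' load so that downstream effective-length arithmetic can assume disjoint
#' intervals.
#'
#' @param path BED file.
#' @return merged interval `data.frame`.
#' @export
read_mappability <- function(path) {
  merge_intervals(read_bed(path))
}
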