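#' Build a tag library from 5'-end positions
#'
#' A tag library holds one condition's uniquely mapped tag 5'-end positions,
#' sorted per chromosome, plus the library-wide total used for all
#' normalization (TPM, library-size ratio in the combined z-score, Fisher
#' test margins).
#'
#' @param positions named list of integer vectors, one per chromosome,
#'   0-based 5'-end positions (any order; sorted on construction).
#' @param condition label such as `"VPA"` or `"Veh"`.
#' @return object of class `tag_library` with elements `condition`,
#'   `positions` and `n_total`.
#' @export
tag_library <- function(positions, condition = "sample") {
  stopifnot(is.list(positions))
  if (length(positions) && is.null(names(positions))) {
    stop("positions must be a named (per-chromosome) list")
  }
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  structure(
    list(condition = condition, positions = positions,
         n_total = sum(lengths(positions))),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d tags on %d chromosome(s)\n",
              x$condition, x$n_total, length(x$positions)))
  invisible(x)
}

#' Load tag 5'-end positions from a BED file
#'
#' Each BED record is reduced to a single 5'-end position at load time: the
#' `start` for `+`/unstranded records and `end - 1` for `-` records, matching
#' the cut-site semantics of DNase tags. Strand information is then dropped;
#' counting treats cut sites as strandless events.
#'
#' @param path BED file of mapped tags.
#' @param condition condition label stored on the library.
#' @return a [tag_library()].
#' @export
read_tag_bed <- function(path, condition = "sample") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(tag_library(stats::setNames(list(), character()), condition))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  strand <- ifelse(lengths(fields) >= 6, vapply(fields, function(f) f[6], ""), ".")
  pos <- ifelse(strand == "-", end - 1L, start)
  tag_library(split(pos, chrom), condition)
}

#' Count tags whose 5' end falls in an interval
#'
#' Binary-search count of positions `p` with `start <= p < end` in a sorted
#' tag library, the small- and big-window counting rule of the DHSS caller.
#'
#' @param library a [tag_library()].
#' @param chrom chromosome name (scalar).
#' @param start,end equal-length integer vectors of 0-based half-open bounds.
#' @return integer vector of counts, one per interval.
#' @export
count_tags <- function(library, chrom, start, end) {
  stopifnot(inherits(library, "tag_library"), length(chrom) == 1)
  pos <- library$positions[[chrom]]
  if (is.null(pos) || !length(pos)) return(integer(length(start)))
  findInterval(end - 1L, pos) - findInterval(start - 1L, pos)
}

# Sum of tag counts over the rows of an interval table.
count_tags_intervals <- function(library, intervals) {
  if (nrow(intervals) == 0) return(integer())
  out <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    i <- which(intervals$chrom == ch)
    out[i] <- count_tags(library, ch, intervals$start[i], intervals$end[i])
  }
  out
}
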