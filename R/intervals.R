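#' Genomic interval in zero-based half-open coordinates
#'
#' All internal computation in regulocus uses zero-based half-open
#' coordinates (the BED convention). One-based inclusive coordinates, as
#' printed by genome browsers and in publications, are converted exactly
#' once at the input boundary by [parse_region()].
#'
#' @param chrom Contig identifier.
#' @param start,end Zero-based half-open coordinates, `start < end`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr11", 67103533, 67145377)
#' interval_width(gi)  # 41844
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing numbers")
  if (start < 0) stop("start must be >= 0 (zero-based half-open)")
  if (start >= end) stop("interval must satisfy start < end, got [",
                         start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format(x), " (zero-based half-open, width ",
      interval_width(x), ")\n", sep = "")
  invisible(x)
}

#' Width of a genomic interval
#' @param x A `genomic_interval`.
#' @return Width in bp (`end - start`).
#' @export
interval_width <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' Parse a region string into a genomic interval
#'
#' Accepts both machine style (`"chr1:100-200"`) and publication style with
#' commas, spaces and an en-dash (`"chr11: 67,103,534–67,145,377"`).
#' Publication-style coordinates are one-based inclusive, so the default
#' coordinate system is `"one_inclusive"`; pass
#' `coords = "zero_half_open"` for BED-convention input. The result is
#' always zero-based half-open.
#'
#' @param text Region string, `"chrom:start-end"`.
#' @param coords Coordinate system of the input numbers.
#' @return A [genomic_interval()].
#' @examples
#' parse_region("chr11: 67,103,534–67,145,377")       # width 41844
#' parse_region("chr1:100-200", coords = "zero_half_open") # width 100
#' @export
parse_region <- function(text, coords = c("one_inclusive", "zero_half_open")) {
  coords <- match.arg(coords)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("region must be a non-empty string")
  m <- regexec("^\\s*([^:[:space:]]+)\\s*:\\s*([0-9,]+)\\s*[-–—]\\s*([0-9,]+)\\s*$",
               text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4L)
    stop("cannot parse region string ", sQuote(text),
         "; expected 'chrom:start-end'")
  num <- function(tok) {
    v <- suppressWarnings(as.numeric(gsub(",", "", tok, fixed = TRUE)))
    if (is.na(v)) stop("malformed coordinate token ", sQuote(tok),
                       " in region ", sQuote(text))
    v
  }
  start <- num(parts[3]); end <- num(parts[4])
  if (coords == "one_inclusive") {
    if (start < 1) stop("one-based coordinate must be >= 1 in ", sQuote(text))
    start <- start - 1  # end stays: [start-1, end) spans the inclusive range
  }
  genomic_interval(parts[2], start, end)
}

# Midpoint-in-interval membership for parallel start/end vectors.
# `region` may be a single genomic_interval or a list of them.
#' @noRd
midpoint_in_region <- function(chrom, start, end, region) {
  mids <- (start + end) / 2
  if (inherits(region, "genomic_interval")) region <- list(region)
  hit <- rep(FALSE, length(mids))
  for (r in region)
    hit <- hit | (chrom == r$chrom & mids >= r$start & mids < r$end)
  hit
}

#' @noRd
interval_contains <- function(outer, inner) {
  outer$chrom == inner$chrom &&
    inner$start >= outer$start && inner$end <= outer$end
}
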