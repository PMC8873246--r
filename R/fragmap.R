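#' @noRd
new_fragment_map <- function(chrom, start, end, blind = NA, seqlen,
                             first_cutter = NA_character_,
                             second_cutter = NA_character_) {
  n <- length(start)
  map <- data.frame(chrom = rep_len(as.character(chrom), n),
                    start = as.numeric(start), end = as.numeric(end),
                    index = seq_len(n), blind = rep_len(blind, n))
  attr(map, "seqlen") <- as.numeric(seqlen)
  attr(map, "first_cutter") <- first_cutter
  attr(map, "second_cutter") <- second_cutter
  class(map) <- c("fragment_map", "data.frame")
  validate_fragment_map(map)
}

#' @noRd
validate_fragment_map <- function(map) {
  n <- nrow(map)
  if (n == 0L) return(map)
  if (length(unique(map$chrom)) != 1L)
    stop("fragment_map supports a single contig")
  if (any(map$start >= map$end)) stop("fragment with start >= end")
  if (map$start[1] != 0) stop("first fragment must start at 0")
  if (!isTRUE(all.equal(map$end[n], attr(map, "seqlen"))))
    stop("last fragment must end at the contig length")
  if (n > 1L && any(map$start[-1] != map$end[-n]))
    stop("fragments must tile the contig with no gaps or overlaps")
  map
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map> ", nrow(x), " fragments on ", x$chrom[1], " [0, ",
      attr(x, "seqlen"), "); cutter ", attr(x, "first_cutter"),
      if (!is.na(attr(x, "second_cutter")))
        paste0(" / ", attr(x, "second_cutter")), "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' In-silico restriction digestion of one contig
#'
#' Scans every position of the sequence for occurrences of the cutter
#' motif (overlapping occurrences included) and places a cut at the 5'
#' start of each occurrence, the convention for enzymes such as DpnII that
#' cleave ^GATC and leave the motif on the downstream fragment. A motif at
#' position 0 produces no leading zero-length fragment. `N` bases never
#' match.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param motif Cutter recognition motif over A/C/G/T, default `"GATC"`.
#' @param chrom Contig name for the resulting map.
#' @return A `fragment_map`: a data.frame with columns chrom, start, end,
#'   index, blind (NA until [annotate_blind()] is run), tiling `[0, L)`.
#' @examples
#' digest_genome("TTGATCAAGATCGG")  # fragments [0,2), [2,8), [8,14)
#' @export
digest_genome <- function(sequence, motif = "GATC", chrom = "chr1") {
  check_motif(motif)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("sequence must be a single contig string")
  L <- nchar(sequence)
  if (L == 0L)
    return(new_fragment_map(chrom, numeric(0), numeric(0), NA, 0,
                            first_cutter = motif))
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains symbols outside {A,C,G,T,N}")
  cuts <- motif_starts(sequence, motif)  # 0-based, every position scanned
  bounds <- sort(unique(c(0, cuts, L)))
  new_fragment_map(chrom, bounds[-length(bounds)], bounds[-1],
                   seqlen = L, first_cutter = motif)
}

#' @noRd
check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a non-empty DNA string")
  if (grepl("[^ACGT]", toupper(motif)))
    stop("invalid motif alphabet: ", motif, " (A/C/G/T only)")
  toupper(motif)
}

# All 0-based start positions of `motif` in `sequence`, overlapping
# occurrences included (Biostrings::matchPattern scans every position).
#' @noRd
motif_starts <- function(sequence, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence))
  IRanges::start(methods::as(hits, "IRanges")) - 1L
}

#' Flag blind fragments from the secondary cutter
#'
#' A fragment is blind when no occurrence of the secondary motif lies
#' fully within its half-open span; such fragments are poorly recoverable
#' in double-digest 4C libraries. Blind fragments are flagged but retained
#' by default throughout the pipeline.
#'
#' @param map `fragment_map` produced from `sequence`.
#' @param sequence The same contig sequence the map was digested from.
#' @param secondary_motif Secondary cutter motif, default `"CATG"`.
#' @return The map with its `blind` column filled in.
#' @export
annotate_blind <- function(map, sequence, secondary_motif = "CATG") {
  stopifnot(inherits(map, "fragment_map"))
  secondary_motif <- check_motif(secondary_motif)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) != attr(map, "seqlen"))
    stop("sequence length (", nchar(sequence),
         ") does not match fragment map contig length (",
         attr(map, "seqlen"), ")")
  starts <- motif_starts(sequence, secondary_motif)
  m <- nchar(secondary_motif)
  blind <- rep(TRUE, nrow(map))
  if (length(starts)) {
    frag <- findInterval(starts, map$start)
    contained <- starts + m <= map$end[frag]
    blind[unique(frag[contained])] <- FALSE
  }
  map$blind <- blind
  attr(map, "second_cutter") <- secondary_motif
  map
}

#' Assign positional count records to fragments
#'
#' Each record's count is added to the unique fragment whose half-open
#' span contains its position (a position exactly at a fragment start
#' belongs to that fragment). Out-of-bounds or off-contig records are
#' dropped with a warning; total assigned count equals total retained
#' input count exactly.
#'
#' @param map A `fragment_map`.
#' @param records `data.frame` with columns chrom, position, count.
#' @return Numeric vector of per-fragment counts, length `nrow(map)`.
#' @export
assign_counts <- function(map, records) {
  stopifnot(inherits(map, "fragment_map"))
  stopifnot(all(c("chrom", "position", "count") %in% names(records)))
  vals <- numeric(nrow(map))
  if (nrow(records) == 0L) return(vals)
  ok <- records$chrom == map$chrom[1] & records$position >= 0 &
    records$position < attr(map, "seqlen") & !is.na(records$position)
  if (any(!ok))
    warning(sum(!ok), " record(s) outside contig bounds dropped")
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0L) return(vals)
  idx <- findInterval(rec$position, map$start)
  add <- rowsum(rec$count, idx)
  vals[as.integer(rownames(add))] <- vals[as.integer(rownames(add))] + add[, 1]
  vals
}

#' Locate the fragment holding a viewpoint
#'
#' Resolution is by the viewpoint's midpoint, so a viewpoint straddling a
#' cut site maps to the fragment containing its midpoint.
#'
#' @param map A `fragment_map`.
#' @param viewpoint A [genomic_interval()].
#' @return Fragment index (1-based ordinal along the contig).
#' @export
locate_viewpoint <- function(map, viewpoint) {
  stopifnot(inherits(map, "fragment_map"),
            inherits(viewpoint, "genomic_interval"))
  if (viewpoint$chrom != map$chrom[1])
    stop("viewpoint contig ", viewpoint$chrom, " not present in map")
  mid <- (viewpoint$start + viewpoint$end) / 2
  if (mid < 0 || mid >= attr(map, "seqlen"))
    stop("viewpoint midpoint outside contig")
  findInterval(mid, map$start)
}

#' @noRd
fragment_midpoints <- function(map) (map$start + map$end) / 2

#' @noRd
same_fragment_map <- function(a, b) {
  identical(a$chrom, b$chrom) &&
    isTRUE(all.equal(a$start, b$start)) && isTRUE(all.equal(a$end, b$end))
}
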