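#' Stitch signal peaks into candidate enhancer regions
#'
#' Sorts peaks and merges every run of peaks in which consecutive gaps
#' (next start minus previous end) are at most `distance` bp — the
#' transitive closure of the ROSE stitching rule, default 12.5 kb.
#' Overlapping or adjacent input peaks always merge. Signal is summed, so
#' total signal is conserved exactly.
#'
#' @param peaks `data.frame` with columns chrom, start, end, signal
#'   (signal non-negative).
#' @param distance Stitching distance in bp, `>= 0`.
#' @return `data.frame` chrom, start, end, n_peaks, signal, one row per
#'   stitched region, sorted by coordinate.
#' @export
stitch_peaks <- function(peaks, distance = 12500) {
  stopifnot(all(c("chrom", "start", "end", "signal") %in% names(peaks)))
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("stitching distance must be a single number >= 0")
  if (any(peaks$signal < 0)) stop("peak signal must be >= 0")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_peaks = integer(0),
                      signal = numeric(0)))
  p <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  new_cluster <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)] |
                     p$start[-1] - cummax_by_chrom(p) > distance)
  cl <- cumsum(new_cluster)
  out <- data.frame(
    chrom = tapply(p$chrom, cl, `[`, 1L),
    start = as.numeric(tapply(p$start, cl, min)),
    end = as.numeric(tapply(p$end, cl, max)),
    n_peaks = as.integer(tapply(p$start, cl, length)),
    signal = as.numeric(tapply(p$signal, cl, sum)),
    row.names = NULL)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Running maximum of peak ends within each chrom, lagged by one, so a
# peak contained in its predecessor still stitches to the cluster.
#' @noRd
cummax_by_chrom <- function(p) {
  ends <- numeric(nrow(p) - 1L)
  cur_chrom <- p$chrom[1]; cur_max <- p$end[1]
  for (i in seq_len(nrow(p) - 1L)) {
    ends[i] <- cur_max
    nxt <- i + 1L
    if (p$chrom[nxt] != cur_chrom) {
      cur_chrom <- p$chrom[nxt]; cur_max <- p$end[nxt]
    } else cur_max <- max(cur_max, p$end[nxt])
  }
  ends
}

#' Hockey-stick cutoff on a ranked signal landscape
#'
#' Sorts signals ascending, scales ranks and signals to the unit square
#' and finds the point past which the curve's forward-difference slope
#' stays above 1 — the discrete analogue of the ROSE rule placing the
#' cutoff where a line of slope 1 is tangent to the hockey-stick curve.
#' The threshold is the unscaled signal at that point; regions with
#' signal strictly above it are super-enhancers.
#'
#' @param stitched `data.frame` with a `signal` column (>= 3 rows), or a
#'   bare numeric vector of signals.
#' @return List: `threshold`, `is_super` (aligned to the input order),
#'   `cutoff_index` (position in the ascending sort), `scaled`
#'   (`data.frame` of the unit-square curve: `x`, `y`, ascending order).
#' @examples
#' hockey_stick_cutoff(c(1, 2, 3, 4, 100))$threshold  # 4
#' @export
hockey_stick_cutoff <- function(stitched) {
  s <- if (is.data.frame(stitched)) stitched$signal else as.numeric(stitched)
  if (is.null(s)) stop("stitched regions must carry a signal column")
  n <- length(s)
  if (n < 3L) stop("need at least 3 regions to place a cutoff")
  if (diff(range(s)) == 0) {
    warning("degenerate landscape: all signals equal; no super-enhancers")
    return(list(threshold = Inf, is_super = rep(FALSE, n),
                cutoff_index = NA_integer_,
                scaled = data.frame(x = (seq_len(n) - 1) / (n - 1),
                                    y = rep(0, n))))
  }
  ord <- order(s)
  s2 <- s[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s2 - s2[1]) / (s2[n] - s2[1])
  slope <- diff(y) / diff(x)
  below <- which(slope <= 1)
  cutoff_index <- if (length(below)) below[length(below)] + 1L else 1L
  threshold <- s2[cutoff_index]
  list(threshold = threshold, is_super = s > threshold,
       cutoff_index = cutoff_index, scaled = data.frame(x = x, y = y))
}

#' Call super-enhancers from signal peaks
#'
#' Stitch -> rank -> hockey-stick cutoff. Ranking is strictly by summed
#' signal, rank 1 highest; ties are broken deterministically in favour of
#' the earlier genomic coordinate.
#'
#' @param peaks `data.frame` chrom, start, end, signal.
#' @param distance Stitching distance in bp (default 12500).
#' @param out Optional output prefix; writes `<out>.tsv` (full ranked
#'   table) and `<out>.bed` (BED6, score = signal, name = rank with an
#'   `_SE` suffix on super calls).
#' @return `data.frame` sorted by rank: chrom, start, end, n_peaks,
#'   signal, rank, scaled_x, scaled_y, is_super.
#' @export
call_superenhancers <- function(peaks, distance = 12500, out = NULL) {
  st <- stitch_peaks(peaks, distance = distance)
  cut <- hockey_stick_cutoff(st)
  ord_rank <- order(-st$signal, st$chrom, st$start)
  st$rank <- integer(nrow(st))
  st$rank[ord_rank] <- seq_len(nrow(st))
  asc <- order(st$signal, -st$rank)  # ascending signal, matching cutoff sort
  st$scaled_x <- numeric(nrow(st)); st$scaled_y <- numeric(nrow(st))
  st$scaled_x[asc] <- cut$scaled$x
  st$scaled_y[asc] <- cut$scaled$y
  st$is_super <- cut$is_super
  st <- st[order(st$rank), , drop = FALSE]
  rownames(st) <- NULL
  attr(st, "threshold") <- cut$threshold
  if (!is.null(out)) {
    write_tsv(st, paste0(out, ".tsv"))
    bed <- data.frame(chrom = st$chrom, start = st$start, end = st$end,
                      name = paste0("rank", st$rank,
                                    ifelse(st$is_super, "_SE", "")),
                      score = st$signal, strand = ".")
    write_bed(bed, paste0(out, ".bed"))
  }
  st
}
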