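#' Construct a viewpoint contact profile
#'
#' A `four_c_profile` holds one viewpoint's per-fragment 4C signal in one
#' condition, together with its fragment map, viewpoint, masking state and
#' processing stage. Stages advance strictly raw -> masked -> normalized
#' -> smoothed; each transform checks the stage of its input, so e.g. the
#' differential test cannot accidentally consume smoothed values.
#'
#' @param map A `fragment_map`.
#' @param values Per-fragment signal, length `nrow(map)`.
#' @param viewpoint A [genomic_interval()]; its fragment is located by
#'   midpoint.
#' @param condition Condition label (e.g. `"quadriceps"`).
#' @param stage Processing stage; new profiles are `"raw"`.
#' @return A `four_c_profile` object.
#' @export
four_c_profile <- function(map, values, viewpoint, condition,
                           stage = "raw") {
  stopifnot(inherits(map, "fragment_map"))
  values <- as.numeric(values)
  if (length(values) != nrow(map))
    stop("values length (", length(values), ") must equal fragment count (",
         nrow(map), ")")
  stage <- match.arg(stage, c("raw", "masked", "normalized", "smoothed"))
  if (stage %in% c("raw", "normalized") && any(values < 0, na.rm = TRUE))
    stop("negative signal not allowed at stage ", stage)
  vp_index <- locate_viewpoint(map, viewpoint)
  structure(list(map = map, values = values,
                 mask = is.na(values) & stage != "raw",
                 viewpoint = viewpoint, vp_index = vp_index,
                 condition = condition, stage = stage),
            class = "four_c_profile")
}

#' @export
print.four_c_profile <- function(x, ...) {
  cat("<four_c_profile> condition ", x$condition, ", stage ", x$stage, ", ",
      nrow(x$map), " fragments, viewpoint ", format(x$viewpoint),
      " (fragment ", x$vp_index, "), ", sum(x$mask), " masked\n", sep = "")
  invisible(x)
}

#' @noRd
require_stage <- function(profile, allowed, op) {
  stopifnot(inherits(profile, "four_c_profile"))
  if (!profile$stage %in% allowed)
    stop(op, " requires a profile at stage ",
         paste(allowed, collapse = "/"), ", got ", sQuote(profile$stage),
         " (pipeline order is raw -> masked -> normalized -> smoothed)")
  invisible(profile)
}

#' Mask fragments around the viewpoint
#'
#' The viewpoint fragment, plus every fragment overlapping the window
#' `margin` bp up- and downstream of it, is set to a missing value and
#' excluded from all downstream normalization, smoothing and testing.
#' The conventional margin is 2 kb. Idempotent.
#'
#' @param profile A raw (or already masked) `four_c_profile`.
#' @param margin_bp Exclusion margin in bp on each side, `>= 0`.
#' @return The profile at stage `"masked"`.
#' @export
mask_viewpoint <- function(profile, margin_bp = 2000) {
  require_stage(profile, c("raw", "masked"), "mask_viewpoint")
  if (!is.numeric(margin_bp) || length(margin_bp) != 1L || margin_bp < 0)
    stop("margin_bp must be a single number >= 0")
  map <- profile$map
  vp <- map[profile$vp_index, ]
  win_start <- vp$start - margin_bp
  win_end <- vp$end + margin_bp
  hit <- map$start < win_end & map$end > win_start
  profile$mask <- profile$mask | hit
  profile$values[profile$mask] <- NA_real_
  profile$stage <- "masked"
  profile
}

#' Normalize a profile to a reference region
#'
#' Multiplies every unmasked value by one factor chosen so that the summed
#' signal over fragments whose midpoints fall in the reference region
#' equals `scale` exactly. With the reference spanning the TADs
#' surrounding the locus, this makes profiles from different conditions
#' directly comparable.
#'
#' @param profile A masked `four_c_profile`.
#' @param reference A [genomic_interval()] or list of them.
#' @param scale Target reference-region sum (default 1e6, i.e.
#'   reads-per-million-in-reference units).
#' @return The profile at stage `"normalized"`.
#' @export
normalize_to_region <- function(profile, reference, scale = 1e6) {
  require_stage(profile, "masked", "normalize_to_region")
  map <- profile$map
  in_ref <- midpoint_in_region(map$chrom, map$start, map$end, reference)
  use <- in_ref & !profile$mask
  if (!any(use))
    stop("no unmasked fragment overlaps the reference region")
  ref_sum <- sum(profile$values[use])
  if (!is.finite(ref_sum) || ref_sum <= 0)
    stop("degenerate profile: reference-region signal sum is ", ref_sum)
  profile$values[!profile$mask] <- profile$values[!profile$mask] *
    (scale / ref_sum)
  profile$stage <- "normalized"
  profile
}

#' Running-mean smoothing in fragment space
#'
#' Replaces each unmasked fragment's value by the mean of unmasked values
#' in a window of `window` fragments centred on it (fragment-index space,
#' not bp). At contig edges the half-width shrinks symmetrically to the
#' available fragments, so a linear ramp is left unchanged everywhere.
#' Masked fragments stay masked and never contribute to a neighbour's
#' mean.
#'
#' @param profile A normalized `four_c_profile`.
#' @param window Odd window size, default 11 fragments.
#' @return The profile at stage `"smoothed"`.
#' @export
running_mean <- function(profile, window = 11) {
  require_stage(profile, "normalized", "running_mean")
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop("window must be an odd integer >= 1")
  h <- (window - 1) / 2
  v <- profile$values
  n <- length(v)
  out <- v
  unm <- which(!profile$mask)
  for (i in unm) {
    hi <- min(h, i - 1L, n - i)
    idx <- (i - hi):(i + hi)
    out[i] <- mean(v[idx], na.rm = TRUE)
  }
  profile$values <- out
  profile$stage <- "smoothed"
  profile
}

#' Between-condition log2 ratio track
#'
#' @param profile_a,profile_b Smoothed `four_c_profile`s on the same
#'   fragment map.
#' @param pseudocount Added to both numerator and denominator before the
#'   log, `> 0`. Default 1 (in per-million reference units).
#' @return `data.frame` chrom, start, end, value with the per-fragment
#'   `log2((a + eps) / (b + eps))`; fragments masked in either profile are
#'   `NA`.
#' @export
ratio_track <- function(profile_a, profile_b, pseudocount = 1) {
  require_stage(profile_a, "smoothed", "ratio_track")
  require_stage(profile_b, "smoothed", "ratio_track")
  if (!same_fragment_map(profile_a$map, profile_b$map))
    stop("profiles are on different fragment maps")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  mask <- profile_a$mask | profile_b$mask
  r <- log2((profile_a$values + pseudocount) /
              (profile_b$values + pseudocount))
  r[mask] <- NA_real_
  map <- profile_a$map
  data.frame(chrom = map$chrom, start = map$start, end = map$end, value = r)
}

#' Export a profile as a bedGraph data.frame
#' @param profile A `four_c_profile`.
#' @return `data.frame` chrom, start, end, value (masked fragments `NA`).
#' @export
profile_track <- function(profile) {
  stopifnot(inherits(profile, "four_c_profile"))
  data.frame(chrom = profile$map$chrom, start = profile$map$start,
             end = profile$map$end, value = profile$values)
}

#' Rebuild a profile from a track file written at a known stage
#'
#' Used by the command-line `difftest` path, where normalized unsmoothed
#' tracks are exchanged as bedGraph. `NA` values are interpreted as
#' masked fragments.
#'
#' @param track `data.frame` chrom, start, end, value matching `map`
#'   row-for-row.
#' @param map The `fragment_map` the track was computed on.
#' @param viewpoint,condition,stage As in [four_c_profile()].
#' @return A `four_c_profile`.
#' @export
profile_from_track <- function(track, map, viewpoint, condition, stage) {
  if (nrow(track) != nrow(map) ||
      !isTRUE(all.equal(track$start, map$start)) ||
      !isTRUE(all.equal(track$end, map$end)) ||
      !all(track$chrom == map$chrom))
    stop("track fragments do not match the fragment map")
  p <- four_c_profile(map, track$value, viewpoint, condition, stage = "raw")
  p$stage <- stage
  p$mask <- is.na(track$value)
  p
}
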