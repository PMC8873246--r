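#' Configuration for the synthetic locus generator
#'
#' The defaults describe one fixed synthetic world emulating a clustered
#' multi-gene locus under super-enhancer control: a single 500 kb contig
#' partitioned into five 100 kb TADs, a gene cluster and a 41,844 bp
#' super-enhancer region inside the middle TAD, a 4C viewpoint at the
#' promoter of the most distal gene of the cluster, power-law contact
#' decay with negative-binomial counting noise and a multiplicative
#' viewpoint-SE loop active in one condition only, an enhancer-signal
#' landscape of isolated gamma-distributed background peaks plus one
#' plantable heavy 7-peak cluster inside the SE, and a nucleus-by-promoter
#' accessibility matrix over four fiber-type classes with the class sizes
#' 64/59/249/495.
#'
#' @param genome_length Contig length in bp.
#' @param chrom Contig name.
#' @param cutter_motif First (fragmenting) cutter motif, default GATC.
#' @param secondary_motif Second cutter motif, default CATG.
#' @param motif_spacing_mean Mean distance between planted cutter sites
#'   (bp); 500 bp gives fragments of typical 4-cutter size.
#' @param n_genes Number of clustered genes (promoters spaced 8 kb from
#'   the focal TAD start).
#' @param tad_boundaries Strictly increasing internal TAD boundaries (bp).
#' @param se_interval [genomic_interval()] of the plantable
#'   super-enhancer; must lie inside exactly one TAD.
#' @param viewpoint_anchor Position (bp) whose fragment becomes the 4C
#'   viewpoint; `NULL` places it 200 bp into the last gene's promoter.
#' @param read_depth Total 4C reads per profile (expected), default 1e5.
#' @param decay_exponent Power-law contact decay exponent alpha > 0.
#' @param decay_offset Decay offset d0 in bp (> 0).
#' @param loop_enrichment Multiplicative loop strength beta >= 0 applied
#'   to SE fragments in the loop-active condition.
#' @param active_condition Condition label carrying the loop.
#' @param conditions The two condition labels.
#' @param dispersion Negative-binomial size theta > 0 (Poisson as
#'   theta -> Inf).
#' @param n_background_peaks Background peaks in the enhancer landscape
#'   (>= 30).
#' @param background_signal_mean,background_signal_shape Gamma parameters
#'   of background peak signal.
#' @param n_nuclei Named integer vector of per-class nucleus counts.
#' @param accessibility_effect Fold accessibility increase at a nucleus's
#'   own class promoter (>= 1; 1 = uninformative).
#' @param nucleus_depth_mean Mean promoter-window fragments per nucleus.
#' @param qc_fail_frac Fraction of nuclei planted as QC violators (each
#'   violating one randomly chosen rule).
#' @param seed Default seed used by the generators when no explicit seed
#'   is passed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 500000,
                       chrom = "chrS",
                       cutter_motif = "GATC",
                       secondary_motif = "CATG",
                       motif_spacing_mean = 500,
                       n_genes = 4,
                       tad_boundaries = c(1e5, 2e5, 3e5, 4e5),
                       se_interval = genomic_interval("chrS", 240000, 281844),
                       viewpoint_anchor = NULL,
                       read_depth = 1e5,
                       decay_exponent = 1,
                       decay_offset = 1000,
                       loop_enrichment = 1,
                       active_condition = "quadriceps",
                       conditions = c("quadriceps", "soleus"),
                       dispersion = 10,
                       n_background_peaks = 30,
                       background_signal_mean = 50,
                       background_signal_shape = 20,
                       n_nuclei = c(Myh7 = 64, Myh2 = 59, Myh1 = 249,
                                    Myh4 = 495),
                       accessibility_effect = 10,
                       nucleus_depth_mean = 300,
                       qc_fail_frac = 0.1,
                       seed = 1L) {
  cfg <- list(genome_length = genome_length, chrom = chrom,
              cutter_motif = check_motif(cutter_motif),
              secondary_motif = check_motif(secondary_motif),
              motif_spacing_mean = motif_spacing_mean, n_genes = n_genes,
              tad_boundaries = tad_boundaries, se_interval = se_interval,
              viewpoint_anchor = viewpoint_anchor, read_depth = read_depth,
              decay_exponent = decay_exponent, decay_offset = decay_offset,
              loop_enrichment = loop_enrichment,
              active_condition = active_condition, conditions = conditions,
              dispersion = dispersion,
              n_background_peaks = n_background_peaks,
              background_signal_mean = background_signal_mean,
              background_signal_shape = background_signal_shape,
              n_nuclei = n_nuclei,
              accessibility_effect = accessibility_effect,
              nucleus_depth_mean = nucleus_depth_mean,
              qc_fail_frac = qc_fail_frac, seed = seed)
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (genome_length <= 0) stop("genome_length must be > 0")
    if (decay_exponent <= 0) stop("decay_exponent must be > 0")
    if (decay_offset <= 0) stop("decay_offset must be > 0")
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (loop_enrichment < 0) stop("loop_enrichment must be >= 0")
    if (read_depth <= 0) stop("read_depth must be > 0")
    if (accessibility_effect < 1)
      stop("accessibility_effect must be >= 1")
    if (qc_fail_frac < 0 || qc_fail_frac >= 1)
      stop("qc_fail_frac must be in [0, 1)")
    if (is.unsorted(tad_boundaries, strictly = TRUE))
      stop("tad_boundaries must be strictly increasing")
    if (length(tad_boundaries) &&
        (min(tad_boundaries) <= 0 || max(tad_boundaries) >= genome_length))
      stop("tad_boundaries must lie strictly inside the genome")
    if (!inherits(se_interval, "genomic_interval"))
      stop("se_interval must be a genomic_interval")
    if (n_genes < 2) stop("n_genes must be >= 2")
    if (any(n_nuclei < 1)) stop("per-class nucleus counts must be >= 1")
    if (!active_condition %in% conditions)
      stop("active_condition must be one of conditions")
  })
  tads <- tad_table(cfg)
  hit <- cfg$se_interval$start >= tads$start & cfg$se_interval$end <= tads$end
  if (sum(hit) != 1L)
    stop("se_interval must lie inside exactly one TAD")
  structure(cfg, class = "sim_config")
}

#' TAD partition implied by the configured boundaries
#' @param config A `sim_config`.
#' @return `data.frame` chrom, start, end, name tiling the genome.
#' @export
tad_table <- function(config) {
  b <- c(0, config$tad_boundaries, config$genome_length)
  data.frame(chrom = config$chrom, start = b[-length(b)], end = b[-1],
             name = paste0("TAD", seq_len(length(b) - 1L)))
}

#' Gene, promoter, TAD and region annotation of the synthetic locus
#'
#' Genes are placed head-to-tail from the start of the TAD containing the
#' SE (TSS every 8 kb, 6 kb bodies, promoter = TSS - 2 kb to TSS + 500).
#' The normalization reference is the full multi-TAD contig, mirroring
#' normalization to the TADs surrounding a focal TAD. The viewpoint is
#' the full span of the fragment containing `viewpoint_anchor`, so it
#' always overlaps exactly one fragment.
#'
#' @param config A `sim_config`.
#' @param fragmap Optional `fragment_map`; when given, the viewpoint
#'   interval is resolved to its fragment's span.
#' @return List: genes, promoters, tads (`data.frame`s), se_region,
#'   tad_region (focal TAD), reference, viewpoint
#'   ([genomic_interval()]s), viewpoint_anchor.
#' @export
locus_model <- function(config, fragmap = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tads <- tad_table(config)
  hit <- config$se_interval$start >= tads$start &
    config$se_interval$end <= tads$end
  focal <- tads[hit, ]
  tss <- focal$start + 2000 + (seq_len(config$n_genes) - 1L) * 8000
  if (max(tss) + 6000 > config$se_interval$start)
    warning("gene cluster extends into the SE interval")
  genes <- data.frame(chrom = config$chrom, start = tss, end = tss + 6000,
                      name = paste0("gene_", seq_len(config$n_genes)),
                      score = 0, strand = "+")
  promoters <- data.frame(chrom = config$chrom, start = tss - 2000,
                          end = tss + 500, name = genes$name)
  anchor <- config$viewpoint_anchor
  if (is.null(anchor)) anchor <- tss[config$n_genes] + 200
  viewpoint <- genomic_interval(config$chrom, anchor, anchor + 1)
  if (!is.null(fragmap)) {
    i <- locate_viewpoint(fragmap, viewpoint)
    viewpoint <- genomic_interval(config$chrom, fragmap$start[i],
                                  fragmap$end[i])
  }
  list(genes = genes, promoters = promoters, tads = tads,
       se_region = config$se_interval,
       tad_region = genomic_interval(config$chrom, focal$start, focal$end),
       reference = genomic_interval(config$chrom, 0, config$genome_length),
       viewpoint = viewpoint, viewpoint_anchor = anchor)
}

#' Generate a synthetic genome with planted cutter sites
#'
#' Plants first-cutter motifs at positions with mean spacing
#' `motif_spacing_mean` on a random background, then rejection-samples the
#' background until it contains no accidental motif occurrence, so the
#' digestion fragment map is exactly the planted one.
#'
#' @param config A `sim_config`.
#' @param seed Random seed (defaults to `config$seed`).
#' @return List: `sequence` (character scalar), `chrom`, `cut_sites`
#'   (0-based planted motif starts).
#' @export
make_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$genome_length
  motif <- config$cutter_motif
  m <- nchar(motif)
  # inter-start distances: gamma(shape 4) around the mean, floored so
  # planted motifs never overlap
  n_draw <- ceiling(L / config$motif_spacing_mean * 1.5) + 10L
  gaps <- pmax(round(stats::rgamma(n_draw, shape = 4,
                                   rate = 4 / config$motif_spacing_mean)),
               2L * m)
  pos <- cumsum(gaps)
  pos <- pos[pos + m <= L]
  bases <- c("A", "C", "G", "T")
  seq_vec <- sample(bases, L, replace = TRUE)
  motif_vec <- strsplit(motif, "")[[1]]
  planted_idx <- as.vector(outer(seq_len(m), pos, `+`))  # 1-based footprint
  for (k in seq_len(m)) seq_vec[pos + k] <- motif_vec[k]
  protected <- logical(L)
  protected[planted_idx] <- TRUE
  # scrub accidental occurrences; a mutation can create a new occurrence,
  # so iterate (converges in a handful of rounds)
  for (iter in 1:100) {
    s <- paste(seq_vec, collapse = "")
    occ <- motif_starts(s, motif)  # 0-based
    accidental <- setdiff(occ, pos)
    if (!length(accidental)) break
    if (iter == 100L) stop("failed to scrub accidental motif occurrences")
    for (a in accidental) {
      cand <- (a + 1):(a + m)  # 1-based positions of this occurrence
      cand <- cand[!protected[cand]]
      j <- cand[1]
      seq_vec[j] <- sample(setdiff(bases, seq_vec[j]), 1L)
    }
  }
  list(sequence = s, chrom = config$chrom, cut_sites = as.numeric(pos))
}

#' Simulate a 4C viewpoint profile
#'
#' Per-fragment expected counts follow a symmetric power-law decay from
#' the viewpoint, `w_i = (|d_i| + d0)^(-alpha)`, with `d_i` the
#' fragment-midpoint distance to the viewpoint fragment midpoint. In the
#' loop-active condition the weight of every SE fragment is multiplied by
#' `1 + beta`. The viewpoint fragment itself carries weight 0. Weights
#' are scaled to `lambda_i = N * w_i / sum(w)` (so `sum(lambda) = N`
#' exactly) and counts are drawn negative-binomially with mean
#' `lambda_i` and size `theta`.
#'
#' @param config A `sim_config`.
#' @param fragmap A `fragment_map` of the synthetic genome.
#' @param viewpoint [genomic_interval()]; must overlap exactly one
#'   fragment. `NULL` uses the locus-model viewpoint.
#' @param condition Condition label.
#' @param seed Random seed (defaults to `config$seed`).
#' @return A raw `four_c_profile`; the expected counts are attached as
#'   attribute `lambda`.
#' @export
simulate_4c <- function(config, fragmap, viewpoint = NULL,
                        condition = config$active_condition,
                        seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(fragmap, "fragment_map"))
  if (is.null(viewpoint)) viewpoint <- locus_model(config, fragmap)$viewpoint
  n_overlap <- sum(fragmap$start < viewpoint$end &
                     fragmap$end > viewpoint$start &
                     fragmap$chrom == viewpoint$chrom)
  if (n_overlap != 1L)
    stop("viewpoint must overlap exactly one fragment, overlaps ", n_overlap)
  lam <- expected_4c(config, fragmap, viewpoint, condition)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rnbinom(length(lam), mu = lam, size = config$dispersion)
  p <- four_c_profile(fragmap, counts, viewpoint, condition, stage = "raw")
  attr(p, "lambda") <- lam
  p
}

#' Expected (pre-noise) 4C counts under the simulation model
#'
#' @inheritParams simulate_4c
#' @return Numeric vector `lambda` with `sum(lambda) = read_depth`.
#' @export
expected_4c <- function(config, fragmap, viewpoint,
                        condition = config$active_condition) {
  vp_idx <- locate_viewpoint(fragmap, viewpoint)
  mids <- fragment_midpoints(fragmap)
  d <- abs(mids - mids[vp_idx])
  w <- (d + config$decay_offset)^(-config$decay_exponent)
  if (condition == config$active_condition && config$loop_enrichment > 0) {
    in_se <- midpoint_in_region(fragmap$chrom, fragmap$start, fragmap$end,
                                config$se_interval)
    w[in_se] <- w[in_se] * (1 + config$loop_enrichment)
  }
  w[vp_idx] <- 0
  config$read_depth * w / sum(w)
}

#' Simulate an enhancer-signal peak landscape
#'
#' Emits `n_background_peaks` isolated background peaks (kept more than
#' one stitching distance apart and clear of the SE interval) with
#' i.i.d. gamma signal, plus one planted cluster of 7 peaks inside the SE
#' interval whose gaps are all below 12.5 kb and whose per-peak signal is
#' at least 10x the background mean, so stitching welds the cluster into
#' one heavy region.
#'
#' @param config A `sim_config`.
#' @param seed Random seed (defaults to `config$seed`).
#' @return `data.frame` chrom, start, end, signal, planted (logical),
#'   sorted by coordinate.
#' @export
simulate_enhancer_signal <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  se <- config$se_interval
  n_planted <- 7L
  min_footprint <- n_planted * 1500 + (n_planted - 1L) * 500 + 2000
  if (interval_width(se) < min_footprint)
    stop("se_interval too short for the ", n_planted, "-peak cluster (need >= ",
         min_footprint, " bp)")
  if (config$n_background_peaks < 30)
    stop("need at least 30 background peaks")
  if (!is.null(seed)) set.seed(seed)
  guard <- 13000  # one stitching distance + slack around the SE
  sides <- data.frame(start = c(0, se$end + guard),
                      end = c(max(se$start - guard, 0), config$genome_length))
  sides$len <- pmax(sides$end - sides$start, 0)
  n_bg <- config$n_background_peaks
  n_side <- round(n_bg * sides$len / sum(sides$len))
  n_side[1] <- n_bg - n_side[2]
  bg <- NULL
  for (k in 1:2) {
    if (n_side[k] == 0L) next
    slot <- sides$len[k] / n_side[k]
    # slot must leave > one stitching distance between neighbours:
    # width (<= 700) + 2 * jitter (<= 600) + 12500
    if (slot < 13900)
      stop("genome too crowded to keep background peaks unstitched")
    width <- round(stats::runif(n_side[k], 300, 700))
    centre <- sides$start[k] + (seq_len(n_side[k]) - 0.5) * slot +
      stats::runif(n_side[k], -300, 300)
    bg <- rbind(bg, data.frame(start = round(centre - width / 2),
                               end = round(centre + width / 2)))
  }
  bg$signal <- stats::rgamma(n_bg, shape = config$background_signal_shape,
                             rate = config$background_signal_shape /
                               config$background_signal_mean)
  bg$planted <- FALSE
  width_p <- round(stats::runif(n_planted, 800, 1500))
  avail <- interval_width(se) - 2000 - sum(width_p)
  gap_p <- if (avail / (n_planted - 1L) >= 5500) {
    round(stats::runif(n_planted - 1L, 3000, 5000))
  } else {  # narrow SE: shrink gaps to fit, keeping them well under 12.5 kb
    round(stats::runif(n_planted - 1L, 0.6, 0.95) * avail / (n_planted - 1L))
  }
  starts_p <- se$start + 1000 +
    cumsum(c(0, width_p[-n_planted] + gap_p))
  planted <- data.frame(start = starts_p, end = starts_p + width_p,
                        signal = config$background_signal_mean *
                          stats::runif(n_planted, 10, 20),
                        planted = TRUE)
  out <- rbind(bg, planted)
  out <- data.frame(chrom = config$chrom, out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a nucleus QC table and promoter-accessibility matrix
#'
#' Each nucleus gets a true fiber-type class; its promoter-window counts
#' are multinomial with `accessibility_effect`-fold mass on its own class
#' promoter. A planted fraction `qc_fail_frac` of nuclei violate exactly
#' one randomly chosen QC rule; all others pass every rule with margin.
#'
#' @param config A `sim_config`.
#' @param seed Random seed (defaults to `config$seed`).
#' @return List: `metrics` (`data.frame` with barcode, the five QC
#'   metrics, `true_class`, `planted_qc_fail`), `counts` (nucleus x class
#'   promoter count matrix).
#' @export
simulate_nucleus_matrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  classes <- names(config$n_nuclei)
  if (is.null(classes)) classes <- paste0("class", seq_along(config$n_nuclei))
  K <- length(classes)
  n <- sum(config$n_nuclei)
  true_class <- rep(classes, times = config$n_nuclei)
  depth <- stats::rnbinom(n, mu = config$nucleus_depth_mean, size = 10)
  counts <- matrix(0L, n, K, dimnames = list(NULL, classes))
  for (i in seq_len(n)) {
    p <- rep(1, K)
    p[match(true_class[i], classes)] <- config$accessibility_effect
    if (depth[i] > 0)
      counts[i, ] <- stats::rmultinom(1L, depth[i], p / sum(p))[, 1]
  }
  metrics <- data.frame(
    barcode = sprintf("nucleus_%04d", seq_len(n)),
    peak_region_fragments = round(stats::runif(n, 4000, 80000)),
    pct_reads_in_peaks = stats::runif(n, 30, 80),
    blacklist_ratio = stats::runif(n, 0, 0.02),
    nucleosome_signal = stats::runif(n, 0.2, 5),
    tss_enrichment = stats::runif(n, 3, 12),
    true_class = true_class)
  fail <- stats::runif(n) < config$qc_fail_frac
  rule <- sample.int(6L, n, replace = TRUE)
  bad <- which(fail)
  for (i in bad) {
    switch(rule[i],
           metrics$peak_region_fragments[i] <- round(stats::runif(1, 500, 3000)),
           metrics$peak_region_fragments[i] <- round(stats::runif(1, 100000, 150000)),
           metrics$pct_reads_in_peaks[i] <- stats::runif(1, 1, 15),
           metrics$blacklist_ratio[i] <- stats::runif(1, 0.025, 0.1),
           metrics$nucleosome_signal[i] <- stats::runif(1, 10, 20),
           metrics$tss_enrichment[i] <- stats::runif(1, 0, 2))
  }
  metrics$planted_qc_fail <- fail
  list(metrics = metrics, counts = counts)
}
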