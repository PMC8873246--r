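test_that("sim_config validates its stated-world invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(cutter_motif = "GAUC"), "alphabet")
  expect_error(sim_config(decay_exponent = 0), "decay_exponent")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(loop_enrichment = -0.1), "loop_enrichment")
  expect_error(sim_config(accessibility_effect = 0.5), "accessibility_effect")
  expect_error(sim_config(tad_boundaries = c(2e5, 1e5)), "increasing")
  expect_error(sim_config(tad_boundaries = c(1e5, 6e5)), "inside the genome")
  # SE straddling a TAD boundary is rejected
  expect_error(sim_config(se_interval = genomic_interval("chrS", 150000,
                                                         250000)),
               "exactly one TAD")
})

test_that("make_genome plants exactly the motifs it reports", {
  cfg <- tiny_config(seed = 2L)
  gen <- make_genome(cfg)
  expect_equal(nchar(gen$sequence), cfg$genome_length)
  # oracle: exhaustive scan of the emitted sequence
  expect_identical(as.numeric(scan_motif(gen$sequence, "GATC")),
                   gen$cut_sites)
  # mean spacing close to the configured value
  expect_equal(mean(diff(gen$cut_sites)), cfg$motif_spacing_mean,
               tolerance = 0.15)
  # determinism under a fixed seed
  gen2 <- make_genome(tiny_config(seed = 2L))
  expect_identical(gen$sequence, gen2$sequence)
  # a genome too short for any planted motif digests to one fragment
  tiny <- sim_config(genome_length = 60, motif_spacing_mean = 500,
                     tad_boundaries = c(20, 40),
                     se_interval = genomic_interval("chrS", 21, 39),
                     seed = 4L)
  g0 <- make_genome(tiny)
  expect_length(g0$cut_sites, 0L)
  expect_equal(nrow(digest_genome(g0$sequence, chrom = "chrS")), 1L)
})

test_that("simulate_4c draws from the stated decay model", {
  cfg <- tiny_config(seed = 5L, loop_enrichment = 0)
  gen <- make_genome(cfg)
  map <- digest_genome(gen$sequence, chrom = "chrS")
  lm <- locus_model(cfg, map)
  prof <- simulate_4c(cfg, map, lm$viewpoint, condition = "quadriceps")
  lam <- attr(prof, "lambda")
  # sum(lambda) = N to 1e-9 relative
  expect_equal(sum(lam), cfg$read_depth, tolerance = 1e-9)
  # oracle: direct evaluation of N * w_i / sum(w), alpha = 1, d0 = 1000
  mids <- (map$start + map$end) / 2
  vp_idx <- locate_viewpoint(map, lm$viewpoint)
  w <- (abs(mids - mids[vp_idx]) + 1000)^(-1)
  w[vp_idx] <- 0
  expect_equal(lam, cfg$read_depth * w / sum(w), tolerance = 1e-12)
  expect_equal(prof$values[vp_idx], 0)

  # loop enrichment multiplies SE-fragment weights in the active condition
  cfg2 <- tiny_config(seed = 5L, loop_enrichment = 1.5)
  in_se <- mids >= 50000 & mids < 70000
  lam_act <- attr(simulate_4c(cfg2, map, lm$viewpoint,
                              condition = "quadriceps"), "lambda")
  lam_ref <- attr(simulate_4c(cfg2, map, lm$viewpoint,
                              condition = "soleus"), "lambda")
  # both profiles renormalize to depth N, so the loop shows up as the
  # SE / non-SE double ratio, not as a raw per-fragment ratio
  r <- lam_act / lam_ref
  ok <- seq_along(r) != vp_idx
  expect_equal(unique(round(r[!in_se & ok], 12)), r[!in_se & ok][1])
  expect_equal(r[in_se] / r[!in_se & ok][1], rep(2.5, sum(in_se)),
               tolerance = 1e-9)

  # determinism; distinct seeds differ
  p1 <- simulate_4c(cfg, map, lm$viewpoint, seed = 77L)
  p2 <- simulate_4c(cfg, map, lm$viewpoint, seed = 77L)
  expect_identical(p1$values, p2$values)
  expect_false(identical(
    p1$values, simulate_4c(cfg, map, lm$viewpoint, seed = 78L)$values))

  # viewpoint resolution: spanning >1 fragment is an error
  wide <- genomic_interval("chrS", map$start[10], map$end[12])
  expect_error(simulate_4c(cfg, map, wide), "exactly one fragment")
})

test_that("negative-binomial noise approaches Poisson as dispersion grows", {
  cfg <- tiny_config(seed = 6L, dispersion = 1e9, loop_enrichment = 0)
  gen <- make_genome(cfg)
  map <- digest_genome(gen$sequence, chrom = "chrS")
  lm <- locus_model(cfg, map)
  frag <- locate_viewpoint(map, lm$viewpoint) + 5L  # a well-covered fragment
  set.seed(99)
  draws <- vapply(seq_len(10000), function(i)
    simulate_4c(cfg, map, lm$viewpoint, seed = NULL)$values[frag], 0)
  lam <- attr(simulate_4c(cfg, map, lm$viewpoint), "lambda")[frag]
  expect_gt(lam, 20)
  expect_equal(mean(draws), lam, tolerance = 0.05)
  expect_equal(var(draws), lam, tolerance = 0.08)  # Poisson limit: var = mean
})

test_that("under beta = 0 the two conditions are exchangeable over the SE", {
  w <- default_world(beta = 0)
  pp <- world_pair(w, seed_a = 301L, seed_b = 302L)
  signs <- classify_signs(pp$a, pp$b)
  in_se <- midfrag_in <- (w$map$start + w$map$end) / 2
  in_se <- in_se >= w$lm$se_region$start & in_se < w$lm$se_region$end
  frac_up <- mean(signs[in_se] == "increased")
  expect_gt(frac_up, 0.30)
  expect_lt(frac_up, 0.70)
})

test_that("enhancer landscape plants a heavy, tight, in-SE 7-peak cluster", {
  cfg <- sim_config(seed = 8L)
  pks <- simulate_enhancer_signal(cfg)
  planted <- pks[pks$planted, ]
  bg <- pks[!pks$planted, ]
  expect_equal(nrow(planted), 7L)
  expect_gte(nrow(bg), 30L)
  expect_true(all(planted$start >= cfg$se_interval$start &
                    planted$end <= cfg$se_interval$end))
  expect_true(all(diff(planted$start) - (planted$end[-7] - planted$start[-7])
                  < 12500))  # intra-cluster gaps under the stitch distance
  expect_true(all(planted$signal >= 10 * cfg$background_signal_mean))
  expect_gt(sum(planted$signal), max(bg$signal))
  # sorted, non-overlapping: O(n^2) pairwise scan
  for (i in seq_len(nrow(pks) - 1))
    for (j in (i + 1):nrow(pks))
      expect_true(pks$end[i] <= pks$start[j] || pks$end[j] <= pks$start[i])
  # determinism
  expect_identical(pks, simulate_enhancer_signal(sim_config(seed = 8L)))
  # SE too short for the cluster footprint
  short <- sim_config(se_interval = genomic_interval("chrS", 240000, 252000))
  expect_error(simulate_enhancer_signal(short), "too short")
})

test_that("nucleus matrix generator plants classes and QC violations", {
  cfg <- sim_config(seed = 10L)
  nm <- simulate_nucleus_matrix(cfg)
  expect_equal(nrow(nm$metrics), sum(cfg$n_nuclei))
  expect_equal(table(nm$metrics$true_class)[names(cfg$n_nuclei)],
               table(rep(names(cfg$n_nuclei), cfg$n_nuclei))[
                 names(cfg$n_nuclei)])
  expect_identical(colnames(nm$counts), names(cfg$n_nuclei))
  # planted violators are the qc_filter failures, close to qc_fail_frac
  qc <- qc_filter(nm$metrics)
  expect_identical(!qc$pass, nm$metrics$planted_qc_fail)
  expect_equal(mean(!qc$pass), cfg$qc_fail_frac, tolerance = 0.35)
  # uninformative accessibility: argmax accuracy is chance-like
  nm1 <- simulate_nucleus_matrix(sim_config(seed = 10L,
                                            accessibility_effect = 1))
  lab <- classify_fiber_type(score_promoters(nm1$counts), margin = 1)
  acc <- mean(lab == nm1$metrics$true_class)
  expect_gt(acc, 0.18)
  expect_lt(acc, 0.32)
  # determinism
  expect_identical(nm$counts,
                   simulate_nucleus_matrix(sim_config(seed = 10L))$counts)
})
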