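# Shared fixtures, all built in code.

# A uniform fragment map: n fragments of `width` bp on one contig.
uniform_map <- function(n, width = 100, chrom = "chr1") {
  bounds <- (0:n) * width
  regulocus:::new_fragment_map(chrom, bounds[-(n + 1)], bounds[-1],
                               blind = FALSE, seqlen = n * width,
                               first_cutter = "GATC")
}

# A raw profile with given values on a uniform map; viewpoint = fragment vp.
uniform_profile <- function(values, width = 100, vp = 1L,
                            condition = "A") {
  map <- uniform_map(length(values), width = width)
  four_c_profile(map, values,
                 genomic_interval(map$chrom[1], map$start[vp], map$end[vp]),
                 condition)
}

# Small simulation world: ~200 fragments, genes clear of the SE.
tiny_config <- function(...) {
  sim_config(genome_length = 1e5, tad_boundaries = c(30000, 90000),
             se_interval = genomic_interval("chrS", 50000, 70000),
             n_genes = 2, ...)
}

# Default stated world, built once per test run and cached.
.world_cache <- new.env(parent = emptyenv())
default_world <- function(beta = 1) {
  key <- paste0("beta", beta)
  if (is.null(.world_cache[[key]])) {
    cfg <- sim_config(seed = 11L, loop_enrichment = beta)
    gen <- make_genome(cfg)
    map <- digest_genome(gen$sequence, cfg$cutter_motif, chrom = gen$chrom)
    lm <- locus_model(cfg, map)
    .world_cache[[key]] <- list(cfg = cfg, gen = gen, map = map, lm = lm)
  }
  .world_cache[[key]]
}

# Normalized (unsmoothed) profile pair from the default world.
world_pair <- function(w, seed_a, seed_b) {
  a <- simulate_4c(w$cfg, w$map, w$lm$viewpoint,
                   condition = w$cfg$conditions[1], seed = seed_a)
  b <- simulate_4c(w$cfg, w$map, w$lm$viewpoint,
                   condition = w$cfg$conditions[2], seed = seed_b)
  list(a = normalize_to_region(mask_viewpoint(a), w$lm$reference),
       b = normalize_to_region(mask_viewpoint(b), w$lm$reference))
}

# Exhaustive 0-based motif scan (independent of Biostrings).
scan_motif <- function(sequence, motif) {
  L <- nchar(sequence); m <- nchar(motif)
  if (L < m) return(integer(0))
  hits <- vapply(seq_len(L - m + 1L), function(i)
    substring(sequence, i, i + m - 1L) == motif, TRUE)
  which(hits) - 1L
}

# Random non-degenerate 2x2 count table.
random_table <- function() {
  matrix(sample(1:80, 4, replace = TRUE), 2, 2)
}
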