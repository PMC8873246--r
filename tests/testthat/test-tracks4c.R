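test_that("mask_viewpoint masks the margin window and is idempotent", {
  p <- uniform_profile(rep(1, 20), width = 100, vp = 10)
  m0 <- mask_viewpoint(p, margin_bp = 0)
  expect_equal(which(m0$mask), 10L)  # margin 0: only the viewpoint fragment

  m <- mask_viewpoint(p, margin_bp = 250)
  # oracle: linear overlap scan against [vp_start - 250, vp_end + 250)
  map <- p$map
  win <- c(map$start[10] - 250, map$end[10] + 250)
  oracle <- which(map$start < win[2] & map$end > win[1])
  expect_equal(which(m$mask), oracle)
  expect_true(all(is.na(m$values[m$mask])))
  expect_identical(mask_viewpoint(m, 250)$mask, m$mask)  # idempotent

  expect_error(mask_viewpoint(p, margin_bp = -1), "margin")
})

test_that("normalize_to_region applies one exact multiplicative factor", {
  ref <- genomic_interval("chr1", 0, 2000)
  p <- mask_viewpoint(uniform_profile(rep(25, 20), vp = 1), 0)
  # unmasked reference sum = 19 * 25 = 475
  n1 <- normalize_to_region(p, ref, scale = 1e6)
  expect_equal(sum(n1$values[!n1$mask]), 1e6)
  # reference sum 500 with scale 1e6 -> every value x2000
  p2 <- mask_viewpoint(uniform_profile(c(0, rep(25, 20)), vp = 1), 0)
  n2 <- normalize_to_region(p2, genomic_interval("chr1", 0, 2100), 1e6)
  expect_equal(n2$values[2:21], rep(25 * 2000, 20))
  # already at scale: unchanged
  n3 <- normalize_to_region(mask_viewpoint(
    uniform_profile(c(0, rep(1e6 / 19, 19)), vp = 1), 0), ref)
  expect_equal(n3$values[-1], rep(1e6 / 19, 19))
  # two profiles share the reference sum after normalization
  set.seed(1)
  q1 <- normalize_to_region(mask_viewpoint(
    uniform_profile(rpois(20, 50), vp = 1), 0), ref)
  q2 <- normalize_to_region(mask_viewpoint(
    uniform_profile(rpois(20, 500), vp = 1), 0), ref)
  expect_equal(sum(q1$values, na.rm = TRUE), sum(q2$values, na.rm = TRUE))
  # degenerate reference
  z <- mask_viewpoint(uniform_profile(rep(0, 20), vp = 1), 0)
  expect_error(normalize_to_region(z, ref), "degenerate")
})

test_that("normalization is invariant to uniform rescaling of raw input", {
  set.seed(8)
  raw <- rpois(50, 40)
  ref <- genomic_interval("chr1", 0, 3000)
  norm_of <- function(v)
    normalize_to_region(mask_viewpoint(uniform_profile(v, vp = 25), 300),
                        ref)$values
  for (c in c(0.001, 3, 1e4))
    expect_equal(norm_of(raw * c), norm_of(raw), tolerance = 1e-9)
})

test_that("running_mean matches a brute-force windowed mean with masking", {
  set.seed(21)
  v <- rpois(60, 30)
  p <- normalize_to_region(
    mask_viewpoint(uniform_profile(v, vp = 30), 450),
    genomic_interval("chr1", 0, 6000))
  s <- running_mean(p, window = 11)
  h <- 5
  oracle <- p$values
  for (i in which(!p$mask)) {
    hi <- min(h, i - 1, 60 - i)
    acc <- c(); n_acc <- 0
    for (j in (i - hi):(i + hi)) if (!p$mask[j]) acc <- c(acc, p$values[j])
    oracle[i] <- mean(acc)
  }
  expect_equal(s$values, oracle, tolerance = 1e-12)
  expect_identical(s$mask, p$mask)
  expect_error(running_mean(p, window = 10), "odd")
})

test_that("running_mean preserves constants and linear ramps and is linear", {
  ref <- genomic_interval("chr1", 0, 4000)
  mk <- function(v) normalize_to_region(
    mask_viewpoint(uniform_profile(v, vp = 1), 0), ref)
  cst <- running_mean(mk(rep(7, 40)))
  expect_equal(unique(round(cst$values[-1], 12)), cst$values[2])
  ramp <- mk(c(0, 1:39))
  sm <- running_mean(ramp)
  # symmetric windows keep ramps wherever the window holds no masked fragment
  expect_equal(sm$values[7:40], ramp$values[7:40])
  # linearity on unmasked values
  set.seed(3)
  x <- rpois(40, 20); y <- rpois(40, 20)
  px <- mk(x); py <- mk(y)
  pxy <- px; pxy$values <- px$values + py$values
  expect_equal(running_mean(pxy)$values,
               running_mean(px)$values + running_mean(py)$values,
               tolerance = 1e-12)
})

test_that("ratio_track computes masked log2 ratios and checks maps", {
  ref <- genomic_interval("chr1", 0, 3000)
  mk <- function(v) running_mean(normalize_to_region(
    mask_viewpoint(uniform_profile(v, vp = 15), 100), ref))
  set.seed(4)
  a <- mk(rpois(30, 60)); b <- mk(rpois(30, 60))
  r <- ratio_track(a, b, pseudocount = 1)
  expect_equal(r$value, ifelse(a$mask | b$mask, NA_real_,
                               log2((a$values + 1) / (b$values + 1))),
               tolerance = 1e-12)
  r0 <- ratio_track(a, a)
  expect_equal(r0$value[!a$mask], rep(0, sum(!a$mask)))
  # a = 2b with vanishing pseudocount -> ratio -> 1
  b2 <- b; b2$values <- b$values
  a2 <- b; a2$values <- 2 * b$values
  r2 <- ratio_track(a2, b2, pseudocount = 1e-12)
  expect_equal(r2$value[!b$mask], rep(1, sum(!b$mask)), tolerance = 1e-6)
  # mismatched maps rejected
  other <- running_mean(normalize_to_region(mask_viewpoint(
    uniform_profile(rpois(30, 60), width = 99, vp = 15), 100),
    genomic_interval("chr1", 0, 2970)))
  expect_error(ratio_track(a, other), "different fragment maps")
  expect_error(ratio_track(a, b, pseudocount = 0), "pseudocount")
})

test_that("pipeline stage order is enforced", {
  p <- uniform_profile(rpois(20, 10), vp = 10)
  ref <- genomic_interval("chr1", 0, 2000)
  expect_error(normalize_to_region(p, ref), "stage")
  expect_error(running_mean(p), "stage")
  m <- mask_viewpoint(p, 0)
  expect_error(running_mean(m), "stage")
  n <- normalize_to_region(m, ref)
  s <- running_mean(n)
  expect_error(mask_viewpoint(s), "stage")
  expect_error(normalize_to_region(s, ref), "stage")
})
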