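#' Per-fragment sign classification between two conditions
#'
#' Compares the unsmoothed, reference-normalized signal of two profiles
#' fragment by fragment. The differential-contact test is defined on
#' normalized (never smoothed) values; passing a smoothed profile is an
#' error, not a warning.
#'
#' @param norm_a,norm_b `four_c_profile`s at stage `"normalized"` on the
#'   same fragment map.
#' @param tie_tol Absolute difference at or below which a fragment is
#'   tied. Default 0: only exact equality is a tie.
#' @return Character vector over
#'   `{"increased", "decreased", "tied", "masked"}`, one per fragment
#'   (condition A relative to condition B), with the fragment map attached
#'   as attribute `map`.
#' @export
classify_signs <- function(norm_a, norm_b, tie_tol = 0) {
  require_stage(norm_a, "normalized", "classify_signs")
  require_stage(norm_b, "normalized", "classify_signs")
  if (!same_fragment_map(norm_a$map, norm_b$map))
    stop("profiles are on different fragment maps")
  if (!is.numeric(tie_tol) || tie_tol < 0)
    stop("tie_tol must be >= 0")
  d <- norm_a$values - norm_b$values
  signs <- ifelse(d > tie_tol, "increased",
                  ifelse(-d > tie_tol, "decreased", "tied"))
  signs[norm_a$mask | norm_b$mask] <- "masked"
  structure(signs, map = norm_a$map)
}

#' Region-by-direction contingency table
#'
#' Tallies increased/decreased fragments (by midpoint) inside the
#' super-enhancer region (row 1) versus the remainder of the TAD (row 2).
#' Tied and masked fragments carry no directional evidence and are
#' excluded, as are fragments outside the TAD.
#'
#' @param signs Output of [classify_signs()].
#' @param se_region,tad_region [genomic_interval()]s with
#'   `se_region` contained in `tad_region`.
#' @return 2x2 integer matrix, rows `SE`/`TAD_rest`, columns
#'   `increased`/`decreased`.
#' @export
build_table <- function(signs, se_region, tad_region) {
  map <- attr(signs, "map")
  if (is.null(map)) stop("signs must come from classify_signs()")
  if (!interval_contains(tad_region, se_region))
    stop("se_region must be contained in tad_region")
  in_se <- midpoint_in_region(map$chrom, map$start, map$end, se_region)
  in_tad <- midpoint_in_region(map$chrom, map$start, map$end, tad_region)
  O <- matrix(0L, 2, 2,
              dimnames = list(region = c("SE", "TAD_rest"),
                              direction = c("increased", "decreased")))
  for (j in c("increased", "decreased")) {
    O["SE", j] <- sum(signs == j & in_se)
    O["TAD_rest", j] <- sum(signs == j & in_tad & !in_se)
  }
  O
}

#' G-test of independence on a 2x2 table
#'
#' Likelihood-ratio test `G = 2 * sum(O * ln(O / E))` with expected counts
#' `E_ij = row_i * col_j / N`, referred to the upper tail of the
#' chi-square distribution at 1 degree of freedom. Cells with zero
#' observed count contribute nothing to the sum. The optional Williams
#' correction divides G by
#' `q = 1 + (N/r1 + N/r2 - 1) * (N/c1 + N/c2 - 1) / (6N)`.
#'
#' @param O 2x2 matrix of non-negative observed counts.
#' @param williams Apply the Williams small-sample correction
#'   (default `FALSE`).
#' @return Object of class `g_test_result`: observed, expected, `G`,
#'   `df = 1`, `p`, `williams_corrected`.
#' @examples
#' g_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))  # G ~ 20.93
#' @export
g_test <- function(O, williams = FALSE) {
  if (!is.matrix(O) || !all(dim(O) == c(2L, 2L)))
    stop("O must be a 2x2 matrix")
  if (any(O < 0) || any(O != round(O)))
    stop("observed counts must be non-negative integers")
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a row or column margin is zero; ",
         "the comparison is uninformative")
  E <- outer(rs, cs) / N
  pos <- O > 0
  G <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  G <- max(G, 0)  # guard tiny negative rounding on proportional tables
  if (williams) {
    q <- 1 + (N / rs[1] + N / rs[2] - 1) * (N / cs[1] + N / cs[2] - 1) /
      (6 * N)
    G <- G / q
  }
  structure(list(observed = O, expected = E, G = unname(G), df = 1L,
                 p = stats::pchisq(unname(G), df = 1, lower.tail = FALSE),
                 williams_corrected = williams),
            class = "g_test_result")
}

#' @export
print.g_test_result <- function(x, ...) {
  cat("G-test of independence (df = 1",
      if (x$williams_corrected) ", Williams-corrected", ")\n", sep = "")
  print(x$observed)
  cat(sprintf("G = %.4f, p = %.4g\n", x$G, x$p))
  invisible(x)
}

#' Differential-contact test between two 4C profiles
#'
#' Composes [classify_signs()], [build_table()] and [g_test()]: classifies
#' every fragment of the TAD as increased or decreased between the two
#' conditions on unsmoothed normalized signal, tabulates directions for
#' the super-enhancer region against the remainder of the TAD, and tests
#' independence of region and direction.
#'
#' @param norm_a,norm_b Normalized (unsmoothed) `four_c_profile`s.
#' @param se_region,tad_region [genomic_interval()]s,
#'   `se_region` inside `tad_region`.
#' @param tie_tol Tie tolerance for [classify_signs()].
#' @param williams Williams correction for [g_test()].
#' @param out Optional path; when given, a TSV report (table, G, df, p,
#'   fraction increased per region) is written there.
#' @return List with elements `signs`, `table`, `test`
#'   (a `g_test_result`) and `frac_increased` (per region).
#' @export
run_difftest <- function(norm_a, norm_b, se_region, tad_region,
                         tie_tol = 0, williams = FALSE, out = NULL) {
  signs <- classify_signs(norm_a, norm_b, tie_tol = tie_tol)
  O <- build_table(signs, se_region, tad_region)
  res <- g_test(O, williams = williams)
  frac <- O[, "increased"] / rowSums(O)
  if (!is.null(out)) {
    rpt <- data.frame(
      region = rownames(O), increased = O[, "increased"],
      decreased = O[, "decreased"], frac_increased = frac,
      G = res$G, df = res$df, p = res$p, williams = williams)
    write_tsv(rpt, out)
  }
  list(signs = signs, table = O, test = res, frac_increased = frac)
}
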