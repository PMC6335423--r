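#' Alteration frequency with exact half-up rounding
#'
#' Computes the altered fraction and the percentage rounded half-up to
#' one decimal.  The rounding is done on the exact rational
#' `1000 * n_altered / n_total` in integer arithmetic, so no
#' floating-point representation artifact can flip the rounded digit.
#'
#' @param n_altered,n_total non-negative counts, `n_total >= 1`,
#'   `n_altered <= n_total`.
#' @return list with `n_altered`, `n_total`, `fraction`, `percent_1dp`.
#' @examples
#' alterationFrequency(14, 359)$percent_1dp  # 3.9
#' @export
alterationFrequency <- function(n_altered, n_total) {
  n_altered <- as.integer(n_altered)
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 1L)
    stop("n_total must be a positive count", call. = FALSE)
  if (is.na(n_altered) || n_altered < 0L || n_altered > n_total)
    stop("n_altered must lie in [0, n_total]", call. = FALSE)
  num <- 1000 * n_altered            # percent * 10, as an exact integer ratio
  q <- num %/% n_total
  r <- num %% n_total
  tenths <- q + as.integer(2 * r >= n_total)   # half-up
  list(n_altered = n_altered, n_total = n_total,
       fraction = n_altered / n_total, percent_1dp = tenths / 10)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Self-contained implementation by exhaustive hypergeometric
#' enumeration.  With margins fixed, every admissible table is indexed by
#' its top-left count k; the two-sided p-value is the sum of the point
#' probabilities of all tables no more probable than the observed one
#' (point-probability method).  A small relative tolerance (1e-7) on the
#' probability comparison guards against floating-point ties.  Degenerate
#' margins (an all-zero row or column) give p = 1 with a flag.
#'
#' @param table 2x2 matrix of non-negative counts, or the count `a` when
#'   `b`, `c`, `d` are given.
#' @param b,c,d remaining cells when `table` is scalar `a`.
#' @return list with `p_two_sided` and `degenerate`.
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2))$p_two_sided  # 34/70
#' @export
fisherExact2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    a <- table[1, 1]; bb <- table[1, 2]; cc <- table[2, 1]; dd <- table[2, 2]
  } else {
    a <- table; bb <- b; cc <- c; dd <- d
  }
  cnt <- c(a, bb, cc, dd)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("cells must be non-negative integers", call. = FALSE)
  m <- a + bb          # row 1 total
  n2 <- cc + dd        # row 2 total
  k <- a + cc          # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || (bb + dd) == 0)
    return(list(p_two_sided = 1, degenerate = TRUE))
  supp <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(m + n2, k)
  p_obs <- logp[supp == a]
  p <- sum(exp(logp)[logp <= p_obs + log1p(1e-7)])
  list(p_two_sided = min(p, 1), degenerate = FALSE)
}

# Shared 2x2 builder: rows = alteration present/absent, columns = group
# member/non-member, over a fixed sample universe.
.associationFrom2x2 <- function(a, b, c, d, rows = c("altered", "not_altered"),
                                cols = c("in_group", "not_in_group")) {
  tab <- matrix(as.integer(c(a, c, b, d)), nrow = 2,
                dimnames = list(rows, cols))
  ft <- fisherExact2x2(a, b, c, d)
  or <- (a * d) / (b * c)   # raw cross-product; 0/0 -> NaN
  zero_cell <- (b * c == 0) || (a * d == 0)
  dir <- if (is.nan(or) || or == 1) "none"
         else if (or > 1) "co_occurrence" else "exclusivity"
  new("AssociationResult", table = tab, p_two_sided = ft$p_two_sided,
      odds_ratio = or, direction = dir, zero_cell = zero_cell,
      degenerate = ft$degenerate)
}

#' Co-occurrence / mutual-exclusivity test for two alteration sets
#'
#' Builds the 2x2 table of sample membership (altered in gene A x altered
#' in gene B) over a fixed sample universe and applies
#' [fisherExact2x2()].  Direction is read off the raw odds ratio: >1
#' co-occurrence, <1 exclusivity, =1 (or undefined) none.
#'
#' @param samples_a,samples_b sample ids altered in each gene.
#' @param all_samples the sample universe; both sets must be subsets.
#' @return an [AssociationResult-class].
#' @export
cooccurrenceTest <- function(samples_a, samples_b, all_samples) {
  all_samples <- unique(all_samples)
  if (length(all_samples) == 0L)
    stop("empty sample universe", call. = FALSE)
  samples_a <- unique(samples_a)
  samples_b <- unique(samples_b)
  out <- setdiff(c(samples_a, samples_b), all_samples)
  if (length(out))
    stop("alteration set contains sample(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  a <- length(intersect(samples_a, samples_b))
  b <- length(setdiff(samples_a, samples_b))
  c <- length(setdiff(samples_b, samples_a))
  d <- length(all_samples) - a - b - c
  .associationFrom2x2(a, b, c, d, rows = c("A_altered", "A_wild"),
                      cols = c("B_altered", "B_wild"))
}

#' Subgroup enrichment test for an alteration
#'
#' As [cooccurrenceTest()] with the columns defined by membership in a
#' sample subgroup (e.g. activation-signature-high / luminal tumors).
#'
#' @param altered_samples samples carrying the alteration.
#' @param subgroup_samples the subgroup; must be a subset of
#'   `all_samples`.
#' @param all_samples the sample universe.
#' @return an [AssociationResult-class].
#' @export
subgroupEnrichment <- function(altered_samples, subgroup_samples,
                               all_samples) {
  all_samples <- unique(all_samples)
  if (length(all_samples) == 0L)
    stop("empty sample universe", call. = FALSE)
  subgroup_samples <- unique(subgroup_samples)
  if (length(setdiff(subgroup_samples, all_samples)))
    stop("subgroup_samples must be a subset of all_samples", call. = FALSE)
  altered_samples <- unique(altered_samples)
  if (length(setdiff(altered_samples, all_samples)))
    stop("altered_samples must be a subset of all_samples", call. = FALSE)
  a <- length(intersect(altered_samples, subgroup_samples))
  b <- length(setdiff(altered_samples, subgroup_samples))
  c <- length(setdiff(subgroup_samples, altered_samples))
  d <- length(all_samples) - a - b - c
  .associationFrom2x2(a, b, c, d, rows = c("altered", "not_altered"),
                      cols = c("subgroup", "rest"))
}
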