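#' Adjusted Rand index between two labelings
#'
#' Measures agreement between two partitions of the same objects, corrected
#' for chance; 1 means identical partitions (up to label permutation), 0 is
#' the expected value for independent random labelings.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return A single numeric value in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps (master seed, stage name) to an integer seed below
#' 2^31, so adding or removing a pipeline stage never perturbs the random
#' stream of another stage.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1000003
  as.integer((abs(master_seed) %% 1000003L) * 1009 + h) %% 2147483587L
}

# internal: stop with a message built by sprintf
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# internal: polynomial design row basis on ages mapped linearly to [-1, 1].
# Raw month powers (up to 18^3) are numerically hostile; the affine map makes
# the Gram matrices well conditioned and is shared by simulator and fitter.
scale_ages <- function(age_grid, anchor = range(age_grid)) {
  if (diff(anchor) <= 0) stop("age grid must span a positive range")
  2 * (age_grid - anchor[1]) / diff(anchor) - 1
}

poly_basis <- function(age_grid, degree, anchor = range(age_grid)) {
  s <- scale_ages(age_grid, anchor)
  outer(s, 0:degree, `^`)
}
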