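#' Signature-association scores for one dataset
#'
#' Projects a signed signature onto an expression dataset: every gene
#' present in the signature is z-scored across the dataset's samples, and a
#' sample's SA score is the unweighted mean over signature genes of the
#' direction-signed z-scores. Positive scores mean the sample expresses the
#' signature coordinately in its original direction, negative scores in the
#' opposite direction; the mean score across samples is always zero.
#'
#' @param dataset genes x samples expression matrix (at least 2 samples).
#' @param signature a \code{de_signature} or named +1/-1 vector.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present (and non-constant) in the dataset; below it the dataset is
#'   skipped: the function returns \code{NULL} with a warning.
#' @return A named numeric vector of per-sample scores with a
#'   \code{coverage} attribute, or \code{NULL} if coverage is insufficient.
#' @export
sa_scores <- function(dataset, signature, min_coverage = 0.5) {
  validate_expression_matrix(dataset)
  if (ncol(dataset) < 2L) fail("SA scoring needs at least 2 samples")
  signs <- signature_signs(signature)
  if (length(signs) == 0L) fail("signature must be non-empty")
  # duplicate gene rows cannot occur here (validated), but duplicate
  # signature entries could: first occurrence wins
  signs <- signs[!duplicated(names(signs))]
  present <- intersect(names(signs), rownames(dataset))
  sub <- dataset[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  usable <- present[sds > 0]
  coverage <- length(usable) / length(signs)
  if (coverage < min_coverage) {
    warning(sprintf("signature coverage %.2f below %.2f; dataset skipped",
                    coverage, min_coverage), call. = FALSE)
    return(NULL)
  }
  z <- (sub[usable, , drop = FALSE] - rowMeans(sub[usable, , drop = FALSE])) /
    sds[match(usable, present)]
  scores <- colMeans(as.numeric(signs[usable]) * z)
  attr(scores, "coverage") <- coverage
  scores
}

#' Two-sided Fisher exact p-value for a 2 x 2 table
#'
#' Exact two-sided p: with the margins fixed, the sum of hypergeometric
#' probabilities of all tables whose probability does not exceed that of the
#' observed table (with the conventional relative tolerance for
#' floating-point ties).
#'
#' @param table 2 x 2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- if (is.matrix(table)) as.numeric(t(table)) else as.numeric(table)
  if (length(x) != 4L || any(x < 0) || any(x != round(x)))
    fail("need a 2x2 table of non-negative integer counts")
  x <- as.integer(round(x))
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  m <- a + b            # first-row margin
  n <- c_ + d           # second-row margin
  k <- a + c_           # first-column margin
  if (m == 0L || n == 0L || k == 0L || b + d == 0L) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Scan a compendium for enrichment in strong signature-association scores
#'
#' Scores every sample of every dataset with [sa_scores()], pools the
#' absolute scores over all passing datasets, and calls a sample "strong"
#' when its absolute score reaches the pooled \code{strong_quantile}
#' quantile. Each dataset is then tested with a two-sided Fisher exact test
#' on the 2 x 2 table (strong / not strong) x (this dataset / all others),
#' with Benjamini-Hochberg q-values across datasets.
#'
#' @param datasets named list of expression matrices.
#' @param signature a \code{de_signature} or named +1/-1 vector.
#' @param strong_quantile pooled quantile of |SA| defining "strong"
#'   (default 0.90).
#' @param min_coverage per-dataset minimum signature coverage.
#' @return A data.frame sorted by p-value, one row per passing dataset:
#'   \code{dataset_id}, \code{n_samples}, \code{n_strong}, \code{coverage},
#'   \code{fisher_p}, \code{q_value}; per-sample scores are attached as the
#'   \code{"scores"} attribute (named list).
#' @export
scan_compendium <- function(datasets, signature, strong_quantile = 0.90,
                            min_coverage = 0.5) {
  if (strong_quantile < 0 || strong_quantile > 1)
    fail("strong_quantile must be in [0, 1]")
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset_%03d", seq_along(datasets))
  scores <- lapply(datasets, sa_scores, signature = signature,
                   min_coverage = min_coverage)
  passing <- !vapply(scores, is.null, logical(1))
  if (sum(passing) < 2L) fail("fewer than 2 datasets pass the coverage filter")
  scores <- scores[passing]
  pooled <- abs(unlist(scores, use.names = FALSE))
  threshold <- stats::quantile(pooled, strong_quantile, names = FALSE)
  strong <- lapply(scores, function(s) abs(s) >= threshold)
  total_strong <- sum(vapply(strong, sum, numeric(1)))
  total_samples <- length(pooled)
  rows <- lapply(names(scores), function(id) {
    ns <- sum(strong[[id]])
    n <- length(strong[[id]])
    tab <- matrix(c(ns, n - ns,
                    total_strong - ns, (total_samples - n) - (total_strong - ns)),
                  2L, 2L, byrow = TRUE)
    data.frame(dataset_id = id, n_samples = n, n_strong = ns,
               coverage = attr(scores[[id]], "coverage"),
               fisher_p = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$fisher_p)
  out <- out[order(out$fisher_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  attr(out, "strong_threshold") <- threshold
  out
}
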