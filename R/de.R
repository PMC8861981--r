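#' Sex-specific differential-expression screen
#'
#' For every gene, compares male against female samples pooled across all
#' time points with a two-sided Student's two-sample t test assuming equal
#' variances, on non-log-transformed expression values. Multiplicity is
#' controlled with Benjamini-Hochberg q-values over all genes in the matrix.
#'
#' @param matrix genes x samples expression matrix. A matrix whose
#'   \code{scale} attribute is \code{"log2"} is exponentiated to the linear
#'   scale first.
#' @param annot sample annotation with a \code{sex} column; only annotated
#'   samples are used.
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{mean_M}, \code{mean_F}, \code{ratio_MF} (male/female means, NA if
#'   \code{mean_F <= 0}), \code{t_stat}, \code{p_value}, \code{q_value}.
#' @export
sex_ttest <- function(matrix, annot) {
  validate_expression_matrix(matrix)
  annot <- validate_sample_annotation(annot)
  if (identical(attr(matrix, "scale"), "log2")) matrix <- 2^matrix
  annot <- annot[annot$sample_id %in% colnames(matrix), , drop = FALSE]
  m_ids <- annot$sample_id[annot$sex == "M"]
  f_ids <- annot$sample_id[annot$sex == "F"]
  n_m <- length(m_ids); n_f <- length(f_ids)
  if (n_m < 2L || n_f < 2L)
    fail("each sex needs at least 2 samples (have %d M, %d F)", n_m, n_f)
  Xm <- matrix[, m_ids, drop = FALSE]
  Xf <- matrix[, f_ids, drop = FALSE]
  mean_m <- rowMeans(Xm)
  mean_f <- rowMeans(Xf)
  ss_m <- rowSums((Xm - mean_m)^2)
  ss_f <- rowSums((Xf - mean_f)^2)
  df <- n_m + n_f - 2L
  sp2 <- (ss_m + ss_f) / df
  se <- sqrt(sp2 * (1 / n_m + 1 / n_f))
  t_stat <- ifelse(se > 0, (mean_m - mean_f) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  # zero pooled variance with unequal means: infinitely separated groups
  p[se == 0 & mean_m != mean_f] <- 0
  t_stat[se == 0 & mean_m != mean_f] <-
    sign(mean_m - mean_f)[se == 0 & mean_m != mean_f] * Inf
  data.frame(gene_id = rownames(matrix),
             mean_M = mean_m, mean_F = mean_f,
             ratio_MF = ifelse(mean_f > 0, mean_m / mean_f, NA_real_),
             t_stat = t_stat, p_value = p,
             q_value = benjamini_hochberg(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up false-discovery-rate adjustment (via
#' \code{stats::p.adjust}), returned in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\], same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    fail("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Extract a signed sex signature at an FDR threshold
#'
#' Selects genes with \code{q_value < threshold_q} and tags each with the
#' sign of its sex difference: +1 if expression is higher in males, -1 if
#' higher in females. Genes with exactly equal means carry no direction and
#' are excluded.
#'
#' @param records output of [sex_ttest()].
#' @param threshold_q FDR threshold in (0, 1\].
#' @return An object of class \code{"de_signature"}: list with
#'   \code{entries} (named vector of +1/-1), \code{threshold_q},
#'   \code{n_up}, \code{n_down}.
#' @export
extract_signature <- function(records, threshold_q) {
  if (threshold_q <= 0 || threshold_q > 1) fail("threshold_q must be in (0, 1]")
  keep <- records$q_value < threshold_q & records$mean_M != records$mean_F
  signs <- ifelse(records$mean_M[keep] > records$mean_F[keep], 1L, -1L)
  names(signs) <- records$gene_id[keep]
  structure(list(entries = signs, threshold_q = threshold_q,
                 n_up = sum(signs == 1L), n_down = sum(signs == -1L)),
            class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat(sprintf("sex signature at FDR q < %g: %d genes (%d up, %d down in males)\n",
              x$threshold_q, length(x$entries), x$n_up, x$n_down))
  invisible(x)
}

# accept a de_signature or a bare named sign vector
signature_signs <- function(signature) {
  signs <- if (inherits(signature, "de_signature")) signature$entries
  else signature
  if (length(signs) > 0 && (is.null(names(signs)) || !all(signs %in% c(-1, 1))))
    fail("signature must be a named vector of +1/-1 signs")
  signs
}

#' Write a signature to a two-column TSV (gene_id, sign)
#' @param signature a \code{de_signature} or named sign vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(signature, path) {
  signs <- signature_signs(signature)
  utils::write.table(data.frame(gene_id = names(signs), sign = as.integer(signs)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature from a two-column TSV
#' @param path path written by [write_signature()].
#' @return A \code{de_signature} (threshold recorded as NA).
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  signs <- as.integer(df$sign)
  names(signs) <- as.character(df$gene_id)
  if (!all(signs %in% c(-1L, 1L))) fail("signature signs must be +1 or -1")
  structure(list(entries = signs, threshold_q = NA_real_,
                 n_up = sum(signs == 1L), n_down = sum(signs == -1L)),
            class = "de_signature")
}
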