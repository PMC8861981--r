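#' Collapse replicates into gene-by-sex temporal profiles
#'
#' Averages expression over replicates within each (gene, sex, age) group,
#' producing one temporal profile per gene and sex on the observed age grid.
#' These profiles are the unit objects of the clustering stage: each sex's
#' profile of a gene is treated as a distinct object.
#'
#' @param matrix genes x samples expression matrix (see
#'   [read_expression_matrix()]).
#' @param annot sample annotation data.frame with \code{sample_id},
#'   \code{sex}, \code{age_months}, \code{replicate}.
#' @return A \code{profile_set}: list with \code{ids} (data.frame of
#'   \code{gene_id}, \code{sex}), \code{age_grid}, \code{values}
#'   (objects x T matrix) and \code{standardized = FALSE}.
#' @export
collapse_replicates <- function(matrix, annot) {
  validate_expression_matrix(matrix)
  annot <- validate_sample_annotation(annot)
  missing_samples <- setdiff(annot$sample_id, colnames(matrix))
  if (length(missing_samples) > 0L)
    fail("annotated sample '%s' absent from matrix", missing_samples[1L])
  age_grid <- sort(unique(annot$age_months))
  sexes <- intersect(c("M", "F"), unique(annot$sex))
  G <- nrow(matrix)
  for (sx in sexes) {
    for (a in age_grid) {
      if (!any(annot$sex == sx & annot$age_months == a))
        fail("no samples for sex %s at age %g months", sx, a)
    }
  }
  blocks <- lapply(sexes, function(sx) {
    prof <- vapply(age_grid, function(a) {
      cols <- annot$sample_id[annot$sex == sx & annot$age_months == a]
      rowMeans(matrix[, cols, drop = FALSE])
    }, numeric(G))
    if (G == 1L) prof <- base::matrix(prof, nrow = 1L)
    prof
  })
  values <- do.call(rbind, blocks)
  ids <- data.frame(gene_id = rep(rownames(matrix), times = length(sexes)),
                    sex = rep(sexes, each = G), stringsAsFactors = FALSE)
  rownames(values) <- paste(ids$gene_id, ids$sex, sep = ":")
  colnames(values) <- sprintf("age_%g", age_grid)
  structure(list(ids = ids, age_grid = age_grid, values = values,
                 standardized = FALSE, excluded = character(0)),
            class = "profile_set")
}

#' Construct a profile set from a plain matrix
#'
#' Convenience constructor for profiles that are already one value per
#' (object, age) — e.g. draws from [simulate_profiles()].
#'
#' @param values objects x T numeric matrix.
#' @param age_grid ages (strictly increasing), length \code{ncol(values)}.
#' @param ids optional data.frame with \code{gene_id} and \code{sex}.
#' @param standardized logical; whether rows are already centered/scaled.
#' @return A \code{profile_set}.
#' @export
profile_set <- function(values, age_grid, ids = NULL, standardized = FALSE) {
  values <- as.matrix(values)
  if (length(age_grid) != ncol(values)) fail("age_grid length must match columns")
  if (is.unsorted(age_grid, strictly = TRUE)) fail("age_grid must be strictly increasing")
  if (is.null(ids)) {
    nm <- rownames(values)
    if (is.null(nm)) nm <- sprintf("profile_%05d", seq_len(nrow(values)))
    ids <- data.frame(gene_id = nm, sex = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(ids = ids, age_grid = as.numeric(age_grid), values = values,
                 standardized = isTRUE(standardized), excluded = character(0)),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("profile_set: %d objects x %d ages (%s)%s\n",
              nrow(x$values), length(x$age_grid),
              paste(x$age_grid, collapse = ", "),
              if (x$standardized) ", standardized" else ""))
  if (length(x$excluded) > 0L)
    cat(sprintf("  %d degenerate profiles excluded\n", length(x$excluded)))
  invisible(x)
}

#' Standardize temporal profiles
#'
#' Centers each profile (one gene in one sex) by its own mean over the ages
#' and divides by its own sample standard deviation (denominator T-1),
#' making the clustering shape-based: two profiles differing only by an
#' affine transform become identical. Profiles with standard deviation below
#' \code{sd_floor} carry no shape information and are removed; their ids are
#' recorded in the \code{excluded} field.
#'
#' @param profiles an unstandardized \code{profile_set}.
#' @param scope \code{"profile"} (default) centers and scales every
#'   gene-by-sex profile by its own moments, making clustering purely
#'   shape-based; \code{"gene"} uses moments pooled over both sexes of the
#'   gene, so a between-sex level or amplitude difference is retained.
#' @param sd_floor minimum sample SD for a profile to be kept.
#' @return A standardized \code{profile_set}; with \code{scope = "profile"}
#'   every retained row has mean 0 and sample SD 1.
#' @export
standardize_profiles <- function(profiles, scope = c("profile", "gene"),
                                 sd_floor = 1e-8) {
  stopifnot(inherits(profiles, "profile_set"))
  scope <- match.arg(scope)
  if (profiles$standardized) fail("profiles are already standardized")
  if (length(profiles$age_grid) < 3L)
    fail("at least 3 time points are required for the polynomial model")
  if (scope == "profile") {
    mu <- rowMeans(profiles$values)
    sdv <- apply(profiles$values, 1L, stats::sd)
  } else {
    mu <- sdv <- numeric(nrow(profiles$values))
    for (g in unique(profiles$ids$gene_id)) {
      rows <- which(profiles$ids$gene_id == g)
      pooled <- as.numeric(profiles$values[rows, , drop = FALSE])
      mu[rows] <- mean(pooled)
      sdv[rows] <- stats::sd(pooled)
    }
  }
  keep <- sdv >= sd_floor
  excluded <- rownames(profiles$values)[!keep]
  values <- (profiles$values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  structure(list(ids = profiles$ids[keep, , drop = FALSE],
                 age_grid = profiles$age_grid, values = values,
                 standardized = TRUE, excluded = excluded),
            class = "profile_set")
}
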