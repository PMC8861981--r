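#' Read a gene-by-sample expression matrix from TSV
#'
#' The on-disk format is a plain tab-delimited table: a header row of sample
#' identifiers, a first column named \code{gene_id}, and a numeric body.
#' Comment lines starting with \code{#} (e.g. seed metadata written by
#' [write_expression_matrix()]) are skipped. Row and column order are
#' preserved exactly as on disk.
#'
#' @param path path to the TSV file.
#' @param scale_flag either \code{"linear"} or \code{"log2"}, recorded as the
#'   \code{scale} attribute of the returned matrix.
#' @return A numeric matrix with gene ids as rownames, sample ids as
#'   colnames, and a \code{scale} attribute.
#' @export
read_expression_matrix <- function(path, scale_flag = c("linear", "log2")) {
  scale_flag <- match.arg(scale_flag)
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) fail("expression matrix needs a gene_id column and at least one sample")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    fail("non-numeric value '%s' at row %d (gene '%s'), column %d (sample '%s')",
         body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], gene_ids[bad[1L, 1L]],
         bad[1L, 2L], sample_ids[bad[1L, 2L]])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "scale") <- scale_flag
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream stage relies on: unique gene and
#' sample identifiers and an all-finite numeric body.
#'
#' @param x numeric matrix with rownames (genes) and colnames (samples).
#' @return \code{x}, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) fail("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    fail("expression matrix must carry gene rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup) > 0L) fail("duplicate gene id: '%s'", dup[1L])
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup) > 0L) fail("duplicate sample id: '%s'", dup[1L])
  if (any(!is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    fail("non-finite value for gene '%s', sample '%s'",
         rownames(x)[idx[1L]], colnames(x)[idx[2L]])
  }
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 6 significant digits; [read_expression_matrix()]
#' recovers the matrix exactly at that precision. A comment header records
#' optional metadata (e.g. the simulation seed).
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param metadata optional named character vector written as `# key: value`
#'   comment lines.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(x, path, metadata = NULL) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), as.character(metadata)), con)
  }
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(signif(x, 6L), 2L, format, trim = TRUE, scientific = FALSE, digits = 15L)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  writeLines(paste(rownames(x), apply(body, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Requires columns \code{sample_id}, \code{sex}, \code{age_months} and
#' \code{replicate}; extra columns are kept. Sex tokens are normalized to
#' \code{M}/\code{F} (accepting e.g. "male", "f", case-insensitively).
#'
#' @param path path to the TSV file.
#' @return A data.frame with typed columns.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_annotation(df)
}

#' Validate (and normalize) a sample annotation table
#'
#' @param df data.frame with at least sample_id, sex, age_months, replicate.
#' @return The validated data.frame with sex normalized to \code{M}/\code{F}.
#' @export
validate_sample_annotation <- function(df) {
  required <- c("sample_id", "sex", "age_months", "replicate")
  missing_col <- setdiff(required, colnames(df))
  if (length(missing_col) > 0L) fail("missing required column: '%s'", missing_col[1L])
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) fail("duplicate sample id: '%s'", dup[1L])
  sex <- toupper(trimws(as.character(df$sex)))
  sex[sex %in% c("M", "MALE")] <- "M"
  sex[sex %in% c("F", "FEMALE")] <- "F"
  bad <- setdiff(unique(sex), c("M", "F"))
  if (length(bad) > 0L) fail("unknown sex token: '%s'", bad[1L])
  df$sex <- sex
  df$age_months <- as.numeric(df$age_months)
  if (any(is.na(df$age_months) | df$age_months <= 0))
    fail("age_months must be positive and numeric")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate) | df$replicate < 1L))
    fail("replicate must be a positive integer")
  df
}

#' Write a sample annotation table to TSV
#' @param df annotation data.frame.
#' @param path output path.
#' @param metadata optional named character vector of comment-header metadata.
#' @return \code{path}, invisibly.
#' @export
write_sample_annotation <- function(df, path, metadata = NULL) {
  df <- validate_sample_annotation(df)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), as.character(metadata)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited fields
#' \code{name}, \code{description}, then one or more gene identifiers.
#' Duplicate genes within a set are removed; identifier matching throughout
#' the package is exact, case-sensitive string equality.
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors with a \code{descriptions}
#'   attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) fail("GMT line %d has fewer than 3 fields", i)
    name <- fields[1L]
    if (name %in% names(sets)) fail("duplicate gene set name '%s' at line %d", name, i)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) fail("GMT line %d ('%s') has an empty gene list", i, name)
    sets[[name]] <- genes
    descriptions[[name]] <- fields[2L]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @return \code{path}, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    fail("gene sets must have unique names")
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "NA"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fitted cluster model to JSON
#'
#' Dumps mixing proportions, fixed-effect coefficients, random-effect
#' covariances, residual variance, design matrices, the objective trace and
#' fit metadata so a fit can be archived and reloaded without refitting.
#'
#' @param model an object of class \code{"epem"} (see [epem()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "epem"))
  dump <- list(
    K = model$K,
    pi = model$pi,
    beta = model$beta,
    D = model$D,
    sigma2 = model$sigma2,
    age_grid = model$age_grid,
    X = model$X,
    Z = model$Z,
    objective_trace = model$objective_trace,
    converged = model$converged,
    n_objects = model$n_objects,
    lambda = model$lambda,
    seed = model$seed
  )
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted cluster model from JSON
#' @param path path written by [write_cluster_model()].
#' @return An object of class \code{"epem"} (without responsibilities).
#' @export
read_cluster_model <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  dump <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    K = as.integer(dump$K),
    pi = as.numeric(dump$pi),
    beta = matrix(as.numeric(dump$beta), nrow = dump$K),
    D = lapply(seq_len(dump$K), function(k) {
      d <- dump$D
      if (is.list(d)) matrix(as.numeric(d[[k]]), 3L, 3L)
      else matrix(as.numeric(d[k, , ]), 3L, 3L)
    }),
    sigma2 = as.numeric(dump$sigma2),
    age_grid = as.numeric(dump$age_grid),
    X = matrix(as.numeric(dump$X), ncol = 4L),
    Z = matrix(as.numeric(dump$Z), ncol = 3L),
    objective_trace = as.numeric(dump$objective_trace),
    converged = isTRUE(dump$converged),
    n_objects = as.integer(dump$n_objects),
    lambda = as.numeric(dump$lambda),
    seed = if (is.null(dump$seed)) NA_integer_ else as.integer(dump$seed)
  )
  class(model) <- "epem"
  model
}

#' Write a male-by-female cluster cross-tabulation to TSV
#'
#' Rows are male cluster labels, columns female cluster labels, matching the
#' orientation used for reporting concordant/discordant temporal profiles.
#'
#' @param tab K x K integer matrix from [cross_tabulate()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_crosstab <- function(tab, path) {
  df <- data.frame(male_cluster = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a male-by-female cluster cross-tabulation from TSV
#' @param path path written by [write_crosstab()] (first column male labels,
#'   header female labels).
#' @return A K x K integer matrix with labeled dimnames.
#' @export
read_crosstab <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  tab <- as.matrix(df[, -1L, drop = FALSE])
  rownames(tab) <- as.character(df[[1L]])
  storage.mode(tab) <- "integer"
  if (any(is.na(tab)) || any(tab < 0L)) fail("cross-tabulation must be non-negative integers")
  tab
}
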