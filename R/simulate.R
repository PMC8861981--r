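#' Configuration for the synthetic time-course study generator
#'
#' Defines the generative model that the clustering stage assumes: each
#' gene-by-sex temporal profile belongs to one of \code{K_true} clusters with
#' a cubic mean curve \eqn{x(t)'\beta_k} on age mapped linearly to
#' \eqn{[-1,1]}, a gene-specific quadratic random-effect deviation
#' \eqn{z(t)'b, b \sim N(0, D_k)}, and i.i.d. Gaussian replicate noise
#' \eqn{N(0, \sigma^2)}. A configurable fraction of genes is sex-discordant:
#' the female profile is drawn from a different cluster than the male one.
#'
#' The defaults emulate the study design this package targets: 2 sexes,
#' ages 3/6/9/12/18 months, 4 replicates per sex-age group, and four
#' well-separated standardized cluster shapes (rising, falling, mid-life
#' peak, mid-life trough).
#'
#' @param n_genes number of genes.
#' @param K_true true number of clusters.
#' @param age_grid ordered ages in months.
#' @param n_replicates replicates per sex-age group.
#' @param beta_true K_true x 4 cubic fixed-effect coefficients (intercept,
#'   linear, quadratic, cubic on scaled age).
#' @param D_true list of K_true 3 x 3 PSD random-effect covariance matrices.
#' @param sigma2_true replicate noise variance (standardized scale).
#' @param pi_true cluster mixing proportions (sums to 1).
#' @param discordant_fraction probability that a gene's female cluster is
#'   redrawn uniformly from the other clusters.
#' @param baseline_mean,baseline_sd median per-gene baseline and scale of the
#'   affine map from the standardized scale to expression scale
#'   (\code{expr = m_g + s_g * value}).
#' @param baseline_cv lognormal coefficient of spread of per-gene baselines;
#'   0 makes the affine map deterministic (\code{m_g = baseline_mean},
#'   \code{s_g = baseline_sd}).
#' @param seed integer seed; all outputs are deterministic given it.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 1000L,
                       K_true = 4L,
                       age_grid = c(3, 6, 9, 12, 18),
                       n_replicates = 4L,
                       beta_true = NULL,
                       D_true = NULL,
                       sigma2_true = 0.05,
                       pi_true = NULL,
                       discordant_fraction = 0.3,
                       baseline_mean = 100,
                       baseline_sd = 10,
                       baseline_cv = 0.25,
                       seed = 1L) {
  if (is.null(beta_true)) {
    # default curves are standardized to mean 0, SD 1 on the age grid: the
    # clustering operates on per-profile standardized data, so cluster mean
    # curves live on that scale (equal amplitudes also keep the replicate
    # noise level comparable across clusters after standardization)
    beta_true <- default_cluster_curves(K_true)
    X <- poly_basis(as.numeric(age_grid), 3L)
    XtX_inv_Xt <- solve(crossprod(X), t(X))
    for (k in seq_len(as.integer(K_true))) {
      v <- as.numeric(X %*% beta_true[k, ])
      v <- (v - mean(v)) / stats::sd(v)
      beta_true[k, ] <- as.numeric(XtX_inv_Xt %*% v)
    }
  }
  if (is.null(D_true)) {
    D_true <- rep(list(diag(c(0.05, 0.02, 0.01))), K_true)
  }
  if (is.null(pi_true)) pi_true <- rep(1 / K_true, K_true)
  cfg <- list(n_genes = as.integer(n_genes), K_true = as.integer(K_true),
              age_grid = as.numeric(age_grid),
              n_replicates = as.integer(n_replicates),
              beta_true = beta_true, D_true = D_true,
              sigma2_true = sigma2_true, pi_true = pi_true,
              discordant_fraction = discordant_fraction,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              baseline_cv = baseline_cv, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# four standardized-scale cluster shapes; extra clusters are phase-shifted
# linear ramps so any K_true has distinct curves
default_cluster_curves <- function(K_true) {
  base <- rbind(
    c( 0.0,  1.3,  0.0, 0),   # rising
    c( 0.0, -1.3,  0.0, 0),   # falling
    c( 0.9,  0.0, -1.7, 0),   # mid-life peak
    c(-0.9,  0.0,  1.7, 0))   # mid-life trough
  if (K_true <= 4L) return(base[seq_len(K_true), , drop = FALSE])
  extra <- t(vapply(seq_len(K_true - 4L), function(j) {
    c(0.3 * j, 1.3 * cos(j), -0.5 * j, 1.5 * sin(j + 1))
  }, numeric(4)))
  rbind(base, extra)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) fail("n_genes must be positive")
  if (cfg$K_true < 1L) fail("K_true must be positive")
  if (cfg$K_true == 1L && cfg$discordant_fraction > 0)
    fail("discordant_fraction > 0 requires K_true > 1")
  if (cfg$discordant_fraction < 0 || cfg$discordant_fraction > 1)
    fail("discordant_fraction must be in [0, 1]")
  if (abs(sum(cfg$pi_true) - 1) > 1e-12) fail("pi_true must sum to 1")
  if (any(cfg$pi_true < 0)) fail("pi_true must be non-negative")
  if (cfg$sigma2_true < 0) fail("sigma2_true must be non-negative")
  if (length(cfg$pi_true) != cfg$K_true) fail("pi_true must have length K_true")
  if (nrow(cfg$beta_true) != cfg$K_true || ncol(cfg$beta_true) != 4L)
    fail("beta_true must be K_true x 4")
  if (length(cfg$D_true) != cfg$K_true) fail("D_true must have K_true matrices")
  for (D in cfg$D_true) {
    if (!isTRUE(all.equal(D, t(D)))) fail("each D_true must be symmetric")
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      fail("each D_true must be positive semi-definite")
  }
  if (is.unsorted(cfg$age_grid, strictly = TRUE)) fail("age_grid must be strictly increasing")
  invisible(cfg)
}

#' Simulate a two-sex longitudinal expression study
#'
#' Draws, for each gene, a male cluster from \code{pi_true}; with probability
#' \code{discordant_fraction} the female cluster is redrawn uniformly from
#' the remaining clusters, otherwise it equals the male one. Each gene-by-sex
#' profile gets its own random-effect draw (discordant or not), replicate
#' noise is added per sample, and values are mapped to expression scale by a
#' per-gene affine transform with lognormal baselines.
#'
#' @param config a [sim_config()] object.
#' @return A list with components \code{matrix} (genes x samples expression
#'   matrix, linear scale), \code{annotation} (sample annotation data.frame)
#'   and \code{truth} (per-gene data.frame: \code{gene_id},
#'   \code{male_cluster}, \code{female_cluster}, \code{discordant}, plus the
#'   random-effect draws as a \code{b_male}/\code{b_female} attribute).
#' @export
simulate_timecourse_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  Tt <- length(config$age_grid)
  R <- config$n_replicates
  K <- config$K_true
  X <- poly_basis(config$age_grid, 3L)
  Z <- poly_basis(config$age_grid, 2L)

  male_cluster <- sample.int(K, G, replace = TRUE, prob = config$pi_true)
  discordant <- stats::runif(G) < config$discordant_fraction
  female_cluster <- male_cluster
  if (any(discordant)) {
    female_cluster[discordant] <- vapply(male_cluster[discordant], function(k) {
      sample(setdiff(seq_len(K), k), 1L)
    }, integer(1))
  }

  gene_ids <- sprintf("gene_%05d", seq_len(G))
  sexes <- c("M", "F")
  annotation <- expand.grid(replicate = seq_len(R), age_months = config$age_grid,
                            sex = sexes, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  annotation <- annotation[, c("sex", "age_months", "replicate")]
  annotation$sample_id <- sprintf("%s_%gm_r%d", annotation$sex,
                                  annotation$age_months, annotation$replicate)
  annotation <- annotation[, c("sample_id", "sex", "age_months", "replicate")]

  chol_D <- lapply(config$D_true, function(D) {
    ev <- eigen(D, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(D)) %*% t(ev$vectors)
  })

  # per-(gene, sex) random-effect draws and standardized-scale profiles
  draw_profiles <- function(clusters) {
    b <- matrix(0, G, 3L)
    prof <- matrix(0, G, Tt)
    for (k in seq_len(K)) {
      idx <- which(clusters == k)
      if (length(idx) == 0L) next
      b[idx, ] <- matrix(stats::rnorm(length(idx) * 3L), ncol = 3L) %*% chol_D[[k]]
      prof[idx, ] <- matrix(X %*% config$beta_true[k, ], length(idx), Tt,
                            byrow = TRUE) + b[idx, ] %*% t(Z)
    }
    list(b = b, prof = prof)
  }
  male <- draw_profiles(male_cluster)
  female <- draw_profiles(female_cluster)

  # per-gene affine map to expression scale
  if (config$baseline_cv > 0) {
    sdlog <- sqrt(log(1 + config$baseline_cv^2))
    m_g <- stats::rlnorm(G, meanlog = log(config$baseline_mean) - sdlog^2 / 2,
                         sdlog = sdlog)
    s_g <- config$baseline_sd * m_g / config$baseline_mean
  } else {
    m_g <- rep(config$baseline_mean, G)
    s_g <- rep(config$baseline_sd, G)
  }

  values <- matrix(0, G, nrow(annotation))
  for (j in seq_len(nrow(annotation))) {
    prof <- if (annotation$sex[j] == "M") male$prof else female$prof
    t_idx <- match(annotation$age_months[j], config$age_grid)
    eps <- stats::rnorm(G, sd = sqrt(config$sigma2_true))
    values[, j] <- m_g + s_g * (prof[, t_idx] + eps)
  }
  dimnames(values) <- list(gene_ids, annotation$sample_id)
  attr(values, "scale") <- "linear"

  truth <- data.frame(gene_id = gene_ids, male_cluster = male_cluster,
                      female_cluster = female_cluster, discordant = discordant,
                      stringsAsFactors = FALSE)
  attr(truth, "b_male") <- male$b
  attr(truth, "b_female") <- female$b
  list(matrix = values, annotation = annotation, truth = truth)
}

#' Simulate standardized-scale profiles directly from the mixture model
#'
#' Lower-level generator used for parameter-recovery studies: draws \code{N}
#' profiles \eqn{y = X\beta_k + Zb + \epsilon} without the study layout or
#' expression-scale mapping.
#'
#' @param beta K x 4 fixed-effect coefficients.
#' @param D list of K 3 x 3 PSD covariance matrices.
#' @param sigma2 residual variance (a scalar, or one value per cluster).
#' @param pi mixing proportions.
#' @param n number of profiles.
#' @param age_grid ages defining the design matrices.
#' @param seed integer seed.
#' @return A list with \code{values} (n x T matrix), \code{labels} (true
#'   cluster per profile) and \code{age_grid}.
#' @export
simulate_profiles <- function(beta, D, sigma2, pi, n, age_grid = c(3, 6, 9, 12, 18),
                              seed = 1L) {
  stopifnot(nrow(beta) == length(D), length(pi) == nrow(beta))
  set.seed(seed)
  K <- nrow(beta)
  X <- poly_basis(age_grid, 3L)
  Z <- poly_basis(age_grid, 2L)
  Tt <- length(age_grid)
  sigma2 <- rep_len(sigma2, K)
  labels <- sample.int(K, n, replace = TRUE, prob = pi)
  values <- matrix(stats::rnorm(n * Tt), n, Tt)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (length(idx) == 0L) next
    ev <- eigen(D[[k]], symmetric = TRUE)
    half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3L) %*% t(ev$vectors)
    b <- matrix(stats::rnorm(length(idx) * 3L), ncol = 3L) %*% half
    values[idx, ] <- values[idx, ] * sqrt(sigma2[k]) +
      matrix(X %*% beta[k, ], length(idx), Tt, byrow = TRUE) + b %*% t(Z)
  }
  rownames(values) <- sprintf("profile_%05d", seq_len(n))
  list(values = values, labels = labels, age_grid = age_grid)
}

#' Simulate a compendium of expression datasets with an embedded signature
#'
#' Builds \code{n_datasets} independent Gaussian-noise datasets, each
#' containing all signature genes plus decoys. In \code{n_embedded} of them,
#' half the samples are shifted by \code{effect_delta * sign} on the
#' signature genes, emulating a series in which the signature is coordinately
#' regulated.
#'
#' @param signature a signed signature (see [extract_signature()]), or a
#'   named numeric vector of +1/-1 gene signs.
#' @param n_datasets number of datasets.
#' @param n_embedded number of datasets carrying the embedded signal.
#' @param n_samples samples per dataset.
#' @param effect_delta shift applied to signature genes (in within-dataset
#'   standard-deviation units; 0 makes embedded datasets pure noise).
#' @param n_decoys decoy genes per dataset (default: as many as the
#'   signature has).
#' @param seed integer seed.
#' @return A named list of expression matrices; embedded dataset ids carry
#'   the prefix \code{"embedded"}.
#' @export
simulate_compendium <- function(signature, n_datasets, n_embedded, n_samples,
                                effect_delta, n_decoys = NULL, seed = 1L) {
  signs <- signature_signs(signature)
  if (length(signs) == 0L) fail("signature must be non-empty")
  if (n_embedded > n_datasets) fail("n_embedded must not exceed n_datasets")
  if (n_datasets == 0L) return(list())
  if (is.null(n_decoys)) n_decoys <- length(signs)
  set.seed(seed)
  G <- length(signs) + n_decoys
  gene_ids <- c(names(signs), sprintf("decoy_%04d", seq_len(max(n_decoys, 0L))))
  out <- vector("list", n_datasets)
  ids <- character(n_datasets)
  for (d in seq_len(n_datasets)) {
    values <- matrix(stats::rnorm(G * n_samples), G, n_samples)
    embedded <- d <= n_embedded
    if (embedded && effect_delta != 0) {
      shifted <- seq_len(floor(n_samples / 2))
      values[seq_along(signs), shifted] <- values[seq_along(signs), shifted] +
        effect_delta * as.numeric(signs)
    }
    ids[d] <- if (embedded) sprintf("embedded_%03d", d) else sprintf("null_%03d", d)
    dimnames(values) <- list(gene_ids, sprintf("%s_s%03d", ids[d], seq_len(n_samples)))
    attr(values, "scale") <- "linear"
    out[[d]] <- values
  }
  names(out) <- ids
  out
}
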