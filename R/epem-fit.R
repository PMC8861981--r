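#' Marginal log-likelihood of one temporal profile under one cluster
#'
#' Computes the exact Gaussian log-density of a profile under the
#' polynomial mixed-effects model of cluster \eqn{k}:
#' \deqn{y \sim N(X\beta_k,\; Z D_k Z' + \sigma^2 I).}
#' The cubic fixed-effect curve \eqn{X\beta_k} is the cluster mean
#' trajectory; the quadratic random effect with covariance \eqn{D_k}
#' models gene-specific heterogeneity within the cluster.
#'
#' @param y length-T numeric profile.
#' @param beta_k length-4 fixed-effect coefficients.
#' @param D_k 3 x 3 PSD random-effect covariance.
#' @param sigma2 residual variance.
#' @param X T x 4 fixed-effect design matrix.
#' @param Z T x 3 random-effect design matrix.
#' @return The log-density (a single numeric value).
#' @export
profile_loglik <- function(y, beta_k, D_k, sigma2, X, Z) {
  Tt <- length(y)
  stopifnot(nrow(X) == Tt, ncol(X) == 4L, nrow(Z) == Tt, ncol(Z) == 3L,
            length(beta_k) == 4L, all(dim(D_k) == c(3L, 3L)), sigma2 > 0)
  V <- Z %*% D_k %*% t(Z) + diag(sigma2, Tt)
  U <- tryCatch(chol(V), error = function(e)
    fail("profile covariance is not positive definite"))
  e <- y - as.numeric(X %*% beta_k)
  w <- backsolve(U, e, transpose = TRUE)
  -0.5 * (Tt * log(2 * pi) + 2 * sum(log(diag(U))) + sum(w^2))
}

#' Control parameters for the entropy-penalized EM fit
#'
#' @param lambda entropy-penalty weight \eqn{\lambda \ge 0}; the penalized
#'   objective is \eqn{J = \ell + \lambda N \sum_k \pi_k \log \pi_k}, which
#'   rewards low-entropy mixing proportions and drives superfluous clusters'
#'   weights toward zero.
#' @param prune_threshold minimum effective size \eqn{\pi_k N} for a cluster
#'   to be kept; smaller clusters are removed (subject to the ascent guard)
#'   and the proportions renormalized.
#' @param tol relative convergence tolerance: iteration stops once the
#'   penalized objective changes by less than \code{tol * (1 + |J|)}.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of seeded restarts; the fit with the best final
#'   objective is kept.
#' @param variance_floor lower bound applied to \eqn{\sigma^2} and to the
#'   eigenvalues of each \eqn{D_k}, preventing degenerate likelihood blow-up
#'   on noise-free data.
#' @param anneal logical; if \code{TRUE}, \eqn{\lambda} is annealed linearly
#'   to 0 over the first half of the iterations, so pruning happens early and
#'   the fit finishes as pure maximum likelihood.
#' @param pooled_sigma2 logical; if \code{TRUE} (default), a single residual
#'   variance is shared by all clusters — five time points cannot reliably
#'   identify a per-cluster residual variance alongside a full 3 x 3
#'   random-effect covariance. \code{FALSE} fits one \eqn{\sigma^2_k} per
#'   cluster, useful when clusters are expected to carry unequal noise.
#'
#' For per-profile standardized data a penalty of \code{lambda} around
#' 0.2-0.5 is advisable: standardization makes the within-cluster noise
#' anisotropic (it removes variance along the profile mean and amplitude
#' directions), which an isotropic-plus-quadratic covariance cannot fully
#' represent; a weak penalty then lets the mixture split genuine clusters to
#' soak up the misfit.
#' @return A list of class \code{"epem_control"}.
#' @export
epem_control <- function(lambda = 0.1, prune_threshold = 1.0, tol = 1e-5,
                         max_iter = 400L, n_restarts = 10L,
                         variance_floor = 1e-6, anneal = TRUE,
                         pooled_sigma2 = TRUE) {
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1L, n_restarts >= 1L,
            variance_floor > 0)
  structure(list(lambda = lambda, prune_threshold = prune_threshold, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 variance_floor = variance_floor, anneal = isTRUE(anneal),
                 pooled_sigma2 = isTRUE(pooled_sigma2)),
            class = "epem_control")
}

# N x K matrix of per-cluster log-densities (vectorized profile_loglik)
epem_logf <- function(Y, beta, D, sigma2, X, Z) {
  N <- nrow(Y); Tt <- ncol(Y); K <- nrow(beta)
  sigma2 <- rep_len(sigma2, K)
  logf <- matrix(0, N, K)
  for (k in seq_len(K)) {
    V <- Z %*% D[[k]] %*% t(Z) + diag(sigma2[k], Tt)
    U <- chol(V)
    E <- Y - matrix(X %*% beta[k, ], N, Tt, byrow = TRUE)
    W <- E %*% backsolve(U, diag(Tt))
    logf[, k] <- -0.5 * (Tt * log(2 * pi) + 2 * sum(log(diag(U))) +
                           rowSums(W * W))
  }
  logf
}

# penalized objective J(pi) given log-densities; components with pi = 0 are
# excluded from both mixture and penalty
epem_objective <- function(logf, pi, lambda) {
  act <- pi > 0
  Lw <- logf[, act, drop = FALSE] +
    matrix(log(pi[act]), nrow(logf), sum(act), byrow = TRUE)
  m <- apply(Lw, 1L, max)
  ll <- sum(m + log(rowSums(exp(Lw - m))))
  ll + lambda * nrow(logf) * sum(pi[act] * log(pi[act]))
}

epem_responsibilities <- function(logf, pi) {
  Lw <- logf + matrix(log(pi), nrow(logf), length(pi), byrow = TRUE)
  m <- apply(Lw, 1L, max)
  r <- exp(Lw - m)
  r / rowSums(r)
}

# one M-step for (beta, D, sigma2) from posterior random-effect moments at
# the current parameters: the classical EM update for mixtures of linear
# mixed models, guaranteed not to decrease the observed-data likelihood
epem_mstep_theta <- function(Y, r, beta, D, sigma2, X, Z, variance_floor,
                             pooled_sigma2 = FALSE) {
  N <- nrow(Y); Tt <- ncol(Y); K <- ncol(r)
  sigma2 <- rep_len(sigma2, K)
  XtX_inv_Xt <- solve(crossprod(X), t(X))
  beta_new <- beta
  D_new <- D
  rss_k <- numeric(K)
  n_k <- colSums(r)
  for (k in seq_len(K)) {
    if (n_k[k] < 1e-10) next
    V <- Z %*% D[[k]] %*% t(Z) + diag(sigma2[k], Tt)
    Vinv <- chol2inv(chol(V))
    A <- D[[k]] %*% t(Z) %*% Vinv                       # 3 x T
    S <- D[[k]] - A %*% Z %*% D[[k]]                    # posterior covariance
    E <- Y - matrix(X %*% beta[k, ], N, Tt, byrow = TRUE)
    B <- E %*% t(A)                                     # posterior means, N x 3
    rk <- r[, k]
    ybar <- colSums(rk * Y) / n_k[k]
    bbar <- colSums(rk * B) / n_k[k]
    beta_new[k, ] <- as.numeric(XtX_inv_Xt %*% (ybar - Z %*% bbar))
    Dk <- crossprod(B, rk * B) / n_k[k] + S
    Dk <- (Dk + t(Dk)) / 2
    ev <- eigen(Dk, symmetric = TRUE)
    D_new[[k]] <- ev$vectors %*% diag(pmax(ev$values, variance_floor), 3L) %*%
      t(ev$vectors)
    Res <- Y - matrix(X %*% beta_new[k, ], N, Tt, byrow = TRUE) - B %*% t(Z)
    rss_k[k] <- sum(rk * rowSums(Res * Res)) + n_k[k] * sum((Z %*% S) * Z)
  }
  sigma2_new <- if (pooled_sigma2) {
    rep(max(sum(rss_k) / (N * Tt), variance_floor), K)
  } else {
    ifelse(n_k > 1e-10, pmax(rss_k / (n_k * Tt), variance_floor), sigma2)
  }
  list(beta = beta_new, D = D_new, sigma2 = sigma2_new)
}

# refit one component on merged responsibilities (posterior random-effect
# moments taken at the base component's parameters); returns the candidate
# parameters and its log-density column
epem_merge_component <- function(Y, r_m, beta_base, D_base, sigma2_base, X, Z,
                                 variance_floor) {
  sigma2 <- sigma2_base
  N <- nrow(Y); Tt <- ncol(Y)
  n_m <- sum(r_m)
  V <- Z %*% D_base %*% t(Z) + diag(sigma2, Tt)
  Vinv <- chol2inv(chol(V))
  A <- D_base %*% t(Z) %*% Vinv
  S <- D_base - A %*% Z %*% D_base
  E <- Y - matrix(X %*% beta_base, N, Tt, byrow = TRUE)
  B <- E %*% t(A)
  ybar <- colSums(r_m * Y) / n_m
  bbar <- colSums(r_m * B) / n_m
  beta_m <- as.numeric(solve(crossprod(X), t(X) %*% (ybar - Z %*% bbar)))
  Dm <- crossprod(B, r_m * B) / n_m + S
  Dm <- (Dm + t(Dm)) / 2
  ev <- eigen(Dm, symmetric = TRUE)
  Dm <- ev$vectors %*% diag(pmax(ev$values, variance_floor), 3L) %*% t(ev$vectors)
  Vm <- Z %*% Dm %*% t(Z) + diag(sigma2, Tt)
  U <- chol(Vm)
  Em <- Y - matrix(X %*% beta_m, N, Tt, byrow = TRUE)
  W <- Em %*% backsolve(U, diag(Tt))
  logf_m <- -0.5 * (Tt * log(2 * pi) + 2 * sum(log(diag(U))) + rowSums(W * W))
  list(beta = beta_m, D = Dm, logf = logf_m)
}

# single EM run from a seeded initialization
epem_run <- function(Y, age_grid, K_max, control, run_seed) {
  N <- nrow(Y); Tt <- ncol(Y)
  X <- poly_basis(age_grid, 3L)
  Z <- poly_basis(age_grid, 2L)
  set.seed(run_seed)

  n_distinct <- nrow(unique(Y))
  K0 <- min(K_max, n_distinct, N)
  if (K0 < 1L) fail("no profiles to cluster")
  labels0 <- if (K0 == 1L) rep(1L, N) else {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(Y, centers = K0, nstart = 3L, iter.max = 50L)),
      error = function(e) NULL)
    if (is.null(km)) sample.int(K0, N, replace = TRUE) else km$cluster
  }
  XtX_inv_Xt <- solve(crossprod(X), t(X))
  beta <- t(vapply(seq_len(K0), function(k) {
    idx <- which(labels0 == k)
    center <- if (length(idx) > 0L) colMeans(Y[idx, , drop = FALSE]) else
      Y[sample.int(N, 1L), ]
    as.numeric(XtX_inv_Xt %*% center)
  }, numeric(4L)))
  sigma2 <- rep(max(stats::var(as.numeric(Y)) / 4, control$variance_floor), K0)
  D <- rep(list(diag(0.05, 3L)), K0)
  pi <- tabulate(labels0, K0) / N
  pi[pi == 0] <- 1e-6
  pi <- pi / sum(pi)

  half <- max(1L, floor(control$max_iter / 2))
  lambda_at <- function(t) {
    if (!control$anneal) return(control$lambda)
    control$lambda * max(0, 1 - (t - 1) / half)
  }

  trace <- numeric(0)
  logf <- epem_logf(Y, beta, D, sigma2, X, Z)
  pruned_last <- FALSE
  converged <- FALSE
  for (t in seq_len(control$max_iter)) {
    lam <- lambda_at(t)
    J <- epem_objective(logf, pi, lam)
    trace <- c(trace, J)
    lam_stable <- !control$anneal || t > half
    if (t > 1L && lam_stable && !pruned_last &&
        abs(J - trace[t - 1L]) < control$tol * (1 + abs(J))) {
      converged <- TRUE
      break
    }
    pruned_last <- FALSE

    r <- epem_responsibilities(logf, pi)
    theta <- epem_mstep_theta(Y, r, beta, D, sigma2, X, Z,
                              control$variance_floor, control$pooled_sigma2)
    beta <- theta$beta; D <- theta$D; sigma2 <- theta$sigma2
    logf <- epem_logf(Y, beta, D, sigma2, X, Z)

    # mixing-proportion update: safeguarded generalized EM. Candidates are
    # the previous pi, the maximum-likelihood update (guaranteed ascent),
    # and the entropy-penalized fixed point, which shrinks below-average
    # clusters and may zero them out; the best candidate by the penalized
    # objective at the (non-increasing) next lambda is kept, so the
    # recorded objective trace never decreases.
    lam_next <- lambda_at(t + 1L)
    n_k <- colSums(r)
    cand <- list(prev = pi, mle = n_k / N)
    ent <- sum(pi * log(pi))
    yang <- n_k / N + lam_next * pi * (log(pi) - ent)
    yang[yang < 0] <- 0
    if (sum(yang) > 0) cand$yang <- yang / sum(yang)
    # annihilation candidates: zeroing a small cluster trades a likelihood
    # loss (bounded when a sibling cluster covers its members) for an
    # entropy reward; evaluated on the true objective so acceptance still
    # implies ascent
    K_curr <- length(pi)
    if (K_curr > 1L && lam_next > 0) {
      for (k in utils::head(order(pi), 3L)) {
        p_kill <- pi
        p_kill[k] <- 0
        cand[[sprintf("kill_%d", k)]] <- p_kill / sum(p_kill)
      }
    }
    obj <- vapply(cand, function(p) epem_objective(logf, p, lam_next), numeric(1))
    pi <- cand[[which.max(obj)]]
    J_curr <- max(obj)

    # ascent-guarded merging: two clusters tracing near-identical mean
    # curves can be replaced by one whose random-effect covariance absorbs
    # the spread; the entropy reward then outweighs the small likelihood
    # loss. Each candidate (closest curve pairs) is refined with two plain
    # EM iterations before the check, so a merge is accepted exactly when
    # the penalized objective does not decrease.
    em_refine <- function(st, lam, n_iter = 2L) {
      for (i in seq_len(n_iter)) {
        r_i <- epem_responsibilities(st$logf, st$pi)
        th <- epem_mstep_theta(Y, r_i, st$beta, st$D, st$sigma2, X, Z,
                               control$variance_floor, control$pooled_sigma2)
        st$beta <- th$beta; st$D <- th$D; st$sigma2 <- th$sigma2
        st$logf <- epem_logf(Y, st$beta, st$D, st$sigma2, X, Z)
        p_mle <- colSums(r_i) / N
        if (epem_objective(st$logf, p_mle, lam) >=
            epem_objective(st$logf, st$pi, lam)) st$pi <- p_mle
      }
      st$J <- epem_objective(st$logf, st$pi, lam)
      st
    }
    if (length(pi) > 1L && lam_next > 0 && t %% 3L == 0L) {
      curves <- beta %*% t(X)
      dmat <- as.matrix(stats::dist(curves))
      diag(dmat) <- Inf
      ord_pairs <- order(dmat[upper.tri(dmat)])
      idx <- which(upper.tri(dmat), arr.ind = TRUE)[
        utils::head(ord_pairs, 2L), , drop = FALSE]
      for (p_i in seq_len(nrow(idx))) {
        a <- idx[p_i, 1L]; b <- idx[p_i, 2L]
        base <- if (pi[a] >= pi[b]) a else b
        m <- epem_merge_component(Y, r[, a] + r[, b], beta[base, ], D[[base]],
                                  sigma2[base], X, Z, control$variance_floor)
        keep <- setdiff(seq_along(pi), c(a, b))
        sigma2_m <- if (control$pooled_sigma2) sigma2[c(keep, base)] else
          c(sigma2[keep], (pi[a] * sigma2[a] + pi[b] * sigma2[b]) / (pi[a] + pi[b]))
        st <- em_refine(list(pi = c(pi[keep], pi[a] + pi[b]),
                             beta = rbind(beta[keep, , drop = FALSE], m$beta),
                             D = c(D[keep], list(m$D)),
                             sigma2 = sigma2_m,
                             logf = cbind(logf[, keep, drop = FALSE], m$logf)),
                        lam_next, n_iter = 5L)
        if (st$J >= J_curr - 1e-9) {
          pi <- st$pi; beta <- st$beta; D <- st$D; sigma2 <- st$sigma2
          logf <- st$logf
          r <- epem_responsibilities(logf, pi)
          J_curr <- st$J
          pruned_last <- TRUE
          break
        }
      }
    }

    # ascent-guarded pruning of clusters below the effective-size threshold
    weak <- which(pi * N < control$prune_threshold & pi < max(pi))
    if (length(weak) > 0L) {
      pi_drop <- pi
      pi_drop[weak] <- 0
      pi_drop <- pi_drop / sum(pi_drop)
      if (epem_objective(logf, pi_drop, lam_next) >= J_curr - 1e-9) pi <- pi_drop
    }
    drop <- which(pi == 0)
    if (length(drop) > 0L) {
      keep <- setdiff(seq_along(pi), drop)
      pi <- pi[keep] / sum(pi[keep])
      beta <- beta[keep, , drop = FALSE]
      D <- D[keep]
      sigma2 <- sigma2[keep]
      logf <- logf[, keep, drop = FALSE]
      pruned_last <- TRUE
    }
  }

  list(pi = pi, beta = beta, D = D, sigma2 = sigma2, X = X, Z = Z,
       objective_trace = trace, converged = converged, logf = logf,
       # restarts are compared at the nominal penalty weight (even when the
       # anneal has taken lambda to 0), so a lower-entropy solution wins
       # unless a larger K genuinely buys enough likelihood
       final_objective = epem_objective(logf, pi, control$lambda))
}

#' Fit an entropy-penalized mixture of polynomial mixed-effects models
#'
#' The core clustering method: gene-by-sex temporal expression profiles are
#' modeled as a \eqn{K}-component mixture in which cluster \eqn{k} has a
#' cubic fixed-effect mean curve and each profile a quadratic random-effect
#' deviation, \eqn{y_i = X\beta_k + Z b_i + \epsilon_i}, with
#' \eqn{b_i \sim N(0, D_k)} and \eqn{\epsilon_i \sim N(0, \sigma_k^2 I)}.
#' Fitting maximizes the entropy-penalized objective
#' \deqn{J = \sum_i \log \sum_k \pi_k f_k(y_i) +
#'   \lambda N \sum_k \pi_k \log \pi_k}
#' by a generalized EM: starting from \code{K_max} clusters, the penalty
#' shrinks superfluous mixing proportions and clusters whose effective size
#' drops below \code{prune_threshold} are removed, so the number of clusters
#' is selected automatically. Male and female profiles are clustered jointly
#' as distinct objects, which makes the labels directly comparable across
#' sexes without any post-hoc remapping.
#'
#' Clusters in the returned model are relabeled 1..K in order of decreasing
#' membership (ties broken by the first fixed-effect coefficient), so the
#' numbering is deterministic.
#'
#' @param profiles a standardized \code{profile_set} (see
#'   [standardize_profiles()]), or a plain objects x T numeric matrix.
#' @param K_max maximum (initial) number of clusters.
#' @param age_grid ages for the design matrices; required when
#'   \code{profiles} is a plain matrix, ignored otherwise.
#' @param control an [epem_control()] list.
#' @param seed integer seed; the fit is deterministic given it.
#' @return An object of class \code{"epem"} with components \code{K},
#'   \code{pi}, \code{beta} (K x 4), \code{D} (list of 3 x 3), \code{sigma2},
#'   \code{X}, \code{Z}, \code{age_grid}, \code{objective_trace},
#'   \code{converged}, \code{responsibilities}, \code{labels}, \code{ids},
#'   \code{counts} and \code{data}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{plot}, \code{simulate},
#'   \code{residuals}, \code{fitted}, \code{logLik}.
#' @seealso [assign_labels()], [profile_loglik()], [simulate_profiles()]
#' @export
epem <- function(profiles, K_max = 10L, age_grid = NULL,
                 control = epem_control(), seed = 1L) {
  if (inherits(profiles, "profile_set")) {
    if (!profiles$standardized)
      fail("profiles must be standardized; run standardize_profiles() first")
    Y <- profiles$values
    age_grid <- profiles$age_grid
    ids <- profiles$ids
  } else {
    Y <- as.matrix(profiles)
    if (is.null(age_grid)) fail("age_grid is required for a plain matrix input")
    nm <- rownames(Y)
    if (is.null(nm)) nm <- sprintf("profile_%05d", seq_len(nrow(Y)))
    ids <- data.frame(gene_id = nm, sex = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(Y) < K_max) fail("need at least K_max objects (have %d, K_max %d)",
                            nrow(Y), K_max)
  if (length(age_grid) < 3L) fail("at least 3 time points are required")
  stopifnot(inherits(control, "epem_control"))

  runs <- lapply(seq_len(control$n_restarts), function(rs) {
    epem_run(Y, age_grid, K_max, control, run_seed = seed + 1000L * (rs - 1L))
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "final_objective"))]]

  # canonical order: decreasing membership, ties by first beta coefficient
  r <- epem_responsibilities(best$logf, best$pi)
  labels <- max.col(r, ties.method = "first")
  counts <- tabulate(labels, length(best$pi))
  ord <- order(-counts, best$beta[, 1L])
  model <- structure(list(
    K = length(best$pi),
    pi = best$pi[ord],
    beta = best$beta[ord, , drop = FALSE],
    D = best$D[ord],
    sigma2 = rep_len(best$sigma2, length(best$pi))[ord],
    X = best$X, Z = best$Z, age_grid = age_grid,
    objective_trace = best$objective_trace,
    converged = best$converged,
    n_objects = nrow(Y),
    lambda = control$lambda,
    control = control,
    seed = as.integer(seed),
    restart_objectives = vapply(runs, `[[`, numeric(1), "final_objective"),
    ids = ids,
    data = Y
  ), class = "epem")
  rownames(model$beta) <- sprintf("cluster_%d", seq_len(model$K))
  assign <- assign_labels(model, Y)
  model$responsibilities <- attr(assign, "responsibilities")
  model$labels <- assign$label
  model$counts <- tabulate(model$labels, model$K)
  if (!model$converged)
    warning("EPEM did not converge within max_iter; results may be unstable",
            call. = FALSE)
  model
}

#' Assign profiles to the clusters of a fitted model
#'
#' Computes responsibilities \eqn{r_{ik} \propto \pi_k f_k(y_i)} and hard
#' labels (argmax, ties to the lowest cluster index).
#'
#' @param model a fitted \code{"epem"} object.
#' @param profiles a \code{profile_set} or objects x T matrix on the model's
#'   age grid.
#' @return A data.frame with \code{gene_id}, \code{sex}, \code{label} and
#'   \code{max_responsibility}; the full responsibility matrix is attached as
#'   the \code{"responsibilities"} attribute.
#' @export
assign_labels <- function(model, profiles) {
  stopifnot(inherits(model, "epem"))
  if (inherits(profiles, "profile_set")) {
    Y <- profiles$values
    ids <- profiles$ids
  } else {
    Y <- as.matrix(profiles)
    nm <- rownames(Y)
    if (is.null(nm)) nm <- sprintf("profile_%05d", seq_len(nrow(Y)))
    ids <- data.frame(gene_id = nm, sex = NA_character_, stringsAsFactors = FALSE)
  }
  if (ncol(Y) != nrow(model$X)) fail("profiles are not on the model's age grid")
  logf <- epem_logf(Y, model$beta, model$D, model$sigma2, model$X, model$Z)
  r <- epem_responsibilities(logf, model$pi)
  labels <- max.col(r, ties.method = "first")
  out <- data.frame(gene_id = ids$gene_id, sex = ids$sex, label = labels,
                    max_responsibility = r[cbind(seq_len(nrow(r)), labels)],
                    stringsAsFactors = FALSE)
  colnames(r) <- sprintf("cluster_%d", seq_len(ncol(r)))
  attr(out, "responsibilities") <- r
  out
}
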