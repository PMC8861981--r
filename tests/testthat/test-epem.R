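test_that("profile likelihood reduces to independent normals when D = 0", {
  X <- design_X(); Z <- design_Z()
  set.seed(2)
  y <- rnorm(5); beta <- rnorm(4); s2 <- 0.3
  ll <- profile_loglik(y, beta, matrix(0, 3, 3), s2, X, Z)
  expect_equal(ll, sum(dnorm(y, as.numeric(X %*% beta), sqrt(s2), log = TRUE)),
               tolerance = 1e-12)
})

test_that("profile likelihood matches the dense multivariate-normal oracle", {
  X <- design_X(); Z <- design_Z()
  set.seed(5)
  for (i in 1:25) {
    y <- rnorm(5, sd = 2); beta <- rnorm(4); D <- random_psd3()
    s2 <- runif(1, 0.05, 0.5)
    Sigma <- Z %*% D %*% t(Z) + diag(s2, 5)
    expect_equal(profile_loglik(y, beta, D, s2, X, Z),
                 mvn_loglik_oracle(y, as.numeric(X %*% beta), Sigma),
                 tolerance = 1e-10)
  }
})

test_that("at the mean, the log-density falls monotonically as sigma2 grows past the mode", {
  X <- design_X(); Z <- design_Z()
  beta <- c(0, 1, 0, 0)
  y <- as.numeric(X %*% beta)
  D <- diag(0.01, 3)
  lls <- vapply(2^seq(0, 12), function(f)
    profile_loglik(y, beta, D, 0.05 * f, X, Z), numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("identical cubic profiles collapse to one cluster with floored variance", {
  X <- design_X()
  y0 <- as.numeric(X %*% c(0, 1.3, 0, 0))
  y0 <- (y0 - mean(y0)) / sd(y0)
  Y <- matrix(y0, 100, 5, byrow = TRUE)
  fit <- suppressWarnings(
    epem(Y, K_max = 5, age_grid = c(3, 6, 9, 12, 18),
         control = epem_control(n_restarts = 1L, max_iter = 60L), seed = 3))
  expect_identical(fit$K, 1L)
  expect_equal(fit$sigma2, 1e-6, tolerance = 1e-8)
})

test_that("two well-separated curves are recovered exactly from K_max = 6", {
  sim <- simulate_profiles(rbind(c(0, 1.2, 0, 0), c(0, -1.2, 0, 0)),
                           rep(list(matrix(0, 3, 3)), 2), sigma2 = 0.01,
                           pi = c(0.5, 0.5), n = 200, seed = 14)
  fit <- suppressWarnings(
    epem(sim$values, K_max = 6, age_grid = sim$age_grid,
         control = epem_control(n_restarts = 2L, max_iter = 150L), seed = 8))
  expect_identical(fit$K, 2L)
  expect_equal(adjusted_rand_index(fit$labels, sim$labels), 1.0)
})

test_that("the penalized objective trace never decreases", {
  sim <- simulate_profiles(rbind(c(0.5, 0.8, -0.3, 0.2), c(-0.5, -0.2, 0.6, -1)),
                           list(random_psd3(0.1), random_psd3(0.1)),
                           sigma2 = 0.2, pi = c(0.6, 0.4), n = 150, seed = 6)
  fit <- suppressWarnings(
    epem(sim$values, K_max = 5, age_grid = sim$age_grid,
         control = epem_control(n_restarts = 1L, max_iter = 120L), seed = 10))
  expect_true(all(diff(fit$objective_trace) >= -1e-8))
})

test_that("permuting object order permutes assignments and preserves the model", {
  sim <- simulate_profiles(rbind(c(0, 1.2, 0, 0), c(0, -1.2, 0, 0)),
                           rep(list(diag(0.02, 3)), 2), sigma2 = 0.05,
                           pi = c(0.5, 0.5), n = 120, seed = 20)
  fit1 <- suppressWarnings(
    epem(sim$values, K_max = 4, age_grid = sim$age_grid,
         control = epem_control(n_restarts = 1L, max_iter = 120L), seed = 2))
  set.seed(77)
  perm <- sample(nrow(sim$values))
  fit2 <- suppressWarnings(
    epem(sim$values[perm, ], K_max = 4, age_grid = sim$age_grid,
         control = epem_control(n_restarts = 1L, max_iter = 120L), seed = 2))
  expect_identical(fit2$K, fit1$K)
  # canonical relabeling makes the fitted parameters comparable directly
  expect_equal(fit2$pi, fit1$pi, tolerance = 1e-3)
  expect_equal(unname(fit2$beta), unname(fit1$beta), tolerance = 1e-2)
  expect_identical(fit2$labels, fit1$labels[perm])
})

test_that("responsibilities are normalized and confident on-cluster", {
  beta <- rbind(c(0, 1.2, 0, 0), c(0, -1.2, 0, 0))
  model <- structure(list(
    K = 2L, pi = c(0.5, 0.5), beta = beta,
    D = rep(list(diag(1e-4, 3)), 2), sigma2 = 0.01,
    X = design_X(), Z = design_Z(), age_grid = c(3, 6, 9, 12, 18)),
    class = "epem")
  on_curve <- matrix(as.numeric(design_X() %*% beta[1, ]), 1, 5)
  assign <- assign_labels(model, on_curve)
  expect_identical(assign$label, 1L)
  expect_gt(assign$max_responsibility, 0.999)

  set.seed(30)
  Y <- matrix(rnorm(50), 10, 5)
  r <- attr(assign_labels(model, Y), "responsibilities")
  expect_lt(max(abs(rowSums(r) - 1)), 1e-12)

  # a degenerate mixing vector forces every label to the live component
  model$pi <- c(1, 0)
  all_one <- assign_labels(model, Y)
  expect_true(all(all_one$label == 1L))
})

test_that("with lambda = 0 the fit is a stationary point of ordinary mixture EM", {
  sim <- simulate_profiles(rbind(c(0, 1.2, 0, 0), c(0, -1.2, 0, 0)),
                           rep(list(diag(0.02, 3)), 2), sigma2 = 0.05,
                           pi = c(0.5, 0.5), n = 80, seed = 41)
  fit <- suppressWarnings(
    epem(sim$values, K_max = 2, age_grid = sim$age_grid,
         control = epem_control(lambda = 0, anneal = FALSE, tol = 1e-12,
                                max_iter = 3000L, n_restarts = 1L), seed = 7))

  # reference implementation: textbook EM for the same mixture written from
  # the model definition (explicit covariances, mahalanobis distances,
  # posterior random-effect moments)
  X <- design_X(); Z <- design_Z()
  Y <- sim$values
  ref_loglik <- function(pi, beta, D, s2) {
    dens <- sapply(1:2, function(k) {
      Sigma <- Z %*% D[[k]] %*% t(Z) + diag(s2, 5)
      mu <- as.numeric(X %*% beta[k, ])
      exp(-0.5 * (5 * log(2 * base::pi) +
                    as.numeric(determinant(Sigma, TRUE)$modulus) +
                    mahalanobis(Y, mu, Sigma)))
    })
    sum(log(dens %*% pi))
  }
  em_iterate <- function(pi, beta, D, s2) {
    dens <- sapply(1:2, function(k) {
      Sigma <- Z %*% D[[k]] %*% t(Z) + diag(s2, 5)
      mu <- as.numeric(X %*% beta[k, ])
      exp(-0.5 * (5 * log(2 * base::pi) +
                    as.numeric(determinant(Sigma, TRUE)$modulus) +
                    mahalanobis(Y, mu, Sigma)))
    })
    w <- dens * matrix(pi, nrow(Y), 2, byrow = TRUE)
    r <- w / rowSums(w)
    n_k <- colSums(r)
    rss <- 0
    for (k in 1:2) {
      Sigma <- Z %*% D[[k]] %*% t(Z) + diag(s2, 5)
      G <- D[[k]] %*% t(Z) %*% solve(Sigma)
      S <- D[[k]] - G %*% Z %*% D[[k]]
      Ek <- Y - matrix(X %*% beta[k, ], nrow(Y), 5, byrow = TRUE)
      B <- Ek %*% t(G)
      ybar <- colSums(r[, k] * Y) / n_k[k]
      bbar <- colSums(r[, k] * B) / n_k[k]
      beta[k, ] <- solve(crossprod(X), t(X) %*% (ybar - Z %*% bbar))
      D[[k]] <- crossprod(B, r[, k] * B) / n_k[k] + S
      Res <- Y - matrix(X %*% beta[k, ], nrow(Y), 5, byrow = TRUE) - B %*% t(Z)
      rss <- rss + sum(r[, k] * rowSums(Res^2)) + n_k[k] * sum((Z %*% S) * Z)
    }
    list(pi = n_k / nrow(Y), beta = beta, D = D, s2 = rss / (5 * nrow(Y)))
  }
  ll_fit <- ref_loglik(fit$pi, fit$beta, fit$D, fit$sigma2)
  # the package's objective agrees with the reference density computation
  expect_equal(ll_fit, as.numeric(logLik(fit)), tolerance = 1e-8)
  # one reference EM iteration from the fitted parameters moves the
  # log-likelihood by (numerically) nothing: the fit is a fixed point
  step <- em_iterate(fit$pi, fit$beta, fit$D, fit$sigma2)
  ll_step <- ref_loglik(step$pi, step$beta, step$D, step$s2)
  expect_gte(ll_step, ll_fit - 1e-9)
  expect_lt(abs(ll_step - ll_fit), 1e-6)
})

test_that("fitted model methods are coherent", {
  sim <- simulate_profiles(rbind(c(0, 1.2, 0, 0), c(0, -1.2, 0, 0)),
                           rep(list(diag(0.02, 3)), 2), sigma2 = 0.05,
                           pi = c(0.5, 0.5), n = 100, seed = 50)
  fit <- suppressWarnings(
    epem(sim$values, K_max = 3, age_grid = sim$age_grid,
         control = epem_control(n_restarts = 1L, max_iter = 100L), seed = 9))
  expect_s3_class(fit, "epem")
  expect_identical(dim(coef(fit)), c(fit$K, 4L))
  expect_identical(dim(predict(fit)), c(fit$K, 5L))
  expect_identical(predict(fit, type = "label"), fit$labels)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(fit$data),
               tolerance = 1e-12)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  draws <- simulate(fit, nsim = 40L, seed = 4L)
  expect_identical(dim(draws$values), c(40L, 5L))
  expect_output(print(fit), "clusters")
  expect_output(print(summary(fit)), "Residual variance")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("cluster sizes order the canonical labels", {
  sim <- simulate_profiles(rbind(c(0, 1.2, 0, 0), c(0, -1.2, 0, 0)),
                           rep(list(diag(0.02, 3)), 2), sigma2 = 0.05,
                           pi = c(0.8, 0.2), n = 300, seed = 60)
  fit <- suppressWarnings(
    epem(sim$values, K_max = 4, age_grid = sim$age_grid,
         control = epem_control(n_restarts = 1L, max_iter = 100L), seed = 11))
  expect_true(all(diff(fit$counts) <= 0))
})
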