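#' @export
print.epem <- function(x, ...) {
  cat(sprintf("Entropy-penalized mixture of polynomial mixed-effects models\n"))
  cat(sprintf("  %d clusters fitted to %d temporal profiles over ages {%s} months\n",
              x$K, x$n_objects, paste(x$age_grid, collapse = ", ")))
  cat(sprintf("  residual variance sigma^2 in [%.4g, %.4g]; penalized objective = %.4f%s\n",
              min(x$sigma2), max(x$sigma2),
              x$objective_trace[length(x$objective_trace)],
              if (x$converged) "" else " (NOT converged)"))
  cat("  mixing proportions:\n")
  print(round(stats::setNames(x$pi, rownames(x$beta)), 4))
  invisible(x)
}

#' @export
summary.epem <- function(object, ...) {
  out <- list(K = object$K, pi = object$pi, counts = object$counts,
              sigma2 = object$sigma2, beta = object$beta,
              converged = object$converged,
              n_objects = object$n_objects,
              n_iter = length(object$objective_trace),
              objective = object$objective_trace[length(object$objective_trace)],
              re_sd = t(vapply(object$D, function(D) sqrt(diag(D)), numeric(3))),
              mean_max_resp = mean(object$responsibilities[
                cbind(seq_len(nrow(object$responsibilities)), object$labels)]))
  class(out) <- "summary.epem"
  out
}

#' @export
print.summary.epem <- function(x, ...) {
  cat(sprintf("EPEM fit: %d clusters, %d profiles, %d iterations%s\n",
              x$K, x$n_objects, x$n_iter,
              if (x$converged) " (converged)" else " (NOT converged)"))
  cat(sprintf("Residual variance: %s; final objective: %.4f\n",
              paste(signif(x$sigma2, 3), collapse = ", "), x$objective))
  cat(sprintf("Mean maximum responsibility: %.3f\n\n", x$mean_max_resp))
  tab <- data.frame(size = x$counts, pi = round(x$pi, 4),
                    round(x$beta, 3),
                    re_sd_intercept = round(x$re_sd[, 1], 3))
  colnames(tab)[3:6] <- c("b0", "b1", "b2", "b3")
  rownames(tab) <- rownames(x$beta)
  print(tab)
  invisible(x)
}

#' @export
coef.epem <- function(object, ...) object$beta

#' @export
logLik.epem <- function(object, ...) {
  logf <- epem_logf(object$data, object$beta, object$D, object$sigma2,
                    object$X, object$Z)
  ll <- epem_objective(logf, object$pi, lambda = 0)
  df <- (object$K - 1L) + 4L * object$K + 6L * object$K + object$K
  structure(ll, df = df, nobs = object$n_objects, class = "logLik")
}

#' Predict from a fitted EPEM model
#'
#' @param object a fitted \code{"epem"} object.
#' @param newdata optional objects x T matrix or \code{profile_set}; when
#'   omitted, the training profiles are used.
#' @param type \code{"curves"} returns the K x T cluster mean trajectories;
#'   \code{"label"} the hard cluster assignment of each profile;
#'   \code{"responsibility"} the full posterior membership matrix.
#' @param ... unused.
#' @return See \code{type}.
#' @export
predict.epem <- function(object, newdata = NULL,
                         type = c("curves", "label", "responsibility"), ...) {
  type <- match.arg(type)
  if (type == "curves") {
    curves <- object$beta %*% t(object$X)
    dimnames(curves) <- list(rownames(object$beta),
                             sprintf("age_%g", object$age_grid))
    return(curves)
  }
  if (is.null(newdata)) newdata <- object$data
  assign <- assign_labels(object, newdata)
  if (type == "label") assign$label else attr(assign, "responsibilities")
}

#' @export
fitted.epem <- function(object, ...) {
  curves <- object$beta %*% t(object$X)
  out <- curves[object$labels, , drop = FALSE]
  dimnames(out) <- dimnames(object$data)
  out
}

#' @export
residuals.epem <- function(object, ...) {
  object$data - fitted.epem(object)
}

#' Simulate profiles from a fitted EPEM model
#'
#' @param object a fitted \code{"epem"} object.
#' @param nsim number of profiles to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return As [simulate_profiles()].
#' @export
simulate.epem <- function(object, nsim = object$n_objects, seed = 1L, ...) {
  simulate_profiles(object$beta, object$D, object$sigma2, object$pi,
                    n = nsim, age_grid = object$age_grid, seed = seed)
}

#' Plot the fitted cluster mean trajectories
#'
#' Draws one panel per cluster: member profiles as grey spaghetti and the
#' fitted cubic mean curve in red, against age in months.
#'
#' @param x a fitted \code{"epem"} object.
#' @param max_members maximum member profiles drawn per panel.
#' @param ... passed to \code{matplot} for the member profiles.
#' @return \code{x}, invisibly.
#' @export
plot.epem <- function(x, max_members = 100L, ...) {
  K <- x$K
  mfrow <- c(ceiling(K / 3), min(K, 3))
  op <- graphics::par(mfrow = mfrow, mar = c(3.2, 3.2, 2, 0.6),
                      mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  curves <- x$beta %*% t(x$X)
  ylim <- range(x$data, curves)
  for (k in seq_len(K)) {
    idx <- which(x$labels == k)
    if (length(idx) > max_members) idx <- sample(idx, max_members)
    graphics::matplot(x$age_grid, t(x$data[idx, , drop = FALSE]),
                      type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey40", 0.25),
                      xlab = "age (months)", ylab = "standardized expression",
                      ylim = ylim,
                      main = sprintf("C%d (%d)", k, x$counts[k]), ...)
    graphics::lines(x$age_grid, curves[k, ], col = "red", lwd = 2)
  }
  invisible(x)
}
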