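#' @export
coef.polyligand_fit <- function(object, ...) object$coefficients

#' @export
print.fec_fit <- function(x, ...) {
  cat("Force-extension fit (single binding mode)\n")
  cat("Free parameters:", paste(x$free, collapse = ", "),
      " | fixed:", if (length(x$fixed)) paste(x$fixed, collapse = ", ")
      else "none", "\n")
  est <- x$coefficients
  cat(sprintf("  c = %.6g  a = %.6g nm  m = %g\n", est[["c"]], est[["a"]],
              est[["m"]]))
  cat(sprintf("RSS = %.6g nm^2 over %d points\n", x$rss, x$npoints))
  invisible(x)
}

#' @export
summary.fec_fit <- function(object, ...) {
  est <- object$coefficients
  tab <- data.frame(
    estimate = est,
    approx_se = object$se,
    status = ifelse(names(est) %in% object$free, "free", "fixed"),
    row.names = names(est))
  out <- list(coefficients = tab, rss = object$rss,
              sigma = sqrt(object$rss / max(object$npoints -
                                              length(object$free), 1)),
              npoints = object$npoints, convergence = object$convergence,
              nevals = object$nevals, m_profile = object$m_profile)
  class(out) <- "summary.fec_fit"
  out
}

#' @export
print.summary.fec_fit <- function(x, ...) {
  cat("Force-extension fit summary\n\nParameters (SEs are approximate,",
      "from the loss curvature):\n")
  print(x$coefficients, digits = 6)
  cat(sprintf("\nRSS = %.6g nm^2, residual sd = %.4g nm over %d points\n",
              x$rss, x$sigma, x$npoints))
  cat("Convergence code:", x$convergence, "(0 = converged), ",
      x$nevals, "model evaluations\n")
  if (!is.null(x$m_profile)) {
    flat <- diff(range(x$m_profile$rss)) <=
      1e-6 * (1 + min(x$m_profile$rss))
    cat("Integer profile over m:", nrow(x$m_profile), "candidates;",
        if (flat) "profile is flat - a and m are not separately identifiable (only a/m)"
        else sprintf("best m = %d", x$m_profile$m[which.min(x$m_profile$rss)]),
        "\n")
  }
  invisible(x)
}

#' @export
predict.fec_fit <- function(object, force = NULL, ...) {
  if (is.null(force)) force <- object$curve$force
  object$model(force, object$coefficients)
}

#' @export
fitted.fec_fit <- function(object, ...) predict(object)

#' @export
residuals.fec_fit <- function(object, ...)
  object$curve$extension - fitted(object)

#' @export
plot.fec_fit <- function(x, ...) {
  graphics::plot(x$curve$force, x$curve$extension, xlab = "Force (pN)",
                 ylab = "Extension (nm)", pch = 16, cex = 0.5, ...)
  fgrid <- seq(min(x$curve$force), max(x$curve$force), length.out = 200)
  graphics::lines(fgrid, x$model(fgrid, x$coefficients), col = 2, lwd = 2)
  graphics::legend("bottomright", c("data", "fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate noisy force-extension curves from a fitted model
#'
#' Draws `nsim` replicate curves from the fitted force-extension model with
#' i.i.d. Gaussian extension noise at the residual standard deviation.
#'
#' @param object A `fec_fit`.
#' @param nsim Number of replicate curves.
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @param ... Unused.
#' @return A data frame with one `force` column and `nsim` simulated
#'   extension columns.
#' @export
simulate.fec_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  sdres <- sqrt(object$rss / max(object$npoints - length(object$free), 1))
  sims <- with_local_seed(seed,
    replicate(nsim, mu + stats::rnorm(length(mu), 0, sdres)))
  out <- data.frame(force = object$curve$force, sims)
  names(out)[-1] <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("Kinetic rate fit at F =", x$force, "pN\n")
  est <- x$coefficients
  for (nm in names(est))
    cat(sprintf("  %s = %.6g /s (log10 SE %.3g)\n", nm, est[[nm]],
                x$log10_se[[nm]]))
  cat(sprintf("RSS = %.6g nm^2 over %d points\n", x$rss, x$npoints))
  invisible(x)
}

#' @export
summary.kin_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients,
                    log10_estimate = log10(object$coefficients),
                    log10_se = object$log10_se,
                    row.names = names(object$coefficients))
  out <- list(coefficients = tab, rss = object$rss,
              npoints = object$npoints, convergence = object$convergence,
              nevals = object$nevals)
  class(out) <- "summary.kin_fit"
  out
}

#' @export
print.summary.kin_fit <- function(x, ...) {
  cat("Kinetic rate fit summary (rates fitted in log10 space)\n\n")
  print(x$coefficients, digits = 6)
  cat(sprintf("\nRSS = %.6g nm^2 over %d points; convergence %d; %d model evaluations\n",
              x$rss, x$npoints, x$convergence, x$nevals))
  invisible(x)
}

#' @export
predict.kin_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$trace$time
  object$model(time)
}

#' @export
fitted.kin_fit <- function(object, ...) predict(object)

#' @export
residuals.kin_fit <- function(object, ...)
  object$trace$extension - fitted(object)

#' @export
plot.kin_fit <- function(x, ...) {
  graphics::plot(x$trace$time, x$trace$extension, log = "x",
                 xlab = "Time (s)", ylab = "Extension (nm)", pch = 16,
                 cex = 0.5, ...)
  graphics::lines(x$trace$time, fitted(x), col = 2, lwd = 2)
  graphics::legend("topright", c("data", "fit"), pch = c(16, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}
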