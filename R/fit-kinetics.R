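#' Fit effective rate constants to an extension time series
#'
#' Least-squares fit of the binding-kinetics model to an extension-versus-
#' time trace recorded at fixed force. The mode geometries (`m`, `a`) and the
#' polymer elastic parameters are held fixed; any subset of the scheme's rate
#' constants may be freed. Because effective rates span many orders of
#' magnitude, free rates are optimised in log10 space, with bounded
#' quasi-Newton minimisation from a deterministic Halton multi-start grid
#' (reproducible without a seed). The loss is the sum of squared extension
#' residuals (nm^2). Approximate standard errors (on log10 rates) come from
#' the curvature of the loss at the optimum.
#'
#' @param trace Data frame with columns `time` (s) and `extension` (nm).
#' @param polymer A [polymer_spec()].
#' @param scheme A [kinetic_scheme()] providing mode geometries and
#'   starting/fixed rate values.
#' @param force Force at which the trace was recorded, pN.
#' @param free Character vector of rate names to fit. For one mode:
#'   `"kb"`, `"kr"`; for two modes: `"kb1"`, `"kr1"`, `"kb2"`, `"kr2"`, plus
#'   `"k12"`, `"k21"` when the scheme has a conversion block.
#' @param lower,upper Named rate bounds, 1/s (defaults 1e-8 and 1e3).
#' @param n_starts Number of multi-start points.
#' @return An object of class `c("kin_fit", "polyligand_fit")`.
#' @examples
#' \donttest{
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' sch <- kinetic_scheme(binding_mode(m = 35, a = 5, kb = 1, kr = 1e-5))
#' trace <- generate_kinetic_trace(ssdna, sch, force = 5,
#'                                 times = 10^seq(-3, 6, length.out = 80))
#' fit <- fit_kinetics(trace, ssdna, sch, force = 5, free = c("kb", "kr"))
#' coef(fit)
#' }
#' @export
fit_kinetics <- function(trace, polymer, scheme, force, free,
                         lower = NULL, upper = NULL, n_starts = 8) {
  if (!all(c("time", "extension") %in% names(trace)))
    stop("'trace' needs columns 'time' and 'extension'")
  if (!inherits(scheme, "kinetic_scheme"))
    stop("'scheme' must be a kinetic_scheme")
  if (stats::sd(trace$extension) == 0)
    stop("degenerate trace: extension is constant, no kinetic information")
  one <- length(scheme$modes) == 1L
  valid <- if (one) c("kb", "kr") else
    c("kb1", "kr1", "kb2", "kr2",
      if (!is.null(scheme$conversion)) c("k12", "k21"))
  if (!all(free %in% valid) || length(free) == 0)
    stop("'free' must be a non-empty subset of: ",
         paste(valid, collapse = ", "))
  npts <- nrow(trace)
  if (npts < 5 * length(free))
    stop("need at least 5 data points per free parameter")

  lo <- stats::setNames(rep(1e-8, length(free)), free)
  hi <- stats::setNames(rep(1e3, length(free)), free)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  apply_rates <- function(sch, rates) {
    for (nm in names(rates)) {
      v <- rates[[nm]]
      if (one) {
        sch$modes[[1]][[nm]] <- v
      } else if (nm %in% c("k12", "k21")) {
        sch$conversion[[nm]] <- v
      } else {
        i <- as.integer(substring(nm, 3, 3))
        sch$modes[[i]][[substring(nm, 1, 2)]] <- v
      }
    }
    sch
  }

  times <- sort(unique(c(0, trace$time)))
  keep <- match(trace$time, times)
  rss_of <- function(lograte) {
    sch <- apply_rates(scheme, stats::setNames(as.list(10^lograte), free))
    traj <- tryCatch(
      integrate_kinetics(sch, polymer, times = times, force = force),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(traj)) return(1e12)
    sum((traj$extension[keep] - trace$extension)^2)
  }

  llo <- log10(lo[free]); lhi <- log10(hi[free])
  starts <- halton_points(n_starts, length(free))
  starts <- sweep(sweep(starts, 2, lhi - llo, `*`), 2, llo, `+`)
  cur <- vapply(free, function(nm) {
    v <- if (one) scheme$modes[[1]][[nm]]
    else if (nm %in% c("k12", "k21")) scheme$conversion[[nm]]
    else scheme$modes[[as.integer(substring(nm, 3, 3))]][[substring(nm, 1, 2)]]
    if (!is.null(v) && v > 0) log10(v) else NA_real_
  }, numeric(1))
  if (!anyNA(cur)) starts <- rbind(cur, starts)

  best <- NULL
  nev <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], rss_of, lower = llo, upper = lhi,
                    control = list(iter.max = 300, eval.max = 600)),
      error = function(e) NULL)
    if (is.null(res)) next
    nev <- nev + res$evaluations[["function"]]
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed")

  est_log <- stats::setNames(best$par, free)
  est <- 10^est_log
  rss <- best$objective

  se_log <- stats::setNames(rep(NA_real_, length(free)), free)
  if (npts > length(free)) {
    H <- tryCatch(pracma::hessian(rss_of, est_log), error = function(e) NULL)
    if (!is.null(H)) {
      sigma2 <- rss / (npts - length(free))
      eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
      inv <- ifelse(eg$values > max(abs(eg$values)) * 1e-10,
                    1 / eg$values, Inf)
      covm <- eg$vectors %*% diag(2 * sigma2 * inv, length(free)) %*%
        t(eg$vectors)
      se_log <- stats::setNames(sqrt(pmax(diag(covm), 0)), free)
    }
  }

  fitted_scheme <- apply_rates(scheme, as.list(est))
  structure(list(
    coefficients = est, log10_se = se_log, free = free, rss = rss,
    convergence = best$convergence, nevals = nev, trace = trace,
    polymer = polymer, scheme = fitted_scheme, force = force,
    npoints = npts,
    model = function(tt, sch = fitted_scheme) {
      ts <- sort(unique(c(0, tt)))
      traj <- integrate_kinetics(sch, polymer, times = ts, force = force)
      traj$extension[match(tt, ts)]
    }), class = c("kin_fit", "polyligand_fit"))
}
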