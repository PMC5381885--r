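#' Fit coverage and binding-mode geometry to a force-extension curve
#'
#' Weighted least-squares fit of the partially-covered polymer model to a
#' measured force-extension curve, for a single binding mode. The free
#' parameters are any subset of the coverage `c`, the Kuhn length `a` (nm)
#' and the occluded site size `m`; the polymer elastic parameters are held
#' fixed (they are known from bare-polymer pulling experiments). The loss is
#' the weighted sum of squared extension residuals (nm^2): measurements are
#' extension-at-set-force in the optical-tweezers framing, so residuals live
#' in extension space.
#'
#' Continuous parameters are optimised with bounded quasi-Newton
#' minimisation (`stats::nlminb`) from a deterministic multi-start grid of
#' low-discrepancy (Halton) points over the bounds, so fits are reproducible
#' without a seed. Because `m` counts monomers it is treated as an integer:
#' when free, every candidate `m` on the bound range is fitted continuously
#' in the remaining parameters and the best residual sum of squares wins;
#' the per-`m` profile is kept on the result so flat (non-identifiable)
#' profiles are visible. Note that in the high-force regime the extension
#' depends on `a` and `m` only through the ratio `a/m`, so `a` and `m` are
#' not separately identifiable from high-force data.
#'
#' Approximate standard errors come from the curvature (numerical Hessian)
#' of the loss at the optimum, `cov = 2 sigma^2 H^{-1}` with
#' `sigma^2 = RSS/(npoints - nfree)`; directions of vanishing curvature get
#' infinite standard errors.
#'
#' @param curve A [fec()] force-extension curve (or data frame with columns
#'   `force`, `extension`).
#' @param polymer A [polymer_spec()] (fixed).
#' @param free Character vector, subset of `c("c", "a", "m")`.
#' @param start Named list/vector of starting (and fixed) parameter values;
#'   entries for fixed parameters are required, entries for free ones are
#'   optional (the multi-start grid explores the bounds anyway).
#' @param lower,upper Named bounds for the free parameters. Defaults:
#'   `c` in \[0, 1\], `a` in \[0.1, 50\] nm, `m` in \[1, 200\].
#' @param weights Optional per-point weights (default 1). The fit is
#'   invariant under multiplying all weights by a constant.
#' @param n_starts Number of multi-start points for the continuous
#'   parameters.
#' @return An object of class `c("fec_fit", "polyligand_fit")` with methods
#'   [print()], [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()] and [simulate()].
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' curve <- generate_fec(ssdna, binding_mode(m = 35, a = 5), coverage = 0.6,
#'                       forces = 10^seq(-1, log10(60), length.out = 60))
#' fit <- fit_fec(curve, ssdna, free = "c", start = list(a = 5, m = 35))
#' coef(fit)
#' @export
fit_fec <- function(curve, polymer, free = c("c", "a"), start = list(),
                    lower = NULL, upper = NULL, weights = NULL,
                    n_starts = 8) {
  if (!all(c("force", "extension") %in% names(curve)))
    stop("'curve' needs columns 'force' and 'extension'")
  if (!all(free %in% c("c", "a", "m")) || length(free) == 0)
    stop("'free' must be a non-empty subset of c(\"c\", \"a\", \"m\")")
  npts <- nrow(curve)
  if (npts < 5 * length(free))
    stop("need at least 5 data points per free parameter")
  if (is.null(weights)) weights <- rep(1, npts)
  if (length(weights) != npts || any(weights < 0))
    stop("'weights' must be non-negative, one per data point")

  defaults_lo <- c(c = 0, a = 0.1, m = 1)
  defaults_hi <- c(c = 1, a = 50, m = 200)
  lo <- defaults_lo
  hi <- defaults_hi
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(lo[free] >= hi[free])) stop("bounds must satisfy lower < upper")

  fixed <- setdiff(c("c", "a", "m"), free)
  start <- unlist(start)
  if (!all(fixed %in% names(start)))
    stop("fixed parameters need values in 'start': ",
         paste(setdiff(fixed, names(start)), collapse = ", "))

  # Precompute the parameter-independent XWLC factor once per force grid.
  rvec <- xwlc_relative_extension(curve$force, polymer)
  model_x <- function(cc, a, m) {
    polymer$N * ((1 - cc) * polymer$d0 * rvec +
                   cc * (a / m) * langevin(curve$force * a / polymer$kBT))
  }
  rss_of <- function(par) {
    x <- model_x(par[["c"]], par[["a"]], par[["m"]])
    sum(weights * (x - curve$extension)^2)
  }

  cont <- setdiff(free, "m")      # continuously optimised parameters
  fit_given_m <- function(m_val) {
    fill <- function(th) {
      par <- stats::setNames(numeric(3), c("c", "a", "m"))
      par[fixed] <- start[fixed]
      par["m"] <- if ("m" %in% free) m_val else start[["m"]]
      par[cont] <- th
      par
    }
    obj <- function(th) rss_of(fill(th))
    if (length(cont) == 0) {
      return(list(par = fill(numeric(0)), rss = obj(numeric(0)),
                  convergence = 0L, nevals = 1L))
    }
    starts <- halton_points(n_starts, length(cont))
    starts <- sweep(sweep(starts, 2, hi[cont] - lo[cont], `*`), 2,
                    lo[cont], `+`)
    if (all(cont %in% names(start)))
      starts <- rbind(start[cont], starts)
    best <- NULL
    nev <- 0L
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::nlminb(starts[i, ], obj, lower = lo[cont], upper = hi[cont],
                      control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (is.null(res)) next
      nev <- nev + res$evaluations[["function"]]
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    if (is.null(best)) stop("all optimisation starts failed")
    list(par = fill(best$par), rss = best$objective,
         convergence = best$convergence, nevals = nev)
  }

  m_profile <- NULL
  if ("m" %in% free) {
    m_grid <- seq.int(ceiling(lo["m"]), floor(hi["m"]))
    fits <- lapply(m_grid, fit_given_m)
    rss <- vapply(fits, `[[`, numeric(1), "rss")
    m_profile <- data.frame(m = m_grid, rss = rss,
                            c = vapply(fits, function(f) f$par[["c"]],
                                       numeric(1)),
                            a = vapply(fits, function(f) f$par[["a"]],
                                       numeric(1)))
    bestfit <- fits[[which.min(rss)]]
  } else {
    bestfit <- fit_given_m(NA)
  }

  est <- bestfit$par
  rss <- bestfit$rss

  # Curvature-based approximate standard errors for continuous parameters.
  se <- stats::setNames(rep(NA_real_, 3), c("c", "a", "m"))
  if (length(cont) > 0 && npts > length(free)) {
    H <- tryCatch(
      pracma::hessian(function(th) {
        par <- est; par[cont] <- th; rss_of(par)
      }, est[cont]),
      error = function(e) NULL)
    if (!is.null(H)) {
      sigma2 <- rss / (npts - length(free))
      eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
      inv <- ifelse(eg$values > max(abs(eg$values)) * 1e-10,
                    1 / eg$values, Inf)
      covm <- eg$vectors %*% diag(2 * sigma2 * inv, length(cont)) %*%
        t(eg$vectors)
      se[cont] <- sqrt(pmax(diag(covm), 0))
    }
  }

  structure(list(
    coefficients = est, free = free, fixed = fixed, se = se, rss = rss,
    convergence = bestfit$convergence, nevals = bestfit$nevals,
    m_profile = m_profile, curve = curve, polymer = polymer,
    weights = weights, npoints = npts,
    model = function(force, par) {
      rv <- xwlc_relative_extension(force, polymer)
      polymer$N * ((1 - par[["c"]]) * polymer$d0 * rv +
        par[["c"]] * (par[["a"]] / par[["m"]]) *
          langevin(force * par[["a"]] / polymer$kBT))
    }), class = c("fec_fit", "polyligand_fit"))
}
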