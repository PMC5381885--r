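#' Kinetic scheme: binding modes plus optional mode conversion
#'
#' Bundles one or two binding modes (each with rate constants `kb`, `kr`)
#' and, optionally, direct interconversion between two modes. Conversion
#' happens in sets of `s` ligands at rates `k12` (mode 1 to 2) and `k21`
#' (mode 2 to 1) and requires mode 1 to occlude more monomers than mode 2
#' (`m1 > m2`), since a 2-to-1 conversion must recruit `m1 - m2` free
#' monomers per ligand.
#'
#' @param modes A `binding_mode` or list of one or two, each with `kb` and
#'   `kr` set.
#' @param s Conversion set size (positive integer), optional.
#' @param k12,k21 Mode-conversion rates, 1/s; supplied together with `s` to
#'   enable conversion.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(modes, s = NULL, k12 = NULL, k21 = NULL) {
  modes <- as_mode_list(modes)
  if (!length(modes) %in% 1:2)
    stop("a kinetic scheme has one or two binding modes")
  for (md in modes)
    if (is.null(md$kb) || is.null(md$kr))
      stop(sprintf("mode '%s' needs rate constants 'kb' and 'kr'", md$label))
  conv <- NULL
  if (!is.null(s) || !is.null(k12) || !is.null(k21)) {
    if (is.null(s) || is.null(k12) || is.null(k21))
      stop("conversion needs all of 's', 'k12' and 'k21'")
    if (length(modes) != 2L)
      stop("mode conversion requires exactly two binding modes")
    if (modes[[1]]$m <= modes[[2]]$m)
      stop("conversion assumes mode 1 occludes more monomers than mode 2 (m1 > m2)")
    if (s < 1 || s != round(s)) stop("'s' must be a positive integer")
    if (k12 < 0 || k21 < 0) stop("conversion rates must be >= 0")
    conv <- list(s = as.integer(s), k12 = k12, k21 = k21)
  }
  structure(list(modes = modes, conversion = conv), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme with", length(x$modes), "binding mode(s)\n")
  for (md in x$modes) print(md)
  if (!is.null(x$conversion))
    cat(sprintf("Conversion in sets of s = %d: k12 = %g /s, k21 = %g /s\n",
                x$conversion$s, x$conversion$k12, x$conversion$k21))
  invisible(x)
}

#' Closed-form single-mode binding kinetics
#'
#' With one binding mode, `dn/dt = kb (N - n m)/m - kr n` starting from an
#' empty polymer integrates to
#' `n(t) = (N/m) (1 + kr/kb)^-1 (1 - exp(-(kb + kr) t))`,
#' with equilibrium count `N / (m (1 + kr/kb))` (equilibrium coverage
#' `1/(1 + kr/kb)`).
#'
#' @param t Times, s, `>= 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @param mode A `binding_mode` with `kb`, `kr`.
#' @return Bound-ligand count `n(t)`.
#' @export
one_mode_closed_form <- function(t, polymer, mode) {
  if (!inherits(mode, "binding_mode")) stop("'mode' must be a binding_mode")
  if (is.null(mode$kb) || is.null(mode$kr)) stop("'mode' needs kb and kr")
  if (any(t < 0)) stop("times must be >= 0")
  if (mode$kb == 0) return(rep(0, length(t)))
  neq <- (polymer$N / mode$m) / (1 + mode$kr / mode$kb)
  neq * (1 - exp(-(mode$kb + mode$kr) * t))
}

#' Default logarithmic time grid for a kinetic scheme
#'
#' 400 log-spaced points from `1e-3 / fastest_rate` to
#' `20 / slowest_nonzero_rate`, preceded by `t = 0` — wide enough to resolve
#' the fastest transient and reach steady state even when the rates span
#' several orders of magnitude.
#'
#' @param scheme A [kinetic_scheme()].
#' @param n Number of grid points.
#' @return Numeric vector of times, s, starting at 0.
#' @export
default_time_grid <- function(scheme, n = 400) {
  rates <- unlist(lapply(scheme$modes, function(md) c(md$kb, md$kr)))
  if (!is.null(scheme$conversion))
    rates <- c(rates, scheme$conversion$k12, scheme$conversion$k21)
  rates <- rates[rates > 0]
  if (length(rates) == 0) stop("all rates are zero; no time scale")
  c(0, 10^seq(log10(1e-3 / max(rates)), log10(20 / min(rates)),
              length.out = n))
}

# Right-hand side of the binding kinetics ODE systems. y = counts vector.
kinetics_rhs <- function(t, y, parms) {
  N <- parms$N
  m <- parms$m
  holes <- N - sum(y * m)
  dn <- parms$kb * holes / m - parms$kr * y
  cv <- parms$conversion
  if (!is.null(cv)) {
    # Net mean-field conversion: 1->2 at k12 per ligand; 2->1 needs
    # (m1 - m2) free monomers per ligand, rate scaled by the hole count
    # holes/(m1 - m2). The set size s cancels (s * k * n/s).
    flow <- cv$k12 * y[1] - cv$k21 * y[2] * holes / (m[1] - m[2])
    dn[1] <- dn[1] - flow
    dn[2] <- dn[2] + flow
  }
  list(dn)
}

#' Integrate binding kinetics (one, two, or interconverting modes)
#'
#' Integrates the mean-field binding kinetics from an initially naked
#' polymer. Per mode, `dn_i/dt = kb_i (N - sum n_j m_j)/m_i - kr_i n_i`; the
#' binding term is proportional to the number of holes (naked stretches of
#' `m_i` monomers) and vanishes as the polymer fills, keeping
#' `sum(n_i m_i) <= N`. With a conversion block the net inter-mode flow
#' `k12 n1 - k21 n2 (N - sum n_j m_j)/(m1 - m2)` is added (see
#' [kinetic_scheme()]). A stiff-capable adaptive integrator (`lsoda`) is
#' used with relative tolerance 1e-10 and absolute tolerance `1e-12 N`, since
#' the rates may span many orders of magnitude and the closed-form
#' single-mode solution should be reproduced to better than 1e-8 relative. Tiny negative excursions
#' (below `-1e-9 N`) abort; smaller ones are clamped to zero with a warning.
#'
#' @param scheme A [kinetic_scheme()].
#' @param polymer A [polymer_spec()].
#' @param times Output time grid, s, starting at 0; defaults to
#'   [default_time_grid()].
#' @param force Optional force, pN; when given, the extension time series is
#'   filled in (see [extension_timeseries()]).
#' @return An object of class `kinetic_trajectory`: list with `time`,
#'   `counts` (matrix, one column per mode), `coverage` (per-mode coverage
#'   matrix), `force` and `extension` (or `NULL`).
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' sch <- kinetic_scheme(binding_mode(m = 35, a = 5, kb = 1, kr = 1e-5))
#' traj <- integrate_kinetics(sch, ssdna, force = 5)
#' @export
integrate_kinetics <- function(scheme, polymer, times = NULL, force = NULL) {
  if (!inherits(scheme, "kinetic_scheme"))
    stop("'scheme' must be a kinetic_scheme")
  if (is.null(times)) times <- default_time_grid(scheme)
  if (times[1] != 0) times <- c(0, times)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  k <- length(scheme$modes)
  parms <- list(
    N = polymer$N,
    m = vapply(scheme$modes, `[[`, numeric(1), "m"),
    kb = vapply(scheme$modes, `[[`, numeric(1), "kb"),
    kr = vapply(scheme$modes, `[[`, numeric(1), "kr"),
    conversion = scheme$conversion)
  sol <- deSolve::ode(y = rep(0, k), times = times, func = kinetics_rhs,
                      parms = parms, method = "lsoda", rtol = 1e-10,
                      atol = 1e-12 * polymer$N)
  if (attr(sol, "istate")[1] < 0)
    stop("kinetics integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  counts <- matrix(sol[, -1, drop = FALSE], ncol = k)
  colnames(counts) <- vapply(scheme$modes, `[[`, character(1), "label")
  if (any(counts < -1e-9 * polymer$N))
    stop("kinetics integration produced significantly negative counts")
  if (any(counts < 0)) {
    warning("clamping tiny negative ligand counts to zero")
    counts[counts < 0] <- 0
  }
  m <- parms$m
  occ <- counts %*% m
  if (any(occ > polymer$N * (1 + 1e-6)))
    stop("kinetics integration violated the occupancy bound sum(n_i m_i) <= N")
  traj <- structure(list(
    time = times, counts = counts,
    coverage = sweep(counts, 2, m, `*`) / polymer$N,
    force = force, extension = NULL, polymer = polymer,
    modes = scheme$modes), class = "kinetic_trajectory")
  if (!is.null(force)) traj <- extension_timeseries(traj, polymer,
                                                    scheme$modes, force)
  traj
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat("Kinetic trajectory:", length(x$time), "time points, t in [",
      min(x$time), ",", max(x$time), "] s;", ncol(x$counts), "mode(s)\n")
  if (!is.null(x$force))
    cat("Force:", x$force, "pN;",
        if (is.null(x$extension)) "extension not computed" else
          sprintf("extension %g -> %g nm", x$extension[1],
                  x$extension[length(x$extension)]), "\n")
  invisible(x)
}

#' Convert a coverage trajectory into an extension time series
#'
#' Evaluates the partially-covered force-extension model at a fixed force for
#' every stored time point: `x(t) = x_n(F) (N - sum n_i(t) m_i) d0 +
#' sum n_i(t) a_i L(F a_i/kBT)`. The XWLC relative extension at `F` is
#' computed once and reused across the whole trajectory.
#'
#' @param traj A `kinetic_trajectory`.
#' @param polymer A [polymer_spec()].
#' @param modes A `binding_mode` or list of them matching the trajectory
#'   columns.
#' @param force Force, pN; defaults to the force stored on the trajectory.
#' @return The trajectory with `extension` (nm) and `force` filled.
#' @export
extension_timeseries <- function(traj, polymer, modes, force = traj$force) {
  if (is.null(force)) stop("no force set on the trajectory or supplied")
  modes <- as_mode_list(modes)
  m <- vapply(modes, `[[`, numeric(1), "m")
  a <- vapply(modes, `[[`, numeric(1), "a")
  r <- xwlc_relative_extension(force, polymer)
  lang <- langevin(force * a / polymer$kBT)
  naked <- (polymer$N - as.vector(traj$counts %*% m)) * polymer$d0
  traj$extension <- r * naked + as.vector(traj$counts %*% (a * lang))
  traj$force <- force
  traj
}
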