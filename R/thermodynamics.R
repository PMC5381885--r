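# Memo cache for the naked elastic free energy: quadrature results keyed by
# (Lp, K0, kBT, F). transition_force() calls delta_g_naked thousands of
# times at repeated forces during bracketing/bisection.
.dgn_cache <- new.env(parent = emptyenv())

#' Elastic free energy of the naked chain per unit contour length
#'
#' `dg_n(F) = -integral_0^F x_n(F')/Lc(0) dF'` (units pN = pN nm / nm),
#' computed by adaptive quadrature of the XWLC relative extension. Zero at
#' `F = 0` and strictly decreasing in force. Results are memoised per
#' (polymer, force) pair.
#'
#' @param force Force, pN, `>= 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @return Free energy per unit naked contour length, pN, `<= 0`.
#' @export
delta_g_naked <- function(force, polymer) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("delta_g_naked(): 'force' must be finite and >= 0")
  vapply(force, function(f) {
    if (f == 0) return(0)
    key <- sprintf("%.17g|%.17g|%.17g|%.17g",
                   polymer$Lp, polymer$K0, polymer$kBT, f)
    hit <- .dgn_cache[[key]]
    if (!is.null(hit)) return(hit)
    q <- tryCatch(
      stats::integrate(function(ff) xwlc_relative_extension(ff, polymer),
                       lower = 0, upper = f, rel.tol = 1e-8,
                       subdivisions = 200L),
      error = function(e) stop("delta_g_naked(): quadrature failed at F = ",
                               f, " pN: ", conditionMessage(e)))
    val <- -q$value
    .dgn_cache[[key]] <- val
    val
  }, numeric(1))
}

#' Elastic free energy of a covered sub-chain per unit contour length
#'
#' Closed form for the freely-jointed chain,
#' `dg_c(F) = (kBT/a) log(u / sinh(u))` with `u = F a / kBT`, evaluated in
#' the overflow-safe form `(kBT/a) (log u - u + log 2 - log1p(-exp(-2u)))`
#' and by series `-(kBT/a) u^2/6` for tiny `u`. Zero at `F = 0`, always
#' `<= 0`.
#'
#' @param force Force, pN, `>= 0` (vectorized).
#' @param a Kuhn length of the occluded complex, nm.
#' @param kBT Thermal energy, pN nm.
#' @return Free energy per unit covered contour length, pN.
#' @export
delta_g_covered <- function(force, a, kBT = 4.11) {
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single finite positive number (nm)")
  if (any(!is.finite(force)) || any(force < 0))
    stop("delta_g_covered(): 'force' must be finite and >= 0")
  u <- force * a / kBT
  out <- numeric(length(u))
  small <- u < 1e-4
  out[small] <- -(kBT / a) * u[small]^2 / 6
  ub <- u[!small]
  out[!small] <- (kBT / a) * (log(ub) - ub + log(2) - log1p(-exp(-2 * ub)))
  out
}

#' Gibbs free energy of the ligand-polymer system at tension
#'
#' `dG(F, n) = (N - sum n_i m_i) d0 dg_n(F) + sum n_i a_i dg_c_i(F)
#'  + sum n_i (-eps_b_i + kBT (log n_i - 1))`,
#' combining the elastic free energies of the naked and covered regions with
#' the one-dimensional ideal-gas chemical potential of the bound ligands.
#' The entropic term contributes 0 for `n_i = 0` (the `n log n` limit).
#'
#' @param force Force, pN, `>= 0` (scalar).
#' @param polymer A [polymer_spec()].
#' @param modes A `binding_mode` or list of them; each must carry `eps_b`.
#' @param counts Per-mode ligand counts `n_i >= 0`.
#' @return Free energy, pN nm, relative to the naked unstretched polymer
#'   minus the naked elastic term baseline (i.e. 0 at `F = 0`, `n = 0`).
#' @export
gibbs_free_energy <- function(force, polymer, modes, counts) {
  modes <- as_mode_list(modes)
  counts <- coverage_state(counts, modes, polymer)
  eps <- vapply(modes, function(md) {
    if (is.null(md$eps_b))
      stop("every binding mode needs 'eps_b' for free-energy calculations")
    md$eps_b
  }, numeric(1))
  m <- vapply(modes, `[[`, numeric(1), "m")
  a <- vapply(modes, `[[`, numeric(1), "a")
  dgn <- delta_g_naked(force, polymer)
  dgc <- vapply(a, function(ai) delta_g_covered(force, ai, polymer$kBT),
                numeric(1))
  entropic <- ifelse(counts > 0, counts * (log(counts) - 1), 0)
  (polymer$N - sum(counts * m)) * polymer$d0 * dgn +
    sum(counts * a * dgc) +
    sum(-counts * eps + polymer$kBT * entropic)
}

#' Net free-energy gain of binding one ligand at tension
#'
#' `E(F) = eps_b + m d0 dg_n(F) - a dg_c(F)`: the binding energy corrected by
#' the elastic free-energy cost of converting `m` naked monomers into one
#' covered Kuhn segment. Equals `eps_b` at zero force and decreases with
#' force; the ideal-gas equilibrium count is `exp(E/kBT)` and the Tonks-gas
#' coverage is a function of `E` alone.
#'
#' @param force Force, pN, `>= 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @param mode A `binding_mode` carrying `eps_b`.
#' @return Energy, pN nm.
#' @export
binding_drive <- function(force, polymer, mode) {
  if (!inherits(mode, "binding_mode")) stop("'mode' must be a binding_mode")
  if (is.null(mode$eps_b)) stop("'mode' needs 'eps_b'")
  mode$eps_b + mode$m * polymer$d0 * delta_g_naked(force, polymer) -
    mode$a * delta_g_covered(force, mode$a, polymer$kBT)
}

#' Equilibrium ligand counts under ideal-gas statistics
#'
#' Minimising the Gibbs free energy with the one-dimensional ideal-gas
#' chemical potential gives, per mode, `n_i = exp(E_i(F)/kBT)` with `E_i`
#' from [binding_drive()]. All exponentials are handled in log space, so
#' arbitrarily large binding energies cannot overflow. The maximum possible
#' total coverage is 100%: when `sum(n_i m_i) > N` all counts are scaled
#' proportionally onto the constraint and the `capped` flag is set.
#'
#' @param force Force, pN, `>= 0` (scalar).
#' @param polymer A [polymer_spec()].
#' @param modes A `binding_mode` or list of them, each with `eps_b`.
#' @return A list with elements `force`, `counts` (per-mode `n_i`),
#'   `coverage` (per-mode `c_i = n_i m_i / N`), `total_coverage`, and
#'   `capped` (logical).
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' ssb <- binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
#' equilibrium_ideal(5, ssdna, ssb)$total_coverage   # capped at 1
#' @export
equilibrium_ideal <- function(force, polymer, modes) {
  modes <- as_mode_list(modes)
  m <- vapply(modes, `[[`, numeric(1), "m")
  logn <- vapply(modes, function(md)
    binding_drive(force, polymer, md) / polymer$kBT, numeric(1))
  # log of total occluded monomers, computed stably
  lo <- logn + log(m)
  M <- max(lo)
  log_occ <- M + log(sum(exp(lo - M)))
  capped <- log_occ > log(polymer$N)
  if (capped) logn <- logn + log(polymer$N) - log_occ
  counts <- exp(logn)
  # linear-space polish: after the log-space scaling the counts are O(N/m),
  # so a final exact rescale cannot overflow and lands occupancy on N
  if (capped) counts <- counts * (polymer$N / sum(counts * m))
  cov <- counts * m / polymer$N
  if (capped) cov <- cov / sum(cov)   # total coverage exactly 1 at the cap
  list(force = force, counts = stats::setNames(counts, vapply(modes, `[[`,
         character(1), "label")),
       coverage = cov, total_coverage = sum(cov), capped = capped)
}

# Principal Lambert W evaluated on a log-scale argument: W0(exp(rho)) for
# real rho, safe for arbitrarily large rho. Solves w + log(w) = rho by
# Newton iteration on the concave increasing g(w) = w + log(w): starting
# below the root (w0 = z/(1+z) for small arguments, rho - log(rho) for large
# ones, both provably under the root) the iteration converges monotonically
# and quadratically; a hard iteration cap guards termination.
lambertW0_logarg <- function(rho) {
  vapply(rho, function(r) {
    if (r < -36) return(exp(r))   # W0(z) = z + O(z^2), below double precision
    w <- if (r <= 1) { z <- exp(r); z / (1 + z) } else r - log(r)
    for (i in 1:100) {
      dw <- (w + log(w) - r) / (1 + 1 / w)
      w <- w - dw
      if (abs(dw) <= 1e-15 * (1 + abs(w))) break
    }
    w
  }, numeric(1))
}

#' Equilibrium coverage under Tonks-gas (hard-rod) statistics
#'
#' At high coverage the excluded length of already-bound ligands matters; the
#' one-dimensional hard-rod (Tonks) gas entropy then replaces the ideal-gas
#' form. For a single binding mode the implicit equilibrium condition
#' `-eps_b + kBT (log(N/m) + log(c/(1-c)) + c/(1-c)) = m d0 dg_n - a dg_c`
#' has the closed-form solution
#' `c(F) = 1 / (1 + 1/W0((m/N) exp(E(F)/kBT)))`
#' with `W0` the principal Lambert W branch and `E` from [binding_drive()].
#' The argument of `W0` is handled in log space, so large binding energies
#' cannot overflow. The predicted coverage is always strictly below 1.
#'
#' @param force Force, pN, `>= 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @param mode A single `binding_mode` with `eps_b` (the hard-rod closed form
#'   is derived for one mode only).
#' @return Coverage in `[0, 1)`.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' ssb <- binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
#' equilibrium_coverage_tonks(0, ssdna, ssb)   # plateau below 100%
#' @export
equilibrium_coverage_tonks <- function(force, polymer, mode) {
  if (!inherits(mode, "binding_mode"))
    stop("'mode' must be a single binding_mode (hard-rod form is single-mode)")
  vapply(force, function(f) {
    rho <- log(mode$m / polymer$N) + binding_drive(f, polymer, mode) /
      polymer$kBT
    w <- lambertW0_logarg(rho)
    if (w == 0) return(0)
    1 / (1 + 1 / w)
  }, numeric(1))
}

#' Closed-form estimate of the coverage transition force
#'
#' In the high-force limit the naked elastic free energy is dominated by the
#' stretch-modulus term, `dg_n(F) ~ -F^2/K0`, while the covered contribution
#' grows only linearly. Balancing the binding energy against the dominant
#' naked term gives the estimate `F_t ~ sqrt(eps_b K0 / (m d0))`.
#'
#' @param polymer A [polymer_spec()].
#' @param mode A `binding_mode` with `eps_b`.
#' @return Estimated transition force, pN.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' ssb <- binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
#' transition_force_approx(ssdna, ssb)   # ~50 pN
#' @export
transition_force_approx <- function(polymer, mode) {
  if (!inherits(mode, "binding_mode")) stop("'mode' must be a binding_mode")
  if (is.null(mode$eps_b)) stop("'mode' needs 'eps_b'")
  sqrt(mode$eps_b * polymer$K0 / (mode$m * polymer$d0))
}

#' Transition force from the full equilibrium coverage curve
#'
#' The force at which the equilibrium coverage (capped at 100%) first falls
#' below a threshold, located by bracketing on a force grid followed by
#' bisection to 1e-3 pN. "Transition" is defined here as the 50% crossing by
#' default; the threshold is a package convention, exposed so sensitivity can
#' be probed.
#'
#' @param polymer A [polymer_spec()].
#' @param mode A `binding_mode` with `eps_b`.
#' @param threshold Coverage threshold in (0, 1); default 0.5.
#' @param statistics `"ideal"` (capped ideal gas) or `"tonks"` (hard rod).
#' @param fmax Upper force bound for the search, pN.
#' @return Transition force, pN.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' ssb <- binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
#' transition_force(ssdna, ssb)   # full model: ~10-15 pN
#' @export
transition_force <- function(polymer, mode, threshold = 0.5,
                             statistics = c("ideal", "tonks"), fmax = 1000) {
  statistics <- match.arg(statistics)
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  covf <- switch(statistics,
    ideal = function(f) equilibrium_ideal(f, polymer, mode)$total_coverage,
    tonks = function(f) equilibrium_coverage_tonks(f, polymer, mode))
  if (covf(0) <= threshold)
    stop("coverage at F = 0 is already at or below the threshold")
  grid <- c(0, 10^seq(-2, log10(fmax), length.out = 80))
  cv <- vapply(grid, covf, numeric(1))
  idx <- which(cv < threshold)
  if (length(idx) == 0)
    stop("coverage never falls below the threshold on [0, ", fmax, "] pN")
  i <- idx[1]
  stats::uniroot(function(f) covf(f) - threshold,
                 c(grid[i - 1], grid[i]), tol = 1e-3)$root
}
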