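#' Langevin function
#'
#' `L(u) = coth(u) - 1/u`, the orientation average of a freely-jointed chain
#' segment under tension. Evaluated with a series expansion for `u < 0.1`
#' (the direct form loses significant digits to cancellation at small `u`)
#' and the overflow-safe form `1 + 2/expm1(2u) - 1/u` otherwise; the two
#' branches agree to ~1e-15 at the switch.
#'
#' @param u Dimensionless force scale `F a / kBT`, finite and `>= 0`
#'   (vectorized).
#' @return `L(u)` in `[0, 1)`; `L(0) = 0`.
#' @examples
#' langevin(c(0, 1, 10))
#' @export
langevin <- function(u) {
  if (any(!is.finite(u)) || any(u < 0))
    stop("langevin(): 'u' must be finite and >= 0")
  out <- numeric(length(u))
  small <- u < 0.1
  us <- u[small]
  out[small] <- us / 3 - us^3 / 45 + 2 * us^5 / 945 - us^7 / 4725 +
    2 * us^9 / 93555
  ub <- u[!small]
  out[!small] <- 1 + 2 / expm1(2 * ub) - 1 / ub
  out
}

# Residual of the extensible Marko-Siggia interpolation at relative
# extension r: f Lp/kBT = 1/4 (1 - r + f/K0)^-2 - 1/4 + r - f/K0.
# Strictly increasing in r on [0, 1 + f/K0).
xwlc_residual <- function(r, force, polymer) {
  t <- 1 - r + force / polymer$K0
  0.25 / t^2 - 0.25 + r - force / polymer$K0 -
    force * polymer$Lp / polymer$kBT
}

#' Relative extension of the extensible worm-like chain
#'
#' Solves the extensible Marko-Siggia interpolation formula
#' `F Lp/kBT = 1/4 (1 - x/Lc + F/K0)^-2 - 1/4 + x/Lc - F/K0`
#' for the relative extension `x/Lc(0)` of the naked polymer at force `F`.
#' The residual is strictly increasing in the relative extension on the
#' bracket `[0, 1 + F/K0)`, so a bracketed solve always converges; the root
#' is polished with Newton steps to drive the residual to machine precision.
#'
#' @param force Force, pN, finite and `>= 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @return Relative extension(s) in `[0, 1 + F/K0)`; 0 at zero force,
#'   monotone non-decreasing in force.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' xwlc_relative_extension(c(0, 5, 50), ssdna)
#' @export
xwlc_relative_extension <- function(force, polymer) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("xwlc_relative_extension(): 'force' must be finite and >= 0")
  vapply(force, function(f) {
    if (f == 0) return(0)
    upper <- 1 + f / polymer$K0 - 1e-12
    lo <- xwlc_residual(0, f, polymer)
    hi <- xwlc_residual(upper, f, polymer)
    if (lo > 0 || hi < 0)
      stop("internal error: XWLC root not bracketed (residuals ",
           lo, ", ", hi, " at F = ", f, " pN)")
    r <- stats::uniroot(xwlc_residual, c(0, upper), force = f,
                        polymer = polymer, tol = 1e-10)$root
    # Newton polish: residual derivative 1/2 (1-r+f/K0)^-3 + 1 > 0
    for (i in 1:3) {
      t <- 1 - r + f / polymer$K0
      step <- xwlc_residual(r, f, polymer) / (0.5 / t^3 + 1)
      rn <- r - step
      if (rn > 0 && rn < upper) r <- rn
    }
    r
  }, numeric(1))
}

#' Explicit low- and high-force XWLC approximations
#'
#' Closed-form limits of the extensible worm-like chain: in the low-force
#' regime (`F << kBT/Lp`) the relative extension is `(2/3) F Lp / kBT`; in
#' the high-force regime (`F >> kBT/Lp`) it is
#' `1 - (1/2) sqrt(kBT/(F Lp)) + F/K0`. The regime is chosen explicitly by
#' the caller; there is no automatic switch. Both branches fail near the
#' crossover force `kBT/Lp`.
#'
#' @param force Force, pN (vectorized). The high-force branch is undefined at
#'   `F = 0`.
#' @param polymer A [polymer_spec()].
#' @param regime `"low"` or `"high"`.
#' @return Approximate relative extension(s).
#' @export
xwlc_approx <- function(force, polymer, regime = c("low", "high")) {
  regime <- match.arg(regime)
  if (any(!is.finite(force)) || any(force < 0))
    stop("xwlc_approx(): 'force' must be finite and >= 0")
  if (regime == "low") {
    (2 / 3) * force * polymer$Lp / polymer$kBT
  } else {
    if (any(force == 0))
      stop("high-force approximation is undefined at F = 0")
    1 - 0.5 * sqrt(polymer$kBT / (force * polymer$Lp)) + force / polymer$K0
  }
}

#' Contour length of the naked region
#'
#' With `n_i` ligands bound in mode `i`, each occluding `m_i` monomers, the
#' naked sub-chain retains `N - sum(n_i m_i)` monomers of contour length `d0`
#' each.
#'
#' @param polymer A [polymer_spec()].
#' @param modes A `binding_mode` or list of them.
#' @param counts Per-mode ligand counts (see [coverage_state()]).
#' @return Naked contour length, nm, `>= 0`.
#' @export
naked_contour_length <- function(polymer, modes, counts) {
  modes <- as_mode_list(modes)
  counts <- coverage_state(counts, modes, polymer)
  m <- vapply(modes, `[[`, numeric(1), "m")
  max(0, (polymer$N - sum(counts * m)) * polymer$d0)
}

#' Extension of the ligand-covered region
#'
#' The covered region is modelled as one freely-jointed sub-chain per binding
#' mode: `x_c(F) = sum_i n_i a_i L(F a_i / kBT)` with `L` the Langevin
#' function. Saturates at `sum(n_i a_i)` for large force.
#'
#' @param force Force, pN, `>= 0` (vectorized).
#' @param modes A `binding_mode` or list of them.
#' @param counts Per-mode ligand counts.
#' @param kBT Thermal energy, pN nm.
#' @return Covered-region extension, nm.
#' @export
covered_extension <- function(force, modes, counts, kBT = 4.11) {
  modes <- as_mode_list(modes)
  if (length(counts) != length(modes))
    stop("'counts' must have one entry per binding mode")
  if (any(!is.finite(force)) || any(force < 0))
    stop("covered_extension(): 'force' must be finite and >= 0")
  a <- vapply(modes, `[[`, numeric(1), "a")
  vapply(force, function(f) sum(counts * a * langevin(f * a / kBT)),
         numeric(1))
}

#' Force-extension relation of a partially covered polymer
#'
#' Total end-to-end extension as the sum of the naked (XWLC) and covered
#' (FJC) contributions:
#' `x(F) = (N - sum n_i m_i) d0 * xwlc(F) + sum_i n_i a_i L(F a_i/kBT)`.
#' The state may be given either as per-mode ligand counts `n_i` or as
#' per-mode coverages `c_i = n_i m_i / N`; the two forms are algebraically
#' identical and coverages are converted to counts at the boundary.
#'
#' @param force Force, pN, `>= 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @param modes A `binding_mode` or list of them.
#' @param counts Per-mode ligand counts `n_i` (exclusive with `coverage`).
#' @param coverage Per-mode coverages `c_i` in `[0, 1]`, summing to at most 1.
#' @return Extension(s), nm.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' ssb <- binding_mode(m = 65, a = 5)
#' total_extension(10, ssdna, ssb, coverage = 0.5)
#' @export
total_extension <- function(force, polymer, modes, counts = NULL,
                            coverage = NULL) {
  modes <- as_mode_list(modes)
  if (is.null(counts) == is.null(coverage))
    stop("supply exactly one of 'counts' or 'coverage'")
  if (is.null(counts)) counts <- coverage_to_counts(coverage, modes, polymer)
  ln <- naked_contour_length(polymer, modes, counts)
  xwlc_relative_extension(force, polymer) * ln +
    covered_extension(force, modes, counts, polymer$kBT)
}

#' High-force asymptote of the relative extension
#'
#' In the limit `F >> kBT/Lp` and `F >> kBT/a` the relative extension of a
#' partially covered polymer depends only on the coverage `c` and the Kuhn
#' length per occluded monomer `a/m`:
#' `x/(N d0) -> 1 + (a/(m d0) - 1) c + (1 - c) F/K0`.
#'
#' @param force Force, pN, `> 0` (vectorized).
#' @param polymer A [polymer_spec()].
#' @param coverage Coverage `c` in `[0, 1]`.
#' @param a_over_m Kuhn length per occluded monomer `a/m`, nm.
#' @return Asymptotic relative extension `x/(N d0)`.
#' @export
highforce_asymptote <- function(force, polymer, coverage, a_over_m) {
  if (coverage < 0 || coverage > 1) stop("'coverage' must lie in [0, 1]")
  if (any(force <= 0)) stop("'force' must be > 0")
  1 + (a_over_m / polymer$d0 - 1) * coverage +
    (1 - coverage) * force / polymer$K0
}

#' Low-force slope of the relative extension
#'
#' Initial slope of `x/(N d0)` versus force for a single binding mode:
#' `(2 Lp / (3 kBT)) * (1 + c ((a/m) a / (d0 2 Lp) - 1))` per pN. The slope
#' exceeds the naked-chain value `2 Lp/(3 kBT)` when `(a/m) a > 2 d0 Lp`
#' (bracket positive). The formula keeps the entropic terms only: the exact
#' initial slope of the full model carries an extra enthalpic `(1 - c)/K0`
#' from the stretch modulus, a ~1% correction for ssDNA-like parameters.
#'
#' @param polymer A [polymer_spec()].
#' @param coverage Coverage `c` in `[0, 1]`.
#' @param a Kuhn length of the occluded complex, nm.
#' @param m Occluded monomers per ligand.
#' @return Slope of `x/(N d0)` per pN.
#' @export
lowforce_slope <- function(polymer, coverage, a, m) {
  if (coverage < 0 || coverage > 1) stop("'coverage' must lie in [0, 1]")
  (2 * polymer$Lp / (3 * polymer$kBT)) *
    (1 + coverage * ((a / m) * a / (polymer$d0 * 2 * polymer$Lp) - 1))
}
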