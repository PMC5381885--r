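#' Generate a synthetic force-extension curve
#'
#' Evaluates the partially-covered polymer model on a force grid and adds
#' independent Gaussian extension noise, emulating an optical-tweezers pull
#' of a ligand-coated molecule at a frozen coverage. With `noise_sd = 0` the
#' exact model curve is returned; a given `(polymer, state, noise_sd, seed)`
#' combination is bit-reproducible, and the caller's RNG state is never
#' touched.
#'
#' @param polymer A [polymer_spec()].
#' @param modes A `binding_mode` or list of them.
#' @param forces Force grid, pN, strictly increasing; default 200 log-spaced
#'   points on \[0.01, 100\] pN.
#' @param counts,coverage The coverage state, as per-mode ligand counts or
#'   coverages (exactly one).
#' @param noise_sd Gaussian extension noise standard deviation, nm, `>= 0`.
#' @param seed RNG seed for the noise.
#' @return A [fec()] curve.
#' @examples
#' ssdna <- polymer_spec(5080, 0.57, 0.715, 700)
#' curve <- generate_fec(ssdna, binding_mode(m = 65, a = 5), coverage = 0.5,
#'                       noise_sd = 2, seed = 42)
#' head(curve)
#' @export
generate_fec <- function(polymer, modes,
                         forces = 10^seq(-2, 2, length.out = 200),
                         counts = NULL, coverage = NULL, noise_sd = 0,
                         seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  x <- total_extension(forces, polymer, modes, counts = counts,
                       coverage = coverage)
  if (noise_sd > 0)
    x <- x + with_local_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  fec(forces, x)
}

#' Generate a synthetic extension-versus-time trace
#'
#' Integrates a binding-kinetics scheme at fixed force, converts the coverage
#' trajectory to extension, and adds independent Gaussian extension noise.
#' Deterministic for a fixed `(scheme, force, noise_sd, seed)`.
#'
#' @param polymer A [polymer_spec()].
#' @param scheme A [kinetic_scheme()].
#' @param force Force, pN.
#' @param times Time grid, s; defaults to [default_time_grid()].
#' @param noise_sd Gaussian extension noise sd, nm.
#' @param seed RNG seed for the noise.
#' @return A data frame with columns `time` (s) and `extension` (nm), plus
#'   per-mode count columns `n_<label>`.
#' @export
generate_kinetic_trace <- function(polymer, scheme, force, times = NULL,
                                   noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  traj <- integrate_kinetics(scheme, polymer, times = times, force = force)
  x <- traj$extension
  if (noise_sd > 0)
    x <- x + with_local_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  out <- data.frame(time = traj$time, extension = x)
  cn <- colnames(traj$counts)
  for (j in seq_along(cn)) out[[paste0("n_", cn[j])]] <- traj$counts[, j]
  out
}
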