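#' Intrinsic elastic parameters of the bare polymer
#'
#' Bundles the parameters of the extensible worm-like chain (XWLC) that
#' describes the naked (uncovered) polymer: monomer count, contour length per
#' monomer, persistence length, stretch modulus and thermal energy. Units are
#' fixed package-wide: forces in pN, lengths in nm, energies in pN nm, times
#' in s.
#'
#' @param N Total number of monomers (positive integer).
#' @param d0 Contour length per naked monomer, nm.
#' @param Lp Persistence length of the naked polymer, nm.
#' @param K0 Young (stretch) modulus, pN.
#' @param kBT Thermal energy, pN nm. The default 4.11 pN nm corresponds to
#'   25 degrees C.
#' @return An object of class `polymer_spec`.
#' @examples
#' ssdna <- polymer_spec(N = 5080, d0 = 0.57, Lp = 0.715, K0 = 700)
#' ssdna
#' @export
polymer_spec <- function(N, d0, Lp, K0, kBT = 4.11) {
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  for (nm in c("d0", "Lp", "K0", "kBT")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm))
  }
  structure(list(N = as.integer(N), d0 = d0, Lp = Lp, K0 = K0, kBT = kBT),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat("Polymer: N =", x$N, "monomers, d0 =", x$d0, "nm, Lp =", x$Lp,
      "nm, K0 =", x$K0, "pN, kBT =", x$kBT, "pN nm\n")
  cat("Contour length N*d0 =", x$N * x$d0, "nm\n")
  invisible(x)
}

#' One ligand binding mode
#'
#' A binding mode is a distinct way a ligand engages the polymer: it occludes
#' `m` monomers and the occluded complex behaves as a freely-jointed-chain
#' segment of Kuhn length `a`. The binding energy `eps_b` is needed for
#' thermodynamic calculations, the rate constants `kb`/`kr` for kinetics.
#'
#' @param m Monomers occluded per bound ligand (positive integer).
#' @param a Kuhn length of the ligand-occluded complex, nm.
#' @param eps_b Binding energy, pN nm (optional; required by the
#'   thermodynamics functions).
#' @param kb,kr Binding and release rate constants, 1/s (optional; required
#'   by the kinetics functions). `kb` is an effective rate absorbing the
#'   ligand solution concentration.
#' @param label Identifier string.
#' @return An object of class `binding_mode`.
#' @examples
#' # E. coli SSB-like mode: 65 nt occluded, 5 nm Kuhn length
#' binding_mode(m = 65, a = 5, eps_b = 0.5 * 65 * 4.11)
#' @export
binding_mode <- function(m, a, eps_b = NULL, kb = NULL, kr = NULL,
                         label = sprintf("m%d", as.integer(m))) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single finite positive number (nm)")
  if (!is.null(eps_b) && (length(eps_b) != 1L || !is.finite(eps_b)))
    stop("'eps_b' must be a single finite number (pN nm)")
  for (nm in c("kb", "kr")) {
    v <- get(nm)
    if (!is.null(v) && (length(v) != 1L || !is.finite(v) || v < 0))
      stop(sprintf("'%s' must be a single finite non-negative rate (1/s)", nm))
  }
  structure(list(label = label, m = as.integer(m), a = a, eps_b = eps_b,
                 kb = kb, kr = kr),
            class = "binding_mode")
}

#' @export
print.binding_mode <- function(x, ...) {
  cat(sprintf("Binding mode '%s': m = %d monomers, a = %g nm", x$label,
              x$m, x$a))
  if (!is.null(x$eps_b)) cat(sprintf(", eps_b = %g pN nm", x$eps_b))
  if (!is.null(x$kb)) cat(sprintf(", kb = %g /s", x$kb))
  if (!is.null(x$kr)) cat(sprintf(", kr = %g /s", x$kr))
  cat("\n")
  invisible(x)
}

# Normalize `modes` to a list of binding_mode objects.
as_mode_list <- function(modes) {
  if (inherits(modes, "binding_mode")) modes <- list(modes)
  if (!is.list(modes) || !all(vapply(modes, inherits, logical(1), "binding_mode")))
    stop("'modes' must be a binding_mode or a list of binding_mode objects")
  modes
}

#' Per-mode bound-ligand counts
#'
#' Validates a vector of (real-valued, mean-field) ligand counts against a set
#' of binding modes and a polymer: counts must be non-negative and the total
#' number of occluded monomers cannot exceed the polymer length
#' (`sum(n_i * m_i) <= N`).
#'
#' @param counts Numeric vector of per-mode ligand counts `n_i >= 0`, one per
#'   mode.
#' @param modes A `binding_mode` or list of them.
#' @param polymer A [polymer_spec()].
#' @return The validated numeric vector, named by mode label.
#' @export
coverage_state <- function(counts, modes, polymer) {
  modes <- as_mode_list(modes)
  if (length(counts) != length(modes))
    stop("'counts' must have one entry per binding mode")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("ligand counts must be finite and >= 0")
  occ <- sum(counts * vapply(modes, `[[`, numeric(1), "m"))
  # tiny relative slack so a capped 100%-coverage state (occ == N up to
  # rounding in the coverage <-> counts conversion) remains valid
  if (occ > polymer$N * (1 + 1e-9))
    stop(sprintf(
      "over-occlusion: sum(n_i*m_i) = %g exceeds N = %d monomers", occ,
      polymer$N))
  names(counts) <- vapply(modes, `[[`, character(1), "label")
  counts
}

# Convert per-mode coverages c_i = n_i m_i / N to counts.
coverage_to_counts <- function(coverage, modes, polymer) {
  modes <- as_mode_list(modes)
  if (length(coverage) != length(modes))
    stop("'coverage' must have one entry per binding mode")
  if (any(coverage < 0) || sum(coverage) > 1 + 1e-12)
    stop("coverages must be >= 0 and sum to at most 1")
  m <- vapply(modes, `[[`, numeric(1), "m")
  coverage * polymer$N / m
}

#' Force-extension curve container
#'
#' A thin data-frame subclass holding paired force (pN) and end-to-end
#' extension (nm) arrays. Forces must be strictly increasing and
#' non-negative.
#'
#' @param force Numeric vector of forces, pN, strictly increasing, `>= 0`.
#' @param extension Numeric vector of extensions, nm, same length.
#' @return A `data.frame` with class `fec`, columns `force` and `extension`.
#' @export
fec <- function(force, extension) {
  if (length(force) != length(extension))
    stop("'force' and 'extension' must have the same length")
  if (any(!is.finite(force)) || any(!is.finite(extension)))
    stop("force-extension curves must not contain non-finite values")
  if (any(force < 0)) stop("forces must be >= 0")
  if (length(force) > 1 && any(diff(force) <= 0))
    stop("forces must be strictly increasing")
  structure(data.frame(force = force, extension = extension),
            class = c("fec", "data.frame"))
}
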