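# Shared fixtures: ssDNA-like polymer and SSB-like binding modes with the
# parameter values used throughout the package examples.

ssdna <- function() polymer_spec(N = 5080, d0 = 0.57, Lp = 0.715, K0 = 700,
                                 kBT = 4.11)

# SSB-like mode: site size m, Kuhn length 5 nm, binding energy 0.5 kBT per
# occluded monomer.
ssb_mode <- function(m = 65, a = 5, kb = NULL, kr = NULL,
                     label = sprintf("m%d", m))
  binding_mode(m = m, a = a, eps_b = 0.5 * m * 4.11, kb = kb, kr = kr,
               label = label)

# Single fast-binding mode, slow release.
one_mode_scheme <- function()
  kinetic_scheme(binding_mode(m = 35, a = 5, kb = 1, kr = 1e-5))

# Fast weak mode 1 competing with slow strong mode 2.
competing_scheme <- function()
  kinetic_scheme(list(
    binding_mode(m = 65, a = 5, kb = 1, kr = 0.1, label = "mode1"),
    binding_mode(m = 35, a = 5, kb = 5e-2, kr = 1e-5, label = "mode2")))

# Mode 1 binds, then converts to mode 2 in sets of s = 2 ligands.
conversion_scheme <- function()
  kinetic_scheme(list(
    binding_mode(m = 65, a = 5, kb = 1, kr = 1e-5, label = "mode1"),
    binding_mode(m = 35, a = 5, kb = 0, kr = 1e-5, label = "mode2")),
    s = 2, k12 = 1e-3, k21 = 5e-5)

# Independent bisection oracle for the XWLC relative extension: bisect the
# interpolation-formula residual, no derivatives, no shared code path with
# xwlc_relative_extension()'s uniroot + Newton polish.
xwlc_bisect_oracle <- function(force, polymer, tol = 1e-12) {
  lo <- 0
  hi <- 1 + force / polymer$K0 - 1e-12
  resid <- function(r) {
    t <- 1 - r + force / polymer$K0
    0.25 / t^2 - 0.25 + r - force / polymer$K0 -
      force * polymer$Lp / polymer$kBT
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
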