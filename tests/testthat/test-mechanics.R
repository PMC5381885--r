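test_that("Langevin function has correct limits, values, and stability", {
  expect_identical(langevin(0), 0)
  # coth(1) - 1, frozen from high-precision evaluation
  expect_equal(langevin(1), 0.3130352854993312, tolerance = 1e-14)
  # saturation: coth(u) -> 1 for large u, so L(u) = 1 - 1/u
  expect_equal(langevin(1e6), 1 - 1e-6, tolerance = 1e-12)
  # continuity across the series/direct switch at u = 0.1: the jump across
  # the branch cut is dominated by the genuine slope L'(0.1) ~ 1/3 times
  # the 2e-11 step in u, so the branches themselves agree to ~1e-15
  du <- 0.1 * 1e-9
  expect_lt(abs(langevin(0.1 - du) - langevin(0.1 + du)), 1e-10)
  # monotone increasing, bounded in [0, 1)
  u <- 10^seq(-6, 3, length.out = 200)
  lu <- langevin(u)
  expect_true(all(diff(lu) > 0))
  expect_true(all(lu >= 0 & lu < 1))
  expect_error(langevin(-0.1), "finite")
  expect_error(langevin(NaN), "finite")
})

test_that("XWLC relative extension solves the interpolation formula", {
  p <- ssdna()
  expect_identical(xwlc_relative_extension(0, p), 0)
  # agreement with an independent bisection oracle
  for (f in c(0.01, 1, 5.75, 50, 500)) {
    expect_equal(xwlc_relative_extension(f, p), xwlc_bisect_oracle(f, p),
                 tolerance = 1e-9)
  }
  # residual below 1e-9 across a wide log force grid
  fgrid <- 10^seq(-3, 3, length.out = 120)
  r <- xwlc_relative_extension(fgrid, p)
  resid <- abs(0.25 / (1 - r + fgrid / p$K0)^2 - 0.25 + r - fgrid / p$K0 -
                 fgrid * p$Lp / p$kBT)
  expect_lt(max(resid), 1e-9)
  # monotone non-decreasing in force
  expect_true(all(diff(r) >= 0))
  # within 2% of the explicit high-force branch at 50 pN
  expect_equal(xwlc_relative_extension(50, p), xwlc_approx(50, p, "high"),
               tolerance = 0.02)
  expect_error(xwlc_relative_extension(-1, p), "finite")
})

test_that("explicit approximations hold in their regimes and fail at the crossover", {
  p <- ssdna()
  # direct arithmetic: (2/3) F Lp / kBT at F = 1 pN
  expect_equal(xwlc_approx(1, p, "low"), (2 / 3) * 0.715 / 4.11,
               tolerance = 1e-12)
  expect_identical(xwlc_approx(0, p, "low"), 0)
  expect_error(xwlc_approx(0, p, "high"), "undefined")
  fc <- p$kBT / p$Lp     # crossover force splitting the regimes
  # both branches are worse at the crossover than deep in their regime
  err <- function(f, reg) abs(xwlc_approx(f, p, reg) -
                                xwlc_relative_extension(f, p))
  expect_gt(err(fc, "high"), err(10 * fc, "high"))
  expect_gt(err(fc, "low"), err(0.1 * fc, "low"))
  # better than 5% relative agreement well inside each regime
  flow <- 10^seq(-3, log10(0.1 * fc), length.out = 40)
  rel_low <- abs(xwlc_approx(flow, p, "low") /
                   xwlc_relative_extension(flow, p) - 1)
  expect_lt(max(rel_low), 0.05)
  fhigh <- 10^seq(log10(10 * fc), 3, length.out = 40)
  rel_high <- abs(xwlc_approx(fhigh, p, "high") /
                    xwlc_relative_extension(fhigh, p) - 1)
  expect_lt(max(rel_high), 0.05)
})

test_that("naked contour length shrinks with bound ligands and forbids over-occlusion", {
  p <- ssdna()
  md <- ssb_mode(65)
  expect_equal(naked_contour_length(p, md, 0), 5080 * 0.57)
  expect_equal(naked_contour_length(p, md, 78), (5080 - 78 * 65) * 0.57)
  # n m = N exactly fills the polymer
  expect_equal(naked_contour_length(p, ssb_mode(40), 127), 0)
  expect_error(naked_contour_length(p, ssb_mode(40), 127.1),
               "over-occlusion")
})

test_that("covered extension follows the FJC and saturates at the total Kuhn length", {
  md <- binding_mode(m = 65, a = 5)
  expect_identical(covered_extension(0, md, 100), 0)
  # n a L(1) at u = F a / kBT = 1
  expect_equal(covered_extension(4.11 / 5, md, 100, kBT = 4.11),
               100 * 5 * 0.3130352854993312, tolerance = 1e-10)
  # saturation bound |x_c - n a| <= n a kBT / (F a) at large force
  # (the bound is attained exactly once coth(u) reaches 1 in double
  # precision, so the comparison is non-strict)
  n <- 100
  for (f in c(200, 1000)) {
    gap <- abs(covered_extension(f, md, n) - n * 5)
    expect_lte(gap, n * 5 * 4.11 / (f * 5) * (1 + 1e-12))
  }
})

test_that("total extension: count and coverage forms agree, bare limit, slope shifts", {
  p <- ssdna()
  # zero coverage reduces to the bare XWLC curve
  md <- ssb_mode(65)
  f <- c(0.5, 5, 50)
  expect_equal(total_extension(f, p, md, coverage = 0),
               p$N * p$d0 * xwlc_relative_extension(f, p), tolerance = 1e-12)
  # counts vs coverages are the same model (algebraic identity), randomized
  set.seed(11)
  modes <- list(binding_mode(65, 5, label = "A"),
                binding_mode(35, 3, label = "B"))
  for (i in 1:10) {
    cv <- stats::runif(2)
    cv <- cv / sum(cv) * stats::runif(1)      # total coverage < 1
    counts <- cv * p$N / c(65, 35)
    ff <- stats::runif(1, 0, 100)
    expect_equal(total_extension(ff, p, modes, counts = counts),
                 total_extension(ff, p, modes, coverage = cv),
                 tolerance = 1e-12)
  }
  # high force: changing a/m at fixed coverage shifts x(F) but not dx/dF
  h <- 1e-3
  slope_at <- function(a, m, f) {
    md <- binding_mode(m, a)
    (total_extension(f + h, p, md, coverage = 0.5) -
       total_extension(f - h, p, md, coverage = 0.5)) / (2 * h)
  }
  f0 <- 100    # >> kBT/Lp = 5.75 pN
  x1 <- total_extension(f0, p, binding_mode(35, 5), coverage = 0.5)
  x2 <- total_extension(f0, p, binding_mode(35, 8), coverage = 0.5)
  expect_gt(abs(x2 - x1), 100)   # the curves are genuinely shifted
  expect_equal(slope_at(5, 35, f0), slope_at(8, 35, f0), tolerance = 1e-3)
  expect_error(total_extension(5, p, md), "exactly one")
})

test_that("total extension is non-negative, continuous, monotone in force", {
  p <- ssdna()
  modes <- list(binding_mode(65, 5, label = "A"),
                binding_mode(35, 3, label = "B"))
  fgrid <- seq(0, 1000, length.out = 1000)
  x <- total_extension(fgrid, p, modes, coverage = c(0.4, 0.3))
  expect_true(all(x >= 0))
  expect_true(all(diff(x) >= 0))
})

test_that("high-force asymptote is reached and has the stated special cases", {
  p <- ssdna()
  expect_equal(highforce_asymptote(10, p, 0, 5 / 35), 1 + 10 / 700)
  # c = 1 with a/m = d0: force-independent, exactly 1
  expect_equal(highforce_asymptote(c(1, 10, 100), p, 1, p$d0), rep(1, 3))
  expect_error(highforce_asymptote(10, p, 1.2, 0.2), "coverage")
  # the full model approaches the asymptote as F grows: the neglected
  # sqrt(kBT/(F Lp)) term decays as F^-1/2, leaving < 1% by 2000 pN
  md <- binding_mode(35, 5)
  gap <- vapply(c(200, 500, 2000), function(f)
    abs(total_extension(f, p, md, coverage = 0.5) / (p$N * p$d0) /
          highforce_asymptote(f, p, 0.5, 5 / 35) - 1), numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("low-force slope matches the model's initial slope", {
  p <- ssdna()
  naked_slope <- 2 * p$Lp / (3 * p$kBT)
  expect_equal(lowforce_slope(p, 0, 5, 35), naked_slope)
  # bracket vanishes at a^2/m = 2 d0 Lp: slope equals the naked value
  m <- 35
  a_star <- sqrt(2 * p$d0 * p$Lp * m)
  expect_equal(lowforce_slope(p, 1, a_star, m), naked_slope,
               tolerance = 1e-12)
  # numerical differentiation of the full model at F ~ 0: the exact slope
  # is the entropic formula plus the enthalpic stretch term (1 - c)/K0,
  # which the closed-form expression deliberately omits (a ~1% effect here)
  h <- 1e-4
  for (pars in list(c(0.3, 5, 35), c(0.8, 5, 65), c(0.5, 10, 35))) {
    md <- binding_mode(pars[3], pars[2])
    num <- (total_extension(2 * h, p, md, coverage = pars[1]) -
              total_extension(0, p, md, coverage = pars[1])) /
      (2 * h * p$N * p$d0)
    full <- lowforce_slope(p, pars[1], pars[2], pars[3]) +
      (1 - pars[1]) / p$K0
    expect_equal(num, full, tolerance = 1e-3)
    expect_equal(num, lowforce_slope(p, pars[1], pars[2], pars[3]),
                 tolerance = 0.02)
  }
})
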