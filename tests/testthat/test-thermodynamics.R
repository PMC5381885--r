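test_that("naked elastic free energy vanishes at zero force and decreases", {
  p <- ssdna()
  expect_identical(delta_g_naked(0, p), 0)
  fgrid <- seq(0, 30, length.out = 40)
  dg <- delta_g_naked(fgrid, p)
  expect_true(all(diff(dg) < 0))
  expect_lt(delta_g_naked(20, p), delta_g_naked(10, p))
  # high-force: the -F^2/(2 K0) stretch term is present, so dg_n(F) is more
  # negative than the entropic-only bound -(F - 2 sqrt(kBT F / Lp))
  f <- 100
  expect_lt(delta_g_naked(f, p), -(f - 2 * sqrt(p$kBT * f / p$Lp)))
})

test_that("covered elastic free energy matches its closed form and quadrature", {
  expect_identical(delta_g_covered(0, a = 5), 0)
  # (kBT/a) log(1/sinh(1)) at u = 1, frozen from high-precision sinh
  expect_equal(delta_g_covered(4.11 / 5, a = 5, kBT = 4.11),
               -0.13270315521137586, tolerance = 1e-10)
  # huge u: finite, equals the asymptotic (kBT/a)(log(2u) - u)
  u <- 1000
  f <- u * 4.11 / 5
  expect_equal(delta_g_covered(f, 5, 4.11),
               (4.11 / 5) * (log(2 * u) - u), tolerance = 1e-10)
  # equals -(1/(n a)) integral of the covered extension (quadrature oracle)
  a <- 5
  for (f in c(1, 8)) {
    q <- stats::integrate(function(ff) langevin(ff * a / 4.11), 0, f,
                          rel.tol = 1e-10)$value
    expect_equal(delta_g_covered(f, a, 4.11), -q, tolerance = 1e-8)
  }
  fgrid <- seq(0, 30, length.out = 40)
  expect_true(all(diff(delta_g_covered(fgrid, 5)) < 0))
})

test_that("Gibbs free energy is minimised at the ideal-gas equilibrium counts", {
  p <- ssdna()
  md <- ssb_mode(65)
  expect_equal(gibbs_free_energy(0, p, md, 0), 0)
  # stationarity at the uncapped equilibrium, by central finite differences
  for (f in c(12, 14)) {
    eq <- equilibrium_ideal(f, p, md)
    expect_false(eq$capped)
    n <- eq$counts[[1]]
    h <- 1e-5 * n
    grad <- (gibbs_free_energy(f, p, md, n + h) -
               gibbs_free_energy(f, p, md, n - h)) / (2 * h)
    expect_lt(abs(grad) / p$kBT, 1e-6)
    # the free energy decreases along the line from 0+ toward n_eq
    line <- gibbs_free_energy(f, p, md, 1e-6)
    for (frac in seq(0.1, 1, by = 0.1)) {
      g <- gibbs_free_energy(f, p, md, frac * n)
      expect_lt(g, line)
      line <- g
    }
  }
  expect_error(gibbs_free_energy(5, p, md, -1), "finite and >= 0")
})

test_that("stationarity holds for randomized parameters around the reference set", {
  p0 <- ssdna()
  set.seed(21)
  for (i in 1:5) {
    p <- polymer_spec(p0$N, p0$d0 * stats::runif(1, 0.5, 2),
                      p0$Lp * stats::runif(1, 0.5, 2),
                      p0$K0 * stats::runif(1, 0.2, 5), p0$kBT)
    m <- sample(10:100, 1)
    md <- binding_mode(m, stats::runif(1, 2, 10),
                       eps_b = stats::runif(1, 0.1, 1) * m * p$kBT)
    # pick a force where the equilibrium is uncapped
    f <- transition_force(p, md, threshold = 0.9)
    eq <- equilibrium_ideal(f, p, md)
    expect_false(eq$capped)
    n <- eq$counts[[1]]
    h <- 1e-5 * n
    grad <- (gibbs_free_energy(f, p, md, n + h) -
               gibbs_free_energy(f, p, md, n - h)) / (2 * h)
    expect_lt(abs(grad) / p$kBT, 1e-6)
  }
})

test_that("binding drive equals eps_b at rest and decays with force", {
  p <- ssdna()
  md <- ssb_mode(65)
  expect_equal(binding_drive(0, p, md), md$eps_b)
  expect_equal(binding_drive(0, p, md) / p$kBT, 32.5)
  e <- binding_drive(seq(0, 40, length.out = 50), p, md)
  expect_true(all(diff(e) < 0))
})

test_that("ideal-gas equilibrium has the exact zero-energy limit and the 100% cap", {
  p <- ssdna()
  # eps_b = 0, F = 0: exponent 0 and sinh(u)/u -> 1 give exactly n = 1
  md0 <- binding_mode(65, 5, eps_b = 0)
  eq0 <- equilibrium_ideal(0, p, md0)
  expect_equal(eq0$counts[[1]], 1, tolerance = 1e-12)
  expect_false(eq0$capped)
  # reference parameters: full coverage at 5 pN, released by 20 pN
  md <- ssb_mode(65)
  eq5 <- equilibrium_ideal(5, p, md)
  expect_true(eq5$capped)
  expect_equal(eq5$total_coverage, 1)
  expect_lt(equilibrium_ideal(20, p, md)$total_coverage, 1e-3)
  # coverage decays monotonically beyond the plateau
  cv <- vapply(seq(5, 30, length.out = 30), function(f)
    equilibrium_ideal(f, p, md)$total_coverage, numeric(1))
  expect_true(all(diff(cv) <= 1e-12))   # quadrature noise on ~1e-40 tails
  # coverage increases with binding energy at fixed force
  cv_eps <- vapply(c(0.3, 0.4, 0.5, 0.6), function(s)
    equilibrium_ideal(13, p, binding_mode(65, 5, eps_b = s * 65 * p$kBT))$
      total_coverage, numeric(1))
  expect_true(all(diff(cv_eps) > 0))
  # proportional cap across two modes: occupancy lands exactly on N
  modes <- list(ssb_mode(65, label = "A"), ssb_mode(35, label = "B"))
  eq2 <- equilibrium_ideal(5, p, modes)
  expect_true(eq2$capped)
  expect_equal(sum(eq2$counts * c(65, 35)), p$N)
})

test_that("Tonks coverage solves the implicit hard-rod equilibrium", {
  p <- ssdna()
  md <- ssb_mode(65)
  # independent scalar root-finder oracle on the implicit relation
  tonks_oracle <- function(f) {
    e <- binding_drive(f, p, md)
    resid <- function(cc) {
      y <- cc / (1 - cc)
      p$kBT * (log(p$N / md$m) + log(y) + y) - e
    }
    stats::uniroot(resid, c(1e-300, 1 - 1e-15), tol = 1e-13)$root
  }
  # plateau at rest: strictly below full coverage, above 0.9 here
  c0 <- equilibrium_coverage_tonks(0, p, md)
  expect_gt(c0, 0.9)
  expect_lt(c0, 1)
  expect_equal(c0, tonks_oracle(0), tolerance = 1e-8)
  # Lambert-W solution vs direct root-finding across the transition
  # (absolute agreement in coverage; beyond ~18 pN the coverage underflows
  # any relative comparison at root-finder precision)
  for (f in seq(0, 30, length.out = 16)) {
    expect_lt(abs(equilibrium_coverage_tonks(f, p, md) - tonks_oracle(f)),
              1e-8)
  }
  # the log-argument Lambert solver satisfies w + log w = rho, including at
  # arguments on which naive Halley iteration fails to terminate
  for (rho in c(-30, -1, 0.5, 3, 26.398361564657101, 80, 1e4)) {
    w <- polyligand:::lambertW0_logarg(rho)
    expect_equal(w + log(w), rho, tolerance = 1e-12)
  }
  # small-argument limit: W0(z) ~ z recovers the ideal-gas coverage
  weak <- binding_mode(65, 5, eps_b = -20 * p$kBT)
  ci <- equilibrium_ideal(0, p, weak)$total_coverage
  expect_equal(equilibrium_coverage_tonks(0, p, weak), ci,
               tolerance = 1e-5)
  # strong stretching drives coverage to zero
  expect_lt(equilibrium_coverage_tonks(50, p, md), 1e-10)
  # hard-rod coverage never exceeds the capped ideal-gas coverage
  for (f in seq(0, 30, length.out = 31)) {
    expect_lte(equilibrium_coverage_tonks(f, p, md),
               equilibrium_ideal(f, p, md)$total_coverage + 1e-12)
  }
})

test_that("closed-form transition force estimate scales as printed", {
  p <- ssdna()
  md <- ssb_mode(65)
  expect_equal(transition_force_approx(p, md),
               sqrt(0.5 * 4.11 * 700 / 0.57), tolerance = 1e-12)
  # eps_b = 0.5 m kBT makes the estimate independent of the site size
  expect_equal(transition_force_approx(p, ssb_mode(35)),
               transition_force_approx(p, md))
  # square-root scaling in eps_b and K0
  md4 <- binding_mode(65, 5, eps_b = 4 * md$eps_b)
  expect_equal(transition_force_approx(p, md4),
               2 * transition_force_approx(p, md))
  p4 <- polymer_spec(p$N, p$d0, p$Lp, 4 * p$K0, p$kBT)
  expect_equal(transition_force_approx(p4, md),
               2 * transition_force_approx(p, md))
})

test_that("numeric transition force sits far below the closed-form estimate", {
  p <- ssdna()
  for (m in c(65, 35)) {
    tf <- transition_force(p, ssb_mode(m))
    expect_gte(tf, 10)
    expect_lte(tf, 15)
  }
  md <- ssb_mode(65)
  # threshold ordering under monotone coverage decay
  f9 <- transition_force(p, md, threshold = 0.9)
  f5 <- transition_force(p, md, threshold = 0.5)
  f1 <- transition_force(p, md, threshold = 0.1)
  expect_lte(f9, f5)
  expect_lte(f5, f1)
  # hard-rod statistics give a (slightly) earlier transition here
  expect_lte(transition_force(p, md, statistics = "tonks"), f5)
  # a weak binder whose rest coverage is already below threshold errors
  weak <- binding_mode(65, 5, eps_b = -20 * p$kBT)
  expect_error(transition_force(p, weak), "already")
})
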