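spec_on <- function(f, p) as_power_spectrum(f, p)

test_that("pdbsi: boundary cases, toy value, invariances", {
  f <- seq(1, 30, by = 0.1)
  p <- runif(length(f), 0.5, 2)
  same <- spec_on(f, p)
  expect_equal(pdbsi(same, same)$pdbsi, 0)

  # maximal asymmetry: all power on one side
  expect_equal(pdbsi(spec_on(f, rep(0, length(f))),
                     spec_on(f, rep(3, length(f))))$pdbsi, 1)

  # two-bin toy: R = (2, 1), L = (1, 1) -> (|1/3| + 0) / 2
  toy <- pdbsi(spec_on(c(1, 2), c(1, 1)), spec_on(c(1, 2), c(2, 1)),
               band = c(0.5, 3))
  expect_equal(toy$pdbsi, 1 / 6, tolerance = 1e-12)

  # symmetry under left/right swap; invariance under common rescaling;
  # bounded in [0, 1]
  left <- spec_on(f, runif(length(f), 0, 2))
  right <- spec_on(f, runif(length(f), 0, 2))
  a <- pdbsi(left, right)$pdbsi
  expect_equal(pdbsi(right, left)$pdbsi, a)
  expect_equal(pdbsi(spec_on(f, 5 * left$power),
                     spec_on(f, 5 * right$power))$pdbsi, a)
  expect_gte(a, 0); expect_lte(a, 1)
  pf <- pdbsi(left, right)$per_frequency
  expect_true(all(pf >= 0 & pf <= 1))

  # raw-sum mode is the normalized mean times M*N
  raw <- pdbsi(left, right, normalize = FALSE)
  expect_equal(raw$pdbsi, a * raw$n_pairs * raw$n_freqs)

  expect_error(pdbsi(left, right, band = c(40, 50)),
               class = "qeeg_parameter_error")
})

test_that("pdbsi partitions: split halves and N-weighted recombination", {
  f <- seq(1, 30, by = 0.1)
  left <- spec_on(f, runif(length(f), 0.5, 2))
  right <- spec_on(f, runif(length(f), 0.5, 2))

  sp <- pdbsi_split(left, right, split = 10)
  total <- pdbsi(left, right)
  # total equals the N-weighted mean of the parts
  nlo <- sp$low$n_pairs * sp$low$n_freqs
  nhi <- sp$high$n_pairs * sp$high$n_freqs
  expect_equal((sp$low$pdbsi * nlo + sp$high$pdbsi * nhi) / (nlo + nhi),
               total$pdbsi, tolerance = 1e-12)

  # identical spectra -> both halves zero
  sp0 <- pdbsi_split(left, left, split = 10)
  expect_equal(sp0$low$pdbsi, 0)
  expect_equal(sp0$high$pdbsi, 0)

  # asymmetry confined to 20-30 Hz with split at 10 -> low 0, high > 0
  pl <- rep(1, length(f)); pr <- rep(1, length(f))
  pr[f >= 20] <- 2
  sph <- pdbsi_split(spec_on(f, pl), spec_on(f, pr), split = 10)
  expect_equal(sph$low$pdbsi, 0)
  expect_gt(sph$high$pdbsi, 0)

  # flat asymmetry a at all bins -> low = high = a
  spa <- pdbsi_split(spec_on(f, rep(1, length(f))),
                     spec_on(f, rep(3, length(f))), split = 10)
  expect_equal(spa$low$pdbsi, 0.5)
  expect_equal(spa$high$pdbsi, 0.5)

  expect_error(pdbsi_split(left, right, split = 35),
               class = "qeeg_parameter_error")
})

test_that("slowing ratios: definitions, invariances, degenerate input", {
  f <- seq(0.5, 31, by = 0.1)
  flat <- band_powers(as_power_spectrum(f, rep(1, length(f))))
  s <- slowing(flat)
  expect_equal(s$dar, 21 / 51, tolerance = 1e-12)
  expect_equal(s$dtabr, 52 / 112, tolerance = 1e-12)

  # delta sum = alpha sum -> dar = 1
  p <- rep(0, length(f))
  p[f >= 1 & f <= 3] <- 1
  p[f >= 8 & f <= 13] <- 21 / 51
  expect_equal(slowing(band_powers(as_power_spectrum(f, p)))$dar, 1,
               tolerance = 1e-12)

  # invariance under rescaling; monotone in added delta / removed alpha
  q <- runif(length(f), 0.5, 2)
  s0 <- slowing(band_powers(as_power_spectrum(f, q)))
  s5 <- slowing(band_powers(as_power_spectrum(f, 5 * q)))
  expect_equal(s5$dar, s0$dar)
  expect_equal(s5$dtabr, s0$dtabr)
  qd <- q; qd[f >= 1 & f <= 3] <- qd[f >= 1 & f <= 3] + 1
  expect_gt(slowing(band_powers(as_power_spectrum(f, qd)))$dar, s0$dar)
  qa <- q; qa[f >= 8 & f <= 13] <- qa[f >= 8 & f <= 13] * 2
  expect_lt(slowing(band_powers(as_power_spectrum(f, qa)))$dar, s0$dar)

  # alpha = 0 -> degenerate error, not infinity
  z <- rep(1, length(f)); z[f >= 8 & f <= 13] <- 0
  expect_error(slowing(band_powers(as_power_spectrum(f, z))),
               class = "qeeg_degenerate_error")
})

test_that("aperiodic fit: exact recovery, flat slope, robustness to peaks", {
  f <- seq(0.5, 30, by = 0.1)

  # exact power law P = 10^2 * f^-1.5
  ap <- aperiodic_fit(as_power_spectrum(f, 100 * f^-1.5))
  expect_equal(ap$intercept, 2, tolerance = 1e-6)
  expect_equal(ap$slope, 1.5, tolerance = 1e-6)
  expect_lt(ap$residual_rms, 1e-9)

  # flat spectrum -> slope 0
  expect_equal(aperiodic_fit(as_power_spectrum(f, rep(4, length(f))))$slope,
               0, tolerance = 1e-9)

  # alpha peak 10x background at 10 Hz, sigma 1 Hz: slope within 5%
  pk <- 100 * f^-1.5 * (1 + 10 * exp(-(f - 10)^2 / 2))
  ap2 <- aperiodic_fit(as_power_spectrum(f, pk))
  expect_lt(abs(ap2$slope - 1.5) / 1.5, 0.05)

  # nonpositive power in range -> domain error
  bad <- 100 * f^-1.5; bad[50] <- 0
  expect_error(aperiodic_fit(as_power_spectrum(f, bad)),
               class = "qeeg_domain_error")
  expect_error(aperiodic_fit(as_power_spectrum(f, 100 * f^-1.5),
                             fit_range = c(0.5, 1.2)),
               class = "qeeg_parameter_error")
})

test_that("two-pass fit beats single-pass OLS under peak contamination", {
  f <- seq(0.5, 30, by = 0.1)
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    chi <- runif(1, 0.8, 2.2)
    height <- runif(1, 4, 12)
    centre <- runif(1, 6, 20)
    width <- runif(1, 0.5, 2)
    p <- 50 * f^-chi *
      (1 + height * exp(-(f - centre)^2 / (2 * width^2))) *
      exp(rnorm(length(f), 0, 0.02))
    robust <- aperiodic_fit(as_power_spectrum(f, p))$slope
    ols <- -unname(stats::lm.fit(cbind(1, log10(f)), log10(p))$coefficients[2])
    if (abs(robust - chi) < abs(ols - chi)) wins <- wins + 1L
  }
  expect_gte(wins, 16)   # robust pass wins in >= 80% of seeded spectra
})
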