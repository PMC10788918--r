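test_that("FCS model amplitude, limits and positivity", {
  lags <- fcs_lag_grid()
  expect_true(all(diff(lags) > 0))
  # no dark state: pure diffusion with G(0+) = 1/N
  g0 <- fcs_model(fcs_params(n_mol = 4, tau_d = 1e-4), lags)
  expect_equal(g0$g[1], 1 / 4, tolerance = 3e-3)
  expect_lt(g0$g[length(lags)], 1e-3)
  expect_true(all(diff(g0$g) < 0))
  # fast blinking regime: G(0+) = (1/N) (1 + A/(1-A)) = 2/N at A = 0.5
  g1 <- fcs_model(fcs_params(2, 1e-3, a_dark = 0.5, tau_dark = 1e-5),
                  lags = c(1e-8, 1e-7))
  expect_equal(g1$g[1], 2 / 2 * (1 + 1e-8 * 0), tolerance = 2e-3)
  # 2-D geometry: half-decay exactly at tau = tau_d
  g2 <- fcs_model(fcs_params(1, 1e-4), lags = c(1e-7, 1e-4),
                  geometry = "2d")
  expect_equal(g2$g[2], 0.5, tolerance = 1e-3)
  expect_error(fcs_params(1, 1e-4, a_dark = 1), "singular")
  expect_true(all(fcs_model(fcs_params(1, 1e-4, 0.8, 1e-6), lags)$g > 0))
})

test_that("dark terms map photophysics onto the FCS model", {
  # free Cy5: amplitude nearly irradiance-independent when both
  # transitions are photo-driven
  # with both channels photo-driven the amplitude varies only through the
  # excited-state saturation factor; ~0.55 -> 0.50 over 1-100 kW/cm2
  m <- cy5_free()
  As <- vapply(c(1, 3, 10, 30, 100) * 1e3, function(p)
    dark_terms_from_model(m, excitation(p, 640))[["a_dark"]], numeric(1))
  expect_lt((max(As) - min(As)) / mean(As), 0.10)
  expect_lt((max(As[1:4]) - min(As[1:4])) / mean(As[1:4]), 0.05)
  # CF640R: amplitude vanishes at low irradiance, ~0.027 at 16 kW/cm2
  cf <- cf640r()
  expect_lt(dark_terms_from_model(cf, excitation(100, 640))[["a_dark"]],
            5e-3)
  expect_equal(dark_terms_from_model(cf, excitation(16e3, 640))[["a_dark"]],
               0.0275, tolerance = 1e-2)
  # relaxation time is the inverse summed rate
  dt <- dark_terms_from_model(m, excitation(16e3, 640))
  expect_equal(dt[["tau_dark"]],
               1 / sum(effective_iso_rates(m, excitation(16e3, 640))))
})

test_that("fitted dark amplitude of a noiseless curve matches the generator", {
  # dual route: an independent direct (A, tau_dark) fit in this test vs
  # the package's dark_terms_from_model mapping
  m <- cy5_free()
  exc <- excitation(16e3, 640)
  truth <- dark_terms_from_model(m, exc)
  curve <- synth_fcs_curve(m, exc, n_mol = 2, tau_d = 1e-4, noise = 0,
                           seed = 1)$curve
  res <- minpack.lm::nls.lm(
    par = c(n = 1, A = 0.3, lt = -6, ltd = -4),
    lower = c(1e-3, 0, -9, -7), upper = c(1e3, 0.99, -3, 0),
    fn = function(p) {
      gd <- (1 + curve$lag_s / 10^p[4])^-1 *
        (1 + curve$lag_s / (25 * 10^p[4]))^-0.5
      curve$g - gd / p[1] * (1 + p[2] / (1 - p[2]) *
                               exp(-curve$lag_s / 10^p[3]))
    },
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15))
  est <- coef(res)
  expect_equal(est[[2]], truth[["a_dark"]], tolerance = 1e-8)
  expect_equal(10^est[[3]], truth[["tau_dark"]], tolerance = 1e-6)
})

test_that("multi-species mixtures use brightness-squared weights", {
  lags <- fcs_lag_grid(1e-7, 0.1)
  p1 <- fcs_params(2, 5e-5, 0.5, 5e-6)
  p2 <- fcs_params(2, 5e-5, 0, 1e-6)
  # single component: identical to fcs_model bit-for-bit
  expect_identical(
    multispecies_fcs(list(list(R = 1, Q = 3, params = p1)), lags)$g,
    fcs_model(p1, lags)$g)
  # two identical components at R = 0.5: same as a single species
  expect_equal(
    multispecies_fcs(list(list(R = 0.5, Q = 2, params = p1),
                          list(R = 0.5, Q = 2, params = p1)), lags)$g,
    fcs_model(p1, lags)$g, tolerance = 1e-12)
  # 50/50 with Q ratio 2.2: weight of the dimmer species 1/(1 + 2.2^2)
  mix <- multispecies_fcs(list(list(R = 0.5, Q = 1, params = p1),
                               list(R = 0.5, Q = 2.2, params = p2)), lags)
  w1 <- 1 / (1 + 2.2^2)
  expect_equal(mix$g, w1 * fcs_model(p1, lags)$g +
                 (1 - w1) * fcs_model(p2, lags)$g, tolerance = 1e-12)
  expect_error(multispecies_fcs(list(list(R = 0.4, Q = 1, params = p1)),
                                lags), "sum to 1")
})

test_that("global FCS fit recovers shared photophysics without bias", {
  phis <- c(10e3, 30e3, 100e3)
  excs <- lapply(phis, excitation, wavelength = 640)
  # zero noise: near-exact recovery
  m <- cy5_free()
  clean <- lapply(seq_along(excs), function(i)
    synth_fcs_curve(m, excs[[i]], n_mol = 2, tau_d = 5e-5, noise = 0,
                    seed = i)$curve)
  f0 <- global_fit_fcs(clean, excs, "isomerization", sigma = 6.2e-16)
  expect_true(f0$converged)
  expect_equal(unname(coef(f0)["k_iso"]), 29e6, tolerance = 1e-4)
  expect_equal(unname(coef(f0)["sigma_biso"]), 0.15e-16, tolerance = 1e-4)
  # 1% noise, 50 seeded replicates: |bias| < 5% for both schemes
  k_iso_hat <- vapply(1:50, function(rep) {
    curves <- lapply(seq_along(excs), function(i)
      synth_fcs_curve(m, excs[[i]], n_mol = 2, tau_d = 5e-5, noise = 0.01,
                      seed = 7000 + 10 * rep + i)$curve)
    unname(coef(global_fit_fcs(curves, excs, "isomerization",
                               sigma = 6.2e-16))["k_iso"])
  }, numeric(1))
  expect_lt(abs(mean(k_iso_hat) - 29e6) / 29e6, 0.05)

  cf <- cf640r()
  excs2 <- lapply(c(20e3, 60e3, 150e3), excitation, wavelength = 640)
  pars_hat <- vapply(1:50, function(rep) {
    curves <- lapply(seq_along(excs2), function(i)
      synth_fcs_curve(cf, excs2[[i]], n_mol = 2, tau_d = 5e-5,
                      noise = 0.01, seed = 8000 + 10 * rep + i)$curve)
    coef(global_fit_fcs(curves, excs2, "triplet", sigma = 4e-16))[1:2]
  }, numeric(2))
  expect_lt(abs(mean(pars_hat[1, ]) - 0.7e6) / 0.7e6, 0.05)
  expect_lt(abs(mean(pars_hat[2, ]) - 0.5e6) / 0.5e6, 0.05)
})

test_that("mixture-fraction FCS fit recovers frozen-component fractions", {
  p_cy5 <- fcs_params(2, 5e-5, 0.5, 4e-6)
  p_cf <- fcs_params(2, 5e-5, 0.03, 1.4e-6)
  lags <- fcs_lag_grid(1e-7, 0.1)
  for (R in c(0.25, 0.5, 0.75)) {
    clean <- multispecies_fcs(list(list(R = R, Q = 1, params = p_cy5),
                                   list(R = 1 - R, Q = 2.2, params = p_cf)),
                              lags)
    set.seed(round(100 * R))
    noisy <- new_fcs_curve(lags, clean$g *
                             (1 + rnorm(length(lags), 0,
                                        0.01 / sqrt(seq_along(lags)))))
    fit <- fit_fcs_fraction(noisy, list(Q = 1, params = p_cy5),
                            list(Q = 2.2, params = p_cf), R_start = 0.5)
    expect_true(fit$converged)
    expect_lt(abs(unname(coef(fit)["R"]) - R), 0.05)
  }
})

test_that("burst filter excises exactly the injected spikes", {
  set.seed(1)
  tr <- rpois(500, 10)
  spikes <- c(5, 50, 100, 200, 400)
  tr[spikes] <- 100
  bf <- burst_filter(tr, k_sigma = 5)
  expect_equal(which(bf$mask), spikes)
  expect_length(bf$trace, 495)
  # clean trace: identity
  set.seed(100)
  tr2 <- rpois(300, 10)
  bf2 <- burst_filter(tr2, k_sigma = 8)
  expect_identical(bf2$trace, tr2)
  # degenerate traces
  expect_warning(burst_filter(rep(0, 200)), "all-zero")
  cst <- burst_filter(rep(3, 200))
  expect_identical(cst$trace, rep(3, 200))
  expect_error(burst_filter(rpois(50, 5)), "at least 100")
})
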