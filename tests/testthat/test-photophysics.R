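test_that("excitation rate follows the photon-flux formula and is linear", {
  exc <- excitation(16e3, 640)
  # sigma * Phi * lambda / (h c), evaluated by hand
  expect_equal(excitation_rate(6.2e-16, exc), 3.1961e7, tolerance = 1e-4)
  expect_equal(excitation_rate(6.2e-16, excitation(1e3, 638)),
               1.9914e6, tolerance = 1e-4)
  expect_identical(excitation_rate(0, exc), 0)
  # linearity in both arguments
  expect_equal(excitation_rate(6.2e-16, excitation(2e3, 640)),
               2 * excitation_rate(6.2e-16, excitation(1e3, 640)))
  expect_equal(excitation_rate(2 * 6.2e-16, exc),
               2 * excitation_rate(6.2e-16, exc))
  expect_error(excitation_rate(-1e-16, exc), "sigma")
  expect_error(excitation(-1, 640), "irradiance")
  expect_error(excitation(100, 200), "wavelength")
})

test_that("model constructors enforce their invariants", {
  expect_error(iso_model(6.2e-16, 2e9, 0.1e-16), "k10")
  expect_error(iso_model(1e-17, 29e6, 2e-17), "sigma_biso")
  expect_error(triplet_model(4e-16, 2e9, 0.5e6), "k_isc")
  expect_s3_class(cy5_free(), "fluorophore_model")
})

test_that("effective isomerization rates match hand evaluation and limits", {
  m <- cy5_free()
  exc <- excitation(16e3, 640)
  r <- effective_iso_rates(m, exc)
  expect_equal(unname(r["k_iso_eff"]), 8.9815e5, tolerance = 1e-4)
  expect_equal(unname(r["k_biso_eff"]), 7.7324e5, tolerance = 1e-4)
  # no excitation: forward off, backward thermal only
  m2 <- cy5_free(k_biso_th = 1600)
  r0 <- effective_iso_rates(m2, excitation(0, 640))
  expect_identical(unname(r0["k_iso_eff"]), 0)
  expect_equal(unname(r0["k_biso_eff"]), 1600)
  # saturation: k_iso_eff -> k_iso as k_exc >> k10
  sat <- effective_iso_rates(m, excitation(1e12, 640))
  expect_equal(unname(sat["k_iso_eff"]), m$k_iso, tolerance = 1e-2)
  # strictly increasing in irradiance
  phis <- c(1, 3, 10, 30, 100, 1000) * 1e3
  kk <- vapply(phis, function(p)
    effective_iso_rates(m, excitation(p, 640))["k_iso_eff"], numeric(1))
  expect_true(all(diff(kk) > 0))
})

test_that("effective intersystem crossing rate matches hand evaluation", {
  m <- cf640r()
  expect_equal(effective_isc_rate(m, excitation(16e3, 640)),
               1.414e4, tolerance = 1e-3)
  expect_identical(effective_isc_rate(m, excitation(0, 640)), 0)
  # non-saturating calibration condition: negligible triplet amplitude
  k <- effective_isc_rate(m, excitation(20, 640))
  expect_lt(k / m$k_T, 1e-3)
  phis <- c(1, 10, 100, 1000) * 1e3
  kk <- vapply(phis, function(p)
    effective_isc_rate(m, excitation(p, 640)), numeric(1))
  expect_true(all(diff(kk) > 0))
})

test_that("steady-state dark fraction behaves across regimes", {
  # free Cy5 at the FCS irradiance: about half the population in the dark
  # cis state
  expect_equal(steady_state(cy5_free(), excitation(16e3, 640)),
               0.5374, tolerance = 1e-3)
  # zero excitation with a thermal escape channel: fully bright
  expect_identical(steady_state(cy5_free(k_biso_th = 100),
                                excitation(0, 640)), 0)
  # symmetric rates: one half
  m <- triplet_model(4e-16, k_isc = 1e6, k_T = 1e6 * 4e-16 *
                       trastkit::photon_flux(excitation(1e3, 640)) /
                       (4e-16 * trastkit::photon_flux(excitation(1e3, 640)) + 1e9),
                     k10 = 1e9)
  r <- effective_isc_rate(m, excitation(1e3, 640))
  expect_equal(r / (r + m$k_T), 0.5, tolerance = 1e-12)
  expect_error(steady_state(iso_model(6.2e-16, 0, 0), excitation(0, 640)),
               "undefined")
})

test_that("population evolution conserves occupancy and hits its limits", {
  m <- cy5_free(k_biso_th = 1600)
  exc <- excitation(1e3, 638)
  tg <- c(0, 10^seq(-8, -3, length.out = 40))
  p <- evolve_population(m, exc, tg)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
  expect_identical(unname(p[1, "bright"]), 1)
  expect_equal(unname(p[nrow(p), "dark"]), steady_state(m, exc),
               tolerance = 1e-6)
  # monotone relaxation
  expect_true(all(diff(p[, "dark"]) >= -1e-14))
  expect_error(evolve_population(m, exc, c(1e-6, 1e-7)), "sorted")
})

test_that("analytic relaxation agrees with brute-force Euler and expm oracles", {
  m <- cy5_free()
  exc <- excitation(1e3, 640)
  r <- effective_iso_rates(m, exc)
  k_on <- unname(r["k_iso_eff"]); k_off <- unname(r["k_biso_eff"])
  tau <- 1 / (k_on + k_off)
  for (t_end in c(0.3 * tau, tau, 5 * tau)) {
    bright <- evolve_population(m, exc, c(0, t_end))[2, "bright"]
    expect_equal(unname(bright), euler_two_state(k_on, k_off, t_end),
                 tolerance = 1e-6)
    expect_equal(unname(bright), expm_two_state(k_on, k_off, t_end)[1],
                 tolerance = 1e-9)
  }
  # dark fraction at t = tau equals A (1 - 1/e)
  A <- k_on / (k_on + k_off)
  dark <- evolve_population(m, exc, c(0, tau))[2, "dark"]
  expect_equal(unname(dark), A * (1 - exp(-1)), tolerance = 1e-10)
})

test_that("three-state triplet extension conserves occupancy and reduces to 2 states", {
  m <- iso_model(6.2e-16, 29e6, 0.15e-16, k_isc = 1.1e6, k_T = 0.5e6,
                 name = "Cy5+T")
  exc <- excitation(200e3, 640)
  tg <- c(0, 1e-7, 1e-6, 1e-5, 1e-4)
  p3 <- evolve_population(m, exc, tg, triplet_extension = "on")
  expect_equal(ncol(p3), 3L)
  expect_equal(unname(rowSums(p3)), rep(1, nrow(p3)), tolerance = 1e-10)
  # auto mode stays 2-state below the threshold
  p2 <- evolve_population(m, excitation(1e3, 640), tg)
  expect_equal(ncol(p2), 2L)
  # zero triplet branch: the 3-state solution matches the 2-state one
  m0 <- iso_model(6.2e-16, 29e6, 0.15e-16, name = "Cy5")
  a <- evolve_population(m0, exc, tg)
  m0$k_isc <- 1e-9  # vanishing branch, forces the expm path
  b <- evolve_population(m0, exc, tg, triplet_extension = "on")
  expect_equal(unname(b[, "bright"]), unname(a[, "bright"]),
               tolerance = 1e-8)
})

test_that("fluorophore presets load from JSON and round-trip", {
  m <- fluorophore("Cy5_free")
  expect_equal(m$sigma_N, 6.2e-16)
  expect_equal(m$k_iso, 29e6)
  expect_equal(m$sigma_biso, 0.15e-16)
  suv <- fluorophore("Cy5_SUV")
  expect_equal(suv$k_iso, 6.2e6)
  cf <- fluorophore("CF640R")
  expect_equal(cf$k_isc, 0.7e6)
  expect_equal(cf$k_T, 0.5e6)
  tmp <- tempfile(fileext = ".json")
  write_fluorophore(m, tmp)
  m2 <- read_fluorophore(tmp)
  expect_equal(m2[names(m2) != "name"], m[names(m) != "name"])
  expect_error(fluorophore("NotADye"), "unknown")
})
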