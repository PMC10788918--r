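test_that("background subtraction cancels exactly and bleach is corrected", {
  widths <- trast_widths(12)
  gen <- synth_cell_stack(24, widths = widths, photon_budget = Inf,
                          background = 0, seed = 3)
  norm0 <- correct_and_normalize(gen$stack)
  # adding a uniform background that is declared leaves the curves unchanged
  st_b <- gen$stack
  st_b$frames <- st_b$frames + 50
  st_b$background <- 50
  norm_b <- correct_and_normalize(st_b)
  expect_equal(norm_b$curves, norm0$curves, tolerance = 1e-12)
  # monoexponential bleaching at 1%/frame, corrected via reference frames
  n <- length(widths)
  decay <- 0.99^(seq_len(n) - 1)
  st_bl <- gen$stack
  for (k in seq_len(n)) st_bl$frames[, , k] <- st_bl$frames[, , k] * decay[k]
  st_bl$ref_before <- gen$stack$frames[, , 1]
  st_bl$ref_after <- gen$stack$frames[, , 1] * decay[n]
  norm_bl <- correct_and_normalize(st_bl)
  on <- is.finite(norm0$curves) & norm0$curves > 0
  expect_lt(max(abs(norm_bl$curves[on] - norm0$curves[on]) /
                  norm0$curves[on]), 0.005)
  # negative corrected values are clipped with a warning
  st_neg <- gen$stack
  st_neg$background <- 10
  expect_warning(correct_and_normalize(st_neg), "clipped")
})

test_that("3x3 Gaussian smoothing: unit sum, impulse response, variance", {
  cst <- matrix(7, 20, 20)
  expect_equal(smooth_gaussian(cst), cst, tolerance = 1e-12)
  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  sm <- smooth_gaussian(imp)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_true(all(sm[9:13, 9:13] >= 0))
  expect_equal(sum(sm[10:12, 10:12]), 1, tolerance = 1e-12)
  # white noise variance is reduced by the kernel's sum of squares
  k1 <- dnorm(-1:1, sd = 0.85)
  kern <- outer(k1, k1) / sum(outer(k1, k1))
  set.seed(8)
  wn <- matrix(rnorm(400 * 400), 400, 400)
  smw <- smooth_gaussian(wn)
  inner <- smw[20:380, 20:380]
  expect_equal(var(as.vector(inner)), sum(kern^2), tolerance = 0.05)
})

test_that("pixel-wise fitting inverts noiseless stacks exactly", {
  gen <- synth_cell_stack(28, photon_budget = Inf, background = 0, seed = 5)
  im <- fit_pixelwise(correct_and_normalize(gen$stack))
  on <- which(is.finite(gen$truth$A) & is.finite(im$a_map))
  expect_gt(length(on), 50)
  expect_equal(im$a_map[on], gen$truth$A[on], tolerance = 1e-6)
  expect_equal(im$tau_map[on], gen$truth$tau[on], tolerance = 1e-6)
  # an all-background stack yields empty maps
  set.seed(123)
  empty <- trast_stack(array(rpois(10 * 10 * 8, 20), c(10, 10, 8)),
                       widths = trast_widths(8), background = 20)
  im0 <- fit_pixelwise(suppressWarnings(correct_and_normalize(empty)))
  expect_true(all(!is.finite(im0$a_map)))
})

test_that("region medians are recovered at realistic shot noise", {
  gen <- synth_cell_stack(48, seed = 5)
  im <- fit_pixelwise(suppressWarnings(correct_and_normalize(gen$stack)))
  fil <- which(gen$truth$R1 == 1 & is.finite(im$a_map))
  rim <- which(gen$truth$R1 == 0 & is.finite(im$a_map))
  expect_gt(length(fil), 30)
  expect_gt(length(rim), 100)
  expect_equal(median(im$a_map[fil]), 0.45, tolerance = 0.1)
  expect_equal(median(im$tau_map[fil]), 30e-6, tolerance = 0.1)
  expect_equal(median(im$a_map[rim]), 0.2, tolerance = 0.1)
  expect_equal(median(im$tau_map[rim]), 2e-6, tolerance = 0.1)
})

test_that("2-D histograms project to unit-area PDFs with modes at clusters", {
  # constructed bimodal input
  img <- structure(list(
    a_map = matrix(c(rep(0.45, 60), rep(0.15, 60)), 12, 10),
    tau_map = matrix(c(rep(30e-6, 60), rep(2e-6, 60)), 12, 10),
    intensity_map = matrix(1, 12, 10),
    quality_map = matrix(0, 12, 10),
    mask = matrix(TRUE, 12, 10)), class = "trast_image")
  pdf <- build_pdfs(img)
  expect_equal(sum(pdf$pdf_a * diff(pdf$a_edges)), 1, tolerance = 1e-10)
  expect_equal(sum(pdf$pdf_tau * diff(log10(pdf$tau_edges))), 1,
               tolerance = 1e-10)
  # both cluster centers appear among the top projection bins
  peaks_a <- order(pdf$pdf_a, decreasing = TRUE)[1:4]
  expect_true(any(abs(pdf$a_mid[peaks_a] - 0.45) < 0.05))
  expect_true(any(abs(pdf$a_mid[peaks_a] - 0.15) < 0.05))
  peaks_t <- order(pdf$pdf_tau, decreasing = TRUE)[1:4]
  expect_true(any(abs(log10(pdf$tau_mid[peaks_t] / 30e-6)) < 0.2))
  expect_true(any(abs(log10(pdf$tau_mid[peaks_t] / 2e-6)) < 0.2))
  # delta-like single-valued input still has unit-area projections
  img1 <- img
  img1$a_map[] <- 0.3; img1$tau_map[] <- 1e-5
  pdf1 <- build_pdfs(img1)
  expect_equal(sum(pdf1$pdf_a * diff(pdf1$a_edges)), 1, tolerance = 1e-10)
  img_none <- img
  img_none$a_map[] <- NA
  expect_error(build_pdfs(img_none), "no converged")
})

test_that("PDF unmixing separates the two labels and conserves intensity", {
  fitstack <- function(seed, label)
    fit_pixelwise(suppressWarnings(correct_and_normalize(
      synth_cell_stack(48, label = label, seed = seed)$stack)))
  pdf1 <- build_pdfs(lapply(1:2, fitstack, label = "species1"))
  pdf2 <- build_pdfs(lapply(1:2, fitstack, label = "species2"))
  # pure-support pixels land at the endpoints
  um1 <- unmix_pixel(0.45, 30e-6, pdf1, pdf2)
  expect_equal(um1$R, 1)
  um2 <- unmix_pixel(0.15, 1.5e-6, pdf1, pdf2)
  expect_equal(um2$R, 0)
  # outside both supports: NaN with flag
  um_out <- unmix_pixel(0.99, 30e-6, pdf1, pdf2)
  expect_true(um_out$outside)
  expect_true(is.nan(um_out$R))
  # identical references: degenerate pixel reports 0.5
  um_deg <- unmix_pixel(0.45, 30e-6, pdf1, pdf1)
  expect_true(um_deg$degenerate)
  expect_equal(um_deg$R, 0.5)
  # product objective maximizer agrees with a fine grid search on
  # overlapping reference distributions
  mkimg <- function(a, tau) {
    structure(list(a_map = matrix(a, 20, 20),
                   tau_map = matrix(tau, 20, 20),
                   intensity_map = matrix(1, 20, 20),
                   quality_map = matrix(0, 20, 20),
                   mask = matrix(TRUE, 20, 20)), class = "trast_image")
  }
  set.seed(77)
  po1 <- build_pdfs(mkimg(runif(400, 0.2, 0.5),
                          exp(runif(400, log(5e-6), log(5e-5)))))
  po2 <- build_pdfs(mkimg(runif(400, 0.1, 0.4),
                          exp(runif(400, log(1e-6), log(1e-5)))))
  for (pt in list(c(0.3, 6e-6), c(0.25, 3e-6), c(0.42, 2e-5))) {
    e1 <- trastkit:::pdf_eval(po1, pt[1], pt[2])
    e2 <- trastkit:::pdf_eval(po2, pt[1], pt[2])
    grid <- seq(0, 1, by = 1e-3)
    L <- (grid * e1[1] + (1 - grid) * e2[1]) *
      (grid * e1[2] + (1 - grid) * e2[2])
    expect_lt(abs(unmix_pixel(pt[1], pt[2], po1, po2)$R -
                    grid[which.max(L)]), 2e-3)
  }
  # dual-label image: high accuracy on informative pixels
  gen <- synth_cell_stack(48, label = "both", seed = 21)
  im <- fit_pixelwise(suppressWarnings(correct_and_normalize(gen$stack)))
  Rm <- unmix_image(im, pdf1, pdf2)
  ok <- is.finite(Rm) & is.finite(gen$truth$R1)
  expect_gt(sum(ok), 200)
  expect_lt(mean(abs(Rm[ok] - gen$truth$R1[ok])), 0.15)
  # intensity conservation is exact
  comp <- compose_species_images(Rm, im$intensity_map)
  tot <- comp$image_1 + comp$image_2
  expect_equal(tot[ok], im$intensity_map[ok], tolerance = 1e-12)
})
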