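# Pixel-wise TRAST image analysis and two-fluorophore unmixing.
#
# A TRAST image stack holds one intensity frame per pulse-train setting.
# After background subtraction, optional bleach correction and w0
# normalization, every pixel carries its own TRAST curve, which is fitted
# by the monoexponential pulse-window model to yield per-pixel maps of the
# relaxation amplitude A_TRAST and relaxation time tau_TRAST. Reference
# 2-D histograms of (A, tau) from single-labeled samples provide the
# probability density functions used to unmix dual-labeled images.

#' TRAST image stack
#'
#' @param frames Numeric array `height x width x n_widths` of intensities
#'   (counts).
#' @param widths Pulse widths (s), one per frame, increasing.
#' @param w0 Reference width; must be among `widths`.
#' @param background Static ambient background: scalar or
#'   `height x width` matrix; default 0.
#' @param ref_before,ref_after Optional reference frames recorded at `w0`
#'   before and after the series, used for per-pixel bleach correction.
#' @param duty_cycle,t_ill Pulse-train metadata.
#' @return An object of class `"trast_stack"`.
#' @export
trast_stack <- function(frames, widths, w0 = min(widths), background = 0,
                        ref_before = NULL, ref_after = NULL,
                        duty_cycle = 0.01, t_ill = 1e-3) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(widths))
  if (is.unsorted(widths, strictly = TRUE))
    stop("widths must be strictly increasing")
  if (!any(widths == w0)) stop("widths must cover w0")
  structure(list(frames = frames, widths = widths, w0 = w0,
                 background = background, ref_before = ref_before,
                 ref_after = ref_after, duty_cycle = duty_cycle,
                 t_ill = t_ill),
            class = "trast_stack")
}

#' @export
print.trast_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("TRAST image stack: %d x %d pixels, %d pulse widths (%.3g-%.3g s)\n",
              d[1], d[2], d[3], min(x$widths), max(x$widths)))
  invisible(x)
}

#' Background-correct, bleach-correct and w0-normalize a stack
#'
#' Subtracts the static background from every frame, optionally applies a
#' per-pixel multiplicative photobleaching correction (estimated from
#' reference frames at `w0` recorded before and after the series, with the
#' loss interpolated linearly in acquisition order), and normalizes each
#' pixel's curve by its value at the reference width `w0`. Negative
#' background-corrected intensities are clipped at zero; the number of
#' clipped values is attached as attribute `"n_clipped"` (with a warning).
#'
#' @param stack A [trast_stack()].
#' @return List with `curves` (array `h x w x n` of normalized values),
#'   `widths`, `w0` and `intensity` (per-pixel total detected signal).
#' @export
correct_and_normalize <- function(stack) {
  stopifnot(inherits(stack, "trast_stack"))
  fr <- stack$frames
  d <- dim(fr)
  bg <- stack$background
  for (k in seq_len(d[3])) fr[, , k] <- fr[, , k] - bg
  # intensity statistics (used for masking) keep the unclipped values so
  # that background pixels stay centered at zero
  intensity_raw <- apply(fr, c(1, 2), sum)
  n_clipped <- sum(fr < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d negative background-corrected values clipped at 0",
                    n_clipped))
    fr[fr < 0] <- 0
  }
  if (!is.null(stack$ref_before) && !is.null(stack$ref_after)) {
    b0 <- stack$ref_before - bg
    b1 <- stack$ref_after - bg
    ratio <- ifelse(b0 > 0, b1 / b0, 1)  # per-pixel survival over the series
    for (k in seq_len(d[3])) {
      frac <- (k - 1) / max(1, d[3] - 1)
      corr <- 1 + frac * (ratio - 1)     # linear in acquisition order
      fr[, , k] <- fr[, , k] / pmax(corr, 1e-6)
    }
  }
  intensity <- intensity_raw
  i0 <- which(stack$widths == stack$w0)
  ref <- fr[, , i0]
  curves <- fr
  for (k in seq_len(d[3]))
    curves[, , k] <- ifelse(ref > 0, fr[, , k] / ref, NA_real_)
  structure(list(curves = curves, widths = stack$widths, w0 = stack$w0,
                 intensity = intensity),
            n_clipped = n_clipped)
}

#' 3x3 Gaussian smoothing
#'
#' Filters each frame (or a single image) with a 3x3 Gaussian kernel
#' normalized to unit sum; edges are handled by replicate padding, so a
#' constant image is returned unchanged.
#'
#' @param x Matrix, 3-D array, or [trast_stack()].
#' @param sigma Kernel standard deviation in pixels (default 0.85).
#' @return Same shape as the input.
#' @export
smooth_gaussian <- function(x, sigma = 0.85) {
  k1 <- stats::dnorm(-1:1, sd = sigma)
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  smooth_one <- function(img) {
    h <- nrow(img); w <- ncol(img)
    pad <- img[c(1, seq_len(h), h), c(1, seq_len(w), w)]
    out <- matrix(0, h, w)
    for (di in -1:1) for (dj in -1:1)
      out <- out + kern[di + 2, dj + 2] *
        pad[seq_len(h) + 1 + di, seq_len(w) + 1 + dj]
    out
  }
  if (inherits(x, "trast_stack")) {
    for (k in seq_len(dim(x$frames)[3]))
      x$frames[, , k] <- smooth_one(x$frames[, , k])
    x
  } else if (is.matrix(x)) {
    smooth_one(x)
  } else if (length(dim(x)) == 3) {
    for (k in seq_len(dim(x)[3])) x[, , k] <- smooth_one(x[, , k])
    x
  } else stop("expected a matrix, 3-D array or trast_stack")
}

# Normalized monoexponential pulse-average model values for a grid of
# (A, tau), evaluated at the given widths and renormalized at w0.
.pixel_model_matrix <- function(A, tau, widths, w0) {
  f <- function(a, tt, w) {
    x <- w / tt
    1 - a + a * (-expm1(-x)) / x
  }
  m <- mapply(function(a, tt) f(a, tt, widths) / f(a, tt, w0), A, tau)
  matrix(m, nrow = length(widths))
}

#' Pixel-wise monoexponential TRAST fit
#'
#' Fits `value(w) = [1 - A + (A tau / w)(1 - e^{-w/tau})]`, renormalized
#' at `w0`, to every masked pixel's TRAST curve. A coarse grid search over
#' (A, log tau) seeds a damped Gauss-Newton refinement run vectorized
#' across all pixels; pixels whose refinement fails keep NaN in the maps.
#'
#' @param norm A list as returned by [correct_and_normalize()].
#' @param mask Logical matrix of pixels to fit; default: pixels whose
#'   total intensity exceeds `mask_k` times the background SD estimated
#'   from the intensity map's lower quartile.
#' @param mask_k Intensity mask multiplier (default 3).
#' @param n_grid Grid resolution per axis for the seeding search.
#' @param tau_range Search range for tau (s).
#' @param n_refine Gauss-Newton refinement iterations.
#' @return An object of class `"trast_image"`: list with matrices
#'   `a_map`, `tau_map`, `intensity_map`, `quality_map` (residual SS) and
#'   logical `mask`.
#' @export
fit_pixelwise <- function(norm, mask = NULL, mask_k = 3, n_grid = 48,
                          tau_range = c(5e-7, 1e-3), n_refine = 8) {
  curves <- norm$curves
  widths <- norm$widths
  w0 <- norm$w0
  d <- dim(curves)
  if (is.null(mask)) {
    # robust background statistics: median/MAD over the whole intensity map
    # (background-dominated images); threshold = median + k * MAD-sigma
    med <- stats::median(norm$intensity, na.rm = TRUE)
    sig <- stats::mad(norm$intensity, na.rm = TRUE)
    thr <- med + mask_k * sig
    if (!is.finite(thr)) thr <- 0
    mask <- norm$intensity > thr
  }
  idx <- which(mask & apply(!is.na(curves), c(1, 2), all))
  a_map <- tau_map <- q_map <- matrix(NA_real_, d[1], d[2])
  if (length(idx) == 0)
    return(structure(list(a_map = a_map, tau_map = tau_map,
                          intensity_map = norm$intensity,
                          quality_map = q_map, mask = mask),
                     class = "trast_image"))
  Y <- matrix(curves, d[1] * d[2], d[3])[idx, , drop = FALSE]  # pix x widths

  a_grid <- seq(0.01, 0.99, length.out = n_grid)
  tau_grid <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                      length.out = n_grid))
  gg <- expand.grid(A = a_grid, tau = tau_grid)
  M <- .pixel_model_matrix(gg$A, gg$tau, widths, w0)       # widths x grid
  # SSE_pg = |y_p|^2 - 2 y_p.m_g + |m_g|^2; only the cross term varies per g
  cross <- Y %*% M
  m2 <- colSums(M^2)
  best <- max.col(sweep(2 * cross, 2, m2, "-"), ties.method = "first")
  A <- gg$A[best]; tau <- gg$tau[best]

  # damped Gauss-Newton on (A, log tau), vectorized over pixels
  model_and_jac <- function(A, tau) {
    W <- matrix(widths, length(A), length(widths), byrow = TRUE)
    x <- W / tau
    e <- exp(-x)
    base <- (1 - e) / x                      # (tau/w)(1 - e^{-w/tau})
    f <- 1 - A + A * base
    dfdA <- base - 1
    # d base / d log tau = ((1 - e) - e x) / x  [chain rule via x = w/tau]
    dbase <- ((1 - e) - e * x) / x
    dfdl <- A * dbase
    x0 <- widths[widths == w0] / tau
    e0 <- exp(-x0)
    b0 <- (1 - e0) / x0
    f0 <- 1 - A + A * b0
    db0 <- ((1 - e0) - e0 * x0) / x0
    df0dA <- b0 - 1
    df0dl <- A * db0
    g <- f / f0
    list(g = g,
         jA = (dfdA * f0 - f * df0dA) / f0^2,
         jl = (dfdl * f0 - f * df0dl) / f0^2)
  }
  for (it in seq_len(n_refine)) {
    mj <- model_and_jac(A, tau)
    Rres <- Y - mj$g
    jAA <- rowSums(mj$jA^2) + 1e-12
    jll <- rowSums(mj$jl^2) + 1e-12
    jAl <- rowSums(mj$jA * mj$jl)
    bA <- rowSums(mj$jA * Rres)
    bl <- rowSums(mj$jl * Rres)
    det <- jAA * jll - jAl^2
    ok <- is.finite(det) & det > 1e-20
    dA <- ifelse(ok, (jll * bA - jAl * bl) / det, 0)
    dl <- ifelse(ok, (jAA * bl - jAl * bA) / det, 0)
    step <- pmax(abs(dA), abs(dl))
    damp <- ifelse(step > 0.5, 0.5 / step, 1)   # cap step length
    A <- pmin(0.999, pmax(1e-4, A + damp * dA))
    tau <- tau * exp(pmin(1, pmax(-1, damp * dl)))
    tau <- pmin(tau_range[2] * 10, pmax(tau_range[1] / 10, tau))
  }
  mj <- model_and_jac(A, tau)
  sse <- rowSums((Y - mj$g)^2)
  bad <- !is.finite(sse)
  A[bad] <- NA; tau[bad] <- NA
  a_map[idx] <- A
  tau_map[idx] <- tau
  q_map[idx] <- sse
  structure(list(a_map = a_map, tau_map = tau_map,
                 intensity_map = norm$intensity, quality_map = q_map,
                 mask = mask),
            class = "trast_image")
}

#' @export
print.trast_image <- function(x, ...) {
  ok <- sum(is.finite(x$a_map))
  cat(sprintf("TRAST image: %d x %d pixels, %d fitted\n",
              nrow(x$a_map), ncol(x$a_map), ok))
  if (ok > 0)
    cat(sprintf("  median A = %.3f, median tau = %.3g s\n",
                stats::median(x$a_map, na.rm = TRUE),
                stats::median(x$tau_map, na.rm = TRUE)))
  invisible(x)
}

# 1-D smoothing with a Gaussian kernel (sigma in bins), replicate padding.
.smooth1d <- function(y, sigma = 1) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  vapply(seq_len(n), function(i)
    sum(k * ypad[i:(i + 2 * half)]), numeric(1))
}

#' 2-D (A, tau) histogram and axis-projected PDFs
#'
#' Builds the cumulative 2-D histogram of pixel-wise (A_TRAST, tau_TRAST)
#' values over one or more TRAST images, with linear bins in A and
#' logarithmic bins in tau, and the axis-projected probability density
#' functions, each normalized to unit area on its axis (linear A,
#' log10 tau). The projections are lightly smoothed (Gaussian, 1 bin) to
#' avoid zero-probability holes when used for unmixing.
#'
#' @param images A `"trast_image"` or list of them.
#' @param a_edges Bin edges for A (default 50 linear bins on [0, 1]).
#' @param tau_edges Bin edges for tau (default 60 log bins on
#'   [0.5 us, 1 ms]).
#' @param smooth_sigma Projection smoothing in bins (default 1; 0
#'   disables).
#' @return An object of class `"pdf2d"`: `a_edges`, `tau_edges`, `counts`
#'   (matrix A-bins x tau-bins), `pdf_a`, `pdf_tau`, and bin midpoints.
#' @export
build_pdfs <- function(images, a_edges = seq(0, 1, length.out = 51),
                       tau_edges = exp(seq(log(5e-7), log(1e-3),
                                           length.out = 61)),
                       smooth_sigma = 1) {
  if (inherits(images, "trast_image")) images <- list(images)
  a <- unlist(lapply(images, function(im) im$a_map))
  tau <- unlist(lapply(images, function(im) im$tau_map))
  ok <- is.finite(a) & is.finite(tau)
  a <- a[ok]; tau <- tau[ok]
  if (length(a) == 0) stop("no converged pixels to histogram")
  a <- pmin(pmax(a, a_edges[1]), a_edges[length(a_edges)] - 1e-12)
  tau <- pmin(pmax(tau, tau_edges[1]), tau_edges[length(tau_edges)] * (1 - 1e-12))
  ia <- findInterval(a, a_edges, rightmost.closed = TRUE)
  it <- findInterval(tau, tau_edges, rightmost.closed = TRUE)
  na <- length(a_edges) - 1; nt <- length(tau_edges) - 1
  counts <- matrix(0, na, nt)
  tab <- table(factor(ia, levels = seq_len(na)),
               factor(it, levels = seq_len(nt)))
  counts[] <- as.numeric(tab)
  proj_a <- .smooth1d(rowSums(counts), smooth_sigma)
  proj_t <- .smooth1d(colSums(counts), smooth_sigma)
  da <- diff(a_edges)
  dlt <- diff(log10(tau_edges))
  pdf_a <- proj_a / sum(proj_a * da)
  pdf_tau <- proj_t / sum(proj_t * dlt)
  structure(list(a_edges = a_edges, tau_edges = tau_edges, counts = counts,
                 pdf_a = pdf_a, pdf_tau = pdf_tau,
                 a_mid = (a_edges[-1] + a_edges[-length(a_edges)]) / 2,
                 tau_mid = sqrt(tau_edges[-1] * tau_edges[-length(tau_edges)])),
            class = "pdf2d")
}

#' @export
print.pdf2d <- function(x, ...) {
  cat(sprintf("2-D (A, tau) PDF: %d x %d bins, %d pixels\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# Evaluate the axis projections of a pdf2d at (a, tau); 0 outside support.
pdf_eval <- function(pdf, a, tau) {
  na <- length(pdf$a_edges) - 1; nt <- length(pdf$tau_edges) - 1
  ia <- findInterval(a, pdf$a_edges, rightmost.closed = TRUE)
  it <- findInterval(tau, pdf$tau_edges, rightmost.closed = TRUE)
  pa <- ifelse(ia >= 1 & ia <= na, pdf$pdf_a[pmin(pmax(ia, 1), na)], 0)
  pt <- ifelse(it >= 1 & it <= nt, pdf$pdf_tau[pmin(pmax(it, 1), nt)], 0)
  cbind(pa = pa, pt = pt)
}

#' Per-pixel fraction by PDF unmixing
#'
#' Estimates the fraction `R` of the first species in a pixel with fitted
#' values `(a, tau)` by maximizing, over `R` in [0, 1], the product over
#' the two axes of the R-mixture of the reference PDFs:
#' \deqn{L(R) = \prod_{i \in \{A, \tau\}}
#'   [R\,PDF_1^i + (1-R)\,PDF_2^i]}
#' evaluated at the pixel's `(a, tau)`. The product objective is
#' quadratic in `R`, so the maximizer is found in closed form (interior
#' stationary point vs. the endpoints); `objective = "sum"` replaces the
#' product by a sum, which is linear in `R` and selects an endpoint.
#' Pixels where both references are uninformative return `R = 0.5` with
#' `degenerate = TRUE`; pixels outside both supports return `NaN` with
#' `outside = TRUE`.
#'
#' @param a,tau Pixel TRAST amplitude and relaxation time (vectorized).
#' @param pdf1,pdf2 Reference [build_pdfs()] objects on common axes.
#' @param objective `"product"` (default) or `"sum"`.
#' @return Data frame with columns `R`, `degenerate`, `outside`.
#' @export
unmix_pixel <- function(a, tau, pdf1, pdf2,
                        objective = c("product", "sum")) {
  objective <- match.arg(objective)
  if (!identical(pdf1$a_edges, pdf2$a_edges) ||
      !identical(pdf1$tau_edges, pdf2$tau_edges))
    stop("reference PDFs must be built on common axes")
  e1 <- pdf_eval(pdf1, a, tau)
  e2 <- pdf_eval(pdf2, a, tau)
  outside <- (e1[, 1] + e2[, 1] == 0) | (e1[, 2] + e2[, 2] == 0)
  if (objective == "product") {
    # L(R) = (alpha R + beta)(gamma R + delta)
    alpha <- e1[, 1] - e2[, 1]; beta <- e2[, 1]
    gam <- e1[, 2] - e2[, 2]; delta <- e2[, 2]
    Rstar <- ifelse(abs(alpha * gam) > 0,
                    -(alpha * delta + gam * beta) / (2 * alpha * gam), NA)
    cand0 <- beta * delta
    cand1 <- (alpha + beta) * (gam + delta)
    Lstar <- ifelse(is.finite(Rstar) & Rstar > 0 & Rstar < 1,
                    (alpha * Rstar + beta) * (gam * Rstar + delta), -Inf)
    R <- ifelse(Lstar >= pmax(cand0, cand1), Rstar,
                ifelse(cand1 >= cand0, 1, 0))
    degenerate <- abs(cand1 - cand0) < 1e-300 & !is.finite(Lstar)
  } else {
    s1 <- e1[, 1] + e1[, 2]; s2 <- e2[, 1] + e2[, 2]
    R <- ifelse(s1 > s2, 1, ifelse(s1 < s2, 0, 0.5))
    degenerate <- s1 == s2
  }
  R[degenerate] <- 0.5
  R[outside] <- NaN
  data.frame(R = R, degenerate = degenerate & !outside, outside = outside)
}

#' Unmix a fitted TRAST image
#'
#' Applies [unmix_pixel()] to every converged pixel of a fitted
#' `"trast_image"`.
#'
#' @param image A `"trast_image"`.
#' @param pdf1,pdf2 Reference PDFs (species 1 = fraction reported).
#' @param objective Passed to [unmix_pixel()].
#' @return Matrix `R_map` (NaN where unfitted/outside support).
#' @export
unmix_image <- function(image, pdf1, pdf2, objective = "product") {
  idx <- which(is.finite(image$a_map) & is.finite(image$tau_map))
  R_map <- matrix(NA_real_, nrow(image$a_map), ncol(image$a_map))
  if (length(idx) > 0) {
    um <- unmix_pixel(image$a_map[idx], image$tau_map[idx], pdf1, pdf2,
                      objective)
    R_map[idx] <- um$R
  }
  R_map
}

#' Split a total-intensity image into species images
#'
#' Scales the per-pixel fractions with the total fluorescence intensity;
#' the two output images sum exactly to the input intensity wherever `R`
#' is defined.
#'
#' @param R_map Matrix of fractions in [0, 1] (NA allowed).
#' @param intensity_map Matrix of total intensities, same shape.
#' @return List with `image_1` (`R * intensity`) and `image_2`
#'   (`(1 - R) * intensity`).
#' @export
compose_species_images <- function(R_map, intensity_map) {
  stopifnot(identical(dim(R_map), dim(intensity_map)))
  list(image_1 = R_map * intensity_map,
       image_2 = (1 - R_map) * intensity_map)
}
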