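#' Radially symmetric interaction kernels
#'
#' Cell-cell interactions (growth-factor secretion/uptake, daughter-cell
#' dispersal, random jumps) are described by radially symmetric kernels
#' on the plane, parameterised by their total integral and a width.
#' Two families are supported:
#'
#' * `gaussian_kernel(I, sigma)`: \eqn{a(r) = I/(2\pi\sigma^2)\,
#'   \exp(-r^2/(2\sigma^2))}
#' * `tophat_kernel(I, r0)`: \eqn{a(r) = I/(\pi r_0^2)} for \eqn{r \le r_0},
#'   0 beyond.
#'
#' The total mass \eqn{2\pi\int_0^\infty a(r)\, r\, dr} equals `integral`
#' for both families. All lengths are in dimensionless model units.
#'
#' @param integral non-negative total integral \eqn{I} of the kernel
#'   (a rate, probability per unit time).
#' @param sigma positive standard deviation of the Gaussian profile.
#' @param r0 positive interaction radius of the top-hat profile.
#' @return An object of class `radial_kernel` with fields `family`,
#'   `integral` and `width`.
#' @examples
#' B1 <- gaussian_kernel(0.001, 25)
#' kernel_eval(B1, c(0, 25, 50))
#' kernel_mass(B1)
#' @export
gaussian_kernel <- function(integral, sigma) {
  new_radial_kernel("gaussian", integral, sigma)
}

#' @rdname gaussian_kernel
#' @export
tophat_kernel <- function(integral, r0) {
  new_radial_kernel("tophat", integral, r0)
}

new_radial_kernel <- function(family, integral, width) {
  if (!is.numeric(integral) || length(integral) != 1L || is.na(integral) ||
      integral < 0) {
    stop("kernel `integral` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width <= 0) {
    stop("kernel `width` must be a single positive number", call. = FALSE)
  }
  structure(
    list(family = family, integral = as.numeric(integral),
         width = as.numeric(width)),
    class = "radial_kernel"
  )
}

#' @export
print.radial_kernel <- function(x, ...) {
  wname <- if (x$family == "gaussian") "sigma" else "r0"
  cat(sprintf("radial kernel: %s, integral = %g, %s = %g\n",
              x$family, x$integral, wname, x$width))
  invisible(x)
}

#' Evaluate a radial kernel at given pair distances
#'
#' @param kernel a [radial_kernel][gaussian_kernel].
#' @param r numeric vector of non-negative distances.
#' @return numeric vector of kernel values.
#' @export
kernel_eval <- function(kernel, r) {
  stopifnot(inherits(kernel, "radial_kernel"))
  r <- abs(r)
  switch(kernel$family,
    gaussian = {
      s2 <- kernel$width^2
      kernel$integral / (2 * pi * s2) * exp(-r^2 / (2 * s2))
    },
    tophat = {
      ifelse(r <= kernel$width, kernel$integral / (pi * kernel$width^2), 0)
    },
    stop("unknown kernel family: ", kernel$family)
  )
}

#' Total mass of a kernel by adaptive quadrature
#'
#' Computes \eqn{2\pi \int_0^\infty a(r)\, r\, dr} numerically. Both kernel
#' families are negligible beyond 20 widths, so the integral is taken on
#' `[0, 20 * width]`.
#'
#' @inheritParams kernel_eval
#' @param rel.tol relative quadrature tolerance.
#' @return the numerically integrated total mass (should equal
#'   `kernel$integral` up to quadrature error).
#' @export
kernel_mass <- function(kernel, rel.tol = 1e-10) {
  stopifnot(inherits(kernel, "radial_kernel"))
  if (kernel$integral == 0) return(0)
  upper <- 20 * kernel$width
  2 * pi * stats::integrate(function(r) kernel_eval(kernel, r) * r,
                            lower = 0, upper = upper,
                            rel.tol = rel.tol, abs.tol = 0,
                            subdivisions = 400L)$value
}

#' Rescale a kernel towards the long-range interaction limit
#'
#' Returns the kernel \eqn{a_\epsilon(x) = \epsilon^d a(\epsilon x)} with
#' \eqn{d = 2}. The total integral is preserved; the kernel becomes flatter
#' and longer-ranged as `eps` decreases. For both supported families this
#' amounts to dividing the width by `eps`.
#'
#' @inheritParams kernel_eval
#' @param eps positive scaling factor \eqn{\epsilon = 1/\ell}.
#' @return a rescaled `radial_kernel`.
#' @export
scale_kernel <- function(kernel, eps) {
  stopifnot(inherits(kernel, "radial_kernel"))
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps <= 0) {
    stop("`eps` must be a single positive number", call. = FALSE)
  }
  new_radial_kernel(kernel$family, kernel$integral, kernel$width / eps)
}

#' Spectral grid for transform-space computations
#'
#' A uniform grid of spatial frequencies `k` on `[0, k_max]` with trapezoidal
#' quadrature weights, used to discretise the Hankel-transformed covariance
#' equations. Spectra of Gaussian kernels decay as \eqn{\exp(-\sigma^2 k^2/2)},
#' so a `k_max` of `10 / sigma_min` (the default used by
#' [default_spectral_grid()]) fully resolves every model kernel.
#'
#' @param k_max positive upper frequency.
#' @param n number of nodes (>= 2); the grid starts at `k = 0`.
#' @return An object of class `spectral_grid` with fields `k` (frequencies)
#'   and `w` (trapezoidal weights such that `sum(w * f(k))` approximates
#'   \eqn{\int_0^{k_{max}} f(k)\,dk}).
#' @export
spectral_grid <- function(k_max, n = 257L) {
  stopifnot(is.numeric(k_max), length(k_max) == 1L, k_max > 0,
            is.numeric(n), length(n) == 1L, n >= 2)
  n <- as.integer(n)
  k <- seq(0, k_max, length.out = n)
  h <- k[2] - k[1]
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  structure(list(k = k, w = w), class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("spectral grid: %d nodes on [0, %g]\n", length(x$k), max(x$k)))
  invisible(x)
}

#' Default spectral grid for a set of model kernels
#'
#' @param params a [model_params()] object.
#' @param n number of nodes.
#' @return a [spectral_grid()] with `k_max = 10 / sigma_min` over the model's
#'   kernels.
#' @export
default_spectral_grid <- function(params, n = 257L) {
  kerns <- Filter(Negate(is.null),
                  params[c("B1", "B11", "B12", "C", "M1", "M2")])
  sig_min <- min(vapply(kerns, function(k) k$width, numeric(1)))
  spectral_grid(10 / sig_min, n)
}

#' Order-0 Hankel transform of a radial kernel
#'
#' The radial form of the 2-D Fourier transform for radially symmetric
#' functions: \eqn{\tilde a(k) = 2\pi\int_0^\infty a(r) J_0(kr)\, r\, dr}.
#' Computed by trapezoidal quadrature of the kernel profile on a fine radial
#' sample (2048 points to 20 widths). At `k = 0` the transform equals the
#' total integral; for the Gaussian family it equals
#' \eqn{I \exp(-\sigma^2 k^2 / 2)} and for the top-hat family
#' \eqn{2 I J_1(k r_0)/(k r_0)}.
#'
#' @inheritParams kernel_eval
#' @param grid a [spectral_grid()], or a numeric vector of frequencies.
#' @param n_r number of radial quadrature points (forced odd for composite
#'   Simpson weights).
#' @return numeric vector of spectrum values at the grid frequencies.
#' @export
kernel_spectrum <- function(kernel, grid, n_r = 4097L) {
  stopifnot(inherits(kernel, "radial_kernel"))
  k <- if (inherits(grid, "spectral_grid")) grid$k else as.numeric(grid)
  n_r <- as.integer(n_r)
  if (n_r %% 2L == 0L) n_r <- n_r + 1L
  # the top-hat support ends exactly at `width`; sampling past the jump
  # would degrade Simpson's accuracy. The Gaussian profile is below 1e-31
  # of its peak by 12 widths, so truncation there is far below quadrature
  # error while keeping the step size small.
  r_up <- if (kernel$family == "tophat") kernel$width else 12 * kernel$width
  r <- seq(0, r_up, length.out = n_r)
  a_r <- kernel_eval(kernel, r) * r      # radial measure a(r) * r
  hankel_forward(a_r, r, k)
}

# 2*pi * int_r[ f(r) * J0(k r) ] for a tabulated radial profile f(r) = a(r)*r,
# composite Simpson on a uniform grid with an odd number of nodes
hankel_forward <- function(fr, r, k) {
  n <- length(r)
  stopifnot(n %% 2L == 1L)
  h <- r[2] - r[1]
  w <- rep(c(2, 4), length.out = n)
  w[c(1L, n)] <- 1
  w <- w * h / 3
  vapply(k, function(kk) 2 * pi * sum(w * fr * besselJ(kk * r, 0)), numeric(1))
}

#' Inverse order-0 Hankel transform on a spectral grid
#'
#' Recovers a radial function from its spectrum:
#' \eqn{g(r) = (1/2\pi)\int_0^\infty \tilde g(k) J_0(kr)\, k\, dk},
#' approximated by the grid's quadrature weights. The grid must extend far
#' enough in `k` to resolve the spectrum's decay; a spectrum carrying more
#' than 1% of its mass in the last decade of the grid triggers a warning.
#'
#' @param spectrum numeric vector of spectrum values on `grid$k`.
#' @param grid a [spectral_grid()].
#' @param r numeric vector of non-negative radii at which to evaluate.
#' @return numeric vector of function values at `r`.
#' @export
inverse_spectrum <- function(spectrum, grid, r) {
  stopifnot(inherits(grid, "spectral_grid"),
            length(spectrum) == length(grid$k))
  if (!all(is.finite(spectrum))) stop("`spectrum` must be finite", call. = FALSE)
  wk <- grid$w * grid$k * spectrum
  tail_mass <- sum(abs(wk[grid$k > 0.9 * max(grid$k)]))
  tot_mass <- sum(abs(wk))
  if (tot_mass > 0 && tail_mass > 0.01 * tot_mass) {
    warning("spectral grid may be too coarse/short to resolve this spectrum",
            call. = FALSE)
  }
  vapply(r, function(rr) sum(wk * besselJ(grid$k * rr, 0)) / (2 * pi),
         numeric(1))
}
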