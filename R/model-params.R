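#' Parameters of the two-type growth-factor model
#'
#' Bundles every process of the model: autocrine birth of producers (s1),
#' facilitated birth of producers and non-producers (s2) mediated by a
#' growth-factor interaction kernel, density-independent death, optional
#' random jumps, and the interaction length-scale `ell` of the perturbation
#' expansion (`eps = 1/ell`).
#'
#' Defaults reproduce the model's reference parameterisation: Gaussian birth
#' kernels sharing standard deviation 25 with integrals
#' `b1 = 0.001 < b11 = 0.025 < b12 = 0.050`, a Gaussian growth-factor kernel
#' with integral `c = 100` and standard deviation 100, no death and no
#' movement, and `ell = 1`.
#'
#' @param B1 [radial_kernel][gaussian_kernel]: dispersal of s1 daughters born
#'   via autocrine signalling (integral `b1`).
#' @param B11 dispersal of s1 daughters born via growth-factor uptake from
#'   other s1 cells (integral `b11`).
#' @param B12 dispersal of s2 daughters born via growth-factor uptake from s1
#'   cells (integral `b12`).
#' @param C growth-factor secretion/uptake interaction kernel (integral `c`).
#' @param M1,M2 movement (jump) kernels of s1 / s2 cells, or `NULL` for
#'   sessile cells.
#' @param delta1,delta2 non-negative death rates of s1 / s2 cells.
#' @param ell positive interaction length-scale; `eps = 1/ell`.
#' @return an object of class `scm_model`.
#' @examples
#' p <- model_params()
#' p
#' @export
model_params <- function(B1 = gaussian_kernel(0.001, 25),
                         B11 = gaussian_kernel(0.025, 25),
                         B12 = gaussian_kernel(0.050, 25),
                         C = gaussian_kernel(100, 100),
                         M1 = NULL, M2 = NULL,
                         delta1 = 0, delta2 = 0,
                         ell = 1) {
  for (nm in c("B1", "B11", "B12", "C")) {
    k <- get(nm)
    if (!inherits(k, "radial_kernel")) {
      stop("`", nm, "` must be a radial_kernel", call. = FALSE)
    }
  }
  for (nm in c("M1", "M2")) {
    k <- get(nm)
    if (!is.null(k) && !inherits(k, "radial_kernel")) {
      stop("`", nm, "` must be a radial_kernel or NULL", call. = FALSE)
    }
  }
  stopifnot(delta1 >= 0, delta2 >= 0, is.numeric(ell), length(ell) == 1L,
            ell > 0)
  structure(
    list(B1 = B1, B11 = B11, B12 = B12, C = C, M1 = M1, M2 = M2,
         delta1 = as.numeric(delta1), delta2 = as.numeric(delta2),
         ell = as.numeric(ell), eps = 1 / as.numeric(ell)),
    class = "scm_model"
  )
}

#' @export
print.scm_model <- function(x, ...) {
  cat("two-type growth-factor model\n")
  cat(sprintf("  b1 = %g, b11 = %g, b12 = %g (sigma_B = %g)\n",
              x$B1$integral, x$B11$integral, x$B12$integral, x$B1$width))
  cat(sprintf("  c = %g (sigma_C = %g)\n", x$C$integral, x$C$width))
  m1 <- if (is.null(x$M1)) 0 else x$M1$integral
  m2 <- if (is.null(x$M2)) 0 else x$M2$integral
  cat(sprintf("  m1 = %g, m2 = %g; delta1 = %g, delta2 = %g; ell = %g\n",
              m1, m2, x$delta1, x$delta2, x$ell))
  invisible(x)
}

move_rate <- function(params, mark) {
  k <- if (mark == 1L) params$M1 else params$M2
  if (is.null(k)) 0 else k$integral
}

death_rate <- function(params, mark) {
  if (mark == 1L) params$delta1 else params$delta2
}

#' Replace the death rates of a model
#'
#' Convenience used when a treatment (a pair of death rates) is switched on
#' at a treatment time.
#'
#' @param params an [model_params()] object.
#' @param delta1,delta2 new non-negative death rates.
#' @return the modified `scm_model`.
#' @export
with_death_rates <- function(params, delta1, delta2) {
  stopifnot(inherits(params, "scm_model"), delta1 >= 0, delta2 >= 0)
  params$delta1 <- as.numeric(delta1)
  params$delta2 <- as.numeric(delta2)
  params
}
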