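# Relative K/B scaling of dose wedges against the first wedge of the same
# crystal. Placing all wedges on one scale, the scaled intensities are
#
#   I_scaled(h) = K * exp(2 B s^2) * I_meas(h),     s = sin(theta)/lambda,
#
# i.e. a wedge whose high-resolution intensities have decayed relative to
# the reference (I_meas ~ (1/K) exp(-2 B s^2) I_ref) carries a positive
# relative B factor and K > 1 tracks the overall intensity loss. The fit is
# the closed-form log-linear least squares: regressing ln(I_ref/I_meas) on
# 2 s^2 gives slope B and intercept ln K. The reference wedge itself always
# yields K = 1, B = 0.

#' Fit a relative scale (K) and relative B factor against a reference wedge
#'
#' @param subset \code{merged_partial} (or data.frame with h, k, l,
#'   intensity) for the wedge to scale.
#' @param reference \code{merged_partial} for the reference wedge.
#' @param cell_a cubic cell edge (Angstrom), needed for s = 1/(2d).
#' @return object of class \code{scale_fit}: list with \code{K}, \code{B}
#'   (Angstrom^2), \code{n_common}, \code{residual} (RMS of log residuals).
#' @export
fit_relative_scale <- function(subset, reference, cell_a) {
  ks <- hkl_key(subset)
  kr <- hkl_key(reference)
  common <- intersect(ks, kr)
  is_ <- subset$intensity[match(common, ks)]
  ir <- reference$intensity[match(common, kr)]
  keep <- is.finite(is_) & is.finite(ir) & is_ > 0 & ir > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 common reflections with positive intensities; ",
         "cannot fit relative scale")
  }
  is_ <- is_[keep]; ir <- ir[keep]
  hkl <- do.call(rbind, strsplit(common[keep], ",", fixed = TRUE))
  hkl <- matrix(as.integer(hkl), ncol = 3L)
  x <- 2 * stol(hkl, cell_a)^2
  y <- log(ir / is_)
  fit <- stats::lm.fit(cbind(1, x), y)
  K <- exp(fit$coefficients[[1L]])
  B <- fit$coefficients[[2L]]
  structure(list(K = K, B = B, n_common = sum(keep),
                 residual = sqrt(mean(fit$residuals^2))),
            class = "scale_fit")
}

#' Apply a relative scale fit to a wedge
#'
#' Multiplies every intensity by \eqn{K \exp(2 B s^2)}, restoring the wedge
#' to the reference scale; re-fitting the scaled wedge against the same
#' reference returns (K, B) = (1, 0).
#'
#' @param subset \code{merged_partial} to scale.
#' @param fit \code{scale_fit} from \code{\link{fit_relative_scale}}.
#' @param cell_a cubic cell edge (Angstrom).
#' @return the wedge with scaled intensities, same class and attributes.
#' @export
apply_scale <- function(subset, fit, cell_a) {
  stopifnot(inherits(fit, "scale_fit"))
  if (!nrow(subset)) return(subset)
  s2 <- stol(as.matrix(subset[, c("h", "k", "l")]), cell_a)^2
  subset$intensity <- fit$K * exp(2 * fit$B * s2) * subset$intensity
  subset
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("relative scale fit: K = %.6g, B = %.6g A^2 (n = %d, rms log resid = %.3g)\n",
              x$K, x$B, x$n_common, x$residual))
  invisible(x)
}
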