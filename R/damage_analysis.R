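# Dose-wedge subsetting, per-wedge summary statistics, exponential decay
# fitting and derived damage metrics.
#
# The decay model for the normalized mean intensity of a crystal is
#
#   I(D) = I0 * exp(-beta_tot * D) + I1                             (decay)
#
# with absorbed dose D (kGy), damage rate constant beta_tot (kGy^-1), the
# dose-sensitive amplitude I0 and a dose-insensitive constant term I1.
# Derived metrics:
#   specific dose     D*    = 1 / beta_tot
#   half dose         D_1/2 = D* ln[2 I0 / (I0 - I1)]  (defined for I0 > I1)
#   undamaged fraction        I1 / (I0 + I1)
# The half dose is the dose at which I(D) falls from its extrapolated
# zero-dose value I0 + I1 to (I0 + I1)/2; solving the decay model for that
# level gives the minus-sign form above.

#' Dose schedule for wedge splitting
#'
#' @param dose_per_frame absorbed dose per frame in kGy, default 0.808.
#' @param subset_size frames per wedge, default 50.
#' @return list of class \code{dose_schedule}.
#' @export
dose_schedule <- function(dose_per_frame = 0.808, subset_size = 50L) {
  stopifnot(dose_per_frame > 0, subset_size >= 1)
  structure(list(dose_per_frame = dose_per_frame,
                 subset_size = as.integer(subset_size)),
            class = "dose_schedule")
}

#' Cumulative dose at the end of a wedge
#'
#' @param subset_index 1-based wedge index.
#' @param schedule \code{dose_schedule}.
#' @return dose in kGy: subset_index * subset_size * dose_per_frame.
#' @examples
#' subset_dose(1, dose_schedule(0.808, 50))  # 40.4 kGy
#' @export
subset_dose <- function(subset_index, schedule) {
  stopifnot(all(subset_index >= 1))
  subset_index * schedule$subset_size * schedule$dose_per_frame
}

#' Split a crystal's observations into consecutive dose wedges
#'
#' Frames are grouped into floor(n_frames / subset_size) consecutive,
#' non-overlapping wedges in frame order; a trailing remainder of frames is
#' dropped.
#'
#' @param obs observation data.frame with a \code{frame} column, or a
#'   \code{crystal_frames} object.
#' @param schedule \code{dose_schedule}.
#' @param n_frames total frames collected; defaults to max(frame).
#' @return list of observation data.frames, one per wedge, with attributes
#'   \code{subset_index} and \code{dose} (kGy at wedge end).
#' @export
split_subsets <- function(obs, schedule, n_frames = NULL) {
  if (inherits(obs, "crystal_frames")) {
    if (is.null(n_frames)) n_frames <- obs$params$n_frames
    obs <- obs$observations
  }
  if (is.null(n_frames)) n_frames <- max(obs$frame)
  sz <- schedule$subset_size
  if (n_frames < sz) {
    stop("cannot split ", n_frames, " frames into wedges of ", sz)
  }
  n_sub <- n_frames %/% sz
  lapply(seq_len(n_sub), function(i) {
    sub <- obs[obs$frame > (i - 1L) * sz & obs$frame <= i * sz, ,
               drop = FALSE]
    attr(sub, "subset_index") <- i
    attr(sub, "dose") <- subset_dose(i, schedule)
    sub
  })
}

#' Per-wedge summary statistics
#'
#' The mean intensity over all observations of the wedge and the mean
#' I/sigma over observations in a stated high-resolution shell, each also
#' normalized to the first wedge's value. The shell is the half-open
#' resolution interval d in [d_min, d_max).
#'
#' @param obs one wedge's observation data.frame.
#' @param cell_a cubic cell edge (Angstrom).
#' @param shell numeric length-2, (d_max, d_min) of the shell in Angstrom;
#'   default c(2.4, 1.9).
#' @param first \code{subset_stats} of the first wedge, or NULL when
#'   summarizing the first wedge itself.
#' @return object of class \code{subset_stats}: list with
#'   \code{subset_index}, \code{dose}, \code{mean_intensity},
#'   \code{shell_i_over_sigma}, and normalized variants (\code{*_norm}).
#'   Empty shells give NA, not zero.
#' @export
subset_summary <- function(obs, cell_a, shell = c(2.4, 1.9), first = NULL) {
  if (!nrow(obs)) stop("empty wedge")
  d <- d_spacing(obs[, c("h", "k", "l")], cell_a)
  d_hi <- max(shell); d_lo <- min(shell)
  in_shell <- d >= d_lo & d < d_hi
  mean_i <- mean(obs$intensity)
  shell_ios <- if (any(in_shell)) {
    mean(obs$intensity[in_shell] / obs$sigma[in_shell])
  } else NA_real_
  norm_i <- if (is.null(first)) 1 else mean_i / first$mean_intensity
  norm_ios <- if (is.null(first)) {
    if (is.na(shell_ios)) NA_real_ else 1
  } else shell_ios / first$shell_i_over_sigma
  structure(list(subset_index = attr(obs, "subset_index"),
                 dose = attr(obs, "dose"),
                 n_obs = nrow(obs),
                 mean_intensity = mean_i,
                 shell_i_over_sigma = shell_ios,
                 mean_intensity_norm = norm_i,
                 shell_i_over_sigma_norm = norm_ios),
            class = "subset_stats")
}

# heteroscedasticity-consistent (HC3-type sandwich) covariance of the
# decay-fit parameters: the per-wedge noise of normalized mean intensities
# is roughly proportional to the decayed level, so the homoscedastic
# covariance of plain NLS undercovers beta markedly
decay_fit_vcov <- function(dose, y, i0, i1, beta) {
  e <- exp(-beta * dose)
  J <- cbind(i0 = e, i1 = 1, beta = -i0 * dose * e)
  r <- y - (i0 * e + i1)
  bread <- tryCatch(solve(crossprod(J)), error = function(e2) NULL)
  if (is.null(bread)) {
    return(matrix(NA_real_, 3, 3, dimnames = list(colnames(J), colnames(J))))
  }
  h <- pmin(rowSums((J %*% bread) * J), 0.999)
  meat <- crossprod(J * (r / (1 - h)))
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- list(colnames(J), colnames(J))
  vc
}

#' Fit the exponential dose-decay model
#'
#' Unweighted nonlinear least squares of I(D) = I0 exp(-beta D) + I1 to
#' (dose, normalized mean intensity) points. Initialization: I1 from the
#' smallest point, I0 from the first point minus I1, beta from a log-linear
#' fit of (I - I1) against dose; bounds I0 > 0, I1 >= 0, beta > 0 via the
#' port algorithm. Parameter uncertainties are 1-sigma values from a
#' heteroscedasticity-consistent (HC3 sandwich) covariance evaluated at the
#' fit, since the noise of normalized wedge means scales with the decayed
#' intensity level. Derived metrics are filled per the decay model; when
#' I0 <= I1 the half dose is undefined (NA with a warning).
#'
#' @param dose numeric vector of doses (kGy), strictly increasing.
#' @param intensity normalized mean intensities at those doses.
#' @return object of class \code{decay_fit}: I0, I1, beta and their
#'   standard errors, d_star, d_half, undamaged_fraction, covariance,
#'   residual sum of squares.
#' @export
fit_decay <- function(dose, intensity) {
  stopifnot(length(dose) == length(intensity))
  if (length(dose) < 4L) stop("need at least 4 points to fit 3 parameters")
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  if (stats::sd(intensity) < 1e-10 * max(abs(intensity), 1)) {
    stop("intensities are constant: decay rate beta is not identifiable")
  }
  i1_0 <- min(intensity)
  i0_0 <- max(intensity[1L] - i1_0, 0.1 * max(intensity))
  pos <- intensity - i1_0 > 0
  beta_0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(intensity[pos] - i1_0) ~ dose[pos]))[[2L]]
    max(-sl, 1e-6)
  } else 1 / max(dose)
  dat <- data.frame(D = dose, I = intensity)
  fit <- tryCatch(
    stats::nls(I ~ i0 * exp(-beta * D) + i1, data = dat,
               start = list(i0 = i0_0, i1 = i1_0 + 1e-6, beta = beta_0),
               algorithm = "port",
               lower = c(i0 = 1e-12, i1 = 0, beta = 1e-12),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      stop("decay fit did not converge (start: I0=", signif(i0_0, 4),
           ", I1=", signif(i1_0, 4), ", beta=", signif(beta_0, 4), "): ",
           conditionMessage(e))
    })
  co <- stats::coef(fit)
  vc <- decay_fit_vcov(dose, intensity, co[["i0"]], co[["i1"]],
                       co[["beta"]])
  se <- sqrt(diag(vc))
  names(se) <- c("i0", "i1", "beta")
  der <- derived_doses(co[["i0"]], co[["i1"]], beta = co[["beta"]])
  structure(list(I0 = co[["i0"]], I1 = co[["i1"]], beta = co[["beta"]],
                 I0_se = se[["i0"]], I1_se = se[["i1"]],
                 beta_se = se[["beta"]],
                 d_star = der$d_star, d_half = der$d_half,
                 undamaged_fraction = der$undamaged_fraction,
                 vcov = vc,
                 rss = sum(stats::resid(fit)^2),
                 n = length(dose)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay fit: I0 = %.4g +/- %.2g, I1 = %.4g +/- %.2g, beta = %.4g +/- %.2g kGy^-1\n",
    x$I0, x$I0_se, x$I1, x$I1_se, x$beta, x$beta_se))
  cat(sprintf("  D* = %.4g kGy, D_1/2 = %.4g kGy, undamaged fraction = %.3g\n",
              x$d_star, x$d_half, x$undamaged_fraction))
  invisible(x)
}

#' Derived damage metrics from decay parameters
#'
#' Computes the specific dose D* = 1/beta (or accepts a stated D*
#' directly), the half dose D_1/2 = D* ln[2 I0 / (I0 - I1)] and the
#' undamaged fraction I1/(I0 + I1). The half dose is defined only for
#' I0 > I1; otherwise NA is returned with a warning.
#'
#' @param i0,i1 decay amplitudes.
#' @param beta damage rate constant (kGy^-1); used as D* = 1/beta when
#'   \code{d_star} is not supplied.
#' @param d_star specific dose (kGy), overrides \code{1/beta} when given.
#' @return list with \code{d_star}, \code{d_half}, \code{undamaged_fraction}.
#' @examples
#' derived_doses(1.04, 0.236, d_star = 149.1)  # half dose 141.7 kGy
#' @export
derived_doses <- function(i0, i1, beta = NULL, d_star = NULL) {
  if (is.null(d_star)) {
    if (is.null(beta)) stop("supply beta or d_star")
    stopifnot(beta > 0)
    d_star <- 1 / beta
  }
  stopifnot(i0 >= 0, i1 >= 0, d_star > 0)
  if (i0 <= i1) {
    warning("I0 <= I1: the intensity never falls to (I0+I1)/2; ",
            "half dose undefined")
    d_half <- NA_real_
  } else {
    d_half <- d_star * log(2 * i0 / (i0 - i1))
  }
  list(d_star = d_star, d_half = d_half,
       undamaged_fraction = i1 / (i0 + i1))
}

#' Construct a decay-fit record from stated parameters
#'
#' Builds a \code{decay_fit}-compatible record from externally stated
#' (I0, I1) and either beta or D*, filling the derived metrics. Useful for
#' summarizing published fit tables.
#'
#' @inheritParams derived_doses
#' @param d_half optional stated half dose; by default recomputed.
#' @return object of class \code{decay_fit} (uncertainties NA).
#' @export
decay_fit_record <- function(i0, i1, beta = NULL, d_star = NULL,
                             d_half = NULL) {
  der <- derived_doses(i0, i1, beta = beta, d_star = d_star)
  if (is.null(d_half)) d_half <- der$d_half
  structure(list(I0 = i0, I1 = i1,
                 beta = if (is.null(beta)) 1 / der$d_star else beta,
                 I0_se = NA_real_, I1_se = NA_real_, beta_se = NA_real_,
                 d_star = der$d_star, d_half = d_half,
                 undamaged_fraction = der$undamaged_fraction,
                 vcov = NULL, rss = NA_real_, n = NA_integer_),
            class = "decay_fit")
}

#' Cohort summary of per-crystal decay fits
#'
#' Arithmetic means and sample (n-1) standard deviations of the specific
#' dose, half dose and undamaged fraction across crystals, plus the ratio
#' of a configured cryogenic reference half dose to the cohort mean half
#' dose (reported both as a number and as the rounded reciprocal "1/N").
#'
#' @param fits list of \code{decay_fit} objects.
#' @param cryo_half_dose cryogenic reference half dose in kGy,
#'   default 43000 (43 MGy).
#' @return object of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(fits, cryo_half_dose = 43000) {
  stopifnot(length(fits) >= 1L)
  g <- function(f, what) vapply(f, function(x) x[[what]], numeric(1))
  ds <- g(fits, "d_star"); dh <- g(fits, "d_half")
  fr <- g(fits, "undamaged_fraction")
  sdn <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  ratio <- cryo_half_dose / mean(dh, na.rm = TRUE)
  structure(list(
    n = length(fits),
    d_star_mean = mean(ds), d_star_sd = sdn(ds),
    d_half_mean = mean(dh, na.rm = TRUE), d_half_sd = sdn(dh[!is.na(dh)]),
    undamaged_fraction_mean = mean(fr), undamaged_fraction_sd = sdn(fr),
    cryo_half_dose = cryo_half_dose,
    cryo_ratio = ratio,
    cryo_ratio_label = if (is.finite(ratio)) {
      sprintf("1/%d", as.integer(round(ratio)))
    } else NA_character_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d crystals:\n", x$n))
  cat(sprintf("  D*      = %.1f +/- %.1f kGy\n", x$d_star_mean, x$d_star_sd))
  cat(sprintf("  D_1/2   = %.1f +/- %.1f kGy\n", x$d_half_mean, x$d_half_sd))
  cat(sprintf("  undamaged fraction = %.1f%% +/- %.1f%%\n",
              100 * x$undamaged_fraction_mean, 100 * x$undamaged_fraction_sd))
  cat(sprintf("  tolerable dose vs cryo reference (%.0f kGy): %s\n",
              x$cryo_half_dose, x$cryo_ratio_label))
  invisible(x)
}
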