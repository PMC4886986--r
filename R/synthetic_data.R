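# Synthetic serial-crystallography data with known ground truth.
#
# The generator emulates a room-temperature multi-crystal experiment on
# cubic insulin-like crystals: space group I2_1 3 (point group 23, I-centred
# lattice), cell a = 78.8 A, Wilson B ~ 24.58 A^2, 700 frames per crystal at
# 0.808 kGy per frame, per-crystal exponential intensity decay, and a hidden
# two-state indexing mode per crystal.

#' Published per-crystal decay parameters used as simulation defaults
#'
#' Fitted amplitudes (I0, I1, dimensionless, normalized to the first dose
#' wedge) and damage rate constants beta_tot (kGy^-1) for five cubic insulin
#' crystals measured at room temperature. Used as the default ground-truth
#' decay parameters of \code{\link{simulate_experiment}}.
#'
#' @return data.frame with columns crystal, i0, i1, beta.
#' @export
insulin_decay_params <- function() {
  data.frame(
    crystal = paste0("xtal", 1:5),
    i0 = c(1.04, 1.06, 1.02, 1.03, 0.97),
    i1 = c(0.236, 0.188, 0.249, 0.257, 0.280),
    beta = c(0.0067, 0.0061, 0.0055, 0.0083, 0.0067),
    stringsAsFactors = FALSE
  )
}

# run the thunk with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a ground-truth intensity set under Wilson statistics
#'
#' One intensity per unique ASU reflection to \code{d_min}, drawn from an
#' exponential distribution (acentric Wilson limit) whose mean follows the
#' Wilson falloff \eqn{\bar I(s) = I_{mean} \exp(-2 B s^2)} with
#' \eqn{s = \sin\theta/\lambda = 1/(2d)}. Reflections violating the
#' I-centring condition (h+k+l odd) are excluded.
#'
#' @param cell_a cubic cell edge (Angstrom), default 78.8.
#' @param group \code{symmetry_group}, default point group 23.
#' @param d_min high-resolution cutoff (Angstrom), default 1.9.
#' @param d_max low-resolution cutoff, default 30.
#' @param wilson_b Wilson B factor (Angstrom^2), default 24.58.
#' @param mean_intensity mean intensity at zero scattering angle, default 1000.
#' @param seed integer seed; the truth is deterministic given the seed.
#' @return object of class \code{ground_truth}: list with the generating
#'   parameters, \code{hkl} (n x 3 ASU indices) and \code{intensity}.
#' @export
generate_truth <- function(cell_a = 78.8, group = point_group_ops("23"),
                           d_min = 1.9, d_max = 30, wilson_b = 24.58,
                           mean_intensity = 1000, seed = 1L) {
  stopifnot(d_min > 0, mean_intensity > 0, wilson_b >= 0)
  hkl <- enumerate_asu(cell_a, d_min, d_max, group, centred = TRUE)
  if (nrow(hkl) == 0) {
    warning("no reflections in the requested resolution range")
    intensity <- numeric(0)
  } else {
    s2 <- stol(hkl, cell_a)^2
    mu <- mean_intensity * exp(-2 * wilson_b * s2)
    intensity <- with_seed(seed, stats::rexp(length(mu), rate = 1 / mu))
  }
  structure(list(cell_a = cell_a, group = group, d_min = d_min,
                 d_max = d_max, wilson_b = wilson_b,
                 mean_intensity = mean_intensity, seed = seed,
                 hkl = hkl, intensity = intensity),
            class = "ground_truth")
}

#' Per-crystal simulation parameters
#'
#' @param crystal_id label.
#' @param n_frames frames collected, default 700.
#' @param dose_per_frame absorbed dose per frame (kGy), default 0.808.
#' @param i0_frac,i1_frac decay amplitudes: the dose-sensitive and
#'   dose-insensitive fractions of the diffracted intensity.
#' @param beta_true damage rate constant (kGy^-1), > 0.
#' @param obs_per_frame distinct reflections recorded per frame, default 200.
#' @param gain detector gain in counts per intensity unit (Poisson noise
#'   scale); \code{Inf} disables counting noise. Default 1.
#' @param sigma_bg background sigma floor (intensity units), > 0, default 1.
#' @param indexing_mode hidden indexing mode, 0 (reference) or 1 (reindexed).
#' @param seed integer seed for this crystal's noise stream.
#' @return list of class \code{crystal_sim_params}.
#' @export
crystal_sim_params <- function(crystal_id = "xtal1", n_frames = 700L,
                               dose_per_frame = 0.808, i0_frac = 1.04,
                               i1_frac = 0.236, beta_true = 0.0067,
                               obs_per_frame = 200L, gain = 1,
                               sigma_bg = 1, indexing_mode = 0L,
                               seed = 1L) {
  stopifnot(n_frames >= 1, dose_per_frame > 0, i0_frac >= 0, i1_frac >= 0,
            beta_true > 0, obs_per_frame >= 1, gain > 0, sigma_bg > 0,
            indexing_mode %in% c(0L, 1L))
  structure(list(crystal_id = crystal_id, n_frames = as.integer(n_frames),
                 dose_per_frame = dose_per_frame, i0_frac = i0_frac,
                 i1_frac = i1_frac, beta_true = beta_true,
                 obs_per_frame = as.integer(obs_per_frame), gain = gain,
                 sigma_bg = sigma_bg, indexing_mode = as.integer(indexing_mode),
                 seed = as.integer(seed)),
            class = "crystal_sim_params")
}

#' Simulate all frames of one crystal
#'
#' Each frame f carries cumulative dose \eqn{D_f = f \cdot dose\_per\_frame}.
#' \code{obs_per_frame} distinct ASU reflections are sampled uniformly per
#' frame; reflection h on frame f has expected intensity
#' \deqn{I_{true}(h) [i_0 \exp(-\beta D_f) + i_1].}
#' Counting noise is Poisson at the stated gain plus a Gaussian background
#' floor; the recorded sigma is the counting-statistics value
#' \eqn{\sqrt{I_{expected}/gain + \sigma_{bg}^2}} so that standardized
#' residuals are calibrated. With \code{gain = Inf} observations equal their
#' expectations. If the crystal's hidden \code{indexing_mode} is 1, every
#' reported index is transformed by \code{reindex_op} before recording.
#'
#' @param truth \code{ground_truth} object.
#' @param params \code{crystal_sim_params}.
#' @param reindex_op \code{reindex_op} used when \code{indexing_mode == 1}.
#' @return list of class \code{crystal_frames}: \code{crystal_id},
#'   \code{observations} (data.frame), \code{params} (the hidden truth).
#' @export
simulate_crystal <- function(truth, params,
                             reindex_op = reindex_operator()) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(params, "crystal_sim_params"))
  n_refl <- nrow(truth$hkl)
  if (n_refl == 0) stop("ground truth is empty")
  m <- params$obs_per_frame
  if (m > n_refl) {
    warning("obs_per_frame (", m, ") exceeds available reflections (",
            n_refl, "); capped")
    m <- n_refl
  }
  nf <- params$n_frames
  obs <- with_seed(params$seed, {
    sel <- unlist(lapply(seq_len(nf), function(f) sample.int(n_refl, m)))
    frame <- rep(seq_len(nf), each = m)
    dose <- frame * params$dose_per_frame
    decay <- params$i0_frac * exp(-params$beta_true * dose) + params$i1_frac
    i_exp <- truth$intensity[sel] * decay
    if (is.finite(params$gain)) {
      i_obs <- stats::rpois(length(i_exp), lambda = i_exp * params$gain) /
        params$gain +
        stats::rnorm(length(i_exp), sd = params$sigma_bg)
      sigma <- sqrt(i_exp / params$gain + params$sigma_bg^2)
    } else {
      i_obs <- i_exp
      sigma <- rep(params$sigma_bg, length(i_exp))
    }
    hkl <- truth$hkl[sel, , drop = FALSE]
    if (params$indexing_mode == 1L) hkl <- apply_reindex(hkl, reindex_op)
    data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
               intensity = i_obs, sigma = sigma, frame = frame,
               crystal_id = params$crystal_id, stringsAsFactors = FALSE)
  })
  structure(list(crystal_id = params$crystal_id, observations = obs,
                 params = params),
            class = "crystal_frames")
}

#' Default multi-crystal experiment configuration
#'
#' The stated experimental world: five cubic insulin-like crystals, cell
#' a = 78.8 A, point group 23, resolution 30-1.9 A, Wilson B 24.58 A^2,
#' 700 frames x 0.808 kGy per crystal, per-crystal decay parameters from
#' \code{\link{insulin_decay_params}}, hidden indexing modes assigned at
#' random with probability 1/2, quality wedges of 50 frames and merging
#' wedges of 100 frames, high-resolution shell 2.4-1.9 A, cryo reference
#' half dose 43 MGy.
#'
#' @param ... named overrides of any default field.
#' @return list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    cell_a = 78.8,
    point_group = "23",
    d_min = 1.9,
    d_max = 30,
    shell = c(2.4, 1.9),          # high-resolution shell (d_max, d_min)
    wilson_b = 24.58,
    mean_intensity = 1000,
    n_frames = 700L,
    dose_per_frame = 0.808,
    subset_size_quality = 50L,
    subset_size_merge = 100L,
    obs_per_frame = 200L,
    gain = 1,
    sigma_bg = 1,
    min_common = 10L,
    cryo_half_dose = 43000,       # kGy (43 MGy)
    crystals = insulin_decay_params()
  )
  over <- list(...)
  stopifnot(all(nzchar(names(over))))
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Simulate a multi-crystal experiment
#'
#' Draws hidden indexing modes (probability 1/2 each), derives per-crystal
#' seeds from the master seed, simulates every crystal against one shared
#' ground truth, and returns the crystal data together with a manifest of
#' all hidden parameters for truth-recovery tests.
#'
#' @param config \code{run_config}, see \code{\link{default_config}}.
#' @param seed master integer seed; all randomness derives from it.
#' @return list of class \code{sim_experiment}: \code{truth},
#'   \code{crystals} (list of \code{crystal_frames}), \code{manifest}
#'   (data.frame of hidden modes and decay parameters), \code{config}.
#' @export
simulate_experiment <- function(config = default_config(), seed = 1L) {
  stopifnot(inherits(config, "run_config"), nrow(config$crystals) >= 1)
  group <- point_group_ops(config$point_group)
  draws <- with_seed(seed, {
    n <- nrow(config$crystals)
    list(modes = as.integer(stats::runif(n) < 0.5),
         seeds = sample.int(.Machine$integer.max - 1L, n + 1L))
  })
  truth <- generate_truth(cell_a = config$cell_a, group = group,
                          d_min = config$d_min, d_max = config$d_max,
                          wilson_b = config$wilson_b,
                          mean_intensity = config$mean_intensity,
                          seed = draws$seeds[1L])
  op <- reindex_operator(group = group)
  crystals <- lapply(seq_len(nrow(config$crystals)), function(i) {
    p <- config$crystals[i, ]
    params <- crystal_sim_params(
      crystal_id = p$crystal, n_frames = config$n_frames,
      dose_per_frame = config$dose_per_frame, i0_frac = p$i0,
      i1_frac = p$i1, beta_true = p$beta,
      obs_per_frame = config$obs_per_frame, gain = config$gain,
      sigma_bg = config$sigma_bg, indexing_mode = draws$modes[i],
      seed = draws$seeds[i + 1L])
    simulate_crystal(truth, params, reindex_op = op)
  })
  manifest <- data.frame(
    crystal_id = config$crystals$crystal,
    indexing_mode = draws$modes,
    i0 = config$crystals$i0, i1 = config$crystals$i1,
    beta = config$crystals$beta, seed = draws$seeds[-1L],
    stringsAsFactors = FALSE
  )
  structure(list(truth = truth, crystals = crystals, manifest = manifest,
                 config = config, seed = as.integer(seed)),
            class = "sim_experiment")
}
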