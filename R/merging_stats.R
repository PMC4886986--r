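# Standard data-quality statistics for merged serial-crystallography data:
# unweighted-mean merging after ASU mapping, R_merge / R_meas, half-set
# correlation CC1/2 with its CC* estimate, completeness and multiplicity.

# group observations by ASU index; returns list(key, asu matrix rows)
asu_keys <- function(obs, group) {
  asu <- map_to_asu(obs[, c("h", "k", "l")], group)
  list(key = hkl_key(asu), asu = asu)
}

#' Merge observations to unique reflections
#'
#' Unweighted mean intensity per ASU index; merged sigma is the propagated
#' standard error of the mean, \eqn{\sqrt{\sum \sigma_i^2} / n}.
#'
#' @param obs observation data.frame (possibly several crystals).
#' @param group \code{symmetry_group}.
#' @return object of class \code{merged_dataset}: data.frame with columns
#'   h, k, l, intensity, sigma, multiplicity; attributes
#'   \code{total_observations}, \code{unique_reflections}.
#' @export
merge_observations <- function(obs, group) {
  stopifnot(nrow(obs) >= 1L)
  ak <- asu_keys(obs, group)
  key <- ak$key
  n <- rowsum(rep(1L, length(key)), key)        # sorted by key
  sum_i <- rowsum(obs$intensity, key)
  sum_s2 <- rowsum(obs$sigma^2, key)
  first <- !duplicated(key)
  reps <- ak$asu[first, , drop = FALSE]
  reps <- reps[order(key[first]), , drop = FALSE]
  out <- data.frame(h = reps[, 1], k = reps[, 2], l = reps[, 3],
                    intensity = as.numeric(sum_i) / as.numeric(n),
                    sigma = sqrt(as.numeric(sum_s2)) / as.numeric(n),
                    multiplicity = as.integer(n))
  out <- out[order(out$h, out$k, out$l), ]
  rownames(out) <- NULL
  structure(out, total_observations = nrow(obs),
            unique_reflections = nrow(out),
            class = c("merged_dataset", "data.frame"))
}

#' Internal agreement R factors of repeated observations
#'
#' Over ASU indices h with multiplicity n_h >= 2:
#' \deqn{R_{merge} = \sum_h \sum_i |I_i - <I_h>| / \sum_h \sum_i I_i}
#' and R_meas, the multiplicity-corrected form, scales each deviation by
#' \eqn{\sqrt{n_h/(n_h-1)}}. Denominators run over the same multiply
#' observed indices.
#'
#' @param obs observation data.frame.
#' @param group \code{symmetry_group}.
#' @return list with \code{r_merge}, \code{r_meas}; both NA when no index
#'   has multiplicity >= 2.
#' @export
r_factors <- function(obs, group) {
  key <- asu_keys(obs, group)$key
  f <- factor(key)
  fi <- as.integer(f)
  cnt <- tabulate(f)
  nh <- cnt[fi]
  keep <- nh >= 2
  if (!any(keep)) return(list(r_merge = NA_real_, r_meas = NA_real_))
  i <- obs$intensity[keep]
  fi <- fi[keep]
  nh <- nh[keep]
  u <- sort(unique(fi))
  gsum <- rowsum(i, fi)
  gn <- rowsum(rep(1L, length(fi)), fi)
  mean_h <- (as.numeric(gsum) / as.numeric(gn))[match(fi, u)]
  dev <- abs(i - mean_h)
  denom <- sum(i)
  list(r_merge = sum(dev) / denom,
       r_meas = sum(sqrt(nh / (nh - 1)) * dev) / denom)
}

#' Half-set correlation CC1/2 and the derived CC*
#'
#' Observations of each multiply measured ASU index are split at random
#' into two halves (odd counts leave the extra observation in the first
#' half); CC1/2 is the Pearson correlation between the two half-set mean
#' vectors over those indices, and
#' \deqn{CC^* = \sqrt{2 CC_{1/2} / (1 + CC_{1/2})}.}
#' The split is reproducible and independent of input order and of crystal
#' labels: observations are first put into a canonical order keyed on the
#' ASU index, frame, intensity and sigma, then shuffled within each index
#' with a generator seeded only by \code{seed} and assigned alternately.
#'
#' @param obs observation data.frame.
#' @param group \code{symmetry_group}.
#' @param seed integer seed fixing the split.
#' @return list with \code{cc_half}, \code{cc_star} (NA when the radicand
#'   is nonpositive), \code{n_indices}.
#' @export
cc_half <- function(obs, group, seed = 1L) {
  key <- asu_keys(obs, group)$key
  ord <- order(key, obs$frame, obs$intensity, obs$sigma)
  intensity <- obs$intensity[ord]
  key <- key[ord]
  f <- factor(key, levels = unique(key))
  fi <- as.integer(f)
  cnt <- tabulate(f)
  if (sum(cnt >= 2) < 3L) {
    stop("need at least 3 ASU indices with multiplicity >= 2 for CC1/2")
  }
  keep <- cnt[fi] >= 2
  fi <- fi[keep]
  intensity <- intensity[keep]
  u <- with_seed(seed, stats::runif(length(fi)))
  o2 <- order(fi, u)                      # random order within each index
  fi2 <- fi[o2]
  i2 <- intensity[o2]
  pos <- sequence(tabulate(factor(fi2, levels = unique(fi2))))
  half <- (pos - 1L) %% 2L                # 0/1 alternating within index
  g <- cumsum(c(TRUE, diff(fi2) != 0))    # contiguous group ids
  hm <- function(w) {
    as.numeric(rowsum(i2[w], g[w])) / as.numeric(rowsum(rep(1L, sum(w)), g[w]))
  }
  m1 <- hm(half == 0L)
  m2 <- hm(half == 1L)
  cc <- stats::cor(m1, m2)
  cs <- if (is.na(cc) || cc <= 0) NA_real_ else sqrt(2 * cc / (1 + cc))
  list(cc_half = cc, cc_star = cs, n_indices = length(m1))
}

#' Completeness and mean multiplicity against the theoretical reflection set
#'
#' Completeness is the fraction (percent) of theoretically possible unique
#' ASU reflections in the resolution window that were observed; the
#' theoretical set honours the I-centring condition h+k+l even. Mean
#' multiplicity is total observations over unique observed reflections.
#'
#' @param merged \code{merged_dataset} from \code{\link{merge_observations}}.
#' @param cell_a cubic cell edge (Angstrom).
#' @param group \code{symmetry_group}.
#' @param d_min,d_max resolution window (Angstrom).
#' @param centred honour the I-centring condition; default TRUE.
#' @return list with \code{completeness} (percent), \code{multiplicity},
#'   \code{n_observed}, \code{n_theoretical}.
#' @export
completeness_multiplicity <- function(merged, cell_a, group, d_min, d_max,
                                      centred = TRUE) {
  theo <- enumerate_asu(cell_a, d_min, d_max, group, centred = centred)
  if (nrow(theo) == 0) stop("no theoretically possible reflections in range")
  d <- d_spacing(merged[, c("h", "k", "l")], cell_a)
  in_rng <- d >= d_min & d <= d_max
  obs_keys <- unique(hkl_key(merged[in_rng, c("h", "k", "l"), drop = FALSE]))
  n_obs_unique <- sum(obs_keys %in% hkl_key(theo))
  list(completeness = 100 * n_obs_unique / nrow(theo),
       multiplicity = sum(merged$multiplicity[in_rng]) /
         max(sum(in_rng), 1L),
       n_observed = n_obs_unique,
       n_theoretical = nrow(theo))
}

#' Merging-statistics table for one merged wedge
#'
#' Convenience wrapper computing the full statistics block for a set of
#' observations: totals, multiplicity, completeness, mean I/sigma,
#' R_merge, R_meas, CC1/2 and CC*.
#'
#' @param obs observation data.frame (all crystals of one wedge).
#' @param cell_a cubic cell edge.
#' @param group \code{symmetry_group}.
#' @param d_min,d_max resolution window.
#' @param seed seed for the CC1/2 half split.
#' @return one-row data.frame of statistics.
#' @export
merging_statistics <- function(obs, cell_a, group, d_min, d_max,
                               seed = 1L) {
  merged <- merge_observations(obs, group)
  rf <- r_factors(obs, group)
  cc <- tryCatch(cc_half(obs, group, seed = seed),
                 error = function(e) list(cc_half = NA_real_,
                                          cc_star = NA_real_))
  cm <- completeness_multiplicity(merged, cell_a, group, d_min, d_max)
  data.frame(
    total_observations = attr(merged, "total_observations"),
    unique_reflections = attr(merged, "unique_reflections"),
    multiplicity = cm$multiplicity,
    completeness = cm$completeness,
    mean_i_over_sigma = mean(merged$intensity / merged$sigma),
    r_merge = rf$r_merge,
    r_meas = rf$r_meas,
    cc_half = cc$cc_half,
    cc_star = cc$cc_star
  )
}
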