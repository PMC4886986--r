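# Resolution of the two-state indexing ambiguity by correlation
# maximization: partial data sets measured in inconsistent indexing
# conventions correlate poorly; after reindexing the discordant crystals,
# pairwise correlation coefficients of common reflections approach 1.

#' Merge one crystal's observations to per-ASU-index mean intensities
#'
#' @param obs observation data.frame (columns h, k, l, intensity, ...).
#' @param group \code{symmetry_group} used for ASU mapping.
#' @param crystal_id label stored on the result; defaults to the first
#'   crystal_id in \code{obs} if present.
#' @return object of class \code{merged_partial}: data.frame with columns
#'   h, k, l, intensity (unweighted mean) and attribute \code{crystal_id}.
#' @export
merge_partial <- function(obs, group, crystal_id = NULL) {
  if (is.null(crystal_id)) {
    crystal_id <- if (nrow(obs) && "crystal_id" %in% names(obs)) {
      obs$crystal_id[1L]
    } else "unknown"
  }
  if (!nrow(obs)) {
    out <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                      intensity = numeric(0))
  } else {
    asu <- map_to_asu(obs[, c("h", "k", "l")], group)
    key <- hkl_key(asu)
    sums <- rowsum(obs$intensity, key)          # sorted by key
    cnts <- rowsum(rep(1L, length(key)), key)
    first <- !duplicated(key)
    reps <- asu[first, , drop = FALSE]
    reps <- reps[order(key[first]), , drop = FALSE]
    out <- data.frame(h = reps[, 1], k = reps[, 2], l = reps[, 3],
                      intensity = as.numeric(sums) / as.numeric(cnts))
    out <- out[order(out$h, out$k, out$l), ]
    rownames(out) <- NULL
  }
  structure(out, crystal_id = crystal_id,
            class = c("merged_partial", "data.frame"))
}

#' Pearson correlation of common reflections between two partial data sets
#'
#' The product-moment correlation of mean intensities over the intersection
#' of ASU indices. Used to decide between the two indexing conventions: the
#' consistent convention maximizes r.
#'
#' @param a,b \code{merged_partial} objects.
#' @param min_common below this number of common reflections the value is
#'   flagged untrustworthy (\code{trusted = FALSE}); default 10.
#' @return list with \code{r}, \code{n_common}, \code{trusted}.
#' @export
pearson_r <- function(a, b, min_common = 10L) {
  ka <- hkl_key(a)
  kb <- hkl_key(b)
  common <- intersect(ka, kb)
  n <- length(common)
  if (n < 2L) {
    return(list(r = NA_real_, n_common = n, trusted = FALSE))
  }
  ia <- a$intensity[match(common, ka)]
  ib <- b$intensity[match(common, kb)]
  if (stats::sd(ia) == 0 || stats::sd(ib) == 0) {
    stop("zero intensity variance over common reflections; ",
         "correlation undefined")
  }
  list(r = stats::cor(ia, ib), n_common = n, trusted = n >= min_common)
}

# reindex a merged partial and re-merge (the operator can map two distinct
# ASU representatives onto the same orbit only if it were in the Laue
# group, which it is not; still, re-map defensively)
reindex_partial <- function(mp, op, group) {
  if (!nrow(mp)) return(mp)
  hkl <- apply_reindex(mp[, c("h", "k", "l")], op)
  obs <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    intensity = mp$intensity)
  merge_partial(obs, group, crystal_id = attr(mp, "crystal_id"))
}

#' Resolve indexing modes across crystals by correlation maximization
#'
#' Greedy sequential assignment: the first crystal anchors mode 0; every
#' subsequent crystal is correlated against the running merged reference in
#' both its original and its reindexed form, the mode with the larger r
#' wins, and the crystal joins the reference. Assignments are meaningful
#' only up to a global flip of all modes (both conventions are physically
#' equivalent). Ties keep mode 0 with a warning.
#'
#' @param partials list of \code{merged_partial}, one per crystal (indices
#'   as observed, before any reindexing).
#' @param op \code{reindex_op} relating the two conventions.
#' @param group \code{symmetry_group} for re-merging after reindexing.
#' @param min_common minimum common reflections for a trusted correlation;
#'   crystals below it in both modes are left unassigned with a warning.
#' @return object of class \code{mode_assignment}: list with \code{modes}
#'   (named integer vector, NA = unassigned), \code{report} (data.frame of
#'   candidate and chosen correlations per crystal), \code{global_flip_note}.
#' @export
resolve_modes <- function(partials, op = reindex_operator(),
                          group = point_group_ops("23"),
                          min_common = 10L) {
  stopifnot(length(partials) >= 1L)
  ids <- vapply(partials, function(p) as.character(attr(p, "crystal_id")),
                character(1))
  modes <- stats::setNames(rep(NA_integer_, length(partials)), ids)
  modes[1L] <- 0L
  # running reference: mean of assigned crystals' per-index means
  ref_key <- hkl_key(partials[[1L]])
  ref_sum <- stats::setNames(partials[[1L]]$intensity, ref_key)
  ref_n <- stats::setNames(rep(1L, length(ref_key)), ref_key)
  report <- data.frame(crystal_id = character(0), r_orig = numeric(0),
                       r_reindexed = numeric(0), n_orig = integer(0),
                       n_reindexed = integer(0), mode = integer(0),
                       stringsAsFactors = FALSE)
  ref_partial <- function() {
    parts <- do.call(rbind, strsplit(names(ref_sum), ",", fixed = TRUE))
    structure(data.frame(h = as.integer(parts[, 1]),
                         k = as.integer(parts[, 2]),
                         l = as.integer(parts[, 3]),
                         intensity = as.numeric(ref_sum) / as.numeric(ref_n)),
              crystal_id = "reference",
              class = c("merged_partial", "data.frame"))
  }
  add_to_ref <- function(mp) {
    key <- hkl_key(mp)
    known <- key %in% names(ref_sum)
    if (any(known)) {
      ref_sum[key[known]] <<- ref_sum[key[known]] + mp$intensity[known]
      ref_n[key[known]] <<- ref_n[key[known]] + 1L
    }
    if (any(!known)) {
      ref_sum <<- c(ref_sum, stats::setNames(mp$intensity[!known], key[!known]))
      ref_n <<- c(ref_n, stats::setNames(rep(1L, sum(!known)), key[!known]))
    }
  }
  if (length(partials) >= 2L) {
    for (i in 2:length(partials)) {
      ref <- ref_partial()
      orig <- partials[[i]]
      flip <- reindex_partial(orig, op, group)
      c0 <- pearson_r(orig, ref, min_common)
      c1 <- pearson_r(flip, ref, min_common)
      if (!c0$trusted && !c1$trusted) {
        warning("crystal '", ids[i], "': fewer than ", min_common,
                " common reflections in both modes; left unassigned")
        report <- rbind(report, data.frame(
          crystal_id = ids[i], r_orig = c0$r, r_reindexed = c1$r,
          n_orig = c0$n_common, n_reindexed = c1$n_common,
          mode = NA_integer_, stringsAsFactors = FALSE))
        next
      }
      if (isTRUE(all.equal(c0$r, c1$r))) {
        warning("crystal '", ids[i],
                "': tie between indexing modes; keeping mode 0")
        mode <- 0L
      } else {
        mode <- if (isTRUE(c1$r > c0$r)) 1L else 0L
      }
      modes[i] <- mode
      add_to_ref(if (mode == 1L) flip else orig)
      report <- rbind(report, data.frame(
        crystal_id = ids[i], r_orig = c0$r, r_reindexed = c1$r,
        n_orig = c0$n_common, n_reindexed = c1$n_common, mode = mode,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(
    modes = modes, report = report,
    global_flip_note = paste("mode assignments are unique only up to a",
                             "global flip of all modes")),
    class = "mode_assignment")
}

#' @export
print.mode_assignment <- function(x, ...) {
  cat("indexing-mode assignment (", x$global_flip_note, ")\n", sep = "")
  print(x$modes)
  invisible(x)
}

#' Apply resolved indexing modes to raw observations
#'
#' Observations of crystals assigned mode 1 are reindexed by the operator;
#' mode-0 and unassigned crystals pass through (unassigned ones are
#' dropped with a warning).
#'
#' @param crystals list of \code{crystal_frames}.
#' @param assignment \code{mode_assignment} from \code{\link{resolve_modes}}.
#' @param op \code{reindex_op}.
#' @return list of observation data.frames in a consistent convention.
#' @export
apply_modes <- function(crystals, assignment, op = reindex_operator()) {
  stopifnot(inherits(assignment, "mode_assignment"))
  out <- list()
  for (cr in crystals) {
    mode <- assignment$modes[[cr$crystal_id]]
    if (is.na(mode)) {
      warning("crystal '", cr$crystal_id, "' unassigned; dropped")
      next
    }
    obs <- cr$observations
    if (mode == 1L) {
      hkl <- apply_reindex(obs[, c("h", "k", "l")], op)
      obs$h <- hkl[, 1]; obs$k <- hkl[, 2]; obs$l <- hkl[, 3]
    }
    out[[cr$crystal_id]] <- obs
  }
  out
}
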