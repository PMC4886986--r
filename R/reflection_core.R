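# ---- Miller-index utilities -------------------------------------------------

# Indices are handled as integer matrices with columns h, k, l; a single
# index may be given as a length-3 vector. All symmetry operations act as
# R %*% c(h, k, l) with integer 3x3 matrices.

#' Coerce indices to an n x 3 integer matrix
#'
#' @param hkl length-3 vector or n x 3 matrix/data.frame of Miller indices.
#' @return integer matrix with columns h, k, l.
#' @keywords internal
as_hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  if (is.vector(hkl)) {
    if (length(hkl) != 3L) stop("a Miller index has exactly 3 components")
    hkl <- matrix(hkl, nrow = 1L)
  }
  if (ncol(hkl) != 3L) stop("Miller indices must have 3 columns (h, k, l)")
  if (any(hkl != round(hkl))) stop("Miller indices must be integers")
  storage.mode(hkl) <- "integer"
  colnames(hkl) <- c("h", "k", "l")
  hkl
}

#' Resolution of a reflection in a cubic cell
#'
#' For a cubic cell of edge \code{a}, the lattice-plane spacing of
#' reflection (h,k,l) is \eqn{d = a / \sqrt{h^2+k^2+l^2}}.
#'
#' @param hkl Miller index (length-3 vector) or n x 3 matrix.
#' @param cell_a cubic cell edge in Angstrom, > 0.
#' @return d-spacing(s) in Angstrom.
#' @examples
#' d_spacing(c(0, 0, 2), 78.8)  # 39.4
#' @export
d_spacing <- function(hkl, cell_a) {
  stopifnot(is.numeric(cell_a), length(cell_a) == 1L, cell_a > 0)
  m <- as_hkl_matrix(hkl)
  n2 <- rowSums(m^2)
  if (any(n2 == 0)) stop("(0,0,0) is not a valid reflection index")
  cell_a / sqrt(n2)
}

# sin(theta)/lambda for a cubic cell; s = 1/(2 d)
stol <- function(hkl, cell_a) 1 / (2 * d_spacing(hkl, cell_a))

# ---- Point-group machinery --------------------------------------------------

mat_key <- function(m) paste(as.integer(m), collapse = ",")

# brute-force closure of a generator set under matrix multiplication
close_group <- function(gens) {
  ops <- list(diag(3L))
  seen <- mat_key(ops[[1L]])
  grew <- TRUE
  while (grew) {
    grew <- FALSE
    for (a in ops) {
      for (g in gens) {
        p <- g %*% a
        k <- mat_key(p)
        if (!(k %in% seen)) {
          ops[[length(ops) + 1L]] <- p
          seen <- c(seen, k)
          grew <- TRUE
        }
      }
    }
  }
  lapply(ops, function(m) {
    storage.mode(m) <- "integer"
    m
  })
}

#' Proper rotations of a point group
#'
#' Supported groups: \code{"1"} (identity only) and \code{"23"} (the cubic
#' tetrahedral rotation group of order 12: identity, three face twofolds,
#' eight body-diagonal threefolds). The group is built by brute-force
#' closure from generators, so closure holds by construction.
#'
#' @param name point-group label, one of \code{"1"}, \code{"23"}.
#' @return object of class \code{symmetry_group}: list with \code{name} and
#'   \code{rotations} (list of 3x3 integer matrices, determinant +1).
#' @export
point_group_ops <- function(name) {
  name <- as.character(name)
  rots <- switch(name,
    "1" = list(diag(3L)),
    "23" = close_group(list(
      matrix(c(0L, 1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L), 3L, 3L, byrow = TRUE),
      diag(c(1L, -1L, -1L))
    )),
    stop("unsupported point group: '", name, "' (supported: \"1\", \"23\")")
  )
  if (name == "23" && length(rots) != 12L) {
    stop("internal error: point group 23 must have order 12")
  }
  structure(list(name = name, rotations = rots), class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("point group", x$name, "with", length(x$rotations),
      "proper rotations\n")
  invisible(x)
}

#' Default two-state reindexing operator for point group 23
#'
#' In space groups whose Bravais-lattice symmetry exceeds the space-group
#' symmetry, two indexing conventions are equally consistent with the
#' lattice. For a cubic crystal in point group 23 the alternative indexing
#' is related by the operator (h,k,l) -> (k,h,-l), a coset representative
#' of the cubic holohedry m-3m over the Laue group m-3. The operator is
#' validated on construction: it is not an element of the Laue group
#' (rotations of 23 together with their Friedel negatives), and its square
#' is the identity.
#'
#' @param matrix 3x3 integer matrix acting on (h,k,l); default the
#'   (h,k,l) -> (k,h,-l) swap.
#' @param group \code{symmetry_group} against which to validate; default
#'   point group 23.
#' @return object of class \code{reindex_op}.
#' @export
reindex_operator <- function(matrix = NULL, group = point_group_ops("23")) {
  if (is.null(matrix)) {
    matrix <- rbind(c(0L, 1L, 0L), c(1L, 0L, 0L), c(0L, 0L, -1L))
  }
  storage.mode(matrix) <- "integer"
  if (abs(det(matrix)) != 1) stop("reindex operator must have determinant +/-1")
  laue_keys <- unlist(lapply(group$rotations, function(r) {
    c(mat_key(r), mat_key(-r))
  }))
  if (mat_key(matrix) %in% laue_keys) {
    stop("reindex operator is an element of the Laue group; ",
         "it would not change the indexing mode")
  }
  sq <- matrix %*% matrix
  if (!(mat_key(sq) %in% laue_keys)) {
    stop("square of the reindex operator must lie in the Laue group ",
         "(two-state ambiguity)")
  }
  structure(list(matrix = matrix), class = "reindex_op")
}

#' Apply a reindexing operator to Miller indices
#'
#' @param hkl length-3 vector or n x 3 matrix of indices.
#' @param op \code{reindex_op} object.
#' @return indices transformed by the operator, same shape semantics
#'   (always returned as an n x 3 integer matrix).
#' @export
apply_reindex <- function(hkl, op) {
  stopifnot(inherits(op, "reindex_op"))
  m <- as_hkl_matrix(hkl)
  out <- m %*% t(op$matrix)
  storage.mode(out) <- "integer"
  colnames(out) <- c("h", "k", "l")
  out
}

#' Map Miller indices to a canonical asymmetric-unit representative
#'
#' Each index is replaced by the lexicographically greatest member (compared
#' by h, then k, then l) of its orbit under the point-group rotations
#' together with Friedel inversion. The map is idempotent and constant on
#' orbits, so symmetry-equivalent observations (including Friedel mates,
#' which are merged throughout) share one representative.
#'
#' @param hkl length-3 vector or n x 3 matrix.
#' @param group \code{symmetry_group} from \code{\link{point_group_ops}}.
#' @return n x 3 integer matrix of canonical representatives.
#' @export
map_to_asu <- function(hkl, group) {
  stopifnot(inherits(group, "symmetry_group"))
  m <- as_hkl_matrix(hkl)
  if (any(rowSums(m^2) == 0)) stop("(0,0,0) is not a valid reflection index")
  # score = h*M^2 + k*M + l with M wide enough that lexicographic order on
  # (h, k, l) equals numeric order on the score
  M <- 2 * max(abs(m)) + 1
  best <- m
  best_score <- m[, 1] * M^2 + m[, 2] * M + m[, 3]
  for (r in group$rotations) {
    for (sgn in c(1L, -1L)) {
      im <- m %*% t(sgn * r)
      sc <- im[, 1] * M^2 + im[, 2] * M + im[, 3]
      take <- sc > best_score
      if (any(take)) {
        best[take, ] <- im[take, , drop = FALSE]
        best_score[take] <- sc[take]
      }
    }
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}

# string key for joining observation tables on (h,k,l)
hkl_key <- function(hkl) {
  m <- as_hkl_matrix(hkl)
  paste(m[, 1], m[, 2], m[, 3], sep = ",")
}

#' Enumerate unique asymmetric-unit reflections in a resolution range
#'
#' Walks the index ball implied by \code{d_min}, applies the resolution
#' window [d_min, d_max], optionally the body-centred lattice condition
#' h+k+l even, maps to the canonical ASU representative and deduplicates.
#'
#' @param cell_a cubic cell edge (Angstrom).
#' @param d_min,d_max resolution limits in Angstrom (d_min < d_max).
#' @param group \code{symmetry_group}.
#' @param centred if TRUE, keep only h+k+l even (I-centring condition).
#' @return n x 3 integer matrix of unique ASU representatives.
#' @export
enumerate_asu <- function(cell_a, d_min, d_max = Inf, group,
                          centred = TRUE) {
  stopifnot(d_min > 0, d_max > d_min)
  cache_key <- paste(cell_a, d_min, d_max, group$name, centred, sep = "|")
  if (!is.null(.asu_cache[[cache_key]])) return(.asu_cache[[cache_key]])
  hmax <- floor(cell_a / d_min)
  if (hmax < 1) return(as_hkl_matrix(matrix(integer(0), 0, 3)))
  rng <- seq.int(-hmax, hmax)
  grid <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  grid <- grid[rowSums(grid^2) > 0, , drop = FALSE]
  if (centred) grid <- grid[(rowSums(grid) %% 2L) == 0L, , drop = FALSE]
  d <- cell_a / sqrt(rowSums(grid^2))
  grid <- grid[d >= d_min & d <= d_max, , drop = FALSE]
  if (nrow(grid) == 0) return(as_hkl_matrix(matrix(integer(0), 0, 3)))
  asu <- map_to_asu(grid, group)
  out <- asu[!duplicated(hkl_key(asu)), , drop = FALSE]
  .asu_cache[[cache_key]] <- out
  out
}

# memo for enumerate_asu (the 1.9 A index ball is ~600k candidates)
.asu_cache <- new.env(parent = emptyenv())

# ---- Unmerged reflection text format ---------------------------------------

# One observation per line: H K L INTENSITY SIGMA FRAME CRYSTAL_ID,
# whitespace separated; '#' lines are comments. The writer records cell,
# point group and dose-per-frame in header comments.

#' Validate an observation table
#'
#' @param obs data.frame with columns h, k, l, intensity, sigma, frame,
#'   crystal_id.
#' @return the table, invisibly, after checks.
#' @keywords internal
validate_observations <- function(obs) {
  need <- c("h", "k", "l", "intensity", "sigma", "frame", "crystal_id")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("observations lack columns: ", paste(miss, collapse = ", "))
  if (nrow(obs)) {
    if (any(obs$sigma <= 0)) stop("all sigmas must be > 0")
    if (any(obs$frame < 1)) stop("frames are 1-based: frame >= 1 required")
    if (any(obs$h == 0 & obs$k == 0 & obs$l == 0)) {
      stop("(0,0,0) is not a valid reflection index")
    }
  }
  invisible(obs)
}

#' Write unmerged observations to the reflection text format
#'
#' @param obs observation data.frame (see \code{\link{validate_observations}}).
#' @param path output file path.
#' @param cell_a,point_group,dose_per_frame metadata recorded in header
#'   comments (optional).
#' @return \code{path}, invisibly.
#' @export
write_reflections <- function(obs, path, cell_a = NA, point_group = NA,
                              dose_per_frame = NA) {
  validate_observations(obs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# unmerged reflection observations",
    sprintf("# cell_a= %s  point_group= %s  dose_per_frame_kGy= %s",
            format(cell_a), format(point_group), format(dose_per_frame)),
    "# H K L INTENSITY SIGMA FRAME CRYSTAL_ID"
  ), con)
  if (nrow(obs)) {
    writeLines(sprintf("%d %d %d %.10g %.10g %d %s",
                       obs$h, obs$k, obs$l, obs$intensity, obs$sigma,
                       obs$frame, obs$crystal_id), con)
  }
  invisible(path)
}

#' Read unmerged observations from the reflection text format
#'
#' Malformed lines (wrong column count, non-numeric fields, non-positive
#' sigma) raise an error naming the offending line number.
#'
#' @param path input file path.
#' @return observation data.frame.
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      intensity = numeric(0), sigma = numeric(0),
                      frame = integer(0), crystal_id = character(0),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 7L)) {
    bad <- idx[which(nf != 7L)[1L]]
    stop("malformed reflection line ", bad, ": expected 7 columns, got ",
         nf[which(nf != 7L)[1L]])
  }
  m <- matrix(unlist(toks), ncol = 7L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 1:6, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 6L)
  if (any(is.na(num))) {
    bad <- idx[which(rowSums(is.na(num)) > 0)[1L]]
    stop("malformed reflection line ", bad, ": non-numeric field")
  }
  obs <- data.frame(h = as.integer(num[, 1]), k = as.integer(num[, 2]),
                    l = as.integer(num[, 3]), intensity = num[, 4],
                    sigma = num[, 5], frame = as.integer(num[, 6]),
                    crystal_id = m[, 7], stringsAsFactors = FALSE)
  if (any(obs$sigma <= 0)) {
    bad <- idx[which(obs$sigma <= 0)[1L]]
    stop("invalid sigma <= 0 at line ", bad)
  }
  validate_observations(obs)
  obs
}
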