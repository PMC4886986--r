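# Brute-force oracles, written independently of the package internals.

# The 12 rotations of point group 23, constructed directly as the even
# axis permutations combined with sign patterns of positive determinant
# (sign(perm) * prod(signs) = +1).
oracle_rotations_23 <- function() {
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))  # even permutations
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  out <- list()
  for (p in perms) {
    for (s in signs) {
      m <- matrix(0L, 3, 3)
      for (i in 1:3) m[i, p[i]] <- as.integer(s[i])
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

# full orbit of one index under group rotations and Friedel inversion
oracle_orbit <- function(hkl, rots = oracle_rotations_23()) {
  imgs <- list()
  for (r in rots) {
    for (sgn in c(1, -1)) {
      imgs[[length(imgs) + 1L]] <- as.integer(sgn * (r %*% hkl))
    }
  }
  uniq <- unique(vapply(imgs, paste, character(1), collapse = ","))
  do.call(rbind, lapply(strsplit(uniq, ","), as.integer))
}

# lexicographically greatest member of the orbit (compare h, then k, then l)
oracle_asu_rep <- function(hkl, rots = oracle_rotations_23()) {
  orb <- oracle_orbit(hkl, rots)
  best <- orb[1, ]
  for (i in seq_len(nrow(orb))[-1]) {
    x <- orb[i, ]
    if (x[1] > best[1] ||
        (x[1] == best[1] && x[2] > best[2]) ||
        (x[1] == best[1] && x[2] == best[2] && x[3] > best[3])) {
      best <- x
    }
  }
  best
}

# unique ASU reflection count by naive triple loop
oracle_asu_count <- function(cell_a, d_min, d_max, centred = TRUE) {
  hmax <- floor(cell_a / d_min)
  rots <- oracle_rotations_23()
  seen <- character(0)
  for (h in -hmax:hmax) for (k in -hmax:hmax) for (l in -hmax:hmax) {
    if (h == 0 && k == 0 && l == 0) next
    if (centred && (h + k + l) %% 2 != 0) next
    d <- cell_a / sqrt(h^2 + k^2 + l^2)
    if (d < d_min || d > d_max) next
    seen <- c(seen, paste(oracle_asu_rep(c(h, k, l), rots), collapse = ","))
  }
  length(unique(seen))
}

# R factors by naive loops over a list of (key, intensity) pairs
oracle_r_factors <- function(keys, intensities) {
  num_merge <- 0; num_meas <- 0; den <- 0
  for (kk in unique(keys)) {
    ii <- intensities[keys == kk]
    if (length(ii) < 2) next
    m <- mean(ii)
    num_merge <- num_merge + sum(abs(ii - m))
    num_meas <- num_meas + sqrt(length(ii) / (length(ii) - 1)) * sum(abs(ii - m))
    den <- den + sum(ii)
  }
  list(r_merge = num_merge / den, r_meas = num_meas / den)
}

# small observation table builder
make_obs <- function(h, k, l, intensity, sigma = 1, frame = 1,
                     crystal_id = "x") {
  data.frame(h = h, k = k, l = l, intensity = intensity,
             sigma = sigma, frame = frame, crystal_id = crystal_id,
             stringsAsFactors = FALSE)
}

# discrete-dose closed form: expected normalized decay parameters after
# wedge averaging and first-wedge normalization (frames f = 1..n per wedge
# of size m at dose d per frame)
expected_norm_params <- function(i0, i1, beta, dose_per_frame = 0.808,
                                 subset_size = 50L) {
  q <- exp(-beta * dose_per_frame)
  C <- mean(q^(seq_len(subset_size))) / q^subset_size
  d1 <- subset_size * dose_per_frame
  norm <- i0 * C * exp(-beta * d1) + i1
  list(i0 = i0 * C / norm, i1 = i1 / norm, beta = beta)
}
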