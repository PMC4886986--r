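g23 <- point_group_ops("23")

test_that("merge_observations: means, multiplicity, conservation", {
  # one observation per index
  obs1 <- make_obs(c(5, 6), c(1, 2), c(0, 1), intensity = c(10, 20))
  m1 <- merge_observations(obs1, g23)
  expect_equal(nrow(m1), 2)
  expect_true(all(m1$multiplicity == 1))
  expect_setequal(m1$intensity, c(10, 20))

  # duplicates merge to the same mean; symmetry mates merge together
  idx <- map_to_asu(c(5, 1, 0), g23)
  mate <- as.integer(g23$rotations[[5]] %*% as.integer(idx))
  obs2 <- make_obs(c(idx[1], mate[1]), c(idx[2], mate[2]),
                   c(idx[3], mate[3]), intensity = c(90, 110))
  m2 <- merge_observations(obs2, g23)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$intensity, 100)
  expect_equal(m2$multiplicity, 2)

  # hand-computed 6-observation fixture over 2 indices
  obs3 <- make_obs(h = c(5, 5, 5, 6, 6, 6), k = c(1, 1, 1, 2, 2, 2),
                   l = c(0, 0, 0, 0, 0, 0),
                   intensity = c(10, 14, 18, 7, 8, 12),
                   sigma = c(1, 2, 2, 1, 1, 3))
  m3 <- merge_observations(obs3, g23)
  expect_equal(sort(m3$intensity), c(9, 14))   # (7+8+12)/3, (10+14+18)/3
  expect_equal(attr(m3, "total_observations"), 6)
  expect_equal(attr(m3, "unique_reflections"), 2)
  # conservation: sum(multiplicity * mean) = sum of inputs
  expect_equal(sum(m3$multiplicity * m3$intensity), sum(obs3$intensity))
  # propagated sigma: sqrt(sum sigma^2)/n
  expect_equal(sort(m3$sigma),
               sort(c(sqrt(1 + 4 + 4) / 3, sqrt(1 + 1 + 9) / 3)))
})

test_that("R factors match direct arithmetic and the brute-force oracle", {
  obs <- make_obs(c(5, 5), c(1, 1), c(0, 0), intensity = c(90, 110))
  rf <- r_factors(obs, g23)
  expect_equal(rf$r_merge, 0.1)
  expect_equal(rf$r_meas, 0.1 * sqrt(2))

  # identical duplicates: both zero
  same <- make_obs(c(5, 5, 6, 6), c(1, 1, 2, 2), c(0, 0, 1, 1),
                   intensity = c(50, 50, 80, 80))
  rf0 <- r_factors(same, g23)
  expect_equal(rf0$r_merge, 0)
  expect_equal(rf0$r_meas, 0)

  # randomized fixtures against the naive oracle; R_meas >= R_merge always
  set.seed(8)
  for (rep in 1:5) {
    n <- 18
    hkl <- map_to_asu(cbind(sample(4:9, n, TRUE), sample(0:3, n, TRUE),
                            sample(0:2, n, TRUE)), g23)
    hkl[1:3, ] <- hkl[4:6, ]      # guarantee multiply observed indices
    obs <- make_obs(hkl[, 1], hkl[, 2], hkl[, 3],
                    intensity = runif(n, 10, 100))
    rf <- r_factors(obs, g23)
    oracle <- oracle_r_factors(paste(hkl[, 1], hkl[, 2], hkl[, 3]),
                               obs$intensity)
    expect_equal(rf$r_merge, oracle$r_merge)
    expect_equal(rf$r_meas, oracle$r_meas)
    expect_gte(rf$r_meas, rf$r_merge)
  }

  # no multiply-observed index: reported missing
  lone <- make_obs(c(5, 6), c(1, 2), c(0, 1), intensity = c(1, 2))
  expect_true(is.na(r_factors(lone, g23)$r_merge))
})

test_that("cc_half: exact limits, closed-form CC*, invariances", {
  # noiseless duplicates: CC1/2 = CC* = 1
  obs <- make_obs(h = rep(c(5, 6, 7), each = 2),
                  k = rep(c(1, 2, 3), each = 2),
                  l = rep(c(0, 1, 2), each = 2),
                  intensity = rep(c(10, 40, 90), each = 2))
  cc <- cc_half(obs, g23, seed = 1)
  expect_equal(cc$cc_half, 1)
  expect_equal(cc$cc_star, 1)

  # closed form of CC* at CC1/2 = 0.5
  expect_equal(sqrt(2 * 0.5 / 1.5), 0.8164966, tolerance = 1e-6)

  # determinism and input-order / crystal-relabel invariance
  set.seed(3)
  n <- 60
  big <- make_obs(h = rep(5:14, 6), k = rep(0:1, 30), l = rep(0, n),
                  intensity = runif(n, 1, 100),
                  frame = rep(1:6, each = 10),
                  crystal_id = rep(c("a", "b"), 30))
  c1 <- cc_half(big, g23, seed = 7)
  shuffled <- big[sample(n), ]
  c2 <- cc_half(shuffled, g23, seed = 7)
  expect_equal(c1$cc_half, c2$cc_half)
  relabel <- big
  relabel$crystal_id <- rep(c("zz", "yy"), 30)
  expect_equal(cc_half(relabel, g23, seed = 7)$cc_half, c1$cc_half)
  # a different seed changes the split
  expect_false(identical(cc_half(big, g23, seed = 8)$cc_half, c1$cc_half))

  # too few multiply-observed indices
  few <- make_obs(c(5, 5, 6), c(1, 1, 2), c(0, 0, 1), intensity = 1:3)
  expect_error(cc_half(few, g23), "at least 3")

  # synthetic data at known noise: CC1/2 near the analytic expectation
  # var(signal) / (var(signal) + var(noise of half means))
  set.seed(21)
  tr <- generate_truth(d_min = 5, seed = 4)
  nrefl <- nrow(tr$hkl)
  reps <- 8
  noise_sd <- 300
  obs_cc <- make_obs(h = rep(tr$hkl[, 1], reps), k = rep(tr$hkl[, 2], reps),
                     l = rep(tr$hkl[, 3], reps),
                     intensity = rep(tr$intensity, reps) +
                       rnorm(nrefl * reps, sd = noise_sd),
                     frame = rep(seq_len(reps), each = nrefl))
  cc_syn <- cc_half(obs_cc, g23, seed = 5)$cc_half
  v_sig <- var(tr$intensity)
  v_half <- noise_sd^2 / (reps / 2)
  expected <- v_sig / (v_sig + v_half)
  # 3 Monte-Carlo sd of a correlation over nrefl indices
  mc_sd <- (1 - expected^2) / sqrt(nrefl - 3)
  expect_lt(abs(cc_syn - expected), 3 * mc_sd + 0.01)
})

test_that("completeness and multiplicity against brute-force enumeration", {
  g <- g23
  theo <- enumerate_asu(78.8, 6, 30, g, centred = TRUE)
  expect_equal(nrow(theo), oracle_asu_count(78.8, 6, 30, centred = TRUE))

  # full set observed once: 100%, multiplicity 1
  obs <- make_obs(theo[, 1], theo[, 2], theo[, 3],
                  intensity = seq_len(nrow(theo)))
  merged <- merge_observations(obs, g)
  cm <- completeness_multiplicity(merged, 78.8, g, 6, 30)
  expect_equal(cm$completeness, 100)
  expect_equal(cm$multiplicity, 1)

  # half removed: 50% (theo count here is even? compute directly)
  half_n <- floor(nrow(theo) / 2)
  merged_half <- merge_observations(obs[seq_len(half_n), ], g)
  cm2 <- completeness_multiplicity(merged_half, 78.8, g, 6, 30)
  expect_equal(cm2$completeness, 100 * half_n / nrow(theo))

  expect_error(completeness_multiplicity(merged, 78.8, g, 70, 80),
               "no theoretically possible")
})

test_that("merging_statistics assembles a consistent one-row table", {
  tr <- generate_truth(d_min = 5, seed = 9)
  obs <- make_obs(h = rep(tr$hkl[, 1], 2), k = rep(tr$hkl[, 2], 2),
                  l = rep(tr$hkl[, 3], 2),
                  intensity = pmax(rep(tr$intensity, 2) +
                                     rnorm(2 * nrow(tr$hkl), sd = 5), 0.1),
                  frame = rep(1:2, each = nrow(tr$hkl)))
  st <- merging_statistics(obs, 78.8, g23, d_min = 5, d_max = 30, seed = 2)
  expect_equal(st$total_observations, 2 * nrow(tr$hkl))
  expect_equal(st$unique_reflections, nrow(tr$hkl))
  expect_equal(st$multiplicity, 2)
  expect_equal(st$completeness, 100)
  expect_gte(st$r_meas, st$r_merge)
  expect_true(st$cc_half > 0.9 && st$cc_star >= st$cc_half)
})
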