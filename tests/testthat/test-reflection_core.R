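test_that("d_spacing matches the cubic closed form and rejects (0,0,0)", {
  expect_equal(d_spacing(c(0, 0, 2), 78.8), 39.4)
  expect_equal(d_spacing(c(1, 1, 1), 78.8), 78.8 / sqrt(3))
  expect_error(d_spacing(c(0, 0, 0), 78.8), "not a valid reflection")
  # vectorized form agrees with scalar calls
  m <- rbind(c(1, 2, 3), c(4, 0, 0), c(-2, 2, 2))
  expect_equal(d_spacing(m, 78.8),
               vapply(1:3, function(i) d_spacing(m[i, ], 78.8), numeric(1)))
})

test_that("point group 23 has order 12, contains the identity, is closed", {
  g <- point_group_ops("23")
  expect_length(g$rotations, 12)
  keys <- vapply(g$rotations, function(m) paste(m, collapse = ","),
                 character(1))
  expect_true(paste(diag(3L), collapse = ",") %in% keys)
  expect_true(all(vapply(g$rotations, det, numeric(1)) == 1))
  # closure: all 144 pairwise products stay inside
  for (a in g$rotations) for (b in g$rotations) {
    expect_true(paste(a %*% b, collapse = ",") %in% keys)
  }
  # the group equals the independently constructed rotation set
  expect_setequal(keys, vapply(oracle_rotations_23(),
                               function(m) paste(m, collapse = ","),
                               character(1)))
})

test_that("point group '1' is identity only; unknown labels error", {
  g1 <- point_group_ops("1")
  expect_length(g1$rotations, 1)
  expect_equal(g1$rotations[[1]], diag(3L))
  expect_error(point_group_ops("99"), "unsupported point group")
})

test_that("map_to_asu is idempotent and constant on brute-force orbits", {
  g <- point_group_ops("23")
  set.seed(4)
  for (i in 1:25) {
    x <- sample(-8:8, 3, replace = TRUE)
    if (all(x == 0)) x <- c(1, 2, 3)
    a1 <- map_to_asu(x, g)
    expect_equal(map_to_asu(a1, g), a1)
    # every orbit member maps to the same representative, which equals
    # the oracle's lexicographic maximum
    orb <- oracle_orbit(x)
    reps <- map_to_asu(orb, g)
    expect_true(all(reps[, 1] == a1[1, 1] & reps[, 2] == a1[1, 2] &
                      reps[, 3] == a1[1, 3]))
    expect_equal(as.integer(a1[1, ]), oracle_asu_rep(x))
  }
  expect_error(map_to_asu(c(0, 0, 0), g), "not a valid reflection")
})

test_that("ASU orbits over max|hkl| <= 4 partition the index ball", {
  g <- point_group_ops("23")
  rng <- -4:4
  grid <- as.matrix(expand.grid(rng, rng, rng))
  grid <- grid[rowSums(grid^2) > 0, ]
  reps <- map_to_asu(grid, g)
  rep_key <- paste(reps[, 1], reps[, 2], reps[, 3])
  # each representative is a fixed point, and every index in an orbit
  # shares it: orbit sizes sum to the ball size
  urep <- unique(rep_key)
  sizes <- table(rep_key)
  expect_equal(sum(sizes), nrow(grid))
  # representatives themselves lie in the ball and map to themselves
  for (kk in urep[seq(1, length(urep), by = 7)]) {
    x <- as.integer(strsplit(kk, " ")[[1]])
    expect_equal(as.integer(map_to_asu(x, g)), x)
  }
})

test_that("ASU mapping under group '1' merges only Friedel mates", {
  g1 <- point_group_ops("1")
  # canonical rule: lexicographically greatest of {x, -x}
  expect_equal(as.integer(map_to_asu(c(2, 0, 0), g1)), c(2, 0, 0))
  expect_equal(as.integer(map_to_asu(c(-2, 0, 0), g1)), c(2, 0, 0))
  expect_equal(as.integer(map_to_asu(c(-1, 5, -2), g1)), c(1, -5, 2))
})

test_that("the default reindex operator is validated and acts correctly", {
  op <- reindex_operator()
  expect_equal(as.integer(apply_reindex(c(1, 2, 3), op)), c(2, 1, -3))
  # applying twice returns to an index equivalent under the point group
  g <- point_group_ops("23")
  twice <- apply_reindex(apply_reindex(c(1, 2, 3), op), op)
  expect_equal(map_to_asu(twice, g), map_to_asu(c(1, 2, 3), g))
  # (0,0,4) -> (0,0,-4), same ASU representative via Friedel
  expect_equal(as.integer(apply_reindex(c(0, 0, 4), op)), c(0, 0, -4))
  expect_equal(map_to_asu(c(0, 0, -4), g), map_to_asu(c(0, 0, 4), g))
  # a Laue-group element is rejected as an ambiguity operator
  expect_error(reindex_operator(diag(3L)), "element of the Laue group")
  expect_error(reindex_operator(2L * diag(3L)), "determinant")
})

test_that("d_spacing is invariant under symmetry and reindexing", {
  g <- point_group_ops("23")
  op <- reindex_operator()
  set.seed(11)
  for (i in 1:10) {
    x <- sample(-6:6, 3, replace = TRUE)
    if (all(x == 0)) x <- c(1, 1, 2)
    d0 <- d_spacing(x, 78.8)
    for (r in g$rotations) {
      expect_equal(d_spacing(as.integer(r %*% x), 78.8), d0)
    }
    expect_equal(d_spacing(apply_reindex(x, op), 78.8)[1], d0)
  }
})

test_that("reflection files round-trip and reject malformed input", {
  path <- tempfile(fileext = ".hkl")
  obs <- make_obs(h = c(1, 2, -3), k = c(0, 1, 2), l = c(2, -1, 1),
                  intensity = c(10.5, 0.125, 1e4), sigma = c(1, 0.5, 33),
                  frame = c(1, 5, 700), crystal_id = c("a", "a", "b"))
  write_reflections(obs, path, cell_a = 78.8, point_group = "23",
                    dose_per_frame = 0.808)
  back <- read_reflections(path)
  expect_equal(back, obs)

  # empty list round-trips to empty
  empty <- obs[0, ]
  write_reflections(empty, path)
  expect_equal(nrow(read_reflections(path)), 0)

  # malformed column count errors with the line number
  writeLines(c("# header", "1 2 3 4.0 1.0 1 x", "1 2 3 4.0"), path)
  expect_error(read_reflections(path), "line 3")
  # non-positive sigma
  writeLines(c("1 2 3 4.0 -1.0 1 x"), path)
  expect_error(read_reflections(path), "sigma")
  # non-numeric field
  writeLines(c("1 2 z 4.0 1.0 1 x"), path)
  expect_error(read_reflections(path), "non-numeric")
})

test_that("enumerate_asu equals the brute-force orbit count", {
  g <- point_group_ops("23")
  # modest resolution keeps the naive oracle affordable
  for (dmin in c(9, 6)) {
    fast <- enumerate_asu(78.8, dmin, 30, g, centred = TRUE)
    expect_equal(nrow(fast), oracle_asu_count(78.8, dmin, 30, centred = TRUE))
    # every enumerated representative is canonical and in range
    expect_equal(map_to_asu(fast, g), fast)
    d <- d_spacing(fast, 78.8)
    expect_true(all(d >= dmin & d <= 30))
    expect_true(all((rowSums(fast) %% 2) == 0))
  }
  # without centring the count grows
  expect_gt(nrow(enumerate_asu(78.8, 9, 30, g, centred = FALSE)),
            nrow(enumerate_asu(78.8, 9, 30, g, centred = TRUE)))
})
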