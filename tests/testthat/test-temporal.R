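test_that("overlap identities: identical, disjoint, complementary", {
  a <- c(1, 1, 0, 0, 1) > 0
  expect_equal(overlap(a, a), 1)
  expect_equal(overlap(a, !a), 0)
  expect_equal(overlap(a, !a, complementary = TRUE), 1)
  expect_true(is.na(overlap(rep(FALSE, 5), a)))
  b <- c(0, 1, 1, 0, 0) > 0
  expect_equal(overlap(a, b), 1 / 3)
})

test_that("exact complement alternation gives O1 = 0, Obar1 = 1, O2 = 1", {
  s <- c(rep(TRUE, 5), rep(FALSE, 5))
  states <- do.call(rbind, lapply(0:10, function(t) if (t %% 2 == 0) s else !s))
  traj <- structure(list(node_states = states, R_series = rowMeans(states),
                         p = 1, steps = 10L, transient = 0L, seed = NULL,
                         net = list(nodes = matrix(0, 10, 2))),
                    class = "triadic_trajectory")
  expect_true(all(overlap_series(traj, 1)$O == 0))
  expect_true(all(overlap_series(traj, 1, complementary = TRUE)$O == 1))
  expect_true(all(overlap_series(traj, 2)$O == 1))
  # return probabilities under the adaptive threshold
  expect_equal(return_probability(traj, 1), 0)
  expect_equal(return_probability(traj, 2), 1)
  expect_equal(blinking_period(traj), 2L)
})

test_that("adaptive binarisation follows the alpha' = alpha * mean rule", {
  b <- binarize_overlap(c(1, 1, 1), alpha = 0.8)
  expect_equal(b$alpha_prime, 0.8)
  expect_equal(b$binary, c(1L, 1L, 1L))
  b0 <- binarize_overlap(c(0, 0, 0), alpha = 0.8)
  expect_equal(b0$alpha_prime, 0)
  expect_equal(b0$binary, c(0L, 0L, 0L))  # strict inequality
  b2 <- binarize_overlap(c(1, 1, 0, 0), alpha = 0.4)
  expect_equal(b2$alpha_prime, 0.2)
  expect_equal(b2$binary, c(1L, 1L, 0L, 0L))
  bna <- binarize_overlap(c(1, NA, 0.9, 0.1), alpha = 0.8)
  expect_equal(bna$n_excluded, 1L)
  expect_true(is.na(bna$binary[2]))
})

test_that("entropy rate: constant 0, alternation extrapolates to 0, iid near log2(3)", {
  expect_equal(as.numeric(entropy_rate(rep("C", 60))), 0)
  er_alt <- entropy_rate(rep(c("S", "O"), 60))
  expect_equal(as.numeric(er_alt), 0, tolerance = 1e-12)
  # block entropies of strict alternation sit on 1 / L (up to the odd word
  # count of overlapping windows)
  expect_equal(unname(attr(er_alt, "blocks")), c(1, 0.5, 0.25), tolerance = 1e-3)
  set.seed(6)
  er_iid <- entropy_rate(sample(c("C", "O", "S"), 30000, replace = TRUE))
  expect_equal(as.numeric(er_iid), log2(3), tolerance = 0.05)
  expect_lte(as.numeric(er_iid), log2(3) + 1e-9)
  expect_error(entropy_rate(rep("C", 5)), "shorter")
})

test_that("barycenter handles the periodic seam and shifts equivariantly", {
  g <- torus_geometry(10)
  nodes <- rbind(c(0.1, 5), c(9.9, 5))
  b <- barycenter(c(TRUE, TRUE), nodes, g)
  expect_equal(unname(b["x"]), 0, tolerance = 1e-9)
  expect_equal(unname(b["y"]), 5)
  one <- barycenter(c(TRUE, FALSE), nodes, g)
  expect_equal(unname(one), c(0.1, 5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(is.na(barycenter(c(FALSE, FALSE), nodes, g))))
  set.seed(3)
  pts <- cbind(runif(50, 2, 3), runif(50, 7, 8))
  act <- rep(TRUE, 50)
  b0 <- barycenter(act, pts, g)
  sh <- c(4.4, 6.6)
  b1 <- barycenter(act, cbind((pts[, 1] + sh[1]) %% 10, (pts[, 2] + sh[2]) %% 10), g)
  expect_equal((b0 + sh) %% 10, b1, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("wrap-axis detection identifies the wrapping direction of a band", {
  g <- torus_geometry(6, 12)
  set.seed(8)
  n <- 400
  horiz <- cbind(runif(n, 0, 6), runif(n, 3, 4.2))   # wraps x
  expect_equal(pattern_wrap_axis(rep(TRUE, n), horiz, g), "x")
  vert <- cbind(runif(n, 2, 3.1), runif(n, 0, 12))   # wraps y
  expect_equal(pattern_wrap_axis(rep(TRUE, n), vert, g), "y")
})

test_that("frozen patterns return with probability one at every lag", {
  s <- rep(c(TRUE, FALSE), 8)
  states <- matrix(rep(s, 21), nrow = 21, byrow = TRUE)
  traj <- structure(list(node_states = states, R_series = rowMeans(states),
                         p = 1, steps = 20L, transient = 0L, seed = NULL,
                         net = list(nodes = matrix(0, 16, 2))),
                    class = "triadic_trajectory")
  for (tau in 1:3) expect_equal(return_probability(traj, tau), 1)
  expect_equal(blinking_period(traj), 1L)
})
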