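test_that("density grid counts active nodes per cell and conserves totals", {
  g <- torus_geometry(3)
  nodes <- rbind(c(0.1, 0.1), c(2.9, 2.9), c(1.6, 0.2))
  gr <- density_grid(c(TRUE, FALSE, FALSE), nodes, M = 3, g)
  expect_equal(sum(gr), 1)
  expect_equal(gr[1, 1], 1)
  expect_equal(sum(density_grid(rep(FALSE, 3), nodes, M = 3, g)), 0)
  set.seed(2)
  nodes2 <- place_nodes(500, g)
  act <- runif(500) < 0.4
  expect_equal(sum(density_grid(act, nodes2, M = 30, g)), sum(act))
})

test_that("ordinal patterns use stable ascending ranking", {
  p1 <- ordinal_pattern(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(attr(p1, "permutation"), c(0L, 1L, 2L, 3L))
  expect_equal(as.integer(p1), 0L)
  p2 <- ordinal_pattern(matrix(c(2, 1, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(attr(p2, "permutation"), c(1L, 0L, 2L, 3L))
  # ties broken by original position: constant matrix is the identity pattern
  p3 <- ordinal_pattern(matrix(5, 2, 2))
  expect_equal(attr(p3, "permutation"), c(0L, 1L, 2L, 3L))
  # Lehmer indices of random submatrices always land in [0, 24)
  set.seed(1)
  idx <- sapply(1:500, function(i) as.integer(ordinal_pattern(runif(4))))
  expect_true(all(idx >= 0 & idx < 24))
  expect_equal(length(unique(idx)), 24)  # every pattern reachable
})

test_that("ordinal distribution slides with wrap-around and normalises", {
  g <- torus_geometry(3)
  # constant grid -> point mass on the identity pattern
  d0 <- ordinal_distribution(matrix(1, 10, 10))
  expect_equal(sum(d0$p), 1)
  expect_equal(d0$p[1], 1)
  expect_equal(d0$n_windows, 100)  # all M^2 positions contribute (wrapping)
  expect_equal(length(d0$p), 24)
  # iid continuous grid: near-uniform ordinal distribution
  set.seed(3)
  du <- ordinal_distribution(matrix(runif(90000), 300, 300))
  expect_lt(max(abs(du$p - 1 / 24)), 4 * sqrt((1 / 24) * (23 / 24) / 90000) * 3)
})

test_that("entropy, disequilibrium and complexity hit their closed-form anchors", {
  mk <- function(p) structure(list(p = p, dx = 2, dy = 2, n_windows = 100),
                              class = "ordinal_distribution")
  point <- mk(c(1, rep(0, 23)))
  unif <- mk(rep(1 / 24, 24))
  two <- mk(c(0.5, 0.5, rep(0, 22)))
  expect_equal(permutation_entropy(point), 0)
  expect_equal(permutation_entropy(unif), 1)
  expect_equal(permutation_entropy(two), log(2) / log(24))
  expect_equal(disequilibrium(unif), 0)
  expect_equal(disequilibrium(point), 1)
  expect_equal(complexity(point), 0)
  expect_equal(complexity(unif), 0)
  expect_equal(complexity(two), permutation_entropy(two) * disequilibrium(two))

  # independent direct evaluation of the Jensen-Shannon numerator
  set.seed(9)
  for (rep in 1:20) {
    p <- stats::rgamma(24, 0.5); p <- p / sum(p)
    S <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
    pe <- rep(1 / 24, 24)
    q0 <- S((c(1, rep(0, 23)) + pe) / 2) - S(c(1, rep(0, 23))) / 2 - S(pe) / 2
    ref <- (S((p + pe) / 2) - S(p) / 2 - S(pe) / 2) / q0
    expect_equal(disequilibrium(mk(p)), ref, tolerance = 1e-12)
    expect_gte(ref, -1e-12); expect_lte(ref, 1)
  }
})

test_that("H and Q stay in [0,1] and C is nonnegative on random distributions", {
  set.seed(31)
  for (rep in 1:300) {
    k <- sample(1:24, 1)
    p <- rep(0, 24)
    p[sample(24, k)] <- stats::rgamma(k, sample(c(0.2, 1, 5), 1))
    p <- p / sum(p)
    d <- structure(list(p = p, dx = 2, dy = 2, n_windows = 1),
                   class = "ordinal_distribution")
    H <- permutation_entropy(d); Q <- disequilibrium(d)
    expect_gte(H, 0); expect_lte(H, 1 + 1e-12)
    expect_gte(Q, -1e-12); expect_lte(Q, 1 + 1e-12)
    expect_gte(complexity(d), -1e-12)
  }
})

test_that("pattern measures are invariant under torus shifts up to grid discretisation", {
  g <- torus_geometry(5)
  set.seed(13)
  nodes <- place_nodes(2000, g)
  act <- nodes[, 2] > 1 & nodes[, 2] < 2    # band pattern
  base <- pattern_info(act, nodes, g, M = 30)
  # shift the whole pattern by a multiple of the cell size: exactly invariant
  shift <- 5 / 30 * 7
  nodes_s <- cbind(nodes[, 1], (nodes[, 2] + shift) %% 5)
  s1 <- pattern_info(act, nodes_s, g, M = 30)
  expect_equal(s1$H, base$H, tolerance = 1e-12)
  expect_equal(s1$C, base$C, tolerance = 1e-12)
  # generic shift: invariant within a tolerance band
  nodes_g <- cbind((nodes[, 1] + 1.234) %% 5, (nodes[, 2] + 2.08) %% 5)
  s2 <- pattern_info(act, nodes_g, g, M = 30)
  expect_equal(s2$H, base$H, tolerance = 0.08)
  expect_equal(s2$C, base$C, tolerance = 0.08)
})

test_that("structured patterns have lower entropy and higher complexity than surrogates", {
  g <- torus_geometry(5)
  set.seed(40)
  nodes <- place_nodes(2500, g)
  dH <- dC <- numeric(50)
  for (k in 1:50) {
    c0 <- runif(1, 0, 5); w <- runif(1, 0.8, 2)
    act <- (nodes[, 2] - c0) %% 5 < w            # stripe-like pattern
    sur <- surrogate_pattern(act, seed = k)
    a <- pattern_info(act, nodes, g); b <- pattern_info(sur, nodes, g)
    dH[k] <- a$H - b$H; dC[k] <- a$C - b$C
  }
  expect_lt(stats::median(dH), 0)
  expect_gt(stats::median(dC), 0)
})
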