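test_that("template classes carry their advertised loop structure", {
  g <- torus_geometry(5)
  dominant <- function(pd) sum(pd$H1[, 2] - pd$H1[, 1] > g$Lx / 10)
  for (s in 1:12) {
    ptsS <- make_template("S", g, params = list(p_double_stripe = 0), seed = 100 + s)
    pdS <- rips_persistence(torus_distance_matrix(ptsS, g), 1.25, 0.5)
    expect_equal(dominant(pdS), 1)  # one loop per single stripe

    ptsC <- make_template("C", g, seed = 200 + s)
    pdC <- rips_persistence(torus_distance_matrix(ptsC, g), 1.25, 0.5)
    expect_equal(dominant(pdC), 0)  # clusters have no holes

    ptsO <- make_template("O", g, seed = 300 + s)
    pdO <- rips_persistence(torus_distance_matrix(ptsO, g), 1.25, 0.5)
    expect_gte(dominant(pdO), 2)    # octopus variants: at least two loops
  }
  # a double stripe carries one dominant loop per band
  pts2 <- make_template("S", g, params = list(p_double_stripe = 1), seed = 17)
  pd2 <- rips_persistence(torus_distance_matrix(pts2, g), 1.25, 0.5)
  expect_equal(dominant(pd2), 2)
})

test_that("library building is reproducible and sized as requested", {
  g <- torus_geometry(3)
  lib1 <- build_template_library(g, n_per_class = 1, seed = 5)
  expect_equal(length(lib1$entries), 3)
  liba <- build_template_library(g, n_per_class = 4, seed = 9)
  libb <- build_template_library(g, n_per_class = 4, seed = 9)
  expect_equal(liba$entries, libb$entries)
  expect_equal(sort(unique(liba$labels)), c("C", "O", "S"))
  full <- fixture_lib()
  expect_equal(table(full$labels), table(rep(c("C", "O", "S"), 12)),
               ignore_attr = TRUE)
})

test_that("a library template classifies to its own class at zero distance", {
  lib <- fixture_lib()
  for (k in c(1, 15, 30)) {
    e <- lib$entries[[k]]
    res <- classify_pattern(e$diagram, lib)
    expect_equal(res$label, e$label)
    expect_equal(unname(res$distances[e$label]), 0)
  }
})

test_that("held-out template patterns classify to their class on a small library", {
  lib <- fixture_lib()
  g <- lib$geometry
  labs <- c("C", "O", "S")
  pred <- sapply(1:10, function(k) sapply(labs, function(L) {
    pts <- make_template(L, g, seed = 5000 + 3 * k + match(L, labs))
    pd <- rips_persistence(torus_distance_matrix(pts, g), lib$cap,
                           lib$min_persistence)
    classify_pattern(pd, lib)$label
  }))
  expect_gte(mean(pred == labs), 0.9)
})

test_that("within-class diagram distances are smaller than between-class distances", {
  lib <- fixture_lib()
  n <- length(lib$entries)
  within <- c(); between <- c()
  set.seed(4)
  pairs <- cbind(sample(n, 300, TRUE), sample(n, 300, TRUE))
  pairs <- pairs[pairs[, 1] < pairs[, 2], ]
  for (r in seq_len(nrow(pairs))) {
    d <- diagram_distance(lib$entries[[pairs[r, 1]]]$diagram,
                          lib$entries[[pairs[r, 2]]]$diagram)
    if (lib$labels[pairs[r, 1]] == lib$labels[pairs[r, 2]]) {
      within <- c(within, d)
    } else {
      between <- c(between, d)
    }
  }
  expect_lt(mean(within), mean(between))
})

test_that("near-empty patterns are labelled C by convention", {
  lib <- fixture_lib()
  empty <- structure(list(H0 = matrix(numeric(0), 0, 2,
                                      dimnames = list(NULL, c("birth", "death"))),
                          H1 = matrix(numeric(0), 0, 2,
                                      dimnames = list(NULL, c("birth", "death"))),
                          cap = lib$cap), class = "persistence_diagram")
  expect_equal(classify_pattern(empty, lib)$label, "C")
})

test_that("template libraries round-trip through JSON", {
  lib <- fixture_lib()
  path <- withr::local_tempfile(fileext = ".json")
  write_template_library(lib, path)
  back <- read_template_library(path)
  expect_equal(back$labels, lib$labels)
  expect_equal(back$cap, lib$cap)
  for (k in c(1, 20, 36)) {
    expect_equal(unname(back$entries[[k]]$diagram$H0),
                 unname(lib$entries[[k]]$diagram$H0), tolerance = 1e-12)
    expect_equal(unname(back$entries[[k]]$diagram$H1),
                 unname(lib$entries[[k]]$diagram$H1), tolerance = 1e-12)
  }
  # classification with the restored library is unchanged
  q <- lib$entries[[7]]$diagram
  expect_equal(classify_pattern(q, back)$label, classify_pattern(q, lib)$label)
})

test_that("classify_trajectory: dead dynamics gives all C, a frozen band gives all S", {
  lib <- fixture_lib()
  g <- lib$geometry
  set.seed(30)
  nodes <- place_nodes(900, g)
  mk_traj <- function(act) {
    states <- matrix(rep(act, 13), nrow = 13, byrow = TRUE)
    structure(list(node_states = states, R_series = rowMeans(states),
                   p = 1, steps = 12L, transient = 2L, seed = NULL,
                   net = list(nodes = nodes, geometry = g)),
              class = "triadic_trajectory")
  }
  dead <- classify_trajectory(mk_traj(rep(FALSE, 900)), lib)
  expect_true(all(dead$label == "C"))
  expect_equal(nrow(dead), 11)
  band <- nodes[, 2] > 1.2 & nodes[, 2] < 1.8
  frozen <- classify_trajectory(mk_traj(band), lib, seed = 4)
  expect_true(all(frozen$label == "S"))
  # stride thins the analysed steps
  strided <- classify_trajectory(mk_traj(band), lib, stride = 5, seed = 4)
  expect_equal(nrow(strided), 3)
})
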