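# hand-checkable 3-node network: nodes A=1, B=2, C=3; edges AB, BC;
# A positively regulates BC; C negatively regulates AB
toy3 <- function() {
  g <- torus_geometry(2)
  structure(list(
    geometry = g,
    nodes = cbind(x = c(0.5, 1.0, 1.5), y = rep(1, 3)),
    edges = matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("u", "v"))),
    midpoints = rbind(c(0.75, 1), c(1.25, 1)),
    reg = data.frame(regulator = c(1L, 3L), edge = c(2L, 1L),
                     sign = c(1L, -1L)),
    params = list(N = 3, rho = 0.75, c = 1, c_plus = 0.5, c_minus = 0.5,
                  d0 = 1, dr_plus = 1, dr_minus = 1, aspect = 1, seed = 0)
  ), class = "triadic_network")
}

test_that("the two-step iteration follows the regulation rules on a toy network", {
  net <- toy3()
  # t0: all links active -> all nodes in one component
  s0 <- list(node_active = activate_nodes_from_links(net, c(TRUE, TRUE)),
             link_active = c(TRUE, TRUE), t = 0L)
  expect_equal(s0$node_active, rep(TRUE, 3))
  s0$link_active <- update_links(net, s0$node_active, p = 1)
  # AB has active negative regulator C -> off; BC has active positive A -> on
  expect_equal(s0$link_active, c(FALSE, TRUE))
  s1 <- percolation_step(net, s0, p = 1)
  expect_equal(s1$node_active, c(FALSE, TRUE, TRUE))  # component {B, C}
  expect_equal(s1$link_active, c(FALSE, FALSE))       # A inactive: BC loses boost
  s2 <- percolation_step(net, s1, p = 1)
  expect_equal(s2$node_active, rep(FALSE, 3))
  expect_equal(s2$link_active, c(FALSE, FALSE))       # absorbing
  s3 <- percolation_step(net, s2, p = 1)
  expect_equal(s3$node_active, s2$node_active)        # all-inactive is a fixed point
  expect_equal(s3$link_active, s2$link_active)
})

test_that("links without positive regulators stay off; p bounds respected", {
  net <- toy3()
  all_on <- rep(TRUE, 3)
  expect_equal(update_links(net, all_on, p = 0), c(FALSE, FALSE))
  # remove the negative regulation: AB still off (no positive regulator at all)
  net2 <- net
  net2$reg <- net2$reg[net2$reg$sign == 1, ]
  expect_equal(update_links(net2, all_on, p = 1), c(FALSE, TRUE))
})

test_that("a link inactive at t can reactivate when its regulation conditions return", {
  # A - B edge (1), B - C edge (2); B positively regulates both
  g <- torus_geometry(2)
  net <- structure(list(
    geometry = g, nodes = cbind(x = c(0.5, 1, 1.5), y = rep(1, 3)),
    edges = matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("u", "v"))),
    midpoints = rbind(c(0.75, 1), c(1.25, 1)),
    reg = data.frame(regulator = c(2L, 2L), edge = c(1L, 2L), sign = c(1L, 1L)),
    params = list(N = 3, rho = 0.75, c = 1, c_plus = 0.5, c_minus = 0,
                  d0 = 1, dr_plus = 1, dr_minus = 1, aspect = 1, seed = 0)
  ), class = "triadic_network")
  # link 1 off, link 2 on -> B active; both links eligible next step
  s <- list(node_active = activate_nodes_from_links(net, c(FALSE, TRUE)),
            link_active = c(FALSE, TRUE), t = 0L)
  s2 <- percolation_step(net, s, p = 1)
  expect_true(s2$link_active[1])  # reactivated
})

test_that("activation requires the largest component; sub-2 components deactivate all", {
  g <- torus_geometry(3)
  set.seed(3)
  nodes <- place_nodes(6, g)
  edges <- matrix(c(1L, 2L, 2L, 3L, 4L, 5L), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, c("u", "v")))
  net <- structure(list(
    geometry = g, nodes = nodes, edges = edges,
    midpoints = matrix(0.5, 3, 2),
    reg = data.frame(regulator = integer(0), edge = integer(0), sign = integer(0)),
    params = list(N = 6, rho = 1, c = 1, c_plus = 0, c_minus = 0, d0 = 1,
                  dr_plus = 1, dr_minus = 1, aspect = 1, seed = 0)
  ), class = "triadic_network")
  # components {1,2,3} (size 3) and {4,5} (size 2): only the larger is active
  expect_equal(activate_nodes_from_links(net, c(TRUE, TRUE, TRUE)),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # path over all nodes -> all active
  net$edges <- matrix(c(1:5, 2:6), 5, 2, dimnames = list(NULL, c("u", "v")))
  net$midpoints <- matrix(0.5, 5, 2)
  expect_equal(activate_nodes_from_links(net, rep(TRUE, 5)), rep(TRUE, 6))
  # no active links -> all inactive
  expect_equal(activate_nodes_from_links(net, rep(FALSE, 5)), rep(FALSE, 6))
})

test_that("dynamics agrees with the brute-force oracle on small networks", {
  set.seed(99)
  for (case in 1:100) {
    n <- sample(4:12, 1)
    net <- tiny_network(n, seed = 10000 + case)
    if (nrow(net$edges) == 0) next
    link <- rep(TRUE, nrow(net$edges))
    p <- sample(c(1, 1, 0.6), 1)
    seed_step <- 555 + case
    for (t in 1:20) {
      set.seed(seed_step + t)
      ours_nodes <- activate_nodes_from_links(net, link)
      ours_links <- update_links(net, ours_nodes, p)
      set.seed(seed_step + t)
      ref <- oracle_step(net, link, p)
      expect_equal(ours_nodes, ref$node_active)
      expect_equal(ours_links, ref$link_active)
      link <- ours_links
      if (!any(link)) break
    }
  }
})

test_that("run_percolation matches composed steps, is deterministic at p = 1, and bounded", {
  net <- fixture_net()
  tr <- run_percolation(net, p = 1, steps = 200, transient = 50, seed = 5)
  tr2 <- run_percolation(net, p = 1, steps = 200, transient = 50, seed = 99)
  expect_identical(tr$node_states, tr2$node_states)  # p = 1: seed-independent
  expect_true(all(tr$R_series >= 0 & tr$R_series <= 1))
  expect_equal(tr$R_series, rowMeans(tr$node_states))

  # stochastic case: the run loop equals the step-by-step path under one stream
  trs <- run_percolation(net, p = 0.7, steps = 30, seed = 11)
  set.seed(11)
  state <- list(node_active = activate_nodes_from_links(net, rep(TRUE, nrow(net$edges))),
                link_active = NULL, t = 0L)
  state$link_active <- update_links(net, state$node_active, 0.7)
  manual <- matrix(NA, 31, nrow(net$nodes))
  manual[1, ] <- state$node_active
  for (t in 1:30) {
    state <- percolation_step(net, state, 0.7)
    manual[t + 1, ] <- state$node_active
  }
  expect_equal(unname(trs$node_states), unname(manual))

  # long-run average activity stays well below 1 at default parameters
  trl <- run_percolation(net, p = 0.8, steps = 400, transient = 200, seed = 2)
  expect_lt(mean(trl$R_series[201:401]), 0.6)
})

test_that("giant_fraction is the mean activity", {
  expect_equal(giant_fraction(rep(TRUE, 10)), 1)
  expect_equal(giant_fraction(rep(FALSE, 7)), 0)
  expect_equal(giant_fraction(c(rep(TRUE, 250), rep(FALSE, 750))), 0.25)
})
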