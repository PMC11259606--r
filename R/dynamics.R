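#' Node activation from the active-link subgraph (Step 1)
#'
#' Nodes are active iff they belong to the largest connected component of the
#' subgraph formed by the currently active structural links. If the largest
#' component has fewer than two nodes (no active link) every node is inactive;
#' exact size ties are broken towards the component containing the smallest
#' node index, which keeps the deterministic (`p = 1`) dynamics reproducible.
#'
#' @param net a `triadic_network`.
#' @param link_active logical vector over structural links.
#' @return logical node-activity vector of length `N`.
#' @export
activate_nodes_from_links <- function(net, link_active) {
  stopifnot(inherits(net, "triadic_network"))
  if (length(link_active) != nrow(net$edges)) {
    stop("link_active must have one entry per structural link", call. = FALSE)
  }
  largest_component_cpp(nrow(net$nodes), net$edges, as.logical(link_active))
}

# CSR layout of the signed regulator lists: for each edge, the 0-based node
# indices of its positive / negative regulators.
reg_csr <- function(net) {
  E <- nrow(net$edges)
  make <- function(sub) {
    ord <- order(sub$edge)
    idx <- as.integer(sub$regulator[ord] - 1L)
    ptr <- c(0L, cumsum(tabulate(sub$edge[ord], nbins = E)))
    list(ptr = as.integer(ptr), idx = idx)
  }
  list(pos = make(net$reg[net$reg$sign == 1, ]),
       neg = make(net$reg[net$reg$sign == -1, ]))
}

#' Link update from node activity (Step 2)
#'
#' A structural link is active at the next step iff it has no active negative
#' regulator, at least one active positive regulator, and an independent
#' Bernoulli(`p`) retention success (redrawn every step; no draw is consumed
#' when `p = 1`). All structural links are re-evaluated each step, so links
#' inactive at one time can reactivate later.
#'
#' @param net a `triadic_network`.
#' @param node_active logical node-activity vector.
#' @param p link retention probability in `[0, 1]`.
#' @return logical link-activity vector.
#' @export
update_links <- function(net, node_active, p) {
  stopifnot(inherits(net, "triadic_network"), p >= 0, p <= 1)
  if (length(node_active) != nrow(net$nodes)) {
    stop("node_active must have one entry per node", call. = FALSE)
  }
  csr <- reg_csr(net)
  update_links_cpp(nrow(net$nodes), nrow(net$edges), as.logical(node_active),
                   csr$pos$ptr, csr$pos$idx, csr$neg$ptr, csr$neg$idx, p)
}

#' One iteration of the triadic percolation dynamics
#'
#' Applies Step 1 (node activity from the previous link configuration) and
#' then Step 2 (link update from the new node activity).
#'
#' @param net a `triadic_network`.
#' @param state list with elements `node_active`, `link_active`, `t` (as
#'   produced by this function or by the initial condition in [run_percolation()]).
#' @param p link retention probability.
#' @return the next state, same shape, with `t` incremented.
#' @export
percolation_step <- function(net, state, p) {
  node_active <- activate_nodes_from_links(net, state$link_active)
  link_active <- update_links(net, node_active, p)
  list(node_active = node_active, link_active = link_active, t = state$t + 1L)
}

#' Run a triadic percolation trajectory
#'
#' Starts from the all-links-active initial condition and iterates the
#' two-step dynamics. State 0 is the result of applying Step 1 to the initial
#' condition (so `R[1]` is the giant-component fraction of the full structural
#' network), and each subsequent state is one full iteration.
#'
#' @param net a `triadic_network`.
#' @param p link retention probability (annealed disorder); `p = 1` is
#'   deterministic.
#' @param steps number of iterations after state 0 (trajectory holds
#'   `steps + 1` states).
#' @param transient number of initial states flagged for exclusion from
#'   downstream statistics (they are still stored).
#' @param seed optional integer seed for the dynamics stream (independent of
#'   the quenched network seed).
#' @return object of class `triadic_trajectory`: `node_states`
#'   (`(steps+1) x N` logical matrix), `R_series`, `link_final`, `p`,
#'   `transient`, `seed`, and the generating `net`.
#' @examples
#' net <- build_network(N = 400, seed = 1)
#' tr <- run_percolation(net, p = 0.8, steps = 50, transient = 20, seed = 2)
#' plot(tr$R_series, type = "l", xlab = "t", ylab = "R")
#' @export
run_percolation <- function(net, p, steps, transient = 0, seed = NULL) {
  stopifnot(inherits(net, "triadic_network"), p >= 0, p <= 1,
            steps >= 1, transient >= 0, transient <= steps)
  csr <- reg_csr(net)
  res <- with_seed(seed, run_dynamics_cpp(
    nrow(net$nodes), net$edges,
    csr$pos$ptr, csr$pos$idx, csr$neg$ptr, csr$neg$idx,
    p, as.integer(steps)))
  structure(list(
    node_states = res$node_states,
    R_series = as.numeric(res$R),
    link_final = res$link_final,
    p = p, steps = as.integer(steps), transient = as.integer(transient),
    seed = seed, net = net
  ), class = "triadic_trajectory")
}

#' @export
print.triadic_trajectory <- function(x, ...) {
  post <- post_transient_steps(x)
  cat(sprintf(paste0(
    "<triadic_trajectory> %d states (transient %d), p = %.3g\n",
    "  mean R (post-transient): %.4f\n"),
    length(x$R_series), x$transient, x$p, mean(x$R_series[post])))
  invisible(x)
}

# 1-based row indices of post-transient states
post_transient_steps <- function(traj) {
  seq.int(traj$transient + 1L, length(traj$R_series))
}

#' Giant-component fraction of a node-activity vector
#'
#' @param node_active logical/binary node vector.
#' @return mean of the vector, in `[0, 1]`.
#' @export
giant_fraction <- function(node_active) {
  if (length(node_active) == 0L) return(0)
  mean(as.numeric(node_active))
}

#' Write a trajectory summary to disk
#'
#' Writes `trajectory.csv` with columns `t` (0-based), `R`, and a JSON header
#' `trajectory.json` with the run parameters.
#'
#' @param traj a `triadic_trajectory`.
#' @param dir output directory.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(t = seq_along(traj$R_series) - 1L, R = traj$R_series),
    file.path(dir, "trajectory.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(N = nrow(traj$net$nodes), steps = traj$steps, transient = traj$transient,
         p = traj$p, dynamics_seed = traj$seed,
         network_params = traj$net$params),
    file.path(dir, "trajectory.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
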