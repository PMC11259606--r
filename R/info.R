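#' Active-node density grid
#'
#' Bins the active nodes of a pattern into an `M x M` grid of half-open cells
#' covering the torus. Rows index the x direction, columns the y direction.
#'
#' @param node_active logical/binary node-activity vector.
#' @param nodes `N x 2` coordinate matrix.
#' @param M grid size per side, at least 2 (default 30).
#' @param g a [torus_geometry()].
#' @return `M x M` integer matrix of counts; `sum(grid)` equals the number of
#'   active nodes.
#' @export
density_grid <- function(node_active, nodes, M = 30, g) {
  stopifnot(M >= 2, length(node_active) == nrow(nodes))
  act <- nodes[as.logical(node_active), , drop = FALSE]
  gx <- pmin(floor(act[, 1] / (g$Lx / M)), M - 1)  # guard FP edge x == Lx
  gy <- pmin(floor(act[, 2] / (g$Ly / M)), M - 1)
  grid <- matrix(tabulate(gx * M + gy + 1, nbins = M * M), nrow = M, byrow = TRUE)
  grid
}

#' Ordinal pattern of a submatrix
#'
#' Flattens the submatrix row-major to \eqn{(a_0, \ldots, a_{d_x d_y - 1})}
#' and returns the permutation that lists positions in ascending value order,
#' ties broken by original position (stable ranking). The pattern
#' \eqn{(0, 1, 2, 3)} therefore denotes \eqn{a_0 < a_1 < a_2 < a_3}, and a
#' constant submatrix maps to the identity pattern.
#'
#' @param sub numeric matrix (or already-flattened vector in row-major order).
#' @return integer pattern index in `[0, (dx*dy)!)` (Lehmer code of the
#'   permutation), with the 0-based permutation attached as attribute
#'   `"permutation"`.
#' @examples
#' ordinal_pattern(matrix(c(1, 2, 3, 4), 2, byrow = TRUE))  # identity, index 0
#' attr(ordinal_pattern(matrix(c(2, 1, 3, 4), 2, byrow = TRUE)), "permutation")
#' @export
ordinal_pattern <- function(sub) {
  a <- if (is.matrix(sub)) as.vector(t(sub)) else as.vector(sub)
  perm <- order(a) - 1L  # stable: ties keep original position order
  structure(lehmer_index(perm), permutation = perm)
}

# Lehmer code: index of a 0-based permutation in lexicographic order
lehmer_index <- function(perm) {
  n <- length(perm)
  idx <- 0
  for (i in seq_len(n - 1L)) {
    smaller_later <- sum(perm[(i + 1L):n] < perm[i])
    idx <- idx + smaller_later * factorial(n - i)
  }
  as.integer(idx)
}

#' Ordinal-pattern distribution of a grid
#'
#' Slides a `dx x dy` window (stride 1) over all `M^2` positions of the grid,
#' wrapping across the periodic boundary, and tabulates the relative frequency
#' of each ordinal pattern.
#'
#' @param grid numeric matrix, at least `dx x dy`.
#' @param dx,dy embedding dimensions (defaults 2 and 2, giving a
#'   24-letter ordinal alphabet).
#' @return object of class `ordinal_distribution`: list with `p` (probability
#'   vector over all `(dx*dy)!` patterns, indexed by Lehmer code + 1), `dx`,
#'   `dy`, `n_windows`.
#' @export
ordinal_distribution <- function(grid, dx = 2, dy = 2) {
  stopifnot(is.matrix(grid), dx >= 1, dy >= 1, dx * dy >= 2)
  if (nrow(grid) < dx || ncol(grid) < dy) {
    stop("grid smaller than the embedding window", call. = FALSE)
  }
  if (dx * dy > 8) stop("embedding dimension too large: (dx*dy)! patterns", call. = FALSE)
  M1 <- nrow(grid); M2 <- ncol(grid)
  n_pat <- factorial(dx * dy)
  # stack the dx*dy wrapped shifts as columns, row-major window order
  cols <- vector("list", dx * dy)
  k <- 1L
  for (u in 0:(dx - 1L)) {
    for (v in 0:(dy - 1L)) {
      ri <- ((seq_len(M1) - 1L + u) %% M1) + 1L
      ci <- ((seq_len(M2) - 1L + v) %% M2) + 1L
      cols[[k]] <- as.vector(grid[ri, ci])
      k <- k + 1L
    }
  }
  vals <- do.call(cbind, cols)
  idx <- apply(vals, 1L, function(a) lehmer_index(order(a) - 1L))
  counts <- tabulate(idx + 1L, nbins = n_pat)
  structure(list(p = counts / sum(counts), dx = dx, dy = dy,
                 n_windows = nrow(vals)),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution> dx = %d, dy = %d; %d windows, %d/%d patterns seen\n",
              x$dx, x$dy, x$n_windows, sum(x$p > 0), length(x$p)))
  invisible(x)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalised permutation entropy
#'
#' \eqn{H = S[P] / \ln((d_x d_y)!)} with \eqn{S} the Shannon entropy (natural
#' log) of the ordinal-pattern distribution; 1 for the uniform distribution,
#' 0 for a point mass.
#'
#' @param dist an [ordinal_distribution()].
#' @return value in `[0, 1]`.
#' @export
permutation_entropy <- function(dist) {
  stopifnot(inherits(dist, "ordinal_distribution"))
  shannon(dist$p) / log(length(dist$p))
}

#' Jensen-Shannon disequilibrium
#'
#' Normalised Jensen-Shannon divergence between the ordinal distribution and
#' the uniform distribution over the pattern alphabet:
#' \eqn{Q = [S((P+P_e)/2) - S(P)/2 - S(P_e)/2] / Q_0}, where the normalisation
#' \eqn{Q_0} is the same numerator evaluated at a point mass (its maximum), so
#' \eqn{Q \in [0, 1]}: 0 for the uniform distribution, 1 for a point mass.
#'
#' @inheritParams permutation_entropy
#' @return value in `[0, 1]`.
#' @export
disequilibrium <- function(dist) {
  stopifnot(inherits(dist, "ordinal_distribution"))
  n <- length(dist$p)
  pe <- rep(1 / n, n)
  js <- function(p) shannon((p + pe) / 2) - shannon(p) / 2 - shannon(pe) / 2
  q0 <- js(c(1, rep(0, n - 1)))
  js(dist$p) / q0
}

#' LMC statistical complexity
#'
#' \eqn{C = Q \cdot H}: zero at both extremes (fully ordered pattern,
#' \eqn{H = 0}; fully random pattern, \eqn{Q = 0}) and positive in between.
#'
#' @inheritParams permutation_entropy
#' @return nonnegative value.
#' @export
complexity <- function(dist) {
  permutation_entropy(dist) * disequilibrium(dist)
}

#' Entropy and complexity of one activity pattern
#'
#' Convenience wrapper: density grid, ordinal distribution, and the three
#' measures in one call.
#'
#' @inheritParams density_grid
#' @param dx,dy embedding dimensions (defaults 2, 2).
#' @return list with `H`, `Q`, `C`.
#' @export
pattern_info <- function(node_active, nodes, g, M = 30, dx = 2, dy = 2) {
  dist <- ordinal_distribution(density_grid(node_active, nodes, M, g), dx, dy)
  H <- permutation_entropy(dist)
  Q <- disequilibrium(dist)
  list(H = H, Q = Q, C = H * Q)
}

#' Per-step information measures of a trajectory
#'
#' @param traj a `triadic_trajectory`.
#' @inheritParams pattern_info
#' @return data.frame with columns `t` (0-based), `R`, `H`, `C` over the
#'   post-transient window.
#' @export
trajectory_info <- function(traj, M = 30, dx = 2, dy = 2) {
  g <- traj$net$geometry
  rows <- post_transient_steps(traj)
  out <- data.frame(t = rows - 1L, R = traj$R_series[rows],
                    H = NA_real_, C = NA_real_)
  for (k in seq_along(rows)) {
    pi <- pattern_info(traj$node_states[rows[k], ], traj$net$nodes, g, M, dx, dy)
    out$H[k] <- pi$H
    out$C[k] <- pi$C
  }
  out
}

#' Size-matched random surrogate pattern
#'
#' Returns an activity vector with the same number of active nodes, chosen
#' uniformly at random — the null against which the spatial structure of the
#' percolation patterns is measured.
#'
#' @param node_active logical/binary node-activity vector.
#' @param seed optional integer seed.
#' @return logical vector of the same length.
#' @export
surrogate_pattern <- function(node_active, seed = NULL) {
  n <- length(node_active)
  k <- sum(as.logical(node_active))
  with_seed(seed, {
    out <- logical(n)
    out[sample.int(n, k)] <- TRUE
    out
  })
}
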