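#' Point cloud of active nodes
#'
#' Extracts the coordinates of the active nodes of one activity state. When
#' more than `max_points` nodes are active, a uniform seeded subsample of size
#' `max_points` is taken: Vietoris-Rips reduction is cubic in the number of
#' points, and the macroscopic component/loop structure of the patterns
#' survives uniform subsampling.
#'
#' @param node_active logical/binary node-activity vector.
#' @param nodes `N x 2` coordinate matrix.
#' @param max_points maximum cloud size (default 200).
#' @param seed optional integer seed for the subsample.
#' @return a `k x 2` coordinate matrix (`k = 0` when nothing is active).
#' @export
active_point_cloud <- function(node_active, nodes, max_points = 200, seed = NULL) {
  stopifnot(max_points >= 1, length(node_active) == nrow(nodes))
  idx <- which(as.logical(node_active))
  if (length(idx) > max_points) {
    idx <- with_seed(seed, sort(sample(idx, max_points)))
  }
  nodes[idx, , drop = FALSE]
}

#' Density-based denoising of a point cloud
#'
#' Removes low-density outliers before persistence: a point is kept iff the
#' distance to its `k`-th nearest neighbour is at most `factor` times the
#' median such distance over the cloud. The rule is scale-adaptive: on a
#' spatially uniform cloud almost nothing is removed, while the sparse stray
#' nodes that the giant component drags along outside the macroscopic pattern
#' (which would otherwise bridge holes or add spurious components) are
#' discarded.
#'
#' @param points `n x 2` coordinate matrix on the torus.
#' @param g a [torus_geometry()].
#' @param k neighbour order (default 3).
#' @param factor multiple of the median `k`-NN distance kept (default 3).
#' @return the retained rows of `points` (all of them when `n <= k`).
#' @export
denoise_cloud <- function(points, g, k = 3, factor = 3) {
  n <- nrow(points)
  if (n <= k) return(points)
  D <- torus_distance_matrix(points, g)
  dk <- apply(D, 1, function(r) sort(r, partial = k + 1)[k + 1])
  points[dk <= factor * stats::median(dk), , drop = FALSE]
}

#' Vietoris-Rips persistence diagram (H0 and H1)
#'
#' Computes the persistent homology of the Vietoris-Rips filtration of a
#' finite metric space given by its distance matrix, with simplices up to
#' dimension 2 and the filtration capped at `cap`. Classes alive at the cap
#' (essential classes) are assigned death `cap`, so every point of the diagram
#' is finite. Zero-persistence pairs are dropped.
#'
#' @param D symmetric distance matrix (use [torus_distance_matrix()] so that
#'   loops wrapping the periodic domain register in H1).
#' @param cap filtration cap, positive. On a torus any cap below
#'   `min(Lx, Ly) / 2` is meaningful; the classification pipeline uses
#'   `min(Lx, Ly) / 4`, large enough that macroscopic wrapping loops are
#'   long-lived while the triangle enumeration stays affordable.
#' @param min_persistence drop pairs with `death - birth` below this value
#'   (default 0: keep everything). Essential classes (death at the cap) are
#'   always kept: a class still alive at the cap is macroscopic regardless of
#'   how late it was born.
#' @return object of class `persistence_diagram`: list with `H0` and `H1`
#'   (two-column `birth`, `death` matrices) and `cap`.
#' @examples
#' g <- torus_geometry(10)
#' th <- seq(0, 2 * pi, length.out = 25)[-25]
#' circ <- cbind(5 + cos(th), 5 + sin(th))
#' pd <- rips_persistence(torus_distance_matrix(circ, g), cap = 5)
#' pd  # one essential H0 class and one dominant H1 loop
#' @export
rips_persistence <- function(D, cap, min_persistence = 0) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), cap > 0, min_persistence >= 0)
  res <- rips_pairs_cpp(D, cap)
  mk <- function(m) {
    colnames(m) <- c("birth", "death")
    if (min_persistence > 0 && nrow(m) > 0) {
      keep <- (m[, 2] - m[, 1] >= min_persistence) |
        (m[, 2] >= cap * (1 - 1e-12))
      m <- m[keep, , drop = FALSE]
    }
    m
  }
  structure(list(H0 = mk(res$H0), H1 = mk(res$H1), cap = cap),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> cap = %.4g; %d H0 and %d H1 classes\n",
              x$cap, nrow(x$H0), nrow(x$H1)))
  invisible(x)
}

#' @param x a `persistence_diagram`.
#' @param ... passed to [graphics::plot()].
#' @rdname rips_persistence
#' @export
plot.persistence_diagram <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$cap), ylim = c(0, x$cap),
                 xlab = "birth", ylab = "death", ...)
  graphics::abline(0, 1, col = "grey")
  if (nrow(x$H0)) graphics::points(x$H0, pch = 16, col = "steelblue")
  if (nrow(x$H1)) graphics::points(x$H1, pch = 17, col = "firebrick")
  graphics::legend("bottomright", pch = c(16, 17),
                   col = c("steelblue", "firebrick"),
                   legend = c("H0", "H1"), bty = "n")
  invisible(x)
}

#' Wasserstein distance between persistence diagrams
#'
#' Order-1 Wasserstein matching distance with the L-infinity ground metric:
#' points are optimally matched between the two diagrams, and unmatched points
#' pay their distance to the diagonal, `(death - birth) / 2`. The total
#' distance is the sum of the H0 and the H1 contributions. Diagrams must be
#' finite (essential classes capped), which [rips_persistence()] guarantees.
#'
#' For H0 (all births zero) the matching reduces to one-dimensional transport
#' with deletions and is solved exactly by a monotone dynamic program; general
#' diagrams use the Hungarian algorithm on the standard augmented cost matrix.
#'
#' @param d1,d2 `persistence_diagram` objects.
#' @return nonnegative scalar; zero iff the diagrams coincide per dimension.
#' @export
diagram_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "persistence_diagram"), inherits(d2, "persistence_diagram"))
  w1_pairs(d1$H0, d2$H0) + w1_pairs(d1$H1, d2$H1)
}

# dispatch between the zero-birth fast path and the Hungarian solver
w1_pairs <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (all(a[, 1] == 0) && all(b[, 1] == 0)) {
    w1_zero_birth_cpp(a[, 2], b[, 2])
  } else {
    w1_diagrams_cpp(a, b)
  }
}
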