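#' Torus geometry
#'
#' Defines the periodic rectangular domain \eqn{[0, Lx) \times [0, Ly)} on
#' which nodes live. For a square torus of `N` nodes at density `rho`,
#' `L = sqrt(N / rho)`; use [square_torus()] for that case. All distances on
#' the torus follow the minimal-image convention: the Euclidean length of the
#' shortest wrapped displacement.
#'
#' @param Lx,Ly side lengths (spatial units), both positive.
#' @return An object of class `torus_geometry` with fields `Lx`, `Ly`.
#' @examples
#' g <- torus_geometry(10, 10)
#' torus_distance(c(1, 1), c(9, 1), g)  # 2, wrapping through x = 0
#' @export
torus_geometry <- function(Lx, Ly = Lx) {
  stopifnot(is.numeric(Lx), is.numeric(Ly), length(Lx) == 1L, length(Ly) == 1L)
  if (!is.finite(Lx) || !is.finite(Ly) || Lx <= 0 || Ly <= 0) {
    stop("torus side lengths must be positive and finite", call. = FALSE)
  }
  structure(list(Lx = as.numeric(Lx), Ly = as.numeric(Ly)),
            class = "torus_geometry")
}

#' @param N number of nodes.
#' @param rho node density (nodes per unit area).
#' @rdname torus_geometry
#' @export
square_torus <- function(N, rho = 100) {
  stopifnot(N >= 1, rho > 0)
  torus_geometry(sqrt(N / rho))
}

#' @export
print.torus_geometry <- function(x, ...) {
  cat(sprintf("<torus_geometry> %.4g x %.4g (periodic)\n", x$Lx, x$Ly))
  invisible(x)
}

check_in_bounds <- function(pts, g) {
  pts <- rbind(pts)
  if (ncol(pts) != 2L) stop("points must have two coordinates", call. = FALSE)
  if (any(!is.finite(pts))) stop("non-finite coordinate", call. = FALSE)
  if (any(pts[, 1] < 0 | pts[, 1] >= g$Lx | pts[, 2] < 0 | pts[, 2] >= g$Ly)) {
    stop("coordinates out of torus bounds [0, Lx) x [0, Ly)", call. = FALSE)
  }
  pts
}

#' Minimal-image distance on the torus
#'
#' @param a,b points, each a numeric vector of length 2 within bounds.
#' @param g a [torus_geometry()].
#' @return Euclidean length of the shortest wrapped displacement.
#' @export
torus_distance <- function(a, b, g) {
  a <- check_in_bounds(a, g); b <- check_in_bounds(b, g)
  dx <- abs(a[, 1] - b[, 1]); dx <- pmin(dx, g$Lx - dx)
  dy <- abs(a[, 2] - b[, 2]); dy <- pmin(dy, g$Ly - dy)
  d <- sqrt(dx^2 + dy^2)
  if (length(d) == 1L) unname(d) else unname(d)
}

#' Midpoint of two points along the minimal-image segment
#'
#' The midpoint is taken on the shortest wrapped segment joining `a` and `b`
#' and mapped back into bounds, so that it is equidistant (half the torus
#' distance) from both endpoints. On an exact antipodal tie between the
#' wrapped and non-wrapped segment the non-wrapping segment is used, which
#' keeps the construction deterministic.
#'
#' @inheritParams torus_distance
#' @return numeric vector of length 2 in `[0, Lx) x [0, Ly)`.
#' @export
torus_midpoint <- function(a, b, g) {
  a <- drop(check_in_bounds(a, g)); b <- drop(check_in_bounds(b, g))
  mid1 <- function(x, y, L) {
    # shift y to its minimal image around x; ties (|y-x| == L/2) keep the
    # direct (non-wrapping) image
    delta <- y - x
    if (delta > L / 2) delta <- delta - L
    if (delta < -L / 2) delta <- delta + L
    (x + delta / 2) %% L
  }
  c(mid1(a[1], b[1], g$Lx), mid1(a[2], b[2], g$Ly))
}

#' Sample node positions uniformly on the torus
#'
#' @param N number of nodes, at least 1.
#' @param g a [torus_geometry()].
#' @param seed optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return an `N x 2` matrix of coordinates.
#' @export
place_nodes <- function(N, g, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    stop("N must be a positive integer", call. = FALSE)
  }
  with_seed(seed, {
    cbind(x = stats::runif(N, 0, g$Lx), y = stats::runif(N, 0, g$Ly))
  })
}

#' Pairwise minimal-image distance matrix
#'
#' @param points an `n x 2` coordinate matrix within bounds.
#' @param g a [torus_geometry()].
#' @return symmetric `n x n` matrix with zero diagonal.
#' @export
torus_distance_matrix <- function(points, g) {
  points <- check_in_bounds(points, g)
  torus_dist_matrix_cpp(points, g$Lx, g$Ly)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
# seed = NULL leaves the global stream alone (draws advance it as usual).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream splitting: derive a sub-seed for a named stage from a
# base seed, keeping results within 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}
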