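#' Synthetic template patterns for the three topological classes
#'
#' Generates an idealised point pattern of one class on the torus:
#' * `"C"` (cluster): one to a few Gaussian blobs, no wrapping structure —
#'   no persistent loop;
#' * `"S"` (stripe): one or two parallel bands of uniform points wrapping one
#'   torus direction — one persistent loop per band;
#' * `"O"` (octopus): either two crossing bands (one wrapping each
#'   direction) or a near-global active region with one or two macroscopic
#'   holes, optionally carrying a detached remnant fragment inside a hole.
#'   Every variant has at least two independent persistent loops; some have
#'   more than one macroscopic component.
#'
#' The geometric parameters are drawn per template (within the ranges in
#' `params`) so a library spans within-class variability; the ranges default
#' to the morphology the percolation dynamics itself produces at the default
#' model parameters: bands between roughly 0.15 and 0.55 of the short torus
#' side (the deterministic stripe attractor and its complement each cover a
#' large fraction of the domain). Templates are generated noise-free; query
#' clouds are density-denoised ([denoise_cloud()]) before matching, so the
#' stray giant-component nodes outside the main pattern do not enter the
#' comparison. An optional uniform background scatter is available through
#' `scatter_frac`.
#'
#' @param label one of `"C"`, `"O"`, `"S"`.
#' @param g a [torus_geometry()].
#' @param params optional overrides: `n_points` (cloud size, default 200),
#'   `cluster_points` (range of C cloud sizes, default `c(40, 200)`),
#'   `n_blobs` (max blobs for C, default 2; three or more blobs can close a spurious triangle loop), `blob_sd` (range, fraction of the
#'   short side, default `c(0.04, 0.10)`), `band_width` (range, fraction of
#'   the short side, default `c(0.15, 0.55)`), `p_double_stripe`
#'   (probability of a two-band stripe, default 0.3), `scatter_frac`
#'   (fraction of points placed uniformly as background scatter, default 0).
#' @param seed optional integer seed.
#' @return a point matrix on the torus.
#' @export
make_template <- function(label, g, params = list(), seed = NULL) {
  label <- match.arg(label, c("C", "O", "S"))
  p <- utils::modifyList(list(
    n_points = 200L,
    cluster_points = c(40L, 200L),
    n_blobs = 2L,
    blob_sd = c(0.04, 0.10),
    band_width = c(0.15, 0.55),
    p_double_stripe = 0.3,
    scatter_frac = 0
  ), params)
  Lmin <- min(g$Lx, g$Ly)
  with_seed(seed, {
    pts <- switch(label,
      C = template_cluster(g, p, Lmin),
      S = template_stripe(g, p, Lmin),
      O = template_octopus(g, p, Lmin))
    n_sc <- round(p$scatter_frac * nrow(pts))
    if (n_sc > 0) {
      repl <- sample(nrow(pts), n_sc)
      pts[repl, ] <- cbind(stats::runif(n_sc, 0, g$Lx), stats::runif(n_sc, 0, g$Ly))
    }
    colnames(pts) <- c("x", "y")
    pts
  })
}

template_cluster <- function(g, p, Lmin) {
  n <- sample(seq(p$cluster_points[1], p$cluster_points[2]), 1)
  k <- sample(seq_len(p$n_blobs), 1, prob = rev(seq_len(p$n_blobs)))
  centers <- cbind(stats::runif(k, 0, g$Lx), stats::runif(k, 0, g$Ly))
  which_blob <- sample(k, n, replace = TRUE)
  sd <- stats::runif(1, p$blob_sd[1], p$blob_sd[2]) * Lmin
  cbind((centers[which_blob, 1] + stats::rnorm(n, 0, sd)) %% g$Lx,
        (centers[which_blob, 2] + stats::rnorm(n, 0, sd)) %% g$Ly)
}

# a band wrapping the x-axis occupies all x and a y-interval of width w
band_points <- function(n, g, wrap_axis, center, width) {
  if (wrap_axis == "x") {
    cbind(stats::runif(n, 0, g$Lx), (center + stats::runif(n, -width / 2, width / 2)) %% g$Ly)
  } else {
    cbind((center + stats::runif(n, -width / 2, width / 2)) %% g$Lx, stats::runif(n, 0, g$Ly))
  }
}

template_stripe <- function(g, p, Lmin) {
  n <- p$n_points
  double <- stats::runif(1) < p$p_double_stripe
  axis <- sample(c("x", "y"), 1)
  Lperp <- if (axis == "x") g$Ly else g$Lx
  w <- stats::runif(1, p$band_width[1], p$band_width[2]) * Lmin
  if (!double) {
    return(band_points(n, g, axis, stats::runif(1, 0, Lperp), w))
  }
  # two parallel narrower bands, center separation at least 1.5 widths on
  # either side so the bands stay distinct
  w2 <- min(w, 0.2 * Lperp)
  c1 <- stats::runif(1, 0, Lperp)
  gap <- stats::runif(1, 1.5 * w2, Lperp - 1.5 * w2)
  rbind(band_points(ceiling(n / 2), g, axis, c1, w2 / 1.5),
        band_points(floor(n / 2), g, axis, (c1 + gap) %% Lperp, w2 / 1.5))
}

# Octopus patterns span the largest within-class variability: wide lanes
# crossing the domain in both directions, and near-global active regions with
# one or two macroscopic holes, possibly with a detached remnant fragment
# sitting inside a hole (more than one macroscopic component, at least one
# hole).
template_octopus <- function(g, p, Lmin) {
  n <- p$n_points
  if (stats::runif(1) < 0.5) {
    # two crossing bands, one wrapping each direction
    w1 <- stats::runif(1, p$band_width[1], p$band_width[2]) * Lmin
    w2 <- stats::runif(1, p$band_width[1], p$band_width[2]) * Lmin
    n1 <- ceiling(n * w1 / (w1 + w2))
    return(rbind(band_points(n1, g, "x", stats::runif(1, 0, g$Ly), w1),
                 band_points(n - n1, g, "y", stats::runif(1, 0, g$Lx), w2)))
  }
  # complement type: uniform activity minus 1-2 circular holes
  n_holes <- sample(1:2, 1)
  centers <- cbind(stats::runif(n_holes, 0, g$Lx), stats::runif(n_holes, 0, g$Ly))
  radii <- stats::runif(n_holes, 0.15, 0.25) * Lmin
  n_frag <- if (stats::runif(1) < 0.5) round(0.08 * n) else 0L
  cand <- cbind(stats::runif(4 * n, 0, g$Lx), stats::runif(4 * n, 0, g$Ly))
  for (h in seq_len(n_holes)) {
    d <- torus_distance(cand, matrix(centers[h, ], nrow(cand), 2, byrow = TRUE), g)
    cand <- cand[d > radii[h], , drop = FALSE]
  }
  pts <- cand[seq_len(min(n - n_frag, nrow(cand))), , drop = FALSE]
  if (n_frag > 0) {
    # remnant fragment inside the first hole: a detached component that
    # splits the hole into further loops
    frag <- cbind(centers[1, 1] + stats::rnorm(n_frag, 0, 0.03 * Lmin),
                  centers[1, 2] + stats::rnorm(n_frag, 0, 0.03 * Lmin))
    pts <- rbind(pts, cbind(frag[, 1] %% g$Lx, frag[, 2] %% g$Ly))
  }
  pts
}

#' Build a labelled library of template persistence diagrams
#'
#' Generates `n_per_class` template patterns per class (default 33), computes
#' the Vietoris-Rips diagram of each under the torus metric, and stores the
#' diagrams together with the analysis settings that queries must share
#' (filtration cap, persistence floor, subsample size).
#'
#' @param g a [torus_geometry()].
#' @param n_per_class templates per class (default 33).
#' @param params template generator overrides, see [make_template()].
#' @param cap filtration cap (default `min(Lx, Ly) / 4`: comfortably above
#'   the birth scale of the macroscopic loops, so wrapping stripes register as
#'   long-lived H1 classes truncated at the cap, while the Rips reduction
#'   stays affordable per step).
#' @param min_persistence persistence floor applied to template and query
#'   diagrams alike (default `0.5 * cap`). Subsampled clouds carry many short-
#'   and mid-lived classes (density fluctuations inside a pattern) whose count
#'   varies with pattern width and density; summing them in the Wasserstein
#'   matching swamps the macroscopic structure. Above the floor a diagram
#'   retains exactly the macroscopic signature of its class: widely separated
#'   components in H0 and dominant loops in H1 (none for clusters, one per
#'   stripe, two or more for octopus patterns).
#' @param max_points subsample size used for query clouds (stored so
#'   [classify_trajectory()] matches template cloud sizes; default 200).
#' @param seed integer seed; the library is reproducible given the seed.
#' @return object of class `template_library`.
#' @export
build_template_library <- function(g, n_per_class = 33, params = list(),
                                   cap = min(g$Lx, g$Ly) / 4,
                                   min_persistence = 0.5 * cap,
                                   max_points = 200, seed = NULL) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("C", "O", "S"), each = n_per_class)
  params <- utils::modifyList(list(n_points = as.integer(max_points)), params)
  entries <- lapply(seq_along(labels), function(k) {
    pts <- make_template(labels[k], g, params = params,
                         seed = derive_seed(seed, paste0("template", k)))
    pd <- rips_persistence(torus_distance_matrix(pts, g), cap = cap,
                           min_persistence = min_persistence)
    list(label = labels[k], diagram = pd, n_points = nrow(pts))
  })
  structure(list(entries = entries, labels = labels, geometry = g,
                 cap = cap, min_persistence = min_persistence,
                 max_points = max_points, params = params, seed = seed),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates (%s), cap = %.3g\n",
              length(x$entries),
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = ", "),
              x$cap))
  invisible(x)
}

#' Serialise / restore a template library as JSON
#'
#' @param lib a `template_library`.
#' @param path JSON file path.
#' @export
write_template_library <- function(lib, path) {
  obj <- list(
    labels = lib$labels,
    cap = lib$cap, min_persistence = lib$min_persistence,
    max_points = lib$max_points, seed = lib$seed,
    geometry = list(Lx = lib$geometry$Lx, Ly = lib$geometry$Ly),
    params = lib$params,
    diagrams = lapply(lib$entries, function(e) {
      list(label = e$label, n_points = e$n_points,
           H0 = unname(e$diagram$H0), H1 = unname(e$diagram$H1))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_template_library
#' @export
read_template_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- torus_geometry(obj$geometry$Lx, obj$geometry$Ly)
  as_mat <- function(m) {
    m <- if (is.null(m) || length(m) == 0) matrix(numeric(0), 0, 2) else rbind(m)
    m <- matrix(as.numeric(m), ncol = 2)
    colnames(m) <- c("birth", "death")
    m
  }
  entries <- lapply(seq_len(nrow(obj$diagrams)), function(k) {
    row <- obj$diagrams[k, ]
    pd <- structure(list(H0 = as_mat(row$H0[[1]]), H1 = as_mat(row$H1[[1]]),
                         cap = obj$cap), class = "persistence_diagram")
    list(label = row$label, diagram = pd, n_points = row$n_points)
  })
  structure(list(entries = entries, labels = obj$labels, geometry = g,
                 cap = obj$cap, min_persistence = obj$min_persistence,
                 max_points = obj$max_points, params = obj$params,
                 seed = obj$seed),
            class = "template_library")
}

#' Classify one persistence diagram against the template library
#'
#' The distance of the query to a class is the minimum Wasserstein distance
#' ([diagram_distance()]) to that class's templates; the label is the argmin
#' class, with deterministic tie-break C < O < S. An empty diagram (nothing
#' active) is labelled `"C"` by convention.
#'
#' @param diagram a `persistence_diagram` of the query pattern.
#' @param library a `template_library`.
#' @return list with `label` and `distances` (named numeric, one per class).
#' @export
classify_pattern <- function(diagram, library) {
  stopifnot(inherits(library, "template_library"))
  classes <- c("C", "O", "S")
  if (nrow(diagram$H0) == 0 && nrow(diagram$H1) == 0) {
    return(list(label = "C",
                distances = stats::setNames(rep(NA_real_, 3), classes)))
  }
  d_all <- vapply(library$entries,
                  function(e) diagram_distance(diagram, e$diagram), numeric(1))
  distances <- vapply(classes,
                      function(cl) min(d_all[library$labels == cl]), numeric(1))
  list(label = classes[which.min(distances)], distances = distances)
}

#' Classify every analysed step of a trajectory
#'
#' For each post-transient state (thinned by `stride`), builds the active
#' point cloud, removes low-density stragglers ([denoise_cloud()]), subsamples
#' to the library's `max_points`, computes the Vietoris-Rips diagram under the
#' torus metric with the library's cap and persistence floor, and assigns the
#' nearest-template class. States with fewer than `k_min` active nodes are
#' labelled `"C"` directly (near-empty patterns carry no macroscopic
#' topology). The subsample draw is keyed on the pattern content, so identical
#' states always receive identical labels (a periodic trajectory yields an
#' exactly periodic label series).
#'
#' @param traj a `triadic_trajectory`.
#' @param library a `template_library` built on the same geometry.
#' @param stride analyse every `stride`-th post-transient step (default 1).
#' @param k_min minimum active count for persistence computation (default 10).
#' @param denoise_k,denoise_factor outlier-removal parameters, see
#'   [denoise_cloud()]; `denoise_k = 0` disables denoising.
#' @param seed optional integer seed for the subsampling.
#' @return data.frame of class `pattern_labels` with columns `t` (0-based
#'   state index), `label`, `dist_C`, `dist_O`, `dist_S`.
#' @export
classify_trajectory <- function(traj, library, stride = 1, k_min = 10,
                                denoise_k = 3, denoise_factor = 3,
                                seed = NULL) {
  stopifnot(inherits(traj, "triadic_trajectory"),
            inherits(library, "template_library"), stride >= 1)
  g <- traj$net$geometry
  rows <- post_transient_steps(traj)
  rows <- rows[seq(1, length(rows), by = stride)]
  out <- data.frame(t = rows - 1L, label = NA_character_,
                    dist_C = NA_real_, dist_O = NA_real_, dist_S = NA_real_)
  for (k in seq_along(rows)) {
    s <- traj$node_states[rows[k], ]
    idx <- which(as.logical(s))
    if (length(idx) < k_min) {
      out$label[k] <- "C"
      next
    }
    pts <- traj$net$nodes[idx, , drop = FALSE]
    if (denoise_k > 0) pts <- denoise_cloud(pts, g, denoise_k, denoise_factor)
    if (nrow(pts) < k_min) {
      out$label[k] <- "C"
      next
    }
    if (nrow(pts) > library$max_points) {
      # key the subsample on the pattern content: identical states always
      # produce the same cloud, hence the same label
      key <- paste0("sub", length(idx), "_", sum(as.numeric(idx)) %% 1e7)
      pts <- with_seed(derive_seed(if (is.null(seed)) 0 else seed, key), {
        pts[sort(sample.int(nrow(pts), library$max_points)), , drop = FALSE]
      })
    }
    pd <- rips_persistence(torus_distance_matrix(pts, g), cap = library$cap,
                           min_persistence = library$min_persistence)
    cl <- classify_pattern(pd, library)
    out$label[k] <- cl$label
    out[k, c("dist_C", "dist_O", "dist_S")] <- cl$distances
  }
  class(out) <- c("pattern_labels", "data.frame")
  out
}
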