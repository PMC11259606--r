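#' Sample the spatial structural network (Waxman model)
#'
#' Every unordered node pair \eqn{(i, j)} is linked independently with
#' probability \eqn{P_{ij} = c\, e^{-d_{ij}/d_0}}, where \eqn{d_{ij}} is the
#' minimal-image distance. For \eqn{d_0} much larger than the domain the
#' kernel is flat and the graph reduces to Erdos-Renyi with edge probability
#' `c`.
#'
#' @param nodes `N x 2` coordinate matrix on the torus.
#' @param c overall connection scale, `0 < c <= 1`.
#' @param d0 typical structural link range (same units as the torus), positive.
#' @param g a [torus_geometry()].
#' @param seed optional integer seed for the edge draw.
#' @return list of class `structural_network` with fields `nodes`, `edges`
#'   (`E x 2` integer, 1-based, u < v), `midpoints` (`E x 2`, minimal-image
#'   link midpoints), `geometry`.
#' @export
sample_structural <- function(nodes, c, d0, g, seed = NULL) {
  nodes <- check_in_bounds(nodes, g)
  stopifnot(length(c) == 1L, c > 0, c <= 1, length(d0) == 1L, d0 > 0)
  edges <- with_seed(seed, sample_structural_cpp(nodes, c, d0, g$Lx, g$Ly))
  colnames(edges) <- c("u", "v")
  structure(list(
    nodes = nodes,
    edges = edges,
    midpoints = edge_midpoints(nodes, edges, g),
    geometry = g
  ), class = "structural_network")
}

edge_midpoints <- function(nodes, edges, g) {
  if (nrow(edges) == 0L) return(matrix(numeric(0), 0, 2))
  t(vapply(seq_len(nrow(edges)), function(k) {
    torus_midpoint(nodes[edges[k, 1], ], nodes[edges[k, 2], ], g)
  }, numeric(2)))
}

#' @export
print.structural_network <- function(x, ...) {
  cat(sprintf("<structural_network> %d nodes, %d edges on %.3g x %.3g torus\n",
              nrow(x$nodes), nrow(x$edges), x$geometry$Lx, x$geometry$Ly))
  invisible(x)
}

#' Sample the signed spatial regulatory network
#'
#' Each (node `i`, structural link `l`) pair receives at most one signed
#' regulatory interaction: positive with probability
#' \eqn{\hat P^+_{il} = c_+ e^{-d_{il}/d_{r+}}}, negative with probability
#' \eqn{\hat P^-_{il} = c_- e^{-d_{il}/d_{r-}}}, where \eqn{d_{il}} is the
#' torus distance from the node to the link midpoint. The two signs are
#' mutually exclusive by a single categorical draw (no conflicting
#' regulation), which requires `c_plus + c_minus <= 1`.
#'
#' @param net a `structural_network`.
#' @param c_plus,c_minus positive/negative regulation scales, nonnegative with
#'   sum at most 1.
#' @param dr_plus,dr_minus typical regulatory ranges, positive.
#' @param seed optional integer seed.
#' @return data.frame of class `regulatory_network` with columns `regulator`,
#'   `edge`, `sign` (+1/-1).
#' @export
sample_regulatory <- function(net, c_plus, c_minus, dr_plus, dr_minus = dr_plus,
                              seed = NULL) {
  stopifnot(inherits(net, "structural_network"))
  if (c_plus < 0 || c_minus < 0) stop("c_plus and c_minus must be nonnegative", call. = FALSE)
  if (c_plus + c_minus > 1) stop("c_plus + c_minus must not exceed 1", call. = FALSE)
  stopifnot(dr_plus > 0, dr_minus > 0)
  g <- net$geometry
  tri <- with_seed(seed, sample_regulatory_cpp(
    net$nodes, net$midpoints, c_plus, c_minus, dr_plus, dr_minus, g$Lx, g$Ly))
  out <- data.frame(regulator = tri[, 1], edge = tri[, 2], sign = tri[, 3])
  class(out) <- c("regulatory_network", "data.frame")
  out
}

#' Build a spatial higher-order network with triadic interactions
#'
#' Composes [place_nodes()], [sample_structural()] and [sample_regulatory()]
#' into one quenched network realisation. The torus side is derived from the
#' node count and density, `L = sqrt(N / rho)`; a rectangular domain can be
#' requested through `aspect` (`Ly = aspect * Lx` at fixed area).
#'
#' @param N number of nodes.
#' @param rho node density per unit square (default 100).
#' @param c structural connection scale (default 0.4).
#' @param c_plus,c_minus regulatory scales (defaults 0.2 and 0.2).
#' @param d0 structural range (default 0.25).
#' @param dr_plus,dr_minus regulatory ranges (defaults `d0`).
#' @param aspect ratio `Ly / Lx` at fixed total area `N / rho` (default 1).
#' @param seed integer seed for the quenched disorder (node placement and both
#'   samplers draw from one stream derived from it).
#' @return object of class `triadic_network`: fields `geometry`, `nodes`,
#'   `edges`, `midpoints`, `reg` (regulatory triples), `params`.
#' @examples
#' net <- build_network(N = 400, seed = 1)
#' net
#' @export
build_network <- function(N = 10000, rho = 100, c = 0.4,
                          c_plus = 0.2, c_minus = 0.2,
                          d0 = 0.25, dr_plus = d0, dr_minus = dr_plus,
                          aspect = 1, seed = NULL) {
  stopifnot(N >= 1, rho > 0, aspect > 0)
  area <- N / rho
  Lx <- sqrt(area / aspect)
  g <- torus_geometry(Lx, aspect * Lx)
  nodes <- place_nodes(N, g, seed = derive_seed(seed, "nodes"))
  sn <- sample_structural(nodes, c = c, d0 = d0, g = g,
                          seed = derive_seed(seed, "structural"))
  reg <- sample_regulatory(sn, c_plus = c_plus, c_minus = c_minus,
                           dr_plus = dr_plus, dr_minus = dr_minus,
                           seed = derive_seed(seed, "regulatory"))
  structure(list(
    geometry = g,
    nodes = nodes,
    edges = sn$edges,
    midpoints = sn$midpoints,
    reg = reg,
    params = list(N = N, rho = rho, c = c, c_plus = c_plus, c_minus = c_minus,
                  d0 = d0, dr_plus = dr_plus, dr_minus = dr_minus,
                  aspect = aspect, seed = seed)
  ), class = "triadic_network")
}

#' @export
print.triadic_network <- function(x, ...) {
  cat(sprintf(paste0(
    "<triadic_network> N = %d on %.3g x %.3g torus\n",
    "  structural edges: %d (c = %.3g, d0 = %.3g)\n",
    "  regulatory triples: %d positive, %d negative (c+ = %.3g, c- = %.3g)\n"),
    nrow(x$nodes), x$geometry$Lx, x$geometry$Ly,
    nrow(x$edges), x$params$c, x$params$d0,
    sum(x$reg$sign == 1), sum(x$reg$sign == -1),
    x$params$c_plus, x$params$c_minus))
  invisible(x)
}

#' Write / read a triadic network as plain-text tables
#'
#' Layout under `dir`: `nodes.tsv` (id, x, y), `edges.tsv` (u, v),
#' `regulatory.tsv` (regulator, edge_u, edge_v, sign) and `params.json`.
#'
#' @param net a `triadic_network`.
#' @param dir output directory (created if missing).
#' @return `write_network` returns `dir` invisibly; `read_network` returns the
#'   reconstructed `triadic_network`.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "triadic_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(id = seq_len(nrow(net$nodes)),
               x = net$nodes[, 1], y = net$nodes[, 2]),
    file.path(dir, "nodes.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    as.data.frame(net$edges),
    file.path(dir, "edges.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(regulator = net$reg$regulator,
               edge_u = net$edges[net$reg$edge, 1],
               edge_v = net$edges[net$reg$edge, 2],
               sign = net$reg$sign),
    file.path(dir, "regulatory.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  params <- net$params
  params$Lx <- net$geometry$Lx
  params$Ly <- net$geometry$Ly
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @param dir directory previously written by [write_network()].
#' @rdname write_network
#' @export
read_network <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  g <- torus_geometry(params$Lx, params$Ly)
  nodes <- as.matrix(utils::read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                                       sep = "\t"))[, c("x", "y"), drop = FALSE]
  colnames(nodes) <- c("x", "y")
  edges <- as.matrix(utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                                       sep = "\t"))
  storage.mode(edges) <- "integer"
  regtab <- utils::read.table(file.path(dir, "regulatory.tsv"), header = TRUE, sep = "\t")
  # recover edge indices from endpoint pairs
  key <- paste(edges[, 1], edges[, 2])
  eidx <- match(paste(regtab$edge_u, regtab$edge_v), key)
  if (anyNA(eidx)) stop("regulatory.tsv refers to unknown edges", call. = FALSE)
  reg <- data.frame(regulator = as.integer(regtab$regulator),
                    edge = as.integer(eidx), sign = as.integer(regtab$sign))
  class(reg) <- c("regulatory_network", "data.frame")
  structure(list(
    geometry = g, nodes = nodes, edges = edges,
    midpoints = edge_midpoints(nodes, edges, g),
    reg = reg,
    params = params[c("N", "rho", "c", "c_plus", "c_minus", "d0",
                      "dr_plus", "dr_minus", "aspect", "seed")]
  ), class = "triadic_network")
}
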