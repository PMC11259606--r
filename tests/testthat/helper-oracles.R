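# Independent brute-force oracles used to validate the compiled implementations.

# Full boundary-matrix reduction over GF(2), all dimensions at once, naive
# column algebra on small complexes. Returns capped H0/H1 diagrams like
# rips_persistence().
oracle_rips <- function(D, cap) {
  n <- nrow(D)
  filt <- rep(0, n)
  dim <- rep(0L, n)
  faces <- vector("list", n)  # boundary simplex ids (empty for vertices)
  id_of_edge <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] <= cap) {
        filt <- c(filt, D[i, j]); dim <- c(dim, 1L)
        faces <- c(faces, list(c(i, j)))
        id_of_edge[i, j] <- length(filt)
      }
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          dd <- c(D[i, j], D[i, k], D[j, k])
          if (all(dd <= cap)) {
            filt <- c(filt, max(dd)); dim <- c(dim, 2L)
            faces <- c(faces, list(c(id_of_edge[i, j], id_of_edge[i, k],
                                     id_of_edge[j, k])))
          }
        }
      }
    }
  }
  ord <- order(filt, dim, seq_along(filt))   # filtration-compatible order
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  cols <- lapply(seq_along(ord), function(q) sort(pos[faces[[ord[q]]]]))
  fq <- filt[ord]; dq <- dim[ord]

  pivot <- rep(NA_integer_, length(cols))  # row -> column that owns it
  reduced <- vector("list", length(cols))
  positive <- logical(length(cols))
  pairs <- list()
  for (q in seq_along(cols)) {
    col <- cols[[q]]
    repeat {
      if (length(col) == 0) { positive[q] <- TRUE; break }
      low <- max(col)
      if (is.na(pivot[low])) {
        pivot[low] <- q
        reduced[[q]] <- col
        pairs[[length(pairs) + 1]] <- c(low, q)
        break
      }
      other <- reduced[[pivot[low]]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
  }
  H0 <- matrix(numeric(0), 0, 2); H1 <- matrix(numeric(0), 0, 2)
  add <- function(m, b, d) rbind(m, c(b, d))
  paired_births <- integer(0)
  for (pr in pairs) {
    b <- pr[1]; dth <- pr[2]
    paired_births <- c(paired_births, b)
    if (fq[dth] > fq[b]) {
      if (dq[b] == 0) H0 <- add(H0, fq[b], fq[dth])
      if (dq[b] == 1) H1 <- add(H1, fq[b], fq[dth])
    }
  }
  for (q in seq_along(cols)) {
    if (positive[q] && !(q %in% paired_births)) {
      if (dq[q] == 0) H0 <- add(H0, 0, cap)
      if (dq[q] == 1) H1 <- add(H1, fq[q], cap)
    }
  }
  colnames(H0) <- colnames(H1) <- c("birth", "death")
  list(H0 = H0, H1 = H1)
}

# sort diagram rows for comparison
sort_diag <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]

# Brute-force order-1 Wasserstein with L-infinity ground metric by exhaustive
# enumeration of partial matchings (tiny diagrams only).
oracle_w1 <- function(A, B) {
  linf <- function(a, b) max(abs(a - b))
  diag_cost <- function(a) (a[2] - a[1]) / 2
  n <- nrow(A)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      rest <- sum(vapply(setdiff(seq_len(nrow(B)), used),
                         function(j) diag_cost(B[j, ]), numeric(1)))
      best <<- min(best, acc + rest)
      return()
    }
    rec(i + 1, used, acc + diag_cost(A[i, ]))  # send A_i to the diagonal
    for (j in setdiff(seq_len(nrow(B)), used)) {
      rec(i + 1, c(used, j), acc + linf(A[i, ], B[j, ]))
    }
  }
  rec(1, integer(0), 0)
  if (n == 0) best <- sum(apply(B, 1, diag_cost))
  best
}

# Plain-R reference of one dynamics iteration (Step 1 via component scan,
# Step 2 directly from the regulatory table). Draws runif() once per eligible
# link in edge order, matching the compiled path.
oracle_step <- function(net, link_active, p) {
  N <- nrow(net$nodes); E <- nrow(net$edges)
  # components of the active subgraph
  comp <- seq_len(N)
  repeat {
    changed <- FALSE
    for (l in which(link_active)) {
      u <- net$edges[l, 1]; v <- net$edges[l, 2]
      m <- min(comp[u], comp[v])
      if (comp[u] != m || comp[v] != m) {
        comp[comp == comp[u] | comp == comp[v]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  node_active <- rep(FALSE, N)
  if (max(sizes) >= 2) {
    biggest <- as.integer(names(sizes)[sizes == max(sizes)])
    # tie-break: smallest contained node index == smallest component label here
    target <- min(biggest)
    node_active <- comp == target
  }
  new_links <- rep(FALSE, E)
  for (l in seq_len(E)) {
    regs <- net$reg[net$reg$edge == l, ]
    neg_on <- any(node_active[regs$regulator[regs$sign == -1]])
    pos_on <- any(node_active[regs$regulator[regs$sign == 1]])
    if (neg_on || !pos_on) next
    if (p < 1 && stats::runif(1) >= p) next
    new_links[l] <- TRUE
  }
  list(node_active = node_active, link_active = new_links)
}

# small random triadic network for oracle comparisons
tiny_network <- function(n, seed) {
  g <- torus_geometry(2)
  set.seed(seed)
  nodes <- place_nodes(n, g)
  edges <- t(combn(n, 2))
  edges <- edges[runif(nrow(edges)) < 0.5, , drop = FALSE]
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("u", "v")
  E <- nrow(edges)
  reg <- data.frame(regulator = integer(0), edge = integer(0), sign = integer(0))
  if (E > 0) {
    for (l in seq_len(E)) {
      for (i in seq_len(n)) {
        u <- runif(1)
        if (u < 0.25) reg <- rbind(reg, data.frame(regulator = i, edge = l, sign = 1L))
        else if (u < 0.5) reg <- rbind(reg, data.frame(regulator = i, edge = l, sign = -1L))
      }
    }
  }
  structure(list(
    geometry = g, nodes = nodes, edges = edges,
    midpoints = if (E > 0) t(apply(edges, 1, function(e) {
      torus_midpoint(nodes[e[1], ], nodes[e[2], ], g)
    })) else matrix(numeric(0), 0, 2),
    reg = reg,
    params = list(N = n, rho = n / 4, c = 0.5, c_plus = 0.25, c_minus = 0.25,
                  d0 = 1, dr_plus = 1, dr_minus = 1, aspect = 1, seed = seed)
  ), class = "triadic_network")
}
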