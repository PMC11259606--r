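#' Pattern overlap at a time lag
#'
#' \eqn{O_\tau(t) = \sum_i s_i(t) s_i(t+\tau) / \sum_i s_i(t)}; the
#' complementary form replaces \eqn{s_i(t+\tau)} by \eqn{1 - s_i(t+\tau)} and
#' measures the match between the active pattern and the later inactive
#' pattern (large under blinking, where \eqn{s(t+1) \approx 1 - s(t)}).
#'
#' @param s_t,s_lag equal-length binary vectors (states at `t` and `t + tau`).
#' @param complementary use `1 - s_lag` (default `FALSE`).
#' @return value in `[0, 1]`, or `NA` when `s_t` has no active node.
#' @export
overlap <- function(s_t, s_lag, complementary = FALSE) {
  stopifnot(length(s_t) == length(s_lag))
  s_t <- as.numeric(as.logical(s_t)); s_lag <- as.numeric(as.logical(s_lag))
  denom <- sum(s_t)
  if (denom == 0) return(NA_real_)
  if (complementary) s_lag <- 1 - s_lag
  sum(s_t * s_lag) / denom
}

#' Overlap time series of a trajectory
#'
#' @param traj a `triadic_trajectory`.
#' @param tau lag in steps (default 1).
#' @param complementary see [overlap()].
#' @return data.frame with columns `t` (0-based) and `O` over the
#'   post-transient steps for which `t + tau` exists; `O` is `NA` where the
#'   pattern at `t` is empty.
#' @export
overlap_series <- function(traj, tau = 1, complementary = FALSE) {
  stopifnot(inherits(traj, "triadic_trajectory"), tau >= 1)
  rows <- post_transient_steps(traj)
  rows <- rows[rows + tau <= nrow(traj$node_states)]
  if (length(rows) == 0) stop("no post-transient step with t + tau available", call. = FALSE)
  O <- vapply(rows, function(r) {
    overlap(traj$node_states[r, ], traj$node_states[r + tau, ], complementary)
  }, numeric(1))
  data.frame(t = rows - 1L, O = O)
}

#' Binarise an overlap series with an adaptive threshold
#'
#' Two states are macroscopically equivalent when their overlap exceeds
#' \eqn{\alpha' = \alpha \cdot \overline{O_\tau}}, the baseline threshold
#' rescaled by the time-averaged overlap of the series. Undefined overlaps
#' (empty patterns) are excluded from the average and stay `NA`.
#'
#' @param O numeric overlap series (may contain `NA`).
#' @param alpha baseline threshold (default 0.8).
#' @return list with `binary` (0/1/NA vector, 1 iff `O > alpha_prime`),
#'   `alpha_prime`, and `n_excluded` (count of undefined steps). A series that
#'   is undefined on every step (dead dynamics) yields all-`NA` output.
#' @export
binarize_overlap <- function(O, alpha = 0.8) {
  stopifnot(alpha >= 0)
  if (all(is.na(O))) {
    # every pattern empty (dead dynamics): nothing to threshold
    return(list(binary = rep(NA_integer_, length(O)), alpha_prime = NA_real_,
                n_excluded = length(O)))
  }
  alpha_prime <- alpha * mean(O, na.rm = TRUE)
  list(binary = as.integer(O > alpha_prime), alpha_prime = alpha_prime,
       n_excluded = sum(is.na(O)))
}

#' Return probability at lag tau
#'
#' Fraction of analysed steps whose pattern recurs (binary overlap 1) after
#' `tau` steps: high under short-time blinking, low under diffusion.
#'
#' @param traj a `triadic_trajectory`.
#' @param tau lag in steps.
#' @param alpha baseline threshold for [binarize_overlap()].
#' @return value in `[0, 1]` (mean over defined steps).
#' @export
return_probability <- function(traj, tau, alpha = 0.8) {
  O <- overlap_series(traj, tau = tau)$O
  b <- binarize_overlap(O, alpha = alpha)$binary
  if (all(is.na(b))) return(NA_real_)
  mean(b, na.rm = TRUE)
}

#' Entropy rate of a categorical pattern series
#'
#' Block entropies of overlapping words: for each word length \eqn{\hat L},
#' \eqn{\hat H(\hat L) = -\frac{1}{\hat L} \sum_i \tilde p_i \log_2 \tilde p_i}
#' over the relative word frequencies. The entropy rate is the
#' \eqn{1/\hat L \to 0} intercept of the unweighted least-squares line of
#' \eqn{\hat H(\hat L)} against \eqn{1/\hat L} over `word_lengths`, floored at
#' zero.
#'
#' @param labels character (or factor) series, e.g. the `label` column of
#'   [classify_trajectory()] output, or a `pattern_labels` data.frame.
#' @param word_lengths word lengths used for the extrapolation (default
#'   `c(1, 2, 4)`).
#' @return entropy rate in bits per symbol, with the per-length block
#'   entropies attached as attribute `"blocks"`.
#' @examples
#' entropy_rate(rep("C", 100))                      # 0: constant series
#' entropy_rate(rep(c("S", "O"), 50))               # 0: strict alternation
#' @export
entropy_rate <- function(labels, word_lengths = c(1, 2, 4)) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  Lmax <- max(word_lengths)
  if (length(labels) < 2 * Lmax) {
    stop("series shorter than twice the maximum word length", call. = FALSE)
  }
  hl <- vapply(word_lengths, function(L) {
    words <- apply(stats::embed(labels, L), 1L, paste, collapse = "")
    p <- as.numeric(table(words)) / length(words)
    -sum(p * log2(p)) / L
  }, numeric(1))
  fit <- stats::lm(hl ~ I(1 / word_lengths))
  structure(max(0, unname(stats::coef(fit)[1])),
            blocks = stats::setNames(hl, word_lengths))
}

#' Circular barycenter of an activity pattern
#'
#' Per-axis circular mean: coordinates are mapped to angles
#' \eqn{2\pi x / L}, the unit vectors averaged, and the resultant angle mapped
#' back to `[0, L)`. This keeps the barycenter of a pattern straddling the
#' periodic seam inside the pattern, and makes it equivariant under torus
#' shifts.
#'
#' @param node_active logical/binary node-activity vector.
#' @param nodes `N x 2` coordinate matrix.
#' @param g a [torus_geometry()].
#' @return numeric `c(x, y)`, or `c(NA, NA)` for an empty pattern. A
#'   perfectly balanced pattern (zero resultant on an axis) is flagged through
#'   attribute `"degenerate"`.
#' @export
barycenter <- function(node_active, nodes, g) {
  act <- nodes[as.logical(node_active), , drop = FALSE]
  if (nrow(act) == 0) return(c(x = NA_real_, y = NA_real_))
  circ_mean <- function(x, L) {
    th <- 2 * pi * x / L
    v <- c(mean(cos(th)), mean(sin(th)))
    r <- sqrt(sum(v^2))
    ang <- atan2(v[2], v[1]) %% (2 * pi)
    list(mu = ang * L / (2 * pi), resultant = r)
  }
  cx <- circ_mean(act[, 1], g$Lx)
  cy <- circ_mean(act[, 2], g$Ly)
  structure(c(x = cx$mu, y = cy$mu),
            degenerate = c(x = cx$resultant < 1e-10, y = cy$resultant < 1e-10),
            resultant = c(x = cx$resultant, y = cy$resultant))
}

#' Detect exact periodicity of a deterministic trajectory
#'
#' Scans the post-transient node states for an exact recurrence of a full
#' state; once the same state occurs twice, the (deterministic, `p = 1`)
#' dynamics is periodic with the recurrence gap as period. Also applicable to
#' the stochastic case, where recurrence is not guaranteed.
#'
#' @param traj a `triadic_trajectory`.
#' @return smallest detected period (integer), or `NA` if no post-transient
#'   state recurs.
#' @export
blinking_period <- function(traj) {
  rows <- post_transient_steps(traj)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  N <- ncol(traj$node_states)
  pad <- rep(FALSE, (-N) %% 8)
  for (r in rows) {
    key <- paste(packBits(c(traj$node_states[r, ], pad), type = "raw"),
                 collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) return(as.integer(r - prev))
    seen[[key]] <- r
  }
  NA_integer_
}

#' Wrap axis of a pattern
#'
#' Determines along which torus direction a (stripe-like) pattern wraps: the
#' axis whose active coordinates have the larger circular variance
#' \eqn{1 - |\bar{e^{i\theta}}|} (a band wrapping the x axis is spread over
#' all x but confined in y).
#'
#' @inheritParams barycenter
#' @return `"x"` or `"y"` (ties go to `"x"`), or `NA` for an empty pattern.
#' @export
pattern_wrap_axis <- function(node_active, nodes, g) {
  act <- nodes[as.logical(node_active), , drop = FALSE]
  if (nrow(act) == 0) return(NA_character_)
  cv <- function(x, L) 1 - abs(mean(exp(2i * pi * x / L)))
  if (cv(act[, 1], g$Lx) >= cv(act[, 2], g$Ly)) "x" else "y"
}

#' Temporal summary of a trajectory
#'
#' Overlap series at the requested lags, adaptive binarisation, return
#' probabilities, and (when a label series is supplied) the entropy rate.
#'
#' @param traj a `triadic_trajectory`.
#' @param taus lags for the return probabilities (default `1:4`).
#' @param alpha baseline threshold (default 0.8).
#' @param labels optional `pattern_labels` (or character series) for the
#'   entropy rate.
#' @return list with `overlap` (data.frame `t`, `O1`, `O2`, `Obar1`),
#'   `return_prob` (named by tau), `entropy_rate` (or `NA`), `period`.
#' @export
temporal_summary <- function(traj, taus = 1:4, alpha = 0.8, labels = NULL) {
  o1 <- overlap_series(traj, 1)
  o2 <- overlap_series(traj, 2)
  ob <- overlap_series(traj, 1, complementary = TRUE)
  n <- min(nrow(o1), nrow(o2))
  ov <- data.frame(t = o1$t[seq_len(n)], O1 = o1$O[seq_len(n)],
                   O2 = o2$O[seq_len(n)], Obar1 = ob$O[seq_len(n)])
  pr <- vapply(taus, function(tau) return_probability(traj, tau, alpha), numeric(1))
  names(pr) <- paste0("tau", taus)
  list(overlap = ov,
       return_prob = pr,
       entropy_rate = if (is.null(labels)) NA_real_ else as.numeric(entropy_rate(labels)),
       period = blinking_period(traj))
}
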