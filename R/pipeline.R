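#' Experiment configuration
#'
#' Assembles and validates the full configuration of one experiment: network
#' parameters, dynamics parameters, analysis parameters, and one explicit seed
#' per randomised stage (network generation, dynamics, analysis/subsampling).
#' Configurations round-trip losslessly through JSON (and YAML when the
#' `yaml` package is available).
#'
#' @param N,rho,c,c_plus,c_minus,d0,dr_plus,dr_minus,aspect network parameters,
#'   see [build_network()].
#' @param p link retention probability (scalar) — for sweeps see
#'   [run_phase_diagram()]'s `p_grid`.
#' @param steps,transient dynamics length and discarded transient.
#' @param M,dx,dy density-grid size and embedding dimensions.
#' @param max_points,k_min persistence subsample size and minimum active count.
#' @param n_templates templates per class.
#' @param alpha overlap baseline threshold.
#' @param taus return-probability lags.
#' @param word_lengths entropy-rate word lengths.
#' @param stride classification stride.
#' @param template_params generator overrides for [make_template()].
#' @param seeds named list with integer elements `network`, `dynamics`,
#'   `analysis` (all required).
#' @return validated list of class `experiment_config`.
#' @export
experiment_config <- function(N = 2500, rho = 100, c = 0.4,
                              c_plus = 0.2, c_minus = 0.2,
                              d0 = 0.25, dr_plus = d0, dr_minus = dr_plus,
                              aspect = 1, p = 0.8,
                              steps = 1800, transient = 1500,
                              M = 30, dx = 2, dy = 2,
                              max_points = 200, k_min = 10,
                              n_templates = 33, alpha = 0.8,
                              taus = 1:4, word_lengths = c(1, 2, 4),
                              stride = 1, template_params = list(),
                              seeds = list()) {
  cfg <- list(N = N, rho = rho, c = c, c_plus = c_plus, c_minus = c_minus,
              d0 = d0, dr_plus = dr_plus, dr_minus = dr_minus, aspect = aspect,
              p = p, steps = steps, transient = transient,
              M = M, dx = dx, dy = dy, max_points = max_points, k_min = k_min,
              n_templates = n_templates, alpha = alpha, taus = taus,
              word_lengths = word_lengths, stride = stride,
              template_params = template_params, seeds = seeds)
  validate_config(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

validate_config <- function(cfg) {
  bad <- character(0)
  need_seed <- c("network", "dynamics", "analysis")
  missing_seeds <- need_seed[!vapply(need_seed, function(s) {
    !is.null(cfg$seeds[[s]]) && is.numeric(cfg$seeds[[s]])
  }, logical(1))]
  if (length(missing_seeds)) {
    bad <- c(bad, paste0("seeds$", missing_seeds))
  }
  if (!is.numeric(cfg$N) || cfg$N < 1) bad <- c(bad, "N")
  if (!is.numeric(cfg$p) || any(cfg$p < 0 | cfg$p > 1)) bad <- c(bad, "p")
  if (cfg$c <= 0 || cfg$c > 1) bad <- c(bad, "c")
  if (cfg$c_plus < 0 || cfg$c_minus < 0 ||
      cfg$c_plus + cfg$c_minus > 1) bad <- c(bad, "c_plus/c_minus")
  if (cfg$transient >= cfg$steps) bad <- c(bad, "transient")
  if (length(bad)) {
    stop("invalid experiment config, offending keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write an experiment configuration file
#'
#' JSON by default; files ending in `.yml`/`.yaml` use the `yaml` package.
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(experiment_config, raw)
}

#' @param cfg an `experiment_config`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# shared analysis path: classification + information + temporal measures
analyze_run <- function(traj, library, cfg) {
  labels <- classify_trajectory(traj, library, stride = cfg$stride,
                                k_min = cfg$k_min,
                                seed = derive_seed(cfg$seeds$analysis, "subsample"))
  info <- trajectory_info(traj, M = cfg$M, dx = cfg$dx, dy = cfg$dy)
  temporal <- temporal_summary(traj, taus = cfg$taus, alpha = cfg$alpha,
                               labels = labels)
  list(labels = labels, info = info, temporal = temporal)
}

#' Run one end-to-end experiment
#'
#' Generates the network, runs the dynamics, builds (or reuses) the template
#' library, classifies every analysed step, computes the information and
#' temporal measures, and writes all artifacts under `dir` with a manifest.
#'
#' @param cfg an [experiment_config()].
#' @param dir output directory.
#' @param library optional pre-built `template_library` (a new one is built
#'   from the analysis seed otherwise).
#' @return (invisibly) list with `net`, `traj`, `library`, `labels`, `info`,
#'   `temporal`, `dir`.
#' @export
run_experiment <- function(cfg, dir, library = NULL) {
  validate_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- build_network(N = cfg$N, rho = cfg$rho, c = cfg$c,
                       c_plus = cfg$c_plus, c_minus = cfg$c_minus,
                       d0 = cfg$d0, dr_plus = cfg$dr_plus, dr_minus = cfg$dr_minus,
                       aspect = cfg$aspect, seed = cfg$seeds$network)
  traj <- run_percolation(net, p = cfg$p, steps = cfg$steps,
                          transient = cfg$transient, seed = cfg$seeds$dynamics)
  if (is.null(library)) {
    library <- build_template_library(
      net$geometry, n_per_class = cfg$n_templates, params = cfg$template_params,
      max_points = cfg$max_points, seed = derive_seed(cfg$seeds$analysis, "templates"))
  }
  res <- analyze_run(traj, library, cfg)

  write_network(net, file.path(dir, "network"))
  write_trajectory(traj, dir)
  write_node_states(traj, file.path(dir, "states.bin"))
  utils::write.csv(res$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(res$info, file.path(dir, "info.csv"), row.names = FALSE)
  utils::write.csv(res$temporal$overlap, file.path(dir, "overlap.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(return_prob = as.list(res$temporal$return_prob),
         entropy_rate = res$temporal$entropy_rate,
         period = res$temporal$period),
    file.path(dir, "temporal.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  write_template_library(library, file.path(dir, "templates.json"))
  jsonlite::write_json(
    list(config = unclass(cfg), config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("triadicperc")),
         r_version = R.version.string),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(c(list(net = net, traj = traj, library = library, dir = dir), res))
}

#' Packed on-disk node-state matrix
#'
#' Stores the full binary node-state matrix bit-packed, next to a JSON header
#' (`<path>.json`) with the dimensions and run parameters.
#'
#' @param traj a `triadic_trajectory`.
#' @param path output file.
#' @export
write_node_states <- function(traj, path) {
  m <- traj$node_states
  bits <- as.logical(t(m))                   # row-major: one state at a time
  pad <- (-length(bits)) %% 8
  con <- file(path, "wb")
  writeBin(packBits(c(bits, rep(FALSE, pad)), type = "raw"), con)
  close(con)
  jsonlite::write_json(
    list(T = nrow(m) - 1L, N = ncol(m), p = traj$p, transient = traj$transient,
         dynamics_seed = traj$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_node_states
#' @export
read_node_states <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_bits <- (hdr$T + 1) * hdr$N
  raws <- readBin(path, "raw", n = ceiling(n_bits / 8))
  bits <- rawToBits(raws)[seq_len(n_bits)] == 1
  m <- matrix(bits, nrow = hdr$T + 1, ncol = hdr$N, byrow = TRUE)
  attr(m, "header") <- hdr
  m
}

#' Phase-diagram sweep over the control parameter p
#'
#' Runs the dynamics over a grid of `p` values with `replicates` independent
#' realisations (each replicate redraws the network and the dynamics seeds),
#' classifies the patterns, and aggregates the order parameter, information
#' measures, class fractions, entropy rate, and return probabilities per `p`.
#'
#' @param cfg an [experiment_config()]; its `p` entry is ignored in favour of
#'   `p_grid`.
#' @param p_grid vector of `p` values, at least 2 (default
#'   `seq(0.1, 1, by = 0.1)`).
#' @param replicates independent realisations per `p` (default 1).
#' @param library optional shared `template_library`.
#' @param verbose print progress to stderr.
#' @return object of class `phase_diagram`: `table` (one row per `p`:
#'   `R_mean`, `R_sd`, `H_mean`, `C_mean`, `P_C`, `P_O`, `P_S`,
#'   `entropy_rate`, `entropy_rate_sd`, `Pr_tau*`) and `detail` (per
#'   replicate x p).
#' @export
run_phase_diagram <- function(cfg, p_grid = seq(0.1, 1, by = 0.1),
                              replicates = 1, library = NULL, verbose = FALSE) {
  validate_config(cfg)
  stopifnot(length(p_grid) >= 2)
  nets <- lapply(seq_len(replicates), function(r) {
    build_network(N = cfg$N, rho = cfg$rho, c = cfg$c,
                  c_plus = cfg$c_plus, c_minus = cfg$c_minus,
                  d0 = cfg$d0, dr_plus = cfg$dr_plus, dr_minus = cfg$dr_minus,
                  aspect = cfg$aspect,
                  seed = derive_seed(cfg$seeds$network, paste0("rep", r)))
  })
  if (is.null(library)) {
    library <- build_template_library(
      nets[[1]]$geometry, n_per_class = cfg$n_templates,
      params = cfg$template_params, max_points = cfg$max_points,
      seed = derive_seed(cfg$seeds$analysis, "templates"))
  }
  detail <- list()
  for (r in seq_len(replicates)) {
    for (p in p_grid) {
      if (verbose) message(sprintf("replicate %d, p = %.2f", r, p))
      traj <- run_percolation(nets[[r]], p = p, steps = cfg$steps,
                              transient = cfg$transient,
                              seed = derive_seed(cfg$seeds$dynamics,
                                                 sprintf("rep%d_p%.4f", r, p)))
      res <- analyze_run(traj, library, cfg)
      frac <- prop.table(table(factor(res$labels$label, levels = c("C", "O", "S"))))
      detail[[length(detail) + 1L]] <- list(
        replicate = r, p = p,
        R_mean = mean(traj$R_series[post_transient_steps(traj)]),
        H_mean = mean(res$info$H), C_mean = mean(res$info$C),
        P_C = unname(frac["C"]), P_O = unname(frac["O"]), P_S = unname(frac["S"]),
        entropy_rate = res$temporal$entropy_rate,
        return_prob = res$temporal$return_prob,
        labels = res$labels, traj_R = traj$R_series)
    }
  }
  agg <- do.call(rbind, lapply(p_grid, function(p) {
    d <- Filter(function(x) x$p == p, detail)
    num <- function(f) vapply(d, f, numeric(1))
    pr <- do.call(rbind, lapply(d, function(x) x$return_prob))
    row <- data.frame(
      p = p,
      R_mean = mean(num(function(x) x$R_mean)), R_sd = stats::sd(num(function(x) x$R_mean)),
      H_mean = mean(num(function(x) x$H_mean)), C_mean = mean(num(function(x) x$C_mean)),
      P_C = mean(num(function(x) x$P_C)), P_O = mean(num(function(x) x$P_O)),
      P_S = mean(num(function(x) x$P_S)),
      entropy_rate = mean(num(function(x) x$entropy_rate)),
      entropy_rate_sd = stats::sd(num(function(x) x$entropy_rate)))
    # replicates whose dynamics died have undefined return probabilities
    for (cn in colnames(pr)) row[[paste0("Pr_", cn)]] <- mean(pr[, cn], na.rm = TRUE)
    row
  }))
  structure(list(table = agg, detail = detail, p_grid = p_grid,
                 replicates = replicates, config = cfg),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d p values x %d replicate(s)\n",
              length(x$p_grid), x$replicates))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Stripe orientation on a rectangular torus
#'
#' Runs the deterministic dynamics (`p = 1` by default) on a rectangular
#' torus, classifies the patterns, and reports along which axis the
#' stripe-labelled patterns wrap (by circular variance of the active
#' coordinates). Surface minimisation predicts stripes along the shorter
#' dimension.
#'
#' @param cfg an [experiment_config()] with `aspect != 1`.
#' @param p link retention probability (default 1).
#' @param library optional `template_library` on the same geometry.
#' @return list with `n_stripe_steps`, `frac_x`, `frac_y`, `shorter_axis`,
#'   and the per-step table `steps`.
#' @export
stripe_orientation_check <- function(cfg, p = 1, library = NULL) {
  validate_config(cfg)
  if (cfg$aspect == 1) {
    warning("square torus: both orientations are admissible")
  }
  net <- build_network(N = cfg$N, rho = cfg$rho, c = cfg$c,
                       c_plus = cfg$c_plus, c_minus = cfg$c_minus,
                       d0 = cfg$d0, dr_plus = cfg$dr_plus, dr_minus = cfg$dr_minus,
                       aspect = cfg$aspect, seed = cfg$seeds$network)
  traj <- run_percolation(net, p = p, steps = cfg$steps,
                          transient = cfg$transient, seed = cfg$seeds$dynamics)
  if (is.null(library)) {
    library <- build_template_library(
      net$geometry, n_per_class = cfg$n_templates, params = cfg$template_params,
      max_points = cfg$max_points,
      seed = derive_seed(cfg$seeds$analysis, "templates"))
  }
  labels <- classify_trajectory(traj, library, stride = cfg$stride,
                                k_min = cfg$k_min,
                                seed = derive_seed(cfg$seeds$analysis, "subsample"))
  stripe_rows <- labels$t[labels$label == "S"] + 1L
  if (length(stripe_rows) == 0) {
    return(list(n_stripe_steps = 0L, frac_x = NA_real_, frac_y = NA_real_,
                shorter_axis = if (net$geometry$Lx <= net$geometry$Ly) "x" else "y",
                steps = data.frame(t = integer(0), axis = character(0))))
  }
  axes <- vapply(stripe_rows, function(r) {
    pattern_wrap_axis(traj$node_states[r, ], net$nodes, net$geometry)
  }, character(1))
  list(n_stripe_steps = length(stripe_rows),
       frac_x = mean(axes == "x"), frac_y = mean(axes == "y"),
       shorter_axis = if (net$geometry$Lx <= net$geometry$Ly) "x" else "y",
       steps = data.frame(t = stripe_rows - 1L, axis = axes))
}
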