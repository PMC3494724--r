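# Ensembles of independent realizations: grid means, Monte-Carlo standard
# errors, percentage residuals between engines, and the time-per-update
# metric.

#' Run an ensemble of independent realizations
#'
#' Simulates `realizations` independent trajectories (trajectory `i` uses
#' RNG stream `stream_offset + i - 1` of `seed`, so results are independent
#' of batching and execution order), averages the grid-interpolated counts,
#' and reports per-grid-point means and Monte-Carlo standard errors.
#'
#' @inheritParams run_trajectory
#' @param realizations Number of realizations `l` (>= 1).
#' @param stream_offset First RNG stream index.
#' @param batch Run inside the compiled batch loop (default). With
#'   `batch = FALSE` trajectories are run one by one through
#'   [run_trajectory()] and accumulated in the same order; the two paths
#'   give identical results.
#' @return Object of class `ensemble_summary`: `time`, `mean` and `se`
#'   (grid-by-species matrices), `realizations`, `mean_steps` (the average
#'   number of updates `m` per realization), `elapsed` (seconds), `method`.
#' @export
run_ensemble <- function(network, t_final, realizations, record_dt = 0.01,
                         seed = 1L, stream_offset = 0L,
                         method = c("blocked", "odm", "direct"),
                         record_species = NULL, partition = NULL,
                         refresh_interval = 1e4, max_steps = Inf,
                         batch = TRUE, dense_update_threshold = 32L,
                         interpolation = c("linear", "hold")) {
  method <- match.arg(method)
  interpolation <- match.arg(interpolation)
  stopifnot(realizations >= 1)
  M <- n_reactions(network)
  if (is.null(partition)) partition <- block_partition(M)
  rec <- resolve_record_species(network, record_species)
  t0 <- proc.time()[["elapsed"]]
  if (batch) {
    model <- as_engine_model(network)
    graph <- if (method == "direct") empty_engine_graph(M)
             else as_engine_graph(build_dependency_graph(network, partition))
    res <- cpp_run_ensemble(model, graph, partition, method, t_final,
                            record_dt, as.integer(realizations),
                            as.integer(seed), as.integer(stream_offset),
                            rec - 1L, refresh_interval, min(max_steps, 1e15),
                            as.integer(dense_update_threshold),
                            match(interpolation, c("linear", "hold")) - 1L)
    sum_x <- res$sum
    sum_x2 <- res$sumsq
    total_steps <- res$total_steps
  } else {
    sum_x <- NULL
    total_steps <- 0
    for (i in seq_len(realizations)) {
      tr <- run_trajectory(network, t_final, record_dt, seed = seed,
                           stream = stream_offset + i - 1L, method = method,
                           record_species = rec, partition = partition,
                           refresh_interval = refresh_interval,
                           max_steps = max_steps,
                           dense_update_threshold = dense_update_threshold,
                           interpolation = interpolation)
      if (is.null(sum_x)) {
        sum_x <- tr$counts * 0
        sum_x2 <- sum_x
      }
      sum_x <- sum_x + tr$counts
      sum_x2 <- sum_x2 + tr$counts^2
      total_steps <- total_steps + tr$n_steps
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  l <- realizations
  mean_x <- sum_x / l
  if (l > 1) {
    var_x <- (sum_x2 - l * mean_x^2) / (l - 1)
    var_x[var_x < 0] <- 0 # guard tiny negative rounding
    se <- sqrt(var_x / l)
  } else {
    se <- sum_x * NA_real_
  }
  grid <- seq(0, by = record_dt, length.out = nrow(mean_x))
  colnames(mean_x) <- network$species$name[rec]
  colnames(se) <- network$species$name[rec]
  structure(list(time = grid, mean = mean_x, se = se, realizations = l,
                 mean_steps = total_steps / l, total_steps = total_steps,
                 elapsed = elapsed, method = method, seed = seed,
                 stream_offset = stream_offset),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %s: l = %d realizations, m = %.0f mean updates, %d grid points x %d species (%.2fs)\n",
              x$method, x$realizations, x$mean_steps, length(x$time),
              ncol(x$mean), x$elapsed))
  invisible(x)
}

#' Percentage residuals between two ensemble summaries
#'
#' `residual(t, s) = 100 * |mean_a - mean_b| / mean_b`, evaluated at every
#' grid point and recorded species where the reference mean `mean_b` is at
#' least `floor` molecules (points below the floor are excluded and
#' counted, since a percentage of a near-zero mean is not informative).
#'
#' @param summary_a,summary_b Two [run_ensemble()] summaries over the same
#'   grid and species; `summary_b` is the reference (denominator).
#' @param floor Minimum reference mean (default 0.5 molecules).
#' @return Object of class `residual_report`: `residual` matrix (NA below
#'   the floor), `max`, `mean`, `n_excluded`, `floor`.
#' @export
percentage_residuals <- function(summary_a, summary_b, floor = 0.5) {
  if (length(summary_a$time) != length(summary_b$time) ||
      max(abs(summary_a$time - summary_b$time)) > 1e-12)
    stop("comparison error: summaries are on different grids")
  if (!identical(colnames(summary_a$mean), colnames(summary_b$mean)))
    stop("comparison error: summaries record different species")
  ref <- summary_b$mean
  resid <- 100 * abs(summary_a$mean - ref) / ref
  resid[ref < floor] <- NA_real_
  defined <- !is.na(resid)
  structure(list(residual = resid,
                 max = if (any(defined)) max(resid[defined]) else NA_real_,
                 mean = if (any(defined)) mean(resid[defined]) else NA_real_,
                 n_excluded = sum(!defined), floor = floor),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> max %.3f%%, mean %.3f%% (%d points below the %.2f-molecule floor excluded)\n",
              x$max, x$mean, x$n_excluded, x$floor))
  invisible(x)
}

#' Time per update
#'
#' `T_up = T_t / (l * m)`: total computation time divided by the number of
#' realizations times the average number of updates per realization. A
#' hardware-dependent throughput metric -- reported, never asserted against
#' reference values.
#'
#' @param total_time Total computation time `T_t` (seconds).
#' @param l Number of realizations.
#' @param m Average updates per realization.
#' @return Seconds per update.
#' @export
time_per_update <- function(total_time, l, m) {
  if (l <= 0 || m <= 0) stop("metric error: l and m must be positive")
  total_time / (l * m)
}

#' Engine-versus-engine accuracy benchmark
#'
#' The package's standard accuracy protocol: generate a random consistent
#' network, run independent ensembles with the blocked engine and with the
#' reference ODM (disjoint RNG streams, so the two ensembles are
#' statistically independent), interpolate every trajectory onto the
#' recording grid, average, and report the percentage residuals between the
#' two ensemble means over all recorded species and grid points.
#'
#' Defaults are the desk-scale protocol: a 256-reaction, 256-species
#' network with per-reaction dependent counts in 8--16, all rate constants
#' 1, 50 molecules of each species initially, simulated to `t_final = 0.05`
#' (about 3e4 updates per realization) on a 0.01-spaced grid with 2000
#' realizations per engine.
#'
#' @param seed Base seed; the network, both ensembles and their streams
#'   all derive from it.
#' @param realizations Realizations per engine.
#' @param N,M Network size.
#' @param dependency_range Per-reaction dependent-count band.
#' @param initial_count Initial molecules per species.
#' @param t_final,record_dt Simulation horizon and grid spacing.
#' @param floor Residual denominator floor (molecules).
#' @return List with `residuals` (a [percentage_residuals()] report),
#'   `blocked` and `odm` (the two `ensemble_summary` objects), and
#'   `network`.
#' @export
accuracy_benchmark <- function(seed = 1L, realizations = 2000L, N = 256L,
                               M = 256L, dependency_range = c(8L, 16L),
                               initial_count = 50L, t_final = 0.05,
                               record_dt = 0.01, floor = 0.5) {
  net <- random_network(N, M, dependency_range = dependency_range,
                        initial_count = initial_count, seed = seed)
  s_blocked <- run_ensemble(net, t_final, realizations, record_dt,
                            seed = seed, stream_offset = 0L,
                            method = "blocked")
  s_odm <- run_ensemble(net, t_final, realizations, record_dt,
                        seed = seed, stream_offset = realizations,
                        method = "odm")
  list(residuals = percentage_residuals(s_blocked, s_odm, floor = floor),
       blocked = s_blocked, odm = s_odm, network = net)
}

#' Time-per-update and residual convergence versus ensemble size
#'
#' @param network An `ssa_network`.
#' @param t_final,record_dt Simulation grid.
#' @param l_values Ascending realization counts.
#' @param method Engine to run.
#' @param seed Base seed.
#' @param reference Optional reference `ensemble_summary` (or a function of
#'   the grid returning reference means) for residual tracking.
#' @param ... Passed to [run_ensemble()].
#' @return `data.frame` with one row per `l`: `l`, `total_time`,
#'   `mean_steps`, `t_up`, `max_residual`.
#' @export
convergence_curve <- function(network, t_final, l_values, record_dt = 0.01,
                              method = "blocked", seed = 1L,
                              reference = NULL, ...) {
  stopifnot(length(l_values) >= 1, !is.unsorted(l_values))
  rows <- lapply(seq_along(l_values), function(q) {
    l <- l_values[q]
    s <- run_ensemble(network, t_final, realizations = l,
                      record_dt = record_dt, seed = seed, method = method,
                      ...)
    resid <- NA_real_
    if (!is.null(reference)) {
      ref_mean <- if (is.function(reference)) reference(s$time)
                  else reference$mean
      r <- 100 * abs(s$mean - ref_mean) / pmax(ref_mean, 0.5)
      resid <- max(r)
    }
    data.frame(l = l, total_time = s$elapsed, mean_steps = s$mean_steps,
               t_up = time_per_update(max(s$elapsed, .Machine$double.eps),
                                      l, max(s$mean_steps, 1)),
               max_residual = resid)
  })
  do.call(rbind, rows)
}

#' Selection and update work versus block count
#'
#' Runs the blocked engine with different block counts `p` on the same
#' model and RNG stream and reports the measured work per firing: the
#' number of array elements touched during the three-level selection and
#' during the block-sum update. Selection work falls and update work grows
#' with `p` -- the block-count trade-off.
#'
#' @param network An `ssa_network`.
#' @param p_values Block counts to sweep.
#' @param n_steps Firings per run (default 2000).
#' @param seed,stream RNG stream (shared across the sweep).
#' @return `data.frame` with `p`, `block_size`, `steps`,
#'   `selection_per_step`, `update_per_step`.
#' @export
block_sweep <- function(network, p_values, n_steps = 2000, seed = 1L,
                        stream = 0L) {
  M <- n_reactions(network)
  rows <- lapply(p_values, function(p) {
    part <- block_partition(M, num_blocks = p)
    tr <- run_trajectory(network, t_final = 1e9, record_dt = 1e9,
                         seed = seed, stream = stream, method = "blocked",
                         record_species = 1L, partition = part,
                         max_steps = n_steps)
    data.frame(p = part$num_blocks, block_size = part$block_size,
               steps = tr$n_steps,
               selection_per_step = tr$sel_touch / max(tr$n_steps, 1),
               update_per_step = tr$upd_touch / max(tr$n_steps, 1))
  })
  do.call(rbind, rows)
}
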