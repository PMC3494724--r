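# Single-trajectory driver: selection, state update, time advance,
# grid recording, termination.

#' Seedable uniform random stream
#'
#' A deterministic stream of uniforms on `(0, 1]` backed by a counter-based
#' PCG32 generator; the stream is fully determined by `(seed, stream)` and
#' independent of how draws are batched. The simulation contract consumes
#' exactly two uniforms per step, `z1` (reaction selection) then `z2`
#' (waiting time).
#'
#' @param seed Integer seed.
#' @param stream Integer stream (one per trajectory).
#' @return A function `draw(n)` returning the next `n` uniforms.
#' @export
rng_stream <- function(seed, stream = 0L) {
  pos <- 0L
  buf <- numeric(0)
  bufsize <- 4096L
  function(n = 1L) {
    while (length(buf) < n) {
      more <- cpp_rng_uniforms(seed, stream, bufsize, skip = pos + length(buf))
      buf <<- c(buf, more)
    }
    out <- buf[seq_len(n)]
    buf <<- buf[-seq_len(n)]
    pos <<- pos + n
    out
  }
}

#' Exponential waiting time of the next reaction
#'
#' `dt = ln(1 / z2) / a_R`: exponentially distributed with rate `a_R` when
#' `z2` is uniform on `(0, 1]`.
#'
#' @param a_R Total propensity (must be positive).
#' @param z2 Uniform random number in `(0, 1]`.
#' @return The time increment.
#' @export
time_advance <- function(a_R, z2) {
  if (a_R <= 0) stop("time_advance requires a_R > 0")
  if (z2 <= 0 || z2 > 1) stop("z2 must lie in (0, 1]")
  log(1 / z2) / a_R
}

#' Advance a blocked state by one exact-SSA step
#'
#' Composes the hierarchical selection, the time advance, the
#' stoichiometric population update, and the incremental propensity /
#' block-sum update, in that order.
#'
#' @param state A [blocked_state()].
#' @param graph The network's [build_dependency_graph()] under the state's
#'   partition.
#' @param rng A [rng_stream()], or `NULL` when `z` is supplied.
#' @param z Optionally an explicit pair `c(z1, z2)` of uniforms.
#' @return List with `state` (updated), `fired` (reaction index, or
#'   `NA_integer_` if the total propensity is zero and the trajectory has
#'   terminated), and `dt`.
#' @export
ssa_step <- function(state, graph, rng = NULL, z = NULL) {
  if (state$block_sums$a_R <= 0)
    return(list(state = state, fired = NA_integer_, dt = NA_real_))
  if (is.null(z)) z <- rng(2L)
  f <- hierarchical_select(state, z[1])
  dt <- time_advance(state$block_sums$a_R, z[2])
  stoich <- pack_stoichiometry_cached(state$network)
  state$counts <- apply_stoichiometry(state$counts, f, stoich)
  state <- update_after_firing(state, f, graph)
  state$t_sim <- state$t_sim + dt
  state$n_steps <- state$n_steps + 1L
  list(state = state, fired = f, dt = dt)
}

# Cache the packed table on the network object to avoid re-packing per step.
pack_stoichiometry_cached <- function(network) {
  env <- attr(network, ".stoich_cache")
  if (is.null(env)) return(pack_stoichiometry(network))
  env$tab
}

#' Run one exact-SSA trajectory
#'
#' Simulates a single realization until the final time (or until no
#' reaction can fire), recording the configured species on a uniform time
#' grid by linear interpolation between the event states bracketing each
#' grid time. When the total propensity reaches zero before the final time,
#' the terminal state is held constant on the remaining grid.
#'
#' @param network An `ssa_network`.
#' @param t_final Final simulation time.
#' @param record_dt Recording grid spacing (default 0.01 time units).
#' @param seed,stream Integers selecting the RNG stream.
#' @param method One of `"blocked"`, `"odm"`, `"direct"`.
#' @param record_species Indices or names of species to record (default:
#'   all).
#' @param partition Optional [block_partition()].
#' @param refresh_interval Recompute the cumulative block sums from scratch
#'   every this many firings (floating-point drift control; default 1e4).
#' @param max_steps Safety cap on the number of firings.
#' @param max_events Number of leading `(reaction, dt)` events to return
#'   (default 0; used for method-equivalence checks).
#' @param dense_update_threshold Mean dependents per block above which the
#'   dense (lane-group per block) update scheduling path is labelled; the
#'   sparse and dense paths produce bitwise-identical results.
#' @param interpolation Grid recording semantics: `"linear"` (default)
#'   interpolates linearly between the event states bracketing each grid
#'   time; `"hold"` records the piecewise-constant pre-event state. Linear
#'   interpolation of a jump process underestimates the mean by about half
#'   the typical jump (inspection-paradox bias), which cancels when two
#'   engines are compared but matters against closed-form state means.
#' @return Object of class `ssa_trajectory`: list with `time`, `counts`
#'   (grid-by-species matrix), `n_steps`, `method`, and when requested
#'   `events` (data.frame of `reaction`, `dt`).
#' @export
run_trajectory <- function(network, t_final, record_dt = 0.01, seed = 1L,
                           stream = 0L,
                           method = c("blocked", "odm", "direct"),
                           record_species = NULL, partition = NULL,
                           refresh_interval = 1e4, max_steps = Inf,
                           max_events = 0L, dense_update_threshold = 32L,
                           interpolation = c("linear", "hold")) {
  method <- match.arg(method)
  interpolation <- match.arg(interpolation)
  if (t_final < 0) stop("parameter error: t_final must be non-negative")
  M <- n_reactions(network)
  if (is.null(partition)) partition <- block_partition(M)
  rec <- resolve_record_species(network, record_species)
  model <- as_engine_model(network)
  graph <- if (method == "direct") empty_engine_graph(M)
           else as_engine_graph(build_dependency_graph(network, partition))
  res <- cpp_run_trajectory(model, graph, partition, method, t_final,
                            record_dt, as.integer(seed), as.integer(stream),
                            rec - 1L, refresh_interval,
                            min(max_steps, 1e15), as.integer(max_events),
                            as.integer(dense_update_threshold),
                            match(interpolation, c("linear", "hold")) - 1L)
  grid <- seq(0, by = record_dt, length.out = nrow(res$counts))
  counts <- res$counts
  colnames(counts) <- network$species$name[rec]
  out <- list(time = grid, counts = counts, n_steps = res$n_steps,
              t_end = res$t_end, method = method, seed = seed,
              stream = stream, n_refresh = res$n_refresh,
              final_counts = res$final_counts,
              final_propensities = res$final_propensities,
              final_block_cumsum = res$final_block_cumsum,
              a_R = res$a_R, update_path = res$update_path,
              sel_touch = res$sel_touch, upd_touch = res$upd_touch)
  if (max_events > 0L)
    out$events <- data.frame(reaction = res$event_index + 1L,
                             dt = res$event_dt)
  structure(out, class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("<ssa_trajectory> method %s: %g firings to t = %.4g, %d grid points x %d species\n",
              x$method, x$n_steps, x$t_end, length(x$time), ncol(x$counts)))
  invisible(x)
}

resolve_record_species <- function(network, record_species) {
  if (is.null(record_species)) return(seq_len(n_species(network)))
  if (is.character(record_species)) {
    idx <- match(record_species, network$species$name)
    if (anyNA(idx))
      stop("unknown species: ",
           paste(record_species[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(record_species)
}

# Pure-R trajectory runner over the blocked state machinery; used to
# cross-check the compiled engine event by event at small step counts.
run_trajectory_r <- function(network, n_steps, seed = 1L, stream = 0L,
                             partition = NULL) {
  if (is.null(partition)) partition <- block_partition(n_reactions(network))
  cache <- new.env()
  cache$tab <- pack_stoichiometry(network)
  attr(network, ".stoich_cache") <- cache
  graph <- build_dependency_graph(network, partition)
  state <- blocked_state(network, partition)
  rng <- rng_stream(seed, stream)
  fired <- integer(0)
  dts <- numeric(0)
  for (i in seq_len(n_steps)) {
    st <- ssa_step(state, graph, rng)
    if (is.na(st$fired)) break
    state <- st$state
    fired <- c(fired, st$fired)
    dts <- c(dts, st$dt)
  }
  list(events = data.frame(reaction = fired, dt = dts), state = state)
}
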