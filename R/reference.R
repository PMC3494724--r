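# Serial reference engines: Direct Method (full recompute + linear scan)
# and Optimized Direct Method (dependency-graph incremental updates +
# linear scan), plus the access-frequency pre-simulation reordering.

#' One Direct Method step
#'
#' Recomputes every propensity from the counts, selects the next reaction
#' by a linear cumulative-sum scan (smallest index whose prefix sum reaches
#' `z1 * a_R`), applies the stoichiometry and returns the waiting time.
#'
#' @param network An `ssa_network`.
#' @param counts Current species counts.
#' @param z1,z2 Uniforms in `(0, 1]`.
#' @return List with `fired` (`NA_integer_` on termination), `dt`, `counts`
#'   (updated), and `a_R`.
#' @export
direct_method_step <- function(network, counts, z1, z2) {
  a <- propensities(network, counts)
  aR <- 0
  for (x in a) aR <- aR + x
  if (aR <= 0)
    return(list(fired = NA_integer_, dt = NA_real_, counts = counts,
                a_R = 0))
  target <- z1 * aR
  f <- linear_select(a, target)
  dt <- time_advance(aR, z2)
  counts <- apply_stoichiometry(counts, f, pack_stoichiometry(network))
  list(fired = f, dt = dt, counts = counts, a_R = aR)
}

# Linear cumulative-sum selection (the Direct Method search), with the same
# ">=" boundary convention and last-positive fallback as the blocked path.
linear_select <- function(a, target) {
  c <- 0
  last_pos <- NA_integer_
  for (j in seq_along(a)) {
    c <- c + a[j]
    if (a[j] > 0) last_pos <- j
    if (c >= target) return(j)
  }
  last_pos
}

#' Create an Optimized Direct Method state
#'
#' The ODM keeps the propensity vector and the total `a_R` incrementally up
#' to date through the reaction dependency graph; the search for the next
#' reaction is a plain linear scan. An optional permutation (from
#' [presimulate_and_order()]) reorders the reaction list to shorten the
#' scan.
#'
#' @param network An `ssa_network`.
#' @param partition Optional [block_partition()] (the graph is block-sorted
#'   under it).
#' @return Object of class `odm_state`.
#' @export
odm_state <- function(network, partition = NULL) {
  if (is.null(partition)) partition <- block_partition(n_reactions(network))
  counts <- initial_counts(network)
  a <- propensities(network, counts)
  aR <- 0
  for (x in a) aR <- aR + x
  cache <- new.env()
  cache$tab <- pack_stoichiometry(network)
  attr(network, ".stoich_cache") <- cache
  structure(list(network = network,
                 graph = build_dependency_graph(network, partition),
                 counts = counts, propensities = a, a_R = aR,
                 t_sim = 0, scan_length = 0, n_steps = 0L),
            class = "odm_state")
}

#' One Optimized Direct Method step
#'
#' @param state An [odm_state()].
#' @param z1,z2 Uniforms in `(0, 1]`.
#' @return List with `state` (updated), `fired`, `dt`.
#' @export
odm_step <- function(state, z1, z2) {
  if (state$a_R <= 0)
    return(list(state = state, fired = NA_integer_, dt = NA_real_))
  target <- z1 * state$a_R
  f <- linear_select(state$propensities, target)
  state$scan_length <- state$scan_length + f
  dt <- time_advance(state$a_R, z2)
  state$counts <- apply_stoichiometry(
    state$counts, f, pack_stoichiometry_cached(state$network))
  deps <- state$graph$dependents[[f]]
  for (q in seq_len(nrow(deps))) {
    d <- deps$index[q]
    old <- state$propensities[d]
    nw <- propensity(state$network$reactions[[d]], state$counts)
    state$propensities[d] <- nw
    state$a_R <- state$a_R + (nw - old)
  }
  state$t_sim <- state$t_sim + dt
  state$n_steps <- state$n_steps + 1L
  list(state = state, fired = f, dt = dt)
}

#' Pre-simulate and order reactions and species by access frequency
#'
#' Runs a short ODM pre-simulation from the initial state, counting how
#' often each reaction's propensity is recomputed and how often each
#' species' molecular count is updated, then returns both arrays sorted in
#' descending access order (stable for ties). Placing frequently touched
#' reactions and species first keeps the hot data compact in memory and
#' shortens the ODM's linear search.
#'
#' @param network An `ssa_network`.
#' @param presim_steps Number of pre-simulation firings (default 1e4).
#' @param seed,stream RNG stream of the pre-simulation.
#' @param order_by `"access"` (default) orders by access counts;
#'   `"propensity"` orders by time-averaged propensity (the classical ODM
#'   criterion).
#' @return List with `reaction_order` and `species_order` (permutations:
#'   old indices in their new order), `reaction_access`, `species_access`,
#'   `mean_propensity`, and `steps` actually executed.
#' @export
presimulate_and_order <- function(network, presim_steps = 1e4, seed = 1L,
                                  stream = 0L,
                                  order_by = c("access", "propensity")) {
  order_by <- match.arg(order_by)
  stopifnot(presim_steps >= 1)
  partition <- block_partition(n_reactions(network))
  graph <- build_dependency_graph(network, partition)
  res <- cpp_presim_access(as_engine_model(network), as_engine_graph(graph),
                           partition, presim_steps, as.integer(seed),
                           as.integer(stream))
  key_r <- if (order_by == "access") res$reaction_access
           else res$mean_propensity
  list(reaction_order = order(-key_r),
       species_order = order(-res$species_access),
       reaction_access = res$reaction_access,
       species_access = res$species_access,
       mean_propensity = res$mean_propensity,
       steps = res$steps)
}

#' Apply a reaction/species permutation to a network
#'
#' Relabels the network so that `reaction_order[i]` becomes reaction `i`
#' and `species_order[i]` becomes species `i`. The physical model is
#' unchanged: trajectories of the permuted network are the trajectories of
#' the original with relabeled indices.
#'
#' @param network An `ssa_network`.
#' @param reaction_order,species_order Permutations (old indices in new
#'   order); defaults leave the respective axis untouched.
#' @return The relabeled `ssa_network`.
#' @export
reorder_network <- function(network,
                            reaction_order = seq_len(n_reactions(network)),
                            species_order = seq_len(n_species(network))) {
  stopifnot(!anyDuplicated(reaction_order), !anyDuplicated(species_order))
  inv <- integer(length(species_order))
  inv[species_order] <- seq_along(species_order)
  reactions <- lapply(network$reactions[reaction_order], function(r) {
    r$reactants <- inv[r$reactants]
    r$products <- if (length(r$products)) inv[r$products] else r$products
    r
  })
  reaction_network(network$species[species_order, , drop = FALSE],
                   reactions)
}
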