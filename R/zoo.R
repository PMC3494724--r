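# Benchmark network generators: cyclic chain (weakly connected), colloidal
# aggregation (strongly connected), and random consistent networks with a
# controllable dependency range.

#' Cyclic chain model
#'
#' `N` species in a ring with `M = N` unimolecular reactions
#' `S_i -> S_{i+1 mod N}`. The total molecule count is conserved and every
#' reaction has exactly 2 dependents (itself and its successor), making
#' this the canonical weakly connected benchmark.
#'
#' @param N Number of species (>= 2).
#' @param k Rate constant for every reaction (default 1).
#' @param initial_count Initial count of every species (default 1).
#' @return An `ssa_network`.
#' @export
cyclic_chain <- function(N, k = 1, initial_count = 1L) {
  if (N < 2) stop("parameter error: cyclic chain requires N >= 2")
  reactions <- lapply(seq_len(N), function(i)
    reaction(1L, i, (i %% N) + 1L, k = k))
  reaction_network(sprintf("S%d", seq_len(N)), reactions,
                   initial_count = initial_count)
}

#' Colloidal aggregation model
#'
#' Species `A_1 .. A_N` are aggregates of sizes `1 .. N`. For every pair
#' `i <= j` with `i + j <= N` there is an aggregation channel
#' `A_i + A_j -> A_{i+j}` (type 2 when `i != j`, type 3 when `i == j`) and
#' the reverse fragmentation `A_{i+j} -> A_i + A_j` (type 1). Dependency
#' lists grow linearly with `N` (the largest reaches `3N - 7` dependents),
#' making this the canonical strongly connected benchmark.
#'
#' @param N Largest aggregate size (>= 3).
#' @param k Rate constant for every reaction (default 1).
#' @param initial_count Initial count of every species (default 1).
#' @return An `ssa_network`.
#' @export
colloidal_aggregation <- function(N, k = 1, initial_count = 1L) {
  if (N < 3) stop("parameter error: colloidal aggregation requires N >= 3")
  pairs <- colloidal_pairs(N)
  agg <- lapply(seq_len(nrow(pairs)), function(q) {
    i <- pairs$i[q]; j <- pairs$j[q]
    reaction(if (i == j) 3L else 2L, c(i, j), i + j, k = k)
  })
  frag <- lapply(seq_len(nrow(pairs)), function(q) {
    i <- pairs$i[q]; j <- pairs$j[q]
    reaction(1L, i + j, c(i, j), k = k)
  })
  reaction_network(sprintf("A%d", seq_len(N)), c(agg, frag),
                   initial_count = initial_count)
}

# All (i, j) with i <= j, i + j <= N, in ascending (i + j, i) order.
colloidal_pairs <- function(N) {
  out <- do.call(rbind, lapply(2:N, function(s) {
    i <- seq_len(s %/% 2)
    data.frame(i = i, j = s - i)
  }))
  out
}

#' Random consistent reaction network
#'
#' Generates a reproducible random mass-action network in which every
#' species consumed by some reaction is also produced by some reaction
#' (closed species flow), so no species is driven extinct by construction.
#' Three constructions are used depending on the requested dependency
#' range:
#'
#' * `dependency_range = c(2, 2)`: a randomly labelled cyclic chain
#'   (requires `M == N`), reproducing chain-like connectivity.
#' * a general `dependency_range` such as `c(8, 16)`: a "two-hub" design.
#'   Reactions are partitioned into groups sharing a hub reactant; each
#'   reaction is `H_t + s -> H_{sigma(t)} + u` with `sigma` a fixed-point
#'   free permutation of the groups and `s`, `u` ordinary species drawn
#'   from balanced multisets. Every reaction then changes two hub species
#'   (whose consumer lists have the group size) plus two low-degree
#'   ordinary species, pinning the per-reaction dependent count inside the
#'   requested band. The construction is verified with
#'   [connectivity_stats()] and re-drawn until the band holds.
#' * `dependency_range = NULL`: unconstrained molecule-conserving random
#'   network with the requested type mix.
#'
#' @param N Number of species.
#' @param M Number of reactions.
#' @param dependency_range Length-2 integer band for the per-reaction
#'   dependent counts, or `NULL` for unconstrained connectivity.
#' @param type_mix Sampling weights for reaction types 1..3 in the
#'   unconstrained mode.
#' @param k Rate constant for every reaction (default 1).
#' @param initial_count Initial count of every species (default 1).
#' @param seed Generation seed; the same seed reproduces the network
#'   exactly.
#' @param max_tries Bounded retries before a generation error.
#' @return An `ssa_network`.
#' @export
random_network <- function(N, M = N, dependency_range = c(8L, 16L),
                           type_mix = c(0.25, 0.5, 0.25), k = 1,
                           initial_count = 1L, seed = 1L, max_tries = 50L) {
  stopifnot(N >= 2, M >= 1)
  if (!is.null(dependency_range)) {
    stopifnot(length(dependency_range) == 2L,
              dependency_range[1] <= dependency_range[2])
    if (dependency_range[2] <= 2) {
      if (M != N)
        stop("generation error: chain-like connectivity requires M == N")
      return(with_seed(seed, random_chain_network(N, k, initial_count)))
    }
    # candidate hub-group sizes: the band midpoint over 2 first (every
    # reaction changes two hubs), then neighbours for geometries where the
    # ordinary-species degree M/N shifts the counts
    g0 <- max(2L, as.integer(floor(mean(dependency_range) / 2)))
    gs <- unique(pmax(2L, g0 + c(0L, -1L, 1L, -2L, 2L)))
    for (try in seq_len(max_tries)) {
      g <- gs[((try - 1L) %% length(gs)) + 1L]
      net <- with_seed(seed + 7919L * (try - 1L),
                       two_hub_network(N, M, g, k, initial_count))
      if (is.null(net)) next
      st <- connectivity_stats(build_dependency_graph(net))
      if (all(st$counts >= dependency_range[1]) &&
          all(st$counts <= dependency_range[2]) &&
          length(validate_network(net)) == 0L)
        return(net)
    }
    stop("generation error: could not achieve dependent counts in [",
         dependency_range[1], ", ", dependency_range[2], "] after ",
         max_tries, " tries (infeasible N/M/range?)")
  }
  for (try in seq_len(max_tries)) {
    net <- with_seed(seed + 7919L * (try - 1L),
                     free_random_network(N, M, type_mix, k, initial_count))
    if (!is.null(net) && length(validate_network(net)) == 0L) return(net)
  }
  stop("generation error: could not generate a consistent network after ",
       max_tries, " tries")
}

# Chain-like mode: a random cyclic permutation of the species.
random_chain_network <- function(N, k, initial_count) {
  perm <- sample(N)
  reactions <- lapply(seq_len(N), function(i)
    reaction(1L, perm[i], perm[(i %% N) + 1L], k = k))
  reaction_network(sprintf("S%d", seq_len(N)), reactions,
                   initial_count = initial_count)
}

# Two-hub mode: all reactions H_t + s -> H_sigma(t) + u (type 2), hub
# groups of ~g consumers each.
two_hub_network <- function(N, M, g, k, initial_count) {
  T_groups <- as.integer(ceiling(M / g))
  if (T_groups < 2L || N - T_groups < 2L) return(NULL)
  K <- N - T_groups # ordinary species count
  # group sizes as equal as possible
  sizes <- rep(M %/% T_groups, T_groups)
  extra <- M %% T_groups
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  group_of <- rep(seq_len(T_groups), times = sizes)

  ids <- sample(N)
  hub_id <- ids[seq_len(T_groups)]
  ord_id <- ids[(T_groups + 1L):N]

  # fixed-point-free group permutation: a single random cycle
  ord <- sample(T_groups)
  sigma <- integer(T_groups)
  sigma[ord] <- ord[c(2:T_groups, 1L)]

  # balanced ordinary consumption multiset; production is an independent
  # shuffle of the same multiset (closed species flow)
  base <- M %/% K
  rem <- M %% K
  degs <- rep(base, K)
  if (rem > 0L) degs[sample(K, rem)] <- base + 1L
  if (any(degs == 0L)) return(NULL) # every ordinary species must flow
  cons_slots <- sample(rep(ord_id, times = degs))
  prod_slots <- sample(cons_slots)
  # products must differ from the same reaction's ordinary reactant
  for (r in seq_len(M)) {
    if (prod_slots[r] == cons_slots[r]) {
      # after swapping, r receives prod_slots[alt] (must differ from r's
      # reactant) and alt receives cons_slots[r] (must differ from alt's)
      alt <- which(prod_slots != cons_slots[r] & cons_slots != cons_slots[r])
      alt <- alt[alt != r]
      if (length(alt) == 0L) return(NULL)
      swap <- alt[1L]
      tmp <- prod_slots[r]
      prod_slots[r] <- prod_slots[swap]
      prod_slots[swap] <- tmp
    }
  }
  reactions <- lapply(seq_len(M), function(r) {
    t <- group_of[r]
    reaction(2L, c(hub_id[t], cons_slots[r]),
             c(hub_id[sigma[t]], prod_slots[r]), k = k)
  })
  reaction_network(sprintf("S%d", seq_len(N)), reactions,
                   initial_count = initial_count)
}

# Unconstrained mode: molecule-conserving reactions with a random type mix;
# the production multiset is a shuffle of the consumption multiset.
free_random_network <- function(N, M, type_mix, k, initial_count) {
  types <- sample(1:3, M, replace = TRUE, prob = type_mix)
  # balanced reactant-species multiset
  n_slots <- sum(ifelse(types == 2L, 2L, 1L))
  pool <- sample(rep(seq_len(N), length.out = max(n_slots, N)))[
    seq_len(n_slots)]
  slot <- 1L
  reactants <- vector("list", M)
  for (r in seq_len(M)) {
    if (types[r] == 2L) {
      a <- pool[slot]; b <- pool[slot + 1L]
      if (a == b) { # need distinct reactants
        cand <- setdiff(seq_len(N), a)
        b <- cand[sample.int(length(cand), 1L)]
      }
      reactants[[r]] <- c(a, b)
      slot <- slot + 2L
    } else {
      reactants[[r]] <- pool[slot]
      slot <- slot + 1L
    }
  }
  # molecule-level consumption multiset (type 3 consumes two of one species)
  consumed <- unlist(lapply(seq_len(M), function(r)
    if (types[r] == 3L) rep(reactants[[r]], 2L) else reactants[[r]]))
  produced <- sample(consumed)
  # deal products back out reaction by reaction, avoiding net-zero species
  sizes <- ifelse(types == 1L, 1L, 2L)
  pos <- 1L
  products <- vector("list", M)
  for (r in seq_len(M)) {
    products[[r]] <- produced[pos:(pos + sizes[r] - 1L)]
    pos <- pos + sizes[r]
  }
  for (r in seq_len(M)) {
    ok <- function(pr, re, ty) {
      cons <- if (ty == 3L) rep(re[1], 2L) else re
      all_sp <- unique(c(cons, pr))
      deltas <- vapply(all_sp, function(s)
        sum(pr == s) - sum(cons == s), numeric(1))
      all(deltas != 0)
    }
    tries <- 0L
    while (!ok(products[[r]], reactants[[r]], types[r]) && tries < 4L * M) {
      swap <- sample.int(M, 1L)
      q <- sample.int(sizes[swap], 1L)
      w <- sample.int(sizes[r], 1L)
      tmp <- products[[r]][w]
      products[[r]][w] <- products[[swap]][q]
      products[[swap]][q] <- tmp
      tries <- tries + 1L
    }
    if (!ok(products[[r]], reactants[[r]], types[r])) return(NULL)
  }
  # repair pass may have broken earlier reactions; verify all
  for (r in seq_len(M)) {
    cons <- if (types[r] == 3L) rep(reactants[[r]][1], 2L) else reactants[[r]]
    all_sp <- unique(c(cons, products[[r]]))
    deltas <- vapply(all_sp, function(s)
      sum(products[[r]] == s) - sum(cons == s), numeric(1))
    if (any(deltas == 0)) return(NULL)
  }
  reactions <- lapply(seq_len(M), function(r)
    reaction(types[r], reactants[[r]], products[[r]], k = k))
  net <- reaction_network(sprintf("S%d", seq_len(N)), reactions,
                          initial_count = initial_count)
  # closed flow check: consumed species are all produced
  cons_sp <- unique(unlist(reactants))
  prod_sp <- unique(unlist(products))
  if (!all(cons_sp %in% prod_sp)) return(NULL)
  net
}
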