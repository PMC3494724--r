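# Reaction-reaction dependency graph, block-sorted with per-block offsets.
#
# The dependents of a reaction j are exactly the reactions whose propensity
# can change when j fires: every reaction with a reactant among the species
# whose counts j changes (j itself is a dependent whenever it consumes a
# species it changes, the common case). Each dependent entry carries
# denormalized reaction metadata (type, global index, rate constant,
# reactant indices) so an update never has to chase back into the network;
# the list is sorted by the block owning the dependent, and an integer
# offset array stores the end index of every block's slice.
#
# Blocks are contiguous index ranges, so sorting by block coincides with
# sorting by reaction index.

#' Build the reaction-reaction dependency graph
#'
#' @param network An `ssa_network`.
#' @param partition A [block_partition()] covering the `M` reactions;
#'   defaults to the standard geometry.
#' @return Object of class `dependency_graph` with per-source `dependents`
#'   (data.frames with columns `index`, `block`, `type`, `k`, `s1`, `s2`)
#'   and `block_offsets` (per-source integer vector of length `p`; entry `i`
#'   is the end index of block `i`'s slice).
#' @export
build_dependency_graph <- function(network, partition = NULL) {
  M <- n_reactions(network)
  if (is.null(partition)) partition <- block_partition(M)
  stopifnot(partition$M == M)
  b <- partition$block_size
  p <- partition$num_blocks

  consumers <- vector("list", n_species(network)) # species -> reactions
  for (j in seq_len(M)) {
    r <- network$reactions[[j]]
    for (s in unique(r$reactants))
      consumers[[s]] <- c(consumers[[s]], j)
  }
  rtype <- vapply(network$reactions, function(r) r$type, integer(1))
  kvec <- vapply(network$reactions, function(r) r$k, numeric(1))
  s1 <- vapply(network$reactions, function(r) r$reactants[1], integer(1))
  s2 <- vapply(network$reactions, function(r)
    if (length(r$reactants) > 1L) r$reactants[2] else NA_integer_,
    integer(1))

  dependents <- vector("list", M)
  offsets <- vector("list", M)
  for (j in seq_len(M)) {
    changed <- reaction_stoichiometry(network$reactions[[j]])$species
    dep <- sort(unique(unlist(consumers[changed], use.names = FALSE)))
    blk <- ((dep - 1L) %/% b) + 1L
    dependents[[j]] <- data.frame(index = dep, block = blk,
                                  type = rtype[dep], k = kvec[dep],
                                  s1 = s1[dep], s2 = s2[dep])
    offsets[[j]] <- cumsum(tabulate(blk, nbins = p))
  }
  structure(list(dependents = dependents, block_offsets = offsets,
                 partition = partition, M = M),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  st <- connectivity_stats(x)
  cat(sprintf("<dependency_graph> %d reactions, dependents per reaction: mean %.2f, max %d\n",
              x$M, st$mean, st$max))
  invisible(x)
}

#' Dependents of a reaction owned by one block
#'
#' Constant-time slice arithmetic on the per-block offset array.
#'
#' @param graph A `dependency_graph`.
#' @param source_reaction Source reaction index.
#' @param block_index 1-based block index.
#' @return The slice of the source's dependent entries owned by that block
#'   (possibly zero rows).
#' @export
dependents_in_block <- function(graph, source_reaction, block_index) {
  off <- graph$block_offsets[[source_reaction]]
  if (block_index < 1L || block_index > length(off))
    stop("index error: block ", block_index, " outside the partition")
  lo <- if (block_index > 1L) off[block_index - 1L] + 1L else 1L
  hi <- off[block_index]
  deps <- graph$dependents[[source_reaction]]
  if (hi < lo) deps[integer(0), , drop = FALSE]
  else deps[lo:hi, , drop = FALSE]
}

#' Connectivity statistics of a dependency graph
#'
#' @param graph A `dependency_graph`.
#' @return List with `counts` (dependents per reaction), `mean` and `max`.
#' @export
connectivity_stats <- function(graph) {
  counts <- vapply(graph$dependents, nrow, integer(1))
  list(counts = counts, mean = mean(counts), max = max(counts))
}

# Check the denormalized metadata against the network it was built from.
check_graph_consistency <- function(graph, network) {
  bad <- character(0)
  for (j in seq_len(graph$M)) {
    deps <- graph$dependents[[j]]
    for (q in seq_len(nrow(deps))) {
      r <- network$reactions[[deps$index[q]]]
      ok <- r$type == deps$type[q] && r$k == deps$k[q] &&
        r$reactants[1] == deps$s1[q] &&
        (length(r$reactants) < 2L || r$reactants[2] == deps$s2[q])
      if (!ok) bad <- c(bad, sprintf("source %d dependent %d", j, q))
    }
  }
  bad
}

# Flattened graph passed to the compiled engines (0-based indices).
as_engine_graph <- function(graph) {
  lens <- vapply(graph$dependents, nrow, integer(1))
  list(dep_ptr = c(0L, cumsum(lens)),
       dep_idx = unlist(lapply(graph$dependents, function(d) d$index),
                        use.names = FALSE) - 1L)
}

empty_engine_graph <- function(M) {
  list(dep_ptr = integer(M + 1L), dep_idx = integer(0))
}

#' Dump a dependency graph as TSV for inspection
#' @param graph A `dependency_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dependency_graph_tsv <- function(graph, path) {
  rows <- do.call(rbind, lapply(seq_len(graph$M), function(j) {
    d <- graph$dependents[[j]]
    if (nrow(d) == 0L) return(NULL)
    cbind(source = j, d)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
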