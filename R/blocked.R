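# Blocked propensity partial sums and three-level hierarchical selection.
#
# The reaction list is divided into p contiguous blocks of b propensities
# (b a multiple of the chunk size, the chunk size a multiple of the lane
# width). The engine maintains the CUMULATIVE block sums; the last entry is
# the total propensity a_R. Selection proceeds top-down:
#   level 1: first block whose cumulative sum reaches z1 * a_R
#            (the ballot/first-set-bit primitive realized as
#             "first index satisfying a predicate over an array segment")
#   level 2: chunk scan within the block, each chunk summed by lane-strided
#            reduction
#   level 3: prefix scan in batches of lane_width inside the chunk.
# Ties at exact prefix-sum boundaries resolve to the lower index (the
# selection predicate is ">=").

#' Block partition geometry
#'
#' @param M Number of reactions to cover.
#' @param num_blocks Requested number of blocks `p`; by default the block
#'   size is the smallest multiple of `chunk_size` giving at most
#'   `max_blocks` blocks.
#' @param block_size Block size `b`; must be a positive multiple of
#'   `chunk_size`. Overrides `num_blocks`.
#' @param chunk_size Second-level search granularity (default 128).
#' @param lane_width Width of the third-level prefix-scan batches and of the
#'   strided reduction lanes (default 32).
#' @param max_blocks Cap on `p` used by the default geometry (default 25,
#'   the flat region of the block-count trade-off for the serial engine).
#' @return Object of class `block_partition`.
#' @export
block_partition <- function(M, num_blocks = NULL, block_size = NULL,
                            chunk_size = 128L, lane_width = 32L,
                            max_blocks = 25L) {
  M <- as.integer(M)
  chunk_size <- as.integer(chunk_size)
  lane_width <- as.integer(lane_width)
  stopifnot(M >= 1L, chunk_size >= 1L, lane_width >= 1L,
            chunk_size %% lane_width == 0L)
  if (!is.null(block_size)) {
    b <- as.integer(block_size)
    if (b < 1L || b %% chunk_size != 0L)
      stop("block_size must be a positive multiple of chunk_size")
  } else {
    p_target <- if (is.null(num_blocks)) as.integer(max_blocks)
                else as.integer(num_blocks)
    stopifnot(p_target >= 1L)
    b <- chunk_size * max(1L, ceiling(M / (chunk_size * p_target)))
  }
  p <- max(1L, ceiling(M / b))
  structure(list(num_blocks = p, block_size = b, chunk_size = chunk_size,
                 lane_width = lane_width, M = M),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> p = %d blocks of b = %d (chunk %d, lane %d) covering M = %d\n",
              x$num_blocks, x$block_size, x$chunk_size, x$lane_width, x$M))
  invisible(x)
}

block_bounds <- function(partition, block) {
  lo <- (block - 1L) * partition$block_size + 1L
  hi <- min(block * partition$block_size, partition$M)
  c(lo, hi)
}

# Lane-strided reduction: lane j accumulates elements j, j + lane, ...; the
# lane partials are combined in lane order. Matches the compiled engine's
# summation order exactly.
chunk_sum <- function(a) {
  lane <- attr(a, "lane_width")
  if (is.null(lane)) lane <- 32L
  n <- length(a)
  lanes <- numeric(min(lane, 256L))
  for (i in seq_len(n)) {
    j <- ((i - 1L) %% length(lanes)) + 1L
    lanes[j] <- lanes[j] + a[i]
  }
  s <- 0
  for (j in seq_along(lanes)) s <- s + lanes[j]
  s
}

#' Initialize cumulative block partial sums from scratch
#'
#' @param propensities Numeric propensity vector of length `M`.
#' @param partition A [block_partition()].
#' @return Object of class `block_sums`: list with `cumulative` (length `p`,
#'   entry `i` is the sum of propensities of blocks `1..i`) and `a_R` (the
#'   last entry, the total propensity).
#' @export
init_block_sums <- function(propensities, partition) {
  if (length(propensities) == 0L)
    stop("invalid state: empty propensity vector")
  stopifnot(length(propensities) == partition$M)
  p <- partition$num_blocks
  cum <- numeric(p)
  run <- 0
  for (l in seq_len(p)) {
    bb <- block_bounds(partition, l)
    bs <- 0
    for (j in bb[1]:bb[2]) bs <- bs + propensities[j]
    run <- run + bs
    cum[l] <- run
  }
  structure(list(cumulative = cum, a_R = cum[p], partition = partition),
            class = "block_sums")
}

#' Level-1 selection: locate the block containing the target
#'
#' Returns the smallest block index whose cumulative partial sum reaches the
#' selection target `z1 * a_R`.
#'
#' @param block_sums A `block_sums` object.
#' @param target Selection target in `(0, a_R]`.
#' @return 1-based block index.
#' @export
select_block <- function(block_sums, target) {
  cum <- block_sums$cumulative
  if (target > cum[length(cum)])
    stop("selection error: target ", target, " exceeds a_R ",
         cum[length(cum)])
  for (l in seq_along(cum)) if (cum[l] >= target) return(l)
  length(cum)
}

#' Level-2 selection: locate the chunk within a block
#'
#' Scans the block chunk by chunk, each chunk summed with the lane-strided
#' reduction, until the running within-block cumulative sum reaches the
#' residual target.
#'
#' @param propensities Full propensity vector.
#' @param partition A [block_partition()].
#' @param block 1-based block index.
#' @param residual Residual target (selection target minus the cumulative
#'   sum of the preceding blocks).
#' @return List with `chunk` (1-based chunk index within the block) and
#'   `base` (sum of the preceding chunks of this block).
#' @export
select_chunk <- function(propensities, partition, block, residual) {
  bb <- block_bounds(partition, block)
  run <- 0
  chunk <- 0L
  for (cs in seq(bb[1], bb[2], by = partition$chunk_size)) {
    chunk <- chunk + 1L
    ce <- min(cs + partition$chunk_size - 1L, bb[2])
    seg <- propensities[cs:ce]
    attr(seg, "lane_width") <- partition$lane_width
    csum <- chunk_sum(seg)
    if (run + csum >= residual)
      return(list(chunk = chunk, base = run))
    run <- run + csum
  }
  # floating-point edge: residual exceeded the block total by rounding
  list(chunk = chunk, base = run - csum)
}

#' Level-3 selection: locate the reaction within a chunk
#'
#' Prefix-scans the chunk in batches of `lane_width` propensities and
#' returns the first index whose in-chunk prefix sum reaches the residual.
#'
#' @inheritParams select_chunk
#' @param chunk 1-based chunk index within the block.
#' @param residual Residual target within the chunk.
#' @return 1-based global reaction index.
#' @export
select_within_chunk <- function(propensities, partition, block, chunk,
                                residual) {
  bb <- block_bounds(partition, block)
  cs <- bb[1] + (chunk - 1L) * partition$chunk_size
  ce <- min(cs + partition$chunk_size - 1L, bb[2])
  s <- 0
  for (j in cs:ce) {
    s <- s + propensities[j]
    if (s >= residual) return(j)
  }
  # floating-point edge: fall back to the last positive entry
  for (j in ce:cs) if (propensities[j] > 0) return(j)
  stop("selection error: empty chunk")
}

# Core 3-level selection on a raw propensity vector. Mirrors the compiled
# engine, including the floating-point fallbacks.
blocked_select_index <- function(propensities, partition, target) {
  p <- partition$num_blocks
  cum <- init_block_sums(propensities, partition)$cumulative
  l <- p
  for (i in seq_len(p)) if (cum[i] >= target) { l <- i; break }
  residual <- target - if (l > 1L) cum[l - 1L] else 0
  ch <- select_chunk(propensities, partition, l, residual)
  select_within_chunk(propensities, partition, l, ch$chunk,
                      residual - ch$base)
}

#' Hierarchical next-reaction selection
#'
#' Selects the reaction to fire by the three-level blocked search. The
#' result is identical to the Direct Method's linear cumulative-sum scan:
#' the smallest index `f` whose propensity prefix sum reaches `z1 * a_R`.
#'
#' @param state A [blocked_state()].
#' @param z1 Uniform random number in `(0, 1]`.
#' @return 1-based index of the reaction to fire, or `NA_integer_` when the
#'   total propensity is zero (no reaction can fire).
#' @export
hierarchical_select <- function(state, z1) {
  stopifnot(z1 > 0, z1 <= 1)
  aR <- state$block_sums$a_R
  if (aR <= 0) return(NA_integer_)
  target <- z1 * aR
  p <- state$partition$num_blocks
  cum <- state$block_sums$cumulative
  l <- p
  for (i in seq_len(p)) if (cum[i] >= target) { l <- i; break }
  residual <- target - if (l > 1L) cum[l - 1L] else 0
  ch <- select_chunk(state$propensities, state$partition, l, residual)
  select_within_chunk(state$propensities, state$partition, l, ch$chunk,
                      residual - ch$base)
}

#' Batched hierarchical selection against a frozen propensity vector
#'
#' Runs the compiled three-level selection for many targets at once against
#' one fixed propensity vector; used for large-scale equivalence checks
#' against the linear cumulative-sum scan and for next-reaction frequency
#' tests.
#'
#' @param propensities Propensity vector.
#' @param partition A [block_partition()] covering it.
#' @param targets Selection targets in `(0, a_R]`.
#' @return Integer vector of selected (1-based) reaction indices.
#' @export
hierarchical_select_many <- function(propensities, partition, targets) {
  stopifnot(length(propensities) == partition$M)
  cpp_select_many(as.numeric(propensities), partition, as.numeric(targets))
}

#' Mutable blocked simulation state
#'
#' Bundles the species counts, the propensity vector, the cumulative block
#' partial sums and the simulation clock for the blocked engine.
#'
#' @param network An `ssa_network`.
#' @param partition Optional [block_partition()]; defaults to the standard
#'   geometry for `M` reactions.
#' @param counts Optional starting counts (defaults to the network's
#'   initial counts).
#' @return Object of class `blocked_state`.
#' @export
blocked_state <- function(network, partition = NULL,
                          counts = initial_counts(network)) {
  if (is.null(partition)) partition <- block_partition(n_reactions(network))
  a <- propensities(network, counts)
  structure(list(network = network, partition = partition,
                 counts = counts, propensities = a,
                 block_sums = init_block_sums(a, partition),
                 t_sim = 0, n_steps = 0L, steps_since_refresh = 0L),
            class = "blocked_state")
}

#' Incremental propensity and block-sum update after a firing
#'
#' For every dependent of the fired reaction the propensity is recomputed
#' from the current counts; the per-block propensity changes are
#' accumulated, prefix-summed over blocks, and added to the cumulative
#' block sums, so that entry `i` stays the sum of blocks `1..i`.
#'
#' @param state A [blocked_state()] whose `counts` already reflect the
#'   firing.
#' @param fired Index of the fired reaction.
#' @param graph The [build_dependency_graph()] of the network under the same
#'   partition.
#' @return The updated `blocked_state`.
#' @export
update_after_firing <- function(state, fired, graph) {
  deps <- graph$dependents[[fired]]
  p <- state$partition$num_blocks
  delta <- numeric(p)
  for (q in seq_len(nrow(deps))) {
    d <- deps$index[q]
    old <- state$propensities[d]
    nw <- propensity(state$network$reactions[[d]], state$counts)
    if (nw < 0) stop("internal-consistency error: negative propensity")
    state$propensities[d] <- nw
    bl <- deps$block[q]
    delta[bl] <- delta[bl] + (nw - old)
  }
  run <- 0
  for (i in seq_len(p)) {
    run <- run + delta[i]
    state$block_sums$cumulative[i] <- state$block_sums$cumulative[i] + run
  }
  state$block_sums$a_R <- state$block_sums$cumulative[p]
  state
}
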