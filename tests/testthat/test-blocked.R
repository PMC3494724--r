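# Blocked partial sums, three-level selection, incremental updates.

test_that("cumulative block sums are computed exactly from scratch", {
  part <- block_partition(256, block_size = 128)
  bs <- init_block_sums(rep(1, 256), part)
  expect_equal(bs$cumulative, c(128, 256))
  expect_equal(bs$a_R, 256)

  one <- block_partition(1)
  expect_equal(init_block_sums(3.25, one)$cumulative, 3.25)
  expect_error(init_block_sums(numeric(0), one), "invalid state")

  set.seed(5)
  a <- runif(1000)
  p <- block_partition(1000, block_size = 128)
  expect_equal(init_block_sums(a, p)$a_R, sum(a), tolerance = 1e-12)
})

test_that("block selection finds the first cumulative sum >= target", {
  part <- block_partition(512, block_size = 128)
  bs <- list(cumulative = c(10, 20, 30, 40))
  expect_equal(select_block(bs, 25), 3L)   # first cumulative >= 25
  expect_equal(select_block(bs, 10), 1L)   # boundary tie -> lower block
  expect_equal(select_block(bs, 40), 4L)
  expect_error(select_block(bs, 41), "selection error")

  set.seed(6)
  a <- runif(512)
  sums <- init_block_sums(a, part)
  targets <- runif(1e4) * sums$a_R
  got <- vapply(targets, function(t) select_block(sums, t), integer(1))
  want <- findInterval(targets, sums$cumulative, left.open = TRUE) + 1L
  expect_identical(got, want)
})

test_that("chunk and within-chunk selection scan with >= semantics", {
  # block of two chunks with sums 5 and 5
  part <- block_partition(8, block_size = 8, chunk_size = 4, lane_width = 2)
  a <- c(2, 1, 1, 1, 3, 0, 1, 1)
  expect_equal(select_chunk(a, part, 1, 6)$chunk, 2L)
  expect_equal(select_chunk(a, part, 1, 4.5)$chunk, 1L)
  ch <- select_chunk(a, part, 1, 6)
  expect_equal(ch$base, 5)

  # uniform chunk: residual 2.5 lands on the third entry
  part2 <- block_partition(32, block_size = 32, chunk_size = 32)
  expect_equal(select_within_chunk(rep(1, 32), part2, 1, 1, 2.5), 3L)
  # a single positive propensity takes every residual in (0, a]
  b <- c(0, 0, 4, 0, 0, rep(0, 27))
  for (res in c(1e-9, 2, 4))
    expect_equal(select_within_chunk(b, part2, 1, 1, res), 3L)

  set.seed(7)
  for (rep in 1:50) {
    v <- runif(32); v[sample(32, 10)] <- 0
    res <- runif(1) * sum(v)
    expect_equal(select_within_chunk(v, part2, 1, 1, res),
                 linear_select_oracle(v, res))
  }
})

test_that("hierarchical selection equals the linear Direct Method scan", {
  part <- block_partition(256, block_size = 128)
  a <- rep(1, 256)
  expect_equal(blockssa:::blocked_select_index(a, part, 130.5), 131L)

  j <- 77L
  single <- numeric(256); single[j] <- 0.3
  for (z1 in c(1e-9, 0.4, 1))
    expect_equal(blockssa:::blocked_select_index(single, part,
                                                 z1 * sum(single)), j)

  # R path against the compiled path and the linear oracle
  set.seed(8)
  for (rep in 1:20) {
    a <- runif(256); a[sample(256, 100)] <- 0
    targets <- runif(50) * sum(a)
    want <- linear_select_oracle(a, targets)
    expect_identical(hierarchical_select_many(a, part, targets), want)
    got_r <- vapply(targets, function(t)
      blockssa:::blocked_select_index(a, part, t), integer(1))
    expect_identical(got_r, want)
  }
})

test_that("incremental block-sum updates preserve the cumulative invariants", {
  # p = 4 single-reaction blocks so per-block deltas are fully observable
  net <- reaction_network(
    sprintf("S%d", 1:8),
    list(reaction(1L, 1L, 5L), reaction(1L, 2L, 6L),
         reaction(1L, 3L, 7L), reaction(1L, 4L, 8L)),
    initial_count = 10L)
  part <- block_partition(4, block_size = 1, chunk_size = 1, lane_width = 1)
  graph <- build_dependency_graph(net, part)
  state <- blocked_state(net, part)
  expect_equal(state$block_sums$cumulative, c(10, 20, 30, 40))

  # firing reaction 1 only changes its own propensity: delta (-1, 0, 0, 0)
  state$counts <- apply_stoichiometry(state$counts, 1L,
                                      pack_stoichiometry(net))
  state <- update_after_firing(state, 1L, graph)
  expect_equal(state$block_sums$cumulative, c(9, 19, 29, 39))
  expect_equal(state$block_sums$a_R, 39)

  # no dependent changed => block sums unchanged (propensities re-derived
  # from counts that did not move for any dependent)
  before <- state$block_sums$cumulative
  state2 <- update_after_firing(state, 3L, graph) # counts NOT applied
  expect_equal(state2$block_sums$cumulative, before)
})

test_that("incremental updates track the from-scratch sums on a live run", {
  net <- desk_random_network(64, seed = 4, initial_count = 6L)
  part <- block_partition(64, block_size = 32, chunk_size = 32)
  graph <- build_dependency_graph(net, part)
  state <- blocked_state(net, part)
  rng <- rng_stream(11, 0)
  for (i in 1:300) {
    st <- ssa_step(state, graph, rng)
    if (is.na(st$fired)) break
    state <- st$state
    expect_false(is.unsorted(state$block_sums$cumulative)) # monotone
  }
  scratch <- init_block_sums(propensities(net, state$counts), part)
  expect_equal(state$block_sums$cumulative, scratch$cumulative,
               tolerance = 1e-10)
})

test_that("sparse and dense update scheduling give bitwise-identical runs", {
  net <- desk_random_network(64, seed = 4, initial_count = 6L)
  a <- run_trajectory(net, 2, seed = 3, max_events = 500,
                      dense_update_threshold = 0L)
  b <- run_trajectory(net, 2, seed = 3, max_events = 500,
                      dense_update_threshold = 10000L)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)
  expect_identical(a$final_block_cumsum, b$final_block_cumsum)
  expect_false(identical(a$update_path, b$update_path))
})

test_that("selection work falls and update work grows with block count", {
  sweep <- block_sweep(cyclic_chain(2048), c(2, 4, 8, 16), n_steps = 500,
                       seed = 2)
  expect_true(all(diff(sweep$selection_per_step) < 0))
  expect_true(all(diff(sweep$update_per_step) > 0))
})

test_that("partition geometry respects chunk and lane multiples", {
  p <- block_partition(50000)
  expect_true(p$num_blocks <= 25)
  expect_equal(p$block_size %% p$chunk_size, 0L)
  expect_true(p$num_blocks * p$block_size >= 50000)
  expect_error(block_partition(100, block_size = 100), "multiple")
  p2 <- block_partition(256, num_blocks = 2)
  expect_equal(p2$block_size, 128L)
})
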