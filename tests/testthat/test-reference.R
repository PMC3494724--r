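# Direct Method and Optimized Direct Method oracles; pre-simulation
# reordering.

test_that("direct method selection scans the cumulative sum with >=", {
  net <- reaction_network(c("A", "B", "C", "D"),
                          list(reaction(1L, 1L, 2L, k = 3),
                               reaction(1L, 3L, 4L, k = 1)),
                          initial_count = 1L)
  # propensities (3, 1); z1 = 0.7 -> target 2.8 -> reaction 1
  st <- direct_method_step(net, initial_counts(net), z1 = 0.7, z2 = 0.5)
  expect_equal(st$fired, 1L)
  expect_equal(st$a_R, 4)

  # a zero leading propensity is skipped for any z1
  net0 <- reaction_network(c("A", "B", "C", "D"),
                           list(reaction(1L, 1L, 2L, k = 3),
                                reaction(1L, 3L, 4L, k = 5)),
                           initial_count = 1L)
  counts <- c(A = 0, B = 0, C = 1, D = 0)
  for (z1 in c(0.01, 0.5, 1))
    expect_equal(direct_method_step(net0, counts, z1, 0.5)$fired, 2L)
})

test_that("direct, ODM and blocked steppers share trajectories seed-for-seed", {
  net <- desk_random_network(48, seed = 3, initial_count = 4L)
  rng <- rng_stream(17, 0)
  zs <- matrix(rng(400), ncol = 2, byrow = TRUE)

  counts <- initial_counts(net)
  ostate <- odm_state(net)
  part <- block_partition(48)
  graph <- build_dependency_graph(net, part)
  bstate <- blocked_state(net, part)
  for (i in seq_len(nrow(zs))) {
    d <- direct_method_step(net, counts, zs[i, 1], zs[i, 2])
    if (is.na(d$fired)) break
    counts <- d$counts
    o <- odm_step(ostate, zs[i, 1], zs[i, 2])
    ostate <- o$state
    b <- ssa_step(bstate, graph, z = zs[i, ])
    bstate <- b$state
    expect_identical(c(d$fired, o$fired, b$fired), rep(d$fired, 3))
    expect_equal(o$dt, d$dt, tolerance = 1e-12)
    expect_equal(b$dt, d$dt, tolerance = 1e-12)
  }
  expect_equal(unname(ostate$counts), unname(counts))
})

test_that("incremental ODM total matches the from-scratch sum", {
  net <- desk_random_network(48, seed = 5, initial_count = 5L)
  state <- odm_state(net)
  rng <- rng_stream(3, 1)
  for (i in 1:500) {
    s <- odm_step(state, rng(1), rng(1))
    if (is.na(s$fired)) break
    state <- s$state
  }
  expect_equal(state$a_R, sum(propensities(net, state$counts)),
               tolerance = 1e-8)
})

test_that("pre-simulation orders reactions by access with stable ties", {
  # one dominant channel: its reaction is touched most and sorts first
  net <- reaction_network(c("A", "B", "C", "D", "E", "F"),
    list(reaction(1L, 1L, 2L, k = 1e-6),
         reaction(1L, 3L, 4L, k = 1e-6),
         reaction(1L, 5L, 6L, k = 50),
         reaction(1L, 6L, 5L, k = 50)),
    initial_count = 20L)
  ord <- presimulate_and_order(net, presim_steps = 2000, seed = 2)
  expect_true(all(ord$reaction_order[1:2] %in% c(3L, 4L)))
  # untouched reactions keep their relative (stable) order at the tail
  tail2 <- ord$reaction_order[3:4]
  expect_identical(tail2[order(tail2)], tail2)
  # species of the dominant loop lead the species permutation
  expect_true(all(ord$species_order[1:2] %in% c(5L, 6L)))
  # the time-averaged-propensity criterion agrees on the dominant channels
  ord2 <- presimulate_and_order(net, presim_steps = 2000, seed = 2,
                                order_by = "propensity")
  expect_true(all(ord2$reaction_order[1:2] %in% c(3L, 4L)))
})

test_that("frequency ordering shortens the ODM linear scan", {
  # dominant channel deliberately at the END of the reaction list
  M <- 40
  sp <- sprintf("S%d", 1:(2 * M))
  reactions <- lapply(seq_len(M), function(i)
    reaction(1L, 2L * i - 1L, 2L * i,
             k = if (i == M) 1000 else 1e-4))
  net <- reaction_network(sp, reactions, initial_count = 1000L)
  ord <- presimulate_and_order(net, presim_steps = 500, seed = 4)
  sorted <- reorder_network(net, ord$reaction_order, ord$species_order)

  run_scan <- function(n) {
    st <- odm_state(n)
    rng <- rng_stream(31, 0)
    for (i in 1:200) {
      s <- odm_step(st, rng(1), rng(1))
      st <- s$state
    }
    st$scan_length / st$n_steps
  }
  expect_lt(run_scan(sorted), run_scan(net) / 5)
})

test_that("relabeled networks reproduce the physical event sequence", {
  net <- desk_random_network(32, seed = 6, initial_count = 4L)
  set.seed(77)
  rperm <- sample(seq_len(32)) # reaction permutation
  sperm <- sample(seq_len(32)) # species permutation
  relab <- reorder_network(net, rperm, sperm)
  # physical reaction i of `net` is reaction match(i, rperm) of `relab`
  pos <- match(seq_len(32), rperm)

  rng <- rng_stream(41, 0)
  counts <- initial_counts(net)
  counts_p <- initial_counts(relab)
  for (i in 1:150) {
    z <- rng(2)
    d <- direct_method_step(net, counts, z[1], z[2])
    if (is.na(d$fired)) break
    counts <- d$counts
    # map z1 into the interval selecting the same physical reaction in the
    # permuted ordering
    ap <- propensities(relab, counts_p)
    csp <- cumsum(ap)
    fp <- pos[d$fired]
    lo <- if (fp > 1) csp[fp - 1] else 0
    z1p <- (lo + ap[fp] / 2) / csp[length(csp)]
    dp <- direct_method_step(relab, counts_p, z1p, z[2])
    expect_identical(dp$fired, fp)
    expect_equal(dp$dt, d$dt, tolerance = 1e-10)
    counts_p <- dp$counts
  }
  # relabeled state equals the original state under the species map
  inv <- integer(32)
  inv[sperm] <- seq_len(32)
  expect_equal(unname(counts_p), unname(counts[sperm]))
})
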