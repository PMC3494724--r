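# Benchmark model generators.

test_that("cyclic chains have M = N reactions and conserve molecules", {
  net <- cyclic_chain(5)
  expect_equal(length(net$reactions), 5L)
  expect_identical(validate_network(net), character(0))
  res <- blockssa:::run_trajectory_r(net, 100, seed = 3)
  expect_equal(sum(res$state$counts), 5)

  big <- cyclic_chain(50000)
  expect_equal(length(big$reactions), 50000L)
  expect_error(cyclic_chain(1), "parameter error")
})

test_that("colloidal aggregation enumerates all pair channels", {
  # N = 4: aggregations (1,1), (1,2), (1,3), (2,2) plus 4 fragmentations
  net <- colloidal_aggregation(4)
  expect_equal(length(net$reactions), 8L)
  aggs <- Filter(function(r) r$type != 1L, net$reactions)
  pairs <- t(vapply(aggs, function(r) sort(r$reactants), integer(2)))
  expect_equal(pairs[order(pairs[, 1] + pairs[, 2], pairs[, 1]), ],
               rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2)),
               ignore_attr = TRUE)
  # independent enumeration oracle for the reaction count
  count_oracle <- function(N) 2 * sum(vapply(2:N, function(s)
    s %/% 2, numeric(1)))
  for (N in c(4, 7, 20))
    expect_equal(length(colloidal_aggregation(N)$reactions),
                 count_oracle(N))
  expect_error(colloidal_aggregation(2), "parameter error")
})

test_that("colloidal dependency maximum grows as 3N - 7", {
  for (N in c(10, 20)) {
    g <- build_dependency_graph(colloidal_aggregation(N))
    st <- connectivity_stats(g)
    # enumeration oracle: dependents from first principles
    net <- colloidal_aggregation(N)
    reactant_sets <- lapply(net$reactions, function(r) unique(r$reactants))
    changed_sets <- lapply(net$reactions, function(r)
      unique(c(r$reactants, r$products)))
    oracle_counts <- vapply(changed_sets, function(ch)
      sum(vapply(reactant_sets, function(rs) any(rs %in% ch), logical(1))),
      integer(1))
    expect_identical(st$counts, oracle_counts)
    expect_equal(st$max, 3 * N - 7)
  }
})

test_that("the strong-system scale builds and simulates", {
  net <- colloidal_aggregation(252)
  expect_identical(validate_network(net), character(0))
  tr <- run_trajectory(net, t_final = 1e9, record_dt = 1e9, seed = 1,
                       method = "direct", max_steps = 50,
                       record_species = 1L)
  expect_equal(tr$n_steps, 50)
})

test_that("random networks hit the requested dependency band reproducibly", {
  for (spec in list(c(64L, 64L), c(128L, 256L), c(1024L, 1024L))) {
    net <- random_network(spec[1], spec[2], dependency_range = c(8L, 16L),
                          seed = 11)
    expect_identical(validate_network(net), character(0))
    st <- connectivity_stats(build_dependency_graph(net))
    expect_true(all(st$counts >= 8 & st$counts <= 16))
  }

  # byte-identical regeneration under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(random_network(64, 64, seed = 5), f1)
  write_model(random_network(64, 64, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    readLines(f1),
    {
      write_model(random_network(64, 64, seed = 6), f2)
      readLines(f2)
    }))
})

test_that("a [2,2] dependency request reproduces chain connectivity", {
  net <- random_network(40, 40, dependency_range = c(2L, 2L), seed = 9)
  st <- connectivity_stats(build_dependency_graph(net))
  expect_equal(st$mean, 2)
  expect_equal(st$max, 2)
  # ... but it is not the canonical chain labelling
  expect_false(identical(
    vapply(net$reactions, function(r) r$reactants[1], integer(1)),
    1:40))
})

test_that("unconstrained random networks close the species flow", {
  net <- random_network(30, 45, dependency_range = NULL, seed = 13,
                        initial_count = 3L)
  expect_identical(validate_network(net), character(0))
  consumed <- unique(unlist(lapply(net$reactions, function(r) r$reactants)))
  produced <- unique(unlist(lapply(net$reactions, function(r) r$products)))
  expect_true(all(consumed %in% produced))
  # molecule-conserving by construction
  res <- blockssa:::run_trajectory_r(net, 50, seed = 2)
  expect_equal(sum(res$state$counts), 90)
})

test_that("infeasible dependency requests raise a generation error", {
  expect_error(random_network(12, 12, dependency_range = c(30L, 31L),
                              seed = 1, max_tries = 3L),
               "generation error")
  expect_error(random_network(10, 12, dependency_range = c(2L, 2L)),
               "generation error")
})
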