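# Species, reactions, propensities and the packed stoichiometric table.

test_that("mass-action propensities follow the three type formulas", {
  n <- reaction_network(c("A", "B", "C"), list(
    reaction(1L, 1L, 2L, k = 2.0),
    reaction(2L, c(1L, 2L), 3L, k = 0.5),
    reaction(3L, 1L, 2L, k = 1.0)))
  expect_equal(propensity(n$reactions[[1]], c(5, 0, 0)), 10.0)
  expect_equal(propensity(n$reactions[[2]], c(4, 6, 0)), 12.0)
  expect_equal(propensity(n$reactions[[3]], c(1, 0, 0)), 0.0)
  expect_equal(propensity(n$reactions[[3]], c(4, 0, 0)), 6.0)
  bad <- n$reactions[[1]]
  bad$type <- 9L
  expect_error(propensity(bad, c(1, 1, 1)), "invalid-model")
})

test_that("propensity is zero exactly when the reaction cannot fire", {
  # exhaustive over counts 0..10 for each type
  r1 <- reaction(1L, 1L, 2L)
  r2 <- reaction(2L, c(1L, 2L), 3L)
  r3 <- reaction(3L, 1L, 2L)
  st <- pack_stoichiometry(reaction_network(c("A", "B", "C"),
                                            list(r1, r2, r3)))
  for (x in 0:10) for (y in 0:10) {
    counts <- c(x, y, 0)
    expect_identical(propensity(r1, counts) == 0, x == 0)
    expect_identical(propensity(r2, counts) == 0, x == 0 || y == 0)
    expect_identical(propensity(r3, counts) == 0, x < 2)
    # firing with zero propensity is exactly what drives a count negative
    if (propensity(r1, counts) > 0)
      expect_silent(apply_stoichiometry(counts, 1L, st))
    if (propensity(r3, counts) > 0)
      expect_silent(apply_stoichiometry(counts, 3L, st))
  }
})

test_that("packing then unpacking the stoichiometric table is the identity", {
  n <- abc_network()
  tab <- pack_stoichiometry(n)
  expect_length(tab, 4L)
  expect_equal(sum(tab != 0), 3L) # three entries, one null slot
  got <- unpack_stoichiometry(tab)
  expect_equal(got$species, 1:3)
  expect_equal(got$delta, c(-1L, -1L, 1L))

  d <- dimer_network()
  tabd <- pack_stoichiometry(d)
  expect_equal(sum(tabd != 0), 2L)
  expect_equal(unpack_stoichiometry(tabd)$delta, c(-2L, 1L))

  # randomized round-trips over valid (species, delta) entries
  set.seed(42)
  for (i in 1:200) {
    sp0 <- sample(0:(2^29 - 1), 1)
    delta <- sample(c(-2L, -1L, 1L, 2L), 1)
    e <- blockssa:::unpack_entry(blockssa:::pack_entry(sp0, delta))
    expect_equal(c(e$species0, e$delta), c(sp0, delta))
  }
})

test_that("packing rejects field overflows and invalid deltas", {
  expect_error(blockssa:::pack_entry(2^29, 1L), "29-bit")
  expect_error(blockssa:::pack_entry(5, 0L), "invalid-model")
  expect_error(blockssa:::pack_entry(5, 3L), "invalid-model")
  # catalytic species cannot be packed (0 is not a representable delta)
  cat_net <- reaction_network(c("A", "B", "C"),
                              list(reaction(2L, c(1L, 2L), c(1L, 3L))))
  expect_error(pack_stoichiometry(cat_net), "catalytic")
})

test_that("applying stoichiometry updates exactly the listed species", {
  n <- abc_network(a = 3L, b = 2L, cc = 0L)
  st <- pack_stoichiometry(n)
  expect_equal(apply_stoichiometry(c(3, 2, 0), 1L, st), c(2, 1, 1))
  d <- dimer_network()
  std <- pack_stoichiometry(d)
  expect_equal(apply_stoichiometry(c(5, 0), 1L, std), c(3, 1))
  expect_error(apply_stoichiometry(c(1, 0), 1L, std),
               "internal-consistency")
})

test_that("validate_network reports violations without raising", {
  expect_identical(validate_network(cyclic_chain(6)), character(0))

  # reaction referencing a species index beyond N
  bad1 <- cyclic_chain(3)
  bad1$reactions[[2]]$products <- 4L
  v1 <- validate_network(bad1)
  expect_length(v1, 1L)
  expect_match(v1, "out of range")

  # type 2 with equal reactant indices (bypassing the constructor)
  bad2 <- cyclic_chain(3)
  bad2$reactions[[1]] <- structure(
    list(type = 2L, reactants = c(1L, 1L), products = 2L, k = 1),
    class = "ssa_reaction")
  v2 <- validate_network(bad2)
  expect_length(v2, 1L)
  expect_match(v2, "distinct")
})

test_that("summed propensities agree with the vector sum to 1e-9 relative", {
  net <- desk_random_network(64, seed = 7, initial_count = 5L)
  counts <- initial_counts(net)
  a <- propensities(net, counts)
  s <- 0
  for (j in seq_along(a)) s <- s + propensity(net$reactions[[j]], counts)
  expect_equal(s, sum(a), tolerance = 1e-9)
})

test_that("reaction constructor enforces type arity", {
  expect_error(reaction(1L, c(1L, 2L), 3L), "type 1")
  expect_error(reaction(2L, c(1L, 1L), 3L), "type 2")
  expect_error(reaction(2L, 1L, 3L), "type 2")
  expect_error(reaction(4L, 1L, 2L), "unknown")
  expect_error(reaction(1L, 1L, c(2L, 3L, 4L)), "at most 2")
  expect_silent(reaction(3L, 1L, c(2L, 2L))) # 2A -> 2B
})
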