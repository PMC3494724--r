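# Small fixture networks built in code.

# A -> 0 pure death process
decay_network <- function(n0 = 1000L, k = 1) {
  reaction_network(data.frame(name = "A", initial_count = as.integer(n0)),
                   list(reaction(1L, 1L, integer(0), k = k)))
}

# A + B -> C
abc_network <- function(a = 3L, b = 2L, cc = 0L) {
  reaction_network(data.frame(name = c("A", "B", "C"),
                              initial_count = c(a, b, cc)),
                   list(reaction(2L, c(1L, 2L), 3L, k = 1)))
}

# 2A -> B
dimer_network <- function(a = 5L, b = 0L) {
  reaction_network(data.frame(name = c("A", "B"),
                              initial_count = c(a, b)),
                   list(reaction(3L, 1L, 2L, k = 1)))
}

# the standard random consistent test network (desk scale)
desk_random_network <- function(N = 64L, seed = 2L, initial_count = 1L) {
  random_network(N, N, dependency_range = c(8L, 16L), seed = seed,
                 initial_count = initial_count)
}

# linear cumulative-sum selection oracle: smallest index with prefix >= target
linear_select_oracle <- function(a, targets) {
  cs <- cumsum(a)
  findInterval(targets, cs, left.open = TRUE) + 1L
}
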