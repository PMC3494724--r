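# Reaction networks: species, typed mass-action reactions, and the packed
# stoichiometric table.

#' Construct a reaction
#'
#' A reaction channel of one of the three elementary mass-action types:
#' type 1 is unimolecular (`A -> ...`), type 2 is bimolecular with distinct
#' reactants (`A + B -> ...`), and type 3 is bimolecular with identical
#' reactants (`2A -> ...`).
#'
#' @param type Integer reaction type, 1, 2 or 3.
#' @param reactants Integer species indices (1-based). One index for type 1;
#'   two distinct indices for type 2; either one index or the same index
#'   twice for type 3.
#' @param products Integer species indices of the product molecules, with
#'   repetition for double products (`c(3, 3)` means `-> 2 S3`). May be
#'   empty (degradation).
#' @param k Non-negative rate constant.
#' @return An object of class `ssa_reaction`.
#' @export
reaction <- function(type, reactants, products = integer(0), k = 1) {
  type <- as.integer(type)
  reactants <- as.integer(reactants)
  products <- as.integer(products)
  if (!type %in% 1:3) stop("invalid-model error: unknown reaction type ", type)
  if (type == 1L && length(reactants) != 1L)
    stop("invalid-model error: type 1 requires exactly 1 reactant")
  if (type == 2L && (length(reactants) != 2L ||
                     reactants[1] == reactants[2]))
    stop("invalid-model error: type 2 requires 2 distinct reactants")
  if (type == 3L) {
    if (length(reactants) == 1L) reactants <- rep(reactants, 2L)
    if (length(reactants) != 2L || reactants[1] != reactants[2])
      stop("invalid-model error: type 3 requires 2 identical reactants")
  }
  if (length(products) > 2L)
    stop("invalid-model error: at most 2 product molecules per reaction")
  if (!is.finite(k) || k < 0) stop("invalid-model error: rate constant ", k)
  structure(list(type = type, reactants = reactants, products = products,
                 k = as.numeric(k)),
            class = "ssa_reaction")
}

#' Construct a reaction network
#'
#' @param species A `data.frame` with columns `name` and `initial_count`, or
#'   a character vector of names (counts then default to `initial_count`).
#' @param reactions A list of [reaction()] objects.
#' @param initial_count Default count used when `species` is a name vector.
#' @return An object of class `ssa_network` with elements `species`
#'   (data.frame) and `reactions` (list).
#' @export
reaction_network <- function(species, reactions, initial_count = 1L) {
  if (is.character(species))
    species <- data.frame(name = species,
                          initial_count = as.integer(initial_count),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(species),
            all(c("name", "initial_count") %in% names(species)))
  species$name <- as.character(species$name)
  species$initial_count <- as.integer(species$initial_count)
  if (anyDuplicated(species$name)) stop("duplicate species names")
  if (nrow(species) < 1L || length(reactions) < 1L)
    stop("invalid-model error: need at least one species and one reaction")
  net <- structure(list(species = species, reactions = reactions),
                   class = "ssa_network")
  net
}

#' @export
print.ssa_network <- function(x, ...) {
  cat(sprintf("<ssa_network> %d species, %d reactions\n",
              nrow(x$species), length(x$reactions)))
  invisible(x)
}

n_species <- function(network) nrow(network$species)
n_reactions <- function(network) length(network$reactions)

#' Initial molecular counts of a network
#' @param network An `ssa_network`.
#' @return Named numeric vector of counts.
#' @export
initial_counts <- function(network) {
  stats::setNames(as.numeric(network$species$initial_count),
                  network$species$name)
}

# Net stoichiometric deltas of one reaction: data.frame(species, delta),
# deltas restricted to {-2,-1,+1,+2}; net-zero (catalytic) species are an
# invalid-model error because the packed format cannot represent delta 0.
reaction_stoichiometry <- function(r) {
  consumed <- if (r$type == 1L) r$reactants[1] else r$reactants
  all_sp <- sort(unique(c(consumed, r$products)))
  delta <- vapply(all_sp, function(s)
    sum(r$products == s) - sum(consumed == s), numeric(1))
  if (any(delta == 0))
    stop("invalid-model error: catalytic species (net delta 0) ",
         "cannot be represented in the packed stoichiometric table")
  if (any(delta < -2 | delta > 2))
    stop("invalid-model error: stoichiometric delta outside {-2,-1,+1,+2}")
  if (length(all_sp) > 4L)
    stop("invalid-model error: more than 4 species change count")
  data.frame(species = all_sp, delta = as.integer(delta))
}

#' Mass-action propensity of a reaction
#'
#' Computes `a = k * x` (type 1), `a = k * x_i * x_j` (type 2) or
#' `a = k * x * (x - 1) / 2` (type 3) from the current molecular counts.
#' The propensity is zero exactly when the reactants are insufficient for
#' the reaction to fire.
#'
#' @param reaction An [reaction()] object.
#' @param counts Numeric vector of non-negative species counts.
#' @return A single non-negative propensity.
#' @export
propensity <- function(reaction, counts) {
  r <- reaction
  unname(switch(as.character(r$type),
    "1" = r$k * counts[r$reactants[1]],
    "2" = r$k * counts[r$reactants[1]] * counts[r$reactants[2]],
    "3" = {
      x <- counts[r$reactants[1]]
      r$k * x * (x - 1) / 2
    },
    stop("invalid-model error: unknown reaction type ", r$type)))
}

#' Propensity vector of a network
#' @param network An `ssa_network`.
#' @param counts Species counts (defaults to the initial counts).
#' @return Numeric vector of length `M`.
#' @export
propensities <- function(network, counts = initial_counts(network)) {
  vapply(network$reactions, propensity, numeric(1), counts = counts)
}

# ---------------------------------------------------------------------------
# Packed stoichiometric table: one flat array of 4 entries per reaction; each
# entry packs a species index into a 29-bit field and the signed delta into a
# 3-bit field, so an entry is index * 8 + code with code in {1, 2, 6, 7}
# (two's-complement 3-bit +1, +2, -2, -1). Entry 0 is the reserved null.

.delta_code <- c("-2" = 6L, "-1" = 7L, "1" = 1L, "2" = 2L)
.code_delta <- c(`1` = 1L, `2` = 2L, `6` = -2L, `7` = -1L)
.max_species_index <- 2^29 - 1

pack_entry <- function(species0, delta) {
  if (species0 > .max_species_index || species0 < 0)
    stop("invalid-model error: species index ", species0,
         " exceeds the 29-bit field")
  code <- .delta_code[as.character(delta)]
  if (is.na(code))
    stop("invalid-model error: delta ", delta, " not in {-2,-1,+1,+2}")
  species0 * 8 + as.numeric(code)
}

unpack_entry <- function(entry) {
  if (entry == 0) return(NULL)
  code <- entry %% 8
  delta <- .code_delta[as.character(code)]
  if (is.na(delta)) stop("corrupt packed entry: ", entry)
  list(species0 = (entry - code) / 8, delta = as.integer(delta))
}

#' Pack the stoichiometry of a network into a flat bit-packed table
#'
#' The table stores, for each reaction, up to four `(species, delta)` entries
#' in a single flat numeric array; each entry holds the 0-based species index
#' in a 29-bit field and the delta in a 3-bit signed field. Unused slots hold
#' the reserved null entry 0. Packing followed by unpacking is the identity.
#'
#' @param network An `ssa_network`.
#' @return Object of class `stoich_table`: numeric vector of length `4 * M`.
#' @export
pack_stoichiometry <- function(network) {
  M <- n_reactions(network)
  tab <- numeric(4L * M)
  for (j in seq_len(M)) {
    st <- reaction_stoichiometry(network$reactions[[j]])
    for (q in seq_len(nrow(st)))
      tab[4L * (j - 1L) + q] <- pack_entry(st$species[q] - 1L, st$delta[q])
  }
  structure(tab, class = "stoich_table", M = M)
}

#' Unpack a stoichiometric table
#' @param table A `stoich_table`.
#' @param reaction_index Optional single reaction; if omitted, all reactions.
#' @return A `data.frame` with columns `reaction`, `species` (1-based) and
#'   `delta`.
#' @export
unpack_stoichiometry <- function(table, reaction_index = NULL) {
  M <- attr(table, "M")
  js <- if (is.null(reaction_index)) seq_len(M) else as.integer(reaction_index)
  out <- do.call(rbind, lapply(js, function(j) {
    rows <- lapply(1:4, function(q) {
      e <- unpack_entry(table[4L * (j - 1L) + q])
      if (is.null(e)) return(NULL)
      data.frame(reaction = j, species = e$species0 + 1L, delta = e$delta)
    })
    do.call(rbind, rows)
  }))
  if (is.null(out))
    out <- data.frame(reaction = integer(0), species = integer(0),
                      delta = integer(0))
  out
}

#' Apply the stoichiometry of a fired reaction to the species counts
#'
#' At most four species change count; the listed deltas are added and all
#' counts must remain non-negative -- a negative result signals that a
#' reaction fired with zero propensity (an internal-consistency error).
#'
#' @param counts Numeric vector of species counts.
#' @param reaction_index Index of the fired reaction.
#' @param stoich_table A `stoich_table` from [pack_stoichiometry()].
#' @return Updated counts vector.
#' @export
apply_stoichiometry <- function(counts, reaction_index, stoich_table) {
  for (q in 1:4) {
    e <- unpack_entry(stoich_table[4L * (reaction_index - 1L) + q])
    if (is.null(e)) next
    i <- e$species0 + 1L
    counts[i] <- counts[i] + e$delta
    if (counts[i] < 0)
      stop("internal-consistency error: count of species ", i,
           " went negative firing reaction ", reaction_index)
  }
  counts
}

#' Validate a reaction network
#'
#' Checks the structural invariants of the model (reactant arity per type,
#' index bounds, delta ranges, catalytic species, rate constants, counts)
#' and reports violations rather than raising.
#'
#' @param network An `ssa_network`.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_network <- function(network) {
  v <- character(0)
  N <- n_species(network)
  if (any(network$species$initial_count < 0))
    v <- c(v, "negative initial count")
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    pre <- sprintf("reaction %d: ", j)
    idx <- c(r$reactants, r$products)
    if (any(idx < 1 | idx > N)) {
      v <- c(v, paste0(pre, "species index out of range"))
      next
    }
    if (!r$type %in% 1:3) {
      v <- c(v, paste0(pre, "unknown type"))
      next
    }
    if (r$type == 1L && length(r$reactants) != 1L)
      v <- c(v, paste0(pre, "type 1 needs 1 reactant"))
    if (r$type == 2L && (length(r$reactants) != 2L ||
                         r$reactants[1] == r$reactants[2]))
      v <- c(v, paste0(pre, "type 2 needs 2 distinct reactants"))
    if (r$type == 3L && (length(r$reactants) != 2L ||
                         r$reactants[1] != r$reactants[2]))
      v <- c(v, paste0(pre, "type 3 needs 2 identical reactants"))
    if (length(r$products) > 2L)
      v <- c(v, paste0(pre, "more than 2 products"))
    if (!is.finite(r$k) || r$k < 0)
      v <- c(v, paste0(pre, "invalid rate constant"))
    st <- tryCatch(reaction_stoichiometry(r), error = function(e) e)
    if (inherits(st, "error"))
      v <- c(v, paste0(pre, conditionMessage(st)))
  }
  v
}

# Flattened model passed to the compiled engines (0-based indices).
as_engine_model <- function(network) {
  M <- n_reactions(network)
  N <- n_species(network)
  rtype <- vapply(network$reactions, function(r) r$type, integer(1))
  re1 <- vapply(network$reactions, function(r) r$reactants[1], integer(1)) - 1L
  re2 <- vapply(network$reactions, function(r)
    if (length(r$reactants) > 1L) r$reactants[2] else 0L, integer(1)) - 1L
  k <- vapply(network$reactions, function(r) r$k, numeric(1))
  st_sp <- rep.int(-1L, 4L * M)
  st_d <- rep.int(0L, 4L * M)
  for (j in seq_len(M)) {
    st <- reaction_stoichiometry(network$reactions[[j]])
    nq <- nrow(st)
    if (nq > 0) {
      st_sp[4L * (j - 1L) + seq_len(nq)] <- st$species - 1L
      st_d[4L * (j - 1L) + seq_len(nq)] <- st$delta
    }
  }
  list(M = M, N = N, rtype = rtype, re1 = re1, re2 = re2, k = k,
       st_sp = st_sp, st_d = st_d,
       x0 = as.numeric(network$species$initial_count))
}
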