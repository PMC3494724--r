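# Model files (JSON and TSV), trajectory/means TSV output, provenance.
#
# JSON schema:
#   {"species":  [{"name": "S1", "initial_count": 1}, ...],
#    "reactions":[{"type": 2, "reactants": ["S1","S2"],
#                  "products": ["S3","S3"], "k": 1}, ...]}
# TSV twin: one record per row; `species<TAB>name<TAB>count` rows followed
# by `reaction<TAB>type<TAB>reactants<TAB>products<TAB>k` rows with
# comma-joined species names.

#' Write a reaction network to a model file
#'
#' The format is chosen by the file extension: `.json` or `.tsv`.
#' Writing, reading back and writing again is byte-stable.
#'
#' @param network An `ssa_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") write_model_json(network, path)
  else if (ext == "tsv") write_model_tsv(network, path)
  else stop("unknown model format '.", ext, "' (use .json or .tsv)")
  invisible(path)
}

write_model_json <- function(network, path) {
  nm <- network$species$name
  obj <- list(
    species = lapply(seq_len(nrow(network$species)), function(i)
      list(name = nm[i],
           initial_count = network$species$initial_count[i])),
    reactions = lapply(network$reactions, function(r)
      list(type = r$type, reactants = I(nm[r$reactants]),
           products = I(nm[r$products]), k = r$k)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, path)
}

write_model_tsv <- function(network, path) {
  nm <- network$species$name
  sp <- sprintf("species\t%s\t%d", nm, network$species$initial_count)
  rx <- vapply(network$reactions, function(r)
    sprintf("reaction\t%d\t%s\t%s\t%s", r$type,
            paste(nm[r$reactants], collapse = ","),
            paste(nm[r$products], collapse = ","),
            format(r$k, digits = 17)), character(1))
  writeLines(c("# blockssa model v1", sp, rx), path)
}

#' Read a reaction network from a model file
#'
#' @param path A `.json` or `.tsv` model file.
#' @return An `ssa_network`. Malformed files raise a parse error naming the
#'   offending record; structural violations raise a validation report.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  net <- if (ext == "json") read_model_json(path)
         else if (ext == "tsv") read_model_tsv(path)
         else stop("unknown model format '.", ext, "'")
  v <- validate_network(net)
  if (length(v) > 0)
    stop("validation report for ", path, ":\n  ",
         paste(v, collapse = "\n  "))
  net
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$species) || is.null(obj$reactions))
    stop("parse error in ", path, ": need 'species' and 'reactions'")
  species <- data.frame(
    name = vapply(obj$species, function(s) as.character(s$name),
                  character(1)),
    initial_count = vapply(obj$species, function(s)
      as.integer(s$initial_count), integer(1)),
    stringsAsFactors = FALSE)
  build_reactions <- function(rlist) {
    lapply(seq_along(rlist), function(j) {
      r <- rlist[[j]]
      res <- unlist(r$reactants)
      pro <- unlist(r$products)
      if (length(res) > 2L)
        stop("parse error in reaction ", j, ": more than 2 reactants")
      ridx <- match(res, species$name)
      pidx <- if (length(pro)) match(pro, species$name) else integer(0)
      if (anyNA(ridx) || anyNA(pidx)) {
        bad <- c(res[is.na(ridx)], pro[is.na(pidx)])
        stop("parse error in reaction ", j, ": unknown species ",
             paste(bad, collapse = ", "))
      }
      reaction(r$type, ridx, pidx, k = as.numeric(r$k))
    })
  }
  reaction_network(species, build_reactions(obj$reactions))
}

read_model_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[`, character(1), 1L)
  sp <- parts[kind == "species"]
  rx <- parts[kind == "reaction"]
  if (any(!kind %in% c("species", "reaction")))
    stop("parse error in ", path, ": unknown record type '",
         kind[!kind %in% c("species", "reaction")][1], "'")
  if (length(sp) == 0L) stop("parse error in ", path, ": no species rows")
  species <- data.frame(
    name = vapply(sp, `[`, character(1), 2L),
    initial_count = as.integer(vapply(sp, `[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  reactions <- lapply(seq_along(rx), function(j) {
    f <- rx[[j]]
    if (length(f) < 5L)
      stop("parse error in ", path, " reaction row ", j,
           ": expected 5 fields")
    res <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    pro <- if (nzchar(f[4])) strsplit(f[4], ",", fixed = TRUE)[[1]]
           else character(0)
    ridx <- match(res, species$name)
    pidx <- if (length(pro)) match(pro, species$name) else integer(0)
    if (anyNA(ridx) || anyNA(pidx))
      stop("parse error in ", path, " reaction row ", j,
           ": unknown species ",
           paste(c(res[is.na(ridx)], pro[is.na(pidx)]), collapse = ", "))
    reaction(as.integer(f[2]), ridx, pidx, k = as.numeric(f[5]))
  })
  reaction_network(species, reactions)
}

#' Write a trajectory or ensemble means as TSV
#'
#' Header row `time<TAB>species...`, one grid time per row.
#'
#' @param x An `ssa_trajectory` or `ensemble_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(x, path) {
  m <- if (inherits(x, "ensemble_summary")) x$mean else x$counts
  df <- data.frame(time = x$time, m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_residual_tsv <- function(report, time, path) {
  df <- data.frame(time = time, report$residual, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Provenance record: configuration, seeds and versions of a run. Contains
# no timestamps so identical runs produce byte-identical output trees.
write_provenance <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("blockssa"))
  config$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}
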