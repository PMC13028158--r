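read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
}

# map a data-frame row back to its line number in the file (for diagnostics)
table_line_numbers <- function(path, n) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  which(keep)[-1][seq_len(n)]   # drop header
}

#' Read a species table
#'
#' Tab-separated with columns `id`, `formula`, `role` and optionally
#' `g_rel`, `degeneracy`, `provenance`, `anchor`, `tags`, `note`, or the
#' component columns `e_zpe`, `h_corr`, `s_gas`, `g_solv`. `#` lines are
#' comments. Formulas are validated on read; failures cite the file line.
#'
#' @param path File path.
#' @param components_path Optional companion table (`id`, `e_zpe`,
#'   `h_corr`, `s_gas`, `g_solv`) supplying component energies for rows
#'   without `g_rel`; `G_rel` is then assembled and computed on the
#'   reference scale.
#' @param refs A [reference_set()].
#' @return A [species_registry()].
#' @export
read_species_table <- function(path, components_path = NULL,
                               refs = reference_set()) {
  df <- read_tsv_checked(path)
  req <- c("id", "formula", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path,
                                 paste(miss, collapse = ", ")), call. = FALSE)
  ln <- table_line_numbers(path, nrow(df))
  if (anyDuplicated(df$id)) {
    d <- df$id[duplicated(df$id)][1]
    stop(sprintf("%s line %d: duplicate species id '%s'",
                 path, ln[which(df$id == d)[2]], d), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_formula(df$formula[i]), error = function(e) {
      stop(sprintf("%s line %d: %s", path, ln[i], conditionMessage(e)), call. = FALSE)
    })
    if (!df$role[i] %in% c("minimum", "transition_state")) {
      stop(sprintf("%s line %d: bad role '%s'", path, ln[i], df$role[i]),
           call. = FALSE)
    }
  }
  if (!is.null(df$g_rel)) df$g_rel <- suppressWarnings(as.numeric(df$g_rel))
  if (!is.null(df$degeneracy)) df$degeneracy <- suppressWarnings(as.integer(df$degeneracy))
  if (!is.null(components_path)) {
    comp <- read_tsv_checked(components_path)
    for (col in c("e_zpe", "h_corr", "s_gas", "g_solv")) {
      comp[[col]] <- as.numeric(comp[[col]])
    }
    need <- which(is.na(df$g_rel))
    cidx <- match(df$id[need], comp$id)
    still <- need[is.na(cidx)]
    if (length(still)) stop(sprintf(
      "species without g_rel or components: %s",
      paste(df$id[still], collapse = ", ")), call. = FALSE)
    comp_full <- comp[match(df$id, comp$id), ]
    comp_full$formula <- df$formula
    attr(comp_full, "refs") <- refs
    # assemble energies for everything available, then fill missing g_rel
    have_comp <- !is.na(comp_full$e_zpe)
    sub <- comp_full[have_comp, ]
    sub$id <- df$id[have_comp]
    g <- grel_from_components(sub)
    df$g_rel[need] <- g[df$id[need]]
  }
  if (any(is.na(df$g_rel))) {
    bad <- df$id[is.na(df$g_rel)]
    stop(sprintf("species lacking both g_rel and components: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  species_registry(df)
}

#' Write a species table
#'
#' @param registry A [species_registry()].
#' @param path Output path.
#' @export
write_species_table <- function(registry, path) {
  df <- as.data.frame(registry)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a reaction table
#'
#' Tab-separated with columns `id`, `reactants`, `products` and optionally
#' `ts_id`, `category`, `delta_g_printed`, `flag`, `provenance`, `note`.
#'
#' @param path File path.
#' @return Data frame ready for [free_energy_map()].
#' @export
read_reaction_table <- function(path) {
  df <- read_tsv_checked(path)
  if (!is.null(df$delta_g_printed)) {
    df$delta_g_printed <- suppressWarnings(as.numeric(df$delta_g_printed))
  }
  df
}

#' Write a reaction table
#'
#' @param map An `fe_map`.
#' @param path Output path.
#' @export
write_reaction_table <- function(map, path) {
  keep <- intersect(c("id", "reactants", "products", "ts_id", "category",
                      "delta_g_printed", "flag", "provenance", "note"),
                    names(map$reactions))
  utils::write.table(map$reactions[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read isomer-group definitions
#'
#' Minimal YAML-style subset: top-level `label:` blocks, each with indented
#' `members:` and optional `exchange:` inline lists (`[a, b, c]`). `#`
#' starts a comment.
#'
#' @param path File path.
#' @param map Optional `fe_map` to validate balanceability against.
#' @return Named list of [isomer_group()]s.
#' @export
read_group_file <- function(path, map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  groups <- list()
  current <- NULL
  parse_list <- function(s) {
    s <- trimws(sub("^\\[", "", sub("\\]$", "", trimws(s))))
    if (!nzchar(s)) return(character(0))
    trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(trimws(l))) next
    if (!grepl("^\\s", l)) {
      current <- sub(":\\s*$", "", trimws(l))
      groups[[current]] <- list(members = character(0),
                                exchange = c("H2O", "H2SO3"))
    } else {
      if (is.null(current)) stop(sprintf("%s line %d: indented entry before any label",
                                         path, i), call. = FALSE)
      kv <- strsplit(trimws(l), ":", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (!key %in% c("members", "exchange")) {
        stop(sprintf("%s line %d: unknown key '%s'", path, i, key), call. = FALSE)
      }
      groups[[current]][[key]] <- parse_list(paste(kv[-1], collapse = ":"))
    }
  }
  out <- lapply(names(groups), function(lbl) {
    isomer_group(groups[[lbl]]$members, label = lbl,
                 exchange = groups[[lbl]]$exchange, map = map)
  })
  stats::setNames(out, names(groups))
}

#' Export a free-energy map as GraphML
#'
#' Species become nodes (attributes `g_rel`, `role`, `kind = "species"`);
#' each reaction becomes a hyperedge-expansion node (`kind = "reaction"`,
#' attributes `category`, `delta_g`) with stoichiometry-weighted edges from
#' reactants and to products.
#'
#' @param map An `fe_map`.
#' @param path Output path.
#' @export
export_graphml <- function(map, path) {
  sp <- map$species
  nodes <- data.frame(name = c(sp$id, map$reactions$id),
                      kind = c(rep("species", nrow(sp)),
                               rep("reaction", nrow(map$reactions))),
                      g_rel = c(sp$g_rel, rep(NA_real_, nrow(map$reactions))),
                      role = c(sp$role, map$reactions$category),
                      stringsAsFactors = FALSE)
  edges <- list()
  for (i in seq_len(nrow(map$reactions))) {
    rid <- map$reactions$id[i]
    for (s in names(map$lhs[[i]])) {
      edges[[length(edges) + 1L]] <- data.frame(from = s, to = rid,
                                                weight = map$lhs[[i]][[s]])
    }
    for (s in names(map$rhs[[i]])) {
      edges[[length(edges) + 1L]] <- data.frame(from = rid, to = s,
                                                weight = map$rhs[[i]][[s]])
    }
  }
  g <- igraph::graph_from_data_frame(do.call(rbind, edges), directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a free-energy map as JSON
#'
#' @param map An `fe_map`.
#' @param path Output path (or `NULL` to return the JSON string).
#' @export
export_map_json <- function(map, path = NULL) {
  doc <- list(
    reference_set = map$refs$ids,
    species = as.data.frame(map$species),
    reactions = map$reactions,
    delta_g = as.list(stats::setNames(
      vapply(map$reactions$id, function(id) reaction_delta_g(map, id), numeric(1)),
      map$reactions$id)))
  js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Run configuration
#'
#' @param temperature Kelvin.
#' @param entropy_fraction Retained fraction of gas-phase entropy.
#' @param barrierless_barrier Imputed barrier for TS-less steps, kcal/mol.
#' @param barrier_offset Global barrier shift, kcal/mol.
#' @param audit_tol Hess-residual tolerance, kcal/mol.
#' @param seed Integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(temperature = T_STANDARD, entropy_fraction = 0.5,
                       barrierless_barrier = 2.0, barrier_offset = 0,
                       audit_tol = 0.01, seed = 1L) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (audit_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(temperature = temperature, entropy_fraction = entropy_fraction,
                 barrierless_barrier = barrierless_barrier,
                 barrier_offset = barrier_offset, audit_tol = audit_tol,
                 seed = as.integer(seed)), class = "run_config")
}
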