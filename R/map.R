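#' Build a species registry
#'
#' @param df Data frame with columns `id`, `formula`, `role` (one of
#'   `"minimum"`, `"transition_state"`), and optionally `g_rel`,
#'   `degeneracy`, `provenance`, `tags`, `note`.
#' @return A validated data frame of class `species_registry`, with the
#'   element-count matrix attached as attribute `"elements"`.
#' @export
species_registry <- function(df) {
  req <- c("id", "formula", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("species table lacks column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop(sprintf("duplicate species id(s): %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
         call. = FALSE)
  }
  bad_role <- !df$role %in% c("minimum", "transition_state")
  if (any(bad_role)) {
    stop(sprintf("invalid role for species %s (must be minimum or transition_state)",
                 paste(df$id[bad_role], collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$g_rel)) df$g_rel <- NA_real_
  df$g_rel <- as.numeric(df$g_rel)
  if (is.null(df$degeneracy)) df$degeneracy <- 1L
  df$degeneracy[is.na(df$degeneracy)] <- 1L
  if (is.null(df$provenance)) df$provenance <- NA_character_
  if (is.null(df$tags)) df$tags <- ""
  df$tags[is.na(df$tags)] <- ""
  if (is.null(df$note)) df$note <- ""
  E <- formula_matrix(df$formula)
  colnames(E) <- df$id
  rownames(df) <- NULL
  structure(df, elements = E, class = c("species_registry", "data.frame"))
}

# Parse a reaction side like "2 CO2 + 4 H2 + H2SO3" into a named
# multiplicity vector. Coefficient and id are separated by whitespace.
parse_side <- function(s) {
  s <- trimws(s)
  if (!nzchar(s) || is.na(s)) return(stats::setNames(numeric(0), character(0)))
  toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([0-9]+(?:\\.[0-9]+)?)[[:space:]]+(.+)$", tok))[[1]]
    if (length(m) == 3L) {
      coef <- as.numeric(m[2]); id <- m[3]
    } else {
      coef <- 1; id <- tok
    }
    out[id] <- (if (id %in% names(out)) out[[id]] else 0) + coef
  }
  out
}

format_side <- function(v) {
  if (!length(v)) return("")
  paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
}

REACTION_CATEGORIES <- c("adduct_formation", "rearrangement", "dehydration",
                         "enolization", "tautomerization", "aldol",
                         "retro_aldol", "cannizzaro", "ring_closure", "other")

#' Construct a free-energy map
#'
#' A free-energy map bundles a species registry (with `G_rel` values on the
#' common reference scale), a reaction list, and the reference set. Every
#' species id referenced by a reaction must exist; every transition-state
#' species must be attached to exactly one reaction via `ts_id`.
#'
#' @param species A [species_registry()] or a data frame acceptable to it.
#' @param reactions Data frame with columns `id`, `reactants`, `products`
#'   (sides written like `"17 + 1 + H2O"`), and optionally `ts_id`,
#'   `category`, `delta_g_printed`, `flag`, `provenance`, `note`.
#' @param refs A [reference_set()].
#' @param check_balance If `TRUE` (default), error on any element-imbalanced
#'   reaction.
#' @return Object of class `fe_map`.
#' @export
free_energy_map <- function(species, reactions, refs = reference_set(),
                            check_balance = TRUE) {
  if (!inherits(species, "species_registry")) species <- species_registry(species)
  rx <- as.data.frame(reactions, stringsAsFactors = FALSE)
  req <- c("id", "reactants", "products")
  miss <- setdiff(req, names(rx))
  if (length(miss)) stop(sprintf("reaction table lacks column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids", call. = FALSE)
  if (is.null(rx$ts_id)) rx$ts_id <- rep(NA_character_, nrow(rx))
  rx$ts_id[!is.na(rx$ts_id) & rx$ts_id == ""] <- NA_character_
  if (is.null(rx$category)) rx$category <- rep("other", nrow(rx))
  bad_cat <- !rx$category %in% REACTION_CATEGORIES
  if (any(bad_cat)) stop(sprintf("unknown reaction category: %s",
                                 paste(unique(rx$category[bad_cat]), collapse = ", ")),
                         call. = FALSE)
  if (is.null(rx$delta_g_printed)) rx$delta_g_printed <- rep(NA_real_, nrow(rx))
  rx$delta_g_printed <- as.numeric(rx$delta_g_printed)
  if (is.null(rx$flag)) rx$flag <- rep("", nrow(rx))
  rx$flag[is.na(rx$flag)] <- ""
  if (is.null(rx$provenance)) rx$provenance <- rep(NA_character_, nrow(rx))
  if (is.null(rx$note)) rx$note <- rep("", nrow(rx))

  lhs <- lapply(rx$reactants, parse_side)
  rhs <- lapply(rx$products, parse_side)
  all_ids <- unique(c(unlist(lapply(lhs, names)), unlist(lapply(rhs, names))))
  unknown <- setdiff(all_ids, species$id)
  if (length(unknown)) stop(sprintf("reaction(s) reference unknown species: %s",
                                    paste(unknown, collapse = ", ")), call. = FALSE)
  ts_ids <- rx$ts_id[!is.na(rx$ts_id)]
  unknown_ts <- setdiff(ts_ids, species$id)
  if (length(unknown_ts)) stop(sprintf("unknown transition-state id(s): %s",
                                       paste(unknown_ts, collapse = ", ")), call. = FALSE)
  role_of <- stats::setNames(species$role, species$id)
  not_ts <- ts_ids[role_of[ts_ids] != "transition_state"]
  if (length(not_ts)) stop(sprintf("ts_id refers to non-transition-state species: %s",
                                   paste(unique(not_ts), collapse = ", ")), call. = FALSE)
  multi <- names(which(table(ts_ids) > 1L))
  if (length(multi)) stop(sprintf("transition state attached to more than one reaction: %s",
                                  paste(multi, collapse = ", ")), call. = FALSE)
  orphan <- setdiff(species$id[species$role == "transition_state"], ts_ids)
  if (length(orphan)) stop(sprintf("transition-state species not attached to any reaction: %s",
                                   paste(orphan, collapse = ", ")), call. = FALSE)

  map <- structure(list(species = species, reactions = rx,
                        lhs = lhs, rhs = rhs, refs = refs),
                   class = "fe_map")
  if (check_balance) {
    for (i in seq_len(nrow(rx))) {
      imb <- element_balance_check(map, rx$id[i])
      if (length(imb)) {
        stop(sprintf("reaction %s is element-imbalanced: %s", rx$id[i],
                     paste(sprintf("%s%+d", names(imb), imb), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  map
}

#' @export
print.fe_map <- function(x, ...) {
  cat(sprintf("<fe_map> %d species (%d transition states), %d reactions\n",
              nrow(x$species), sum(x$species$role == "transition_state"),
              nrow(x$reactions)))
  cat(sprintf("  reference set: %s (G_rel = 0)\n", paste(x$refs$ids, collapse = ", ")))
  invisible(x)
}

map_grel <- function(map) {
  g <- stats::setNames(map$species$g_rel, map$species$id)
  g[map$refs$ids[map$refs$ids %in% names(g)]] <- 0
  # reference species always contribute zero even if absent from the registry
  for (r in map$refs$ids) if (!r %in% names(g)) g[r] <- 0
  g
}

rxn_index <- function(map, reaction_id) {
  i <- match(reaction_id, map$reactions$id)
  if (is.na(i)) stop(sprintf("unknown reaction id '%s'", reaction_id), call. = FALSE)
  i
}
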