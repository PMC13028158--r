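#' Define a group of interconvertible isomers or adducts
#'
#' Members must be mutually balanceable using only the exchange species
#' (typically water and/or H2SO3, which sit at the reference state and
#' contribute zero free energy): the element-count difference between any
#' member and the first must lie in the span of the exchange formulas.
#'
#' @param members Character vector of member species ids.
#' @param label Human-readable group label.
#' @param exchange Character vector of reference species ids allowed to
#'   balance members against each other (default `c("H2O", "H2SO3")`).
#' @param map The `fe_map` providing formulas (needed for the
#'   balanceability check); if `NULL` the check is deferred.
#' @return Object of class `isomer_group`.
#' @export
isomer_group <- function(members, label = "group",
                         exchange = c("H2O", "H2SO3"), map = NULL) {
  if (!length(members)) stop("empty isomer group", call. = FALSE)
  grp <- structure(list(members = as.character(members), label = label,
                        exchange = exchange), class = "isomer_group")
  if (!is.null(map)) check_group_balanceable(grp, map)
  grp
}

check_group_balanceable <- function(group, map) {
  E <- attr(map$species, "elements")
  missing_ids <- setdiff(group$members, colnames(E))
  if (length(missing_ids)) stop(sprintf("group '%s' references unknown species: %s",
                                        group$label, paste(missing_ids, collapse = ", ")),
                                call. = FALSE)
  X <- formula_matrix(group$exchange)
  base <- E[, group$members[1]]
  for (m in group$members[-1]) {
    v <- E[, m] - base
    ok <- tryCatch({ rat_solve(X, as.integer(v)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf(
      "group '%s': member %s not balanceable against %s using exchange species {%s}",
      group$label, m, group$members[1], paste(group$exchange, collapse = ", ")),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Boltzmann populations of an isomer group
#'
#' Equilibrium fraction of member i is proportional to
#' `g_i * exp(-(G_rel,i - min G_rel) / RT)` where `g_i` is the degeneracy
#' (2 for species standing in for an enantiomer pair). Exchange species are
#' at reference activity and do not shift the distribution.
#'
#' @param group An [isomer_group()] (or character vector of ids).
#' @param map An `fe_map` carrying `G_rel` and degeneracies.
#' @param temperature Kelvin (default 298.15).
#' @return Data frame with columns `id`, `g_rel`, `degeneracy`, `fraction`,
#'   sorted by descending fraction.
#' @export
boltzmann_distribution <- function(group, map, temperature = T_STANDARD) {
  if (is.character(group)) group <- isomer_group(group)
  check_group_balanceable(group, map)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  sp <- map$species
  idx <- match(group$members, sp$id)
  g_rel <- sp$g_rel[idx]
  if (anyNA(g_rel)) stop(sprintf("missing G_rel for: %s",
                                 paste(group$members[is.na(g_rel)], collapse = ", ")),
                         call. = FALSE)
  deg <- sp$degeneracy[idx]
  w <- deg * exp(-(g_rel - min(g_rel)) / (R_KCAL * temperature))
  out <- data.frame(id = group$members, g_rel = g_rel, degeneracy = deg,
                    fraction = w / sum(w), stringsAsFactors = FALSE)
  out[order(-out$fraction, out$id), , drop = FALSE]
}

#' Rank isomer-group members by stability
#'
#' Ascending `G_rel` order; ties (within `tie_tol`) are broken
#' lexicographically by id and reported in a shared `tie_block`.
#'
#' @inheritParams boltzmann_distribution
#' @param tie_tol Energies closer than this are a tie (default 1e-9).
#' @return Data frame with `rank`, `id`, `g_rel`, `gap_to_best`,
#'   `gap_to_prev`, `tie_block`.
#' @export
rank_isomers <- function(group, map, tie_tol = 1e-9) {
  if (is.character(group)) group <- isomer_group(group)
  check_group_balanceable(group, map)
  sp <- map$species
  idx <- match(group$members, sp$id)
  g_rel <- sp$g_rel[idx]
  if (anyNA(g_rel)) stop(sprintf("missing G_rel for: %s",
                                 paste(group$members[is.na(g_rel)], collapse = ", ")),
                         call. = FALSE)
  ord <- order(g_rel, group$members)
  g <- g_rel[ord]
  tie_block <- cumsum(c(1, diff(g) > tie_tol))
  data.frame(rank = seq_along(ord), id = group$members[ord], g_rel = g,
             gap_to_best = g - g[1], gap_to_prev = c(0, diff(g)),
             tie_block = tie_block, stringsAsFactors = FALSE)
}

#' Speciation report for a set of groups
#'
#' @param groups Named list of [isomer_group()]s.
#' @param map An `fe_map`.
#' @param temperature Kelvin.
#' @return Data frame: `group`, `id`, `g_rel`, `fraction`, `rank`.
#' @export
speciation_report <- function(groups, map, temperature = T_STANDARD) {
  out <- lapply(groups, function(grp) {
    bd <- boltzmann_distribution(grp, map, temperature)
    rk <- rank_isomers(grp, map)
    bd$rank <- rk$rank[match(bd$id, rk$id)]
    bd$group <- grp$label
    bd[, c("group", "id", "g_rel", "fraction", "rank")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
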