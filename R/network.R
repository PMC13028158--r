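#' Per-element imbalance of a reaction
#'
#' @param map An [free_energy_map()].
#' @param reaction_id Reaction id.
#' @return Named integer vector of signed imbalances (products minus
#'   reactants), empty when the reaction is balanced.
#' @export
element_balance_check <- function(map, reaction_id) {
  i <- rxn_index(map, reaction_id)
  E <- attr(map$species, "elements")
  tot <- c(C = 0, H = 0, O = 0, S = 0)
  for (s in names(map$lhs[[i]])) tot <- tot - map$lhs[[i]][[s]] * E[, s]
  for (s in names(map$rhs[[i]])) tot <- tot + map$rhs[[i]][[s]] * E[, s]
  imb <- round(tot)
  imb[imb != 0]
}

#' Reaction free energy from the map
#'
#' `dG = sum of product G_rel - sum of reactant G_rel`, with multiplicity.
#' Reference species contribute exactly zero.
#'
#' @inheritParams element_balance_check
#' @return `dG` in kcal/mol.
#' @export
reaction_delta_g <- function(map, reaction_id) {
  i <- rxn_index(map, reaction_id)
  g <- map_grel(map)
  ids <- c(names(map$lhs[[i]]), names(map$rhs[[i]]))
  missing_g <- ids[is.na(g[ids])]
  if (length(missing_g)) {
    stop(sprintf("missing G_rel for: %s", paste(unique(missing_g), collapse = ", ")),
         call. = FALSE)
  }
  sum(map$rhs[[i]] * g[names(map$rhs[[i]])]) -
    sum(map$lhs[[i]] * g[names(map$lhs[[i]])])
}

#' Forward and reverse activation barriers
#'
#' Compares the transition-state `G_rel` with the reactant and product
#' sums. The identity `forward - reverse = dG` holds by construction. A
#' transition state lying below the reactants or products is reported with
#' a `submerged` flag rather than silently returning a negative barrier.
#'
#' @inheritParams element_balance_check
#' @return A list of class `activation_barriers` with elements `forward`,
#'   `reverse`, `delta_g`, `ts_id`, `submerged` (logical), and
#'   `has_barrier`. Reactions without a `ts_id` yield `has_barrier = FALSE`
#'   and `NA` barriers: a typed "no-barrier" result distinct from zero.
#' @export
activation_barriers <- function(map, reaction_id) {
  i <- rxn_index(map, reaction_id)
  dG <- reaction_delta_g(map, reaction_id)
  ts <- map$reactions$ts_id[i]
  if (is.na(ts)) {
    return(structure(list(forward = NA_real_, reverse = NA_real_, delta_g = dG,
                          ts_id = NA_character_, submerged = FALSE,
                          has_barrier = FALSE),
                     class = "activation_barriers"))
  }
  g <- map_grel(map)
  g_ts <- g[[ts]]
  if (is.na(g_ts)) stop(sprintf("missing G_rel for transition state %s", ts),
                        call. = FALSE)
  fwd <- g_ts - sum(map$lhs[[i]] * g[names(map$lhs[[i]])])
  rev <- g_ts - sum(map$rhs[[i]] * g[names(map$rhs[[i]])])
  structure(list(forward = fwd, reverse = rev, delta_g = dG, ts_id = ts,
                 submerged = (fwd < 0 || rev < 0), has_barrier = TRUE),
            class = "activation_barriers")
}

#' @export
print.activation_barriers <- function(x, ...) {
  if (!x$has_barrier) {
    cat(sprintf("no transition state (dG = %.1f kcal/mol)\n", x$delta_g))
  } else {
    cat(sprintf("dG^ fwd = %.1f, rev = %.1f, dG = %.1f kcal/mol (TS %s)%s\n",
                x$forward, x$reverse, x$delta_g, x$ts_id,
                if (x$submerged) " [submerged barrier]" else ""))
  }
  invisible(x)
}

# Stoichiometric matrix over all species appearing in reactions
# (products positive), columns = reactions in table order.
stoich_matrix <- function(map) {
  ids <- map$species$id
  N <- matrix(0, length(ids), nrow(map$reactions),
              dimnames = list(ids, map$reactions$id))
  for (i in seq_len(nrow(map$reactions))) {
    for (s in names(map$lhs[[i]])) N[s, i] <- N[s, i] - map$lhs[[i]][[s]]
    for (s in names(map$rhs[[i]])) N[s, i] <- N[s, i] + map$rhs[[i]][[s]]
  }
  N
}

#' Hess-cycle residuals of a free-energy map
#'
#' Because `G_rel` is a state function, the signed sum of reaction free
#' energies around any closed cycle of the reaction network must vanish.
#' Cycles are the rational null space of the stoichiometric matrix
#' (reactions ordered lexicographically by id, so the basis is
#' deterministic). Residuals are computed from per-reaction `delta_g`
#' values: stored values when `delta_g` is supplied on the reaction table
#' (as after corruption injection), else recomputed from the registry.
#'
#' @param map An `fe_map`.
#' @return Data frame with one row per independent cycle: `cycle` (a
#'   readable signed combination), `residual` (kcal/mol), and the member
#'   reaction ids in `members` (list column). Zero rows for an acyclic map.
#' @export
hess_cycle_residuals <- function(map) {
  ord <- order(map$reactions$id)
  N <- stoich_matrix(map)[, ord, drop = FALSE]
  dg <- reaction_delta_g_all(map)[ord]
  if (ncol(N) == 0L) {
    return(data.frame(cycle = character(0), residual = numeric(0)))
  }
  B <- rat_nullspace(round(N * 840) )  # scale to clear any fractional stoich (840 = lcm 1..8)
  if (ncol(B) == 0L) {
    out <- data.frame(cycle = character(0), residual = numeric(0))
    out$members <- list()
    return(out)
  }
  rxids <- colnames(N)
  res <- numeric(ncol(B)); lab <- character(ncol(B)); mem <- vector("list", ncol(B))
  for (k in seq_len(ncol(B))) {
    c_k <- B[, k]
    res[k] <- sum(c_k * dg)
    nz <- which(c_k != 0)
    lab[k] <- paste(sprintf("%+g %s", c_k[nz], rxids[nz]), collapse = " ")
    mem[[k]] <- rxids[nz]
  }
  out <- data.frame(cycle = lab, residual = res, stringsAsFactors = FALSE)
  out$members <- mem
  out
}

# Per-reaction delta G: stored column `delta_g` wins (used by the
# corruption machinery), else computed from the registry.
reaction_delta_g_all <- function(map) {
  stored <- map$reactions[["delta_g"]]   # [[ avoids partial-matching delta_g_printed
  vapply(seq_len(nrow(map$reactions)), function(i) {
    if (!is.null(stored) && !is.na(stored[i])) stored[i]
    else reaction_delta_g(map, map$reactions$id[i])
  }, numeric(1))
}

#' Audit a free-energy map for thermodynamic consistency
#'
#' Checks element balance of every reaction, compares any stored/printed
#' per-reaction free energies against the registry arithmetic, and
#' evaluates all Hess-cycle residuals.
#'
#' @param map An `fe_map`.
#' @param tol Residual tolerance in kcal/mol (default 0.01).
#' @param printed_tol Tolerance for printed-vs-computed `delta_g`
#'   comparisons (default 0.15, the accumulated-rounding band for values
#'   printed to 0.1 kcal/mol); reactions whose `flag` is nonempty are
#'   reported but do not fail the audit.
#' @return List of class `map_audit` with elements `ok`, `imbalanced`,
#'   `cycle_residuals`, `max_residual`, `printed_mismatch`.
#' @export
audit_map <- function(map, tol = 0.01, printed_tol = 0.15) {
  imb <- list()
  for (id in map$reactions$id) {
    v <- element_balance_check(map, id)
    if (length(v)) imb[[id]] <- v
  }
  cyc <- hess_cycle_residuals(map)
  max_res <- if (nrow(cyc)) max(abs(cyc$residual)) else 0
  pm <- data.frame(id = character(0), printed = numeric(0), computed = numeric(0),
                   flag = character(0), stringsAsFactors = FALSE)
  has_printed <- !is.na(map$reactions$delta_g_printed)
  for (i in which(has_printed)) {
    comp <- reaction_delta_g(map, map$reactions$id[i])
    dev <- abs(map$reactions$delta_g_printed[i] - comp)
    if (dev > printed_tol + 1e-12) {
      pm <- rbind(pm, data.frame(id = map$reactions$id[i],
                                 printed = map$reactions$delta_g_printed[i],
                                 computed = comp, flag = map$reactions$flag[i],
                                 stringsAsFactors = FALSE))
    }
  }
  unflagged <- pm[pm$flag == "", , drop = FALSE]
  ok <- length(imb) == 0L && max_res <= tol && nrow(unflagged) == 0L
  structure(list(ok = ok, imbalanced = imb, cycle_residuals = cyc,
                 max_residual = max_res, printed_mismatch = pm, tol = tol),
            class = "map_audit")
}

#' @export
print.map_audit <- function(x, ...) {
  cat(sprintf("<map_audit> %s: max |cycle residual| = %.3g kcal/mol (%d cycles), %d imbalanced, %d printed mismatches\n",
              if (x$ok) "PASS" else "FAIL", x$max_residual,
              nrow(x$cycle_residuals), length(x$imbalanced), nrow(x$printed_mismatch)))
  invisible(x)
}

#' Compare reaction pairs across network variants
#'
#' For each pair `(base, variant)` of reaction ids, reports
#' `ddG = dG(variant) - dG(base)` and, where both reactions carry
#' transition states, the forward-barrier difference
#' `ddG_ts = dG_fwd(variant) - dG_fwd(base)`.
#'
#' @param map An `fe_map`.
#' @param correspondence Data frame with columns `base` and `variant`
#'   (reaction ids), optionally `label`.
#' @return Data frame with columns `label`, `base`, `variant`,
#'   `delta_g_base`, `delta_g_variant`, `ddG`, `barrier_base`,
#'   `barrier_variant`, `ddG_ts`.
#' @export
variant_ledger <- function(map, correspondence) {
  cc <- as.data.frame(correspondence, stringsAsFactors = FALSE)
  if (!all(c("base", "variant") %in% names(cc))) {
    stop("correspondence needs columns 'base' and 'variant'", call. = FALSE)
  }
  bad <- setdiff(c(cc$base, cc$variant), map$reactions$id)
  if (length(bad)) stop(sprintf("unmatched reaction id(s): %s",
                                paste(unique(bad), collapse = ", ")), call. = FALSE)
  if (is.null(cc$label)) cc$label <- paste(cc$base, "vs", cc$variant)
  out <- lapply(seq_len(nrow(cc)), function(i) {
    b <- activation_barriers(map, cc$base[i])
    v <- activation_barriers(map, cc$variant[i])
    data.frame(label = cc$label[i], base = cc$base[i], variant = cc$variant[i],
               delta_g_base = b$delta_g, delta_g_variant = v$delta_g,
               ddG = v$delta_g - b$delta_g,
               barrier_base = b$forward, barrier_variant = v$forward,
               ddG_ts = if (b$has_barrier && v$has_barrier) v$forward - b$forward
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Free-energy change along a composed path of reactions
#'
#' @param map An `fe_map`.
#' @param reaction_ids Reaction ids traversed in order; prefix an id with
#'   `"-"` to traverse it in reverse (sign-flipped `dG`).
#' @return Total `dG` in kcal/mol.
#' @export
path_delta_g <- function(map, reaction_ids) {
  total <- 0
  for (id in reaction_ids) {
    sgn <- 1
    if (startsWith(id, "-")) { sgn <- -1; id <- substring(id, 2) }
    total <- total + sgn * reaction_delta_g(map, id)
  }
  total
}
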