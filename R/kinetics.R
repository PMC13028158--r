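#' Eyring rate constant from an activation free energy
#'
#' `k = (k_B T / h) * exp(-dG_act / RT)`. The transmission coefficient is
#' taken as 1 and the standard state is 1 M, so bimolecular rate constants
#' come out in 1/(M s) and unimolecular ones in 1/s.
#'
#' @param barrier Activation free energy in kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return Rate constant.
#' @examples
#' eyring_rate(0)       # ~6.21e12 s^-1
#' eyring_rate(5.2)     # ~1e9
#' @export
eyring_rate <- function(barrier, temperature = T_STANDARD) {
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  (KB_SI * temperature / PLANCK_SI) * exp(-barrier / (R_KCAL * temperature))
}

#' Build a mass-action kinetic model from a free-energy map
#'
#' Each selected reaction becomes a reversible elementary step with
#' forward rate from its Eyring barrier and reverse rate fixed by detailed
#' balance, `k_rev = k_fwd * exp(dG / RT)`. Species in `clamped` (reference
#' molecules such as the solvent, or a buffered bisulfite pool) are held at
#' unit activity: they do not appear in the state vector, do not count
#' towards molecularity, and their cumulative net consumption is tracked
#' separately so elemental accounting stays exact.
#'
#' Steps without a transition state are covered by the barrierless policy:
#' they receive `barrierless_barrier` (default 2.0 kcal/mol, the magnitude
#' reported for facile adduct additions) and are labelled `imputed` in the
#' step table. `barrier_offset` shifts every barrier globally, exposing the
#' known systematic barrier uncertainty for sensitivity runs. Submerged
#' barriers are floored at zero and flagged.
#'
#' @param map An `fe_map`.
#' @param reaction_ids Reactions to include (default: all).
#' @param initial Named numeric vector of initial concentrations (mol/L)
#'   for dynamic species; species not named start at 0.
#' @param clamped Species ids held at unit activity (default `"H2O"`).
#' @param barrierless_barrier Imputed barrier (kcal/mol) for steps with no
#'   TS; `NA` makes such steps an error.
#' @param barrier_offset Global additive barrier shift, kcal/mol.
#' @param temperature Kelvin.
#' @return Object of class `kinetic_model`: species vector, `steps` data
#'   frame (with `k_fwd`, `k_rev`, `imputed`, `submerged`), stoichiometry
#'   and order matrices, clamped bookkeeping matrix, temperature.
#' @export
build_rate_model <- function(map, reaction_ids = map$reactions$id,
                             initial = numeric(0), clamped = "H2O",
                             barrierless_barrier = 2.0, barrier_offset = 0,
                             temperature = T_STANDARD) {
  idx <- match(reaction_ids, map$reactions$id)
  if (anyNA(idx)) stop(sprintf("unknown reaction id(s): %s",
                               paste(reaction_ids[is.na(idx)], collapse = ", ")),
                       call. = FALSE)
  # dynamic species = all participants minus clamped
  parts <- unique(unlist(c(lapply(map$lhs[idx], names), lapply(map$rhs[idx], names))))
  dyn <- setdiff(parts, clamped)
  unknown_init <- setdiff(names(initial), dyn)
  if (length(unknown_init)) stop(sprintf(
    "initial concentration(s) for species not in the model: %s",
    paste(unknown_init, collapse = ", ")), call. = FALSE)

  no_ts <- character(0)
  rows <- vector("list", length(idx))
  S <- matrix(0, length(dyn), length(idx), dimnames = list(dyn, reaction_ids))
  Of <- S; Or <- S   # reaction orders, forward / reverse
  Cl <- matrix(0, length(clamped), length(idx), dimnames = list(clamped, reaction_ids))
  RT <- R_KCAL * temperature
  for (j in seq_along(idx)) {
    i <- idx[j]
    lhs <- map$lhs[[i]]; rhs <- map$rhs[[i]]
    dG <- reaction_delta_g(map, map$reactions$id[i])
    mol_f <- sum(lhs[setdiff(names(lhs), clamped)])
    mol_r <- sum(rhs[setdiff(names(rhs), clamped)])
    if (mol_f > 2 || mol_r > 2) {
      stop(sprintf("reaction %s has molecularity > 2 after clamping (fwd %g, rev %g)",
                   map$reactions$id[i], mol_f, mol_r), call. = FALSE)
    }
    ab <- activation_barriers(map, map$reactions$id[i])
    imputed <- !ab$has_barrier
    if (imputed && is.na(barrierless_barrier)) {
      no_ts <- c(no_ts, map$reactions$id[i]); next
    }
    barrier <- if (imputed) max(dG, 0) + barrierless_barrier else ab$forward
    barrier <- barrier + barrier_offset
    submerged <- barrier < 0
    k_fwd <- eyring_rate(max(barrier, 0), temperature)
    k_rev <- k_fwd * exp(dG / RT)
    for (s in names(lhs)) {
      if (s %in% dyn) { S[s, j] <- S[s, j] - lhs[[s]]; Of[s, j] <- Of[s, j] + lhs[[s]] }
      else Cl[s, j] <- Cl[s, j] - lhs[[s]]
    }
    for (s in names(rhs)) {
      if (s %in% dyn) { S[s, j] <- S[s, j] + rhs[[s]]; Or[s, j] <- Or[s, j] + rhs[[s]] }
      else Cl[s, j] <- Cl[s, j] + rhs[[s]]
    }
    rows[[j]] <- data.frame(id = map$reactions$id[i], delta_g = dG,
                            barrier = max(barrier, 0), k_fwd = k_fwd, k_rev = k_rev,
                            imputed = imputed, submerged = submerged,
                            stringsAsFactors = FALSE)
  }
  if (length(no_ts)) stop(sprintf(
    "no transition state and no barrierless policy for: %s",
    paste(no_ts, collapse = ", ")), call. = FALSE)
  steps <- do.call(rbind, rows)
  y0 <- stats::setNames(rep(0, length(dyn)), dyn)
  y0[names(initial)] <- initial
  structure(list(species = dyn, clamped = clamped, y0 = y0, steps = steps,
                 S = S, Of = Of, Or = Or, Cl = Cl, temperature = temperature,
                 elements = attr(map$species, "elements")[, dyn, drop = FALSE],
                 clamped_elements = {
                   E <- attr(map$species, "elements")
                   have <- intersect(clamped, colnames(E))
                   M <- matrix(0, 4, length(clamped),
                               dimnames = list(ELEMENTS, clamped))
                   M[, have] <- E[, have]
                   # clamped species may be pure-reference molecules absent
                   # from the registry; fall back to parsing their id
                   for (s in setdiff(clamped, have)) M[, s] <- parse_formula(s)
                   M
                 }),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d species, %d reversible steps (%d imputed), T = %g K\n",
              length(x$species), nrow(x$steps), sum(x$steps$imputed), x$temperature))
  invisible(x)
}

# rates and Jacobian of the mass-action system
model_rates <- function(model, y) {
  y <- pmax(y, 0)
  vf <- model$steps$k_fwd; vr <- model$steps$k_rev
  for (s in seq_along(model$species)) {
    of <- model$Of[s, ]; orr <- model$Or[s, ]
    nz <- of > 0; if (any(nz)) vf[nz] <- vf[nz] * y[s]^of[nz]
    nz <- orr > 0; if (any(nz)) vr[nz] <- vr[nz] * y[s]^orr[nz]
  }
  vf - vr
}

model_f <- function(model, y) as.vector(model$S %*% model_rates(model, y))

model_jac <- function(model, y) {
  model$S %*% model_dv(model, y)
}

model_dv <- function(model, y) {
  y <- pmax(y, 0)
  n <- length(y); m <- nrow(model$steps)
  dv <- matrix(0, m, n)   # d v_r / d y_s
  for (r in seq_len(m)) {
    of <- model$Of[, r]; orr <- model$Or[, r]
    supp_f <- which(of > 0); supp_r <- which(orr > 0)
    for (s in supp_f) {
      term <- model$steps$k_fwd[r] * of[s] * y[s]^(of[s] - 1)
      for (s2 in setdiff(supp_f, s)) term <- term * y[s2]^of[s2]
      dv[r, s] <- dv[r, s] + term
    }
    for (s in supp_r) {
      term <- model$steps$k_rev[r] * orr[s] * y[s]^(orr[s] - 1)
      for (s2 in setdiff(supp_r, s)) term <- term * y[s2]^orr[s2]
      dv[r, s] <- dv[r, s] - term
    }
  }
  dv
}

#' Integrate a kinetic model
#'
#' Deterministic stiff integration with a 2nd-order L-stable Rosenbrock
#' method (ode23s-type) using the analytic mass-action Jacobian; step size
#' is adapted to the error estimate, concentrations are kept non-negative,
#' and the cumulative net exchange with every clamped pool is integrated
#' alongside the state so elemental totals can be audited exactly.
#'
#' @param model A [build_rate_model()] result.
#' @param t_end End time, s.
#' @param n_out Number of output points (log-spaced from `t_first`).
#' @param t_first First positive output time (default `1e-9`).
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param max_steps Step budget; exceeding it raises a structured error
#'   carrying the last valid state in `$state`.
#' @return Object of class `trajectory`: `time`, concentration matrix
#'   `conc` (species x time), clamped-exchange matrix `clamped_net`, and
#'   the model.
#' @export
simulate_kinetics <- function(model, t_end, n_out = 200L, t_first = 1e-9,
                              rtol = 1e-5, atol = 1e-9, max_steps = 200000L) {
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  grid <- unique(c(0, exp(seq(log(t_first), log(t_end), length.out = n_out))))
  n <- length(model$species)
  ncl <- length(model$clamped)
  # extended state: concentrations plus cumulative net production of each
  # clamped pool (linear bookkeeping rows integrated with full error control)
  z <- c(pmax(model$y0, 0), rep(0, ncl))
  nz_tot <- n + ncl
  d <- 1 / (2 + sqrt(2)); e32 <- 6 + sqrt(2)
  out <- matrix(NA_real_, n, length(grid), dimnames = list(model$species, NULL))
  outcl <- matrix(NA_real_, ncl, length(grid), dimnames = list(model$clamped, NULL))
  out[, 1] <- z[seq_len(n)]; outcl[, 1] <- z[n + seq_len(ncl)]
  f_ext <- function(zz) {
    v <- model_rates(model, zz[seq_len(n)])
    c(as.vector(model$S %*% v), as.vector(model$Cl %*% v))
  }
  jac_ext <- function(zz) {
    J <- matrix(0, nz_tot, nz_tot)
    dv <- model_dv(model, zz[seq_len(n)])
    J[seq_len(n), seq_len(n)] <- model$S %*% dv
    J[n + seq_len(ncl), seq_len(n)] <- model$Cl %*% dv
    J
  }
  # orthonormal basis of the linear invariants of the extended system
  # (left null space of rbind(S, Cl)): every elemental total lies in this
  # span. Each accepted step is projected back, so conservation holds to
  # rounding even though the W solves are ill-conditioned.
  M <- rbind(model$S, model$Cl)
  qrM <- qr(M)
  rk <- qrM$rank
  Qfull <- qr.Q(qrM, complete = TRUE)
  Qn <- if (rk < nz_tot) Qfull[, (rk + 1L):nz_tot, drop = FALSE] else NULL
  z0_inv <- if (!is.null(Qn)) crossprod(Qn, z) else NULL
  t <- 0; gi <- 2L
  h <- min(t_first, t_end) / 10
  steps <- 0L
  # rate evaluations clamp internally; the state itself is not clipped,
  # which keeps linear (elemental) invariants exact to rounding. Tiny
  # negative excursions (O(atol)) are zeroed only on output.
  while (gi <= length(grid)) {
    if (steps >= max_steps) {
      cond <- structure(class = c("kinetics_integration_error", "error", "condition"),
                        list(message = sprintf("step budget exhausted at t = %g s", t),
                             call = NULL, state = z[seq_len(n)], time = t))
      stop(cond)
    }
    h <- min(h, grid[gi] - t)
    f0 <- f_ext(z)
    J <- jac_ext(z)
    rejected <- FALSE
    repeat {
      W <- diag(nz_tot) - h * d * J
      k1 <- tryCatch(solve(W, f0, tol = 0), error = function(e) NULL)
      if (is.null(k1)) { h <- h / 4; next }
      z1 <- z + 0.5 * h * k1
      f1 <- f_ext(z1)
      k2 <- solve(W, f1 - k1, tol = 0) + k1
      znew <- z + h * k2
      f2 <- f_ext(znew)
      k3 <- solve(W, f2 - e32 * (k2 - f1) - 2 * (k1 - f0), tol = 0)
      err_vec <- (h / 6) * (k1 - 2 * k2 + k3)
      sc <- atol + rtol * pmax(abs(z), abs(znew))
      # error control on concentrations only; the cumulative clamped-pool
      # rows are passive bookkeeping and must not throttle the stepper
      err <- sqrt(mean((err_vec[seq_len(n)] / sc[seq_len(n)])^2))
      if (is.finite(err) && err <= 1) break
      rejected <- TRUE
      h <- h * max(0.2, 0.9 / sqrt(max(err, 1e-10)))
      if (h <= 0 || !is.finite(h)) {
        cond <- structure(class = c("kinetics_integration_error", "error", "condition"),
                          list(message = sprintf("step size underflow at t = %g s", t),
                               call = NULL, state = z[seq_len(n)], time = t))
        stop(cond)
      }
    }
    z <- znew
    t <- t + h
    steps <- steps + 1L
    if (gi <= length(grid) && t >= grid[gi] - 1e-12 * max(grid[gi], 1)) {
      # restore the linear invariants (elemental closure) at output times;
      # doing it inside every step would perturb the error controller.
      # The correction is weighted by species magnitude so that abundant
      # species absorb the rounding debt and trace species are untouched.
      if (!is.null(Qn)) {
        r <- z0_inv - crossprod(Qn, z)
        # relative weight floor keeps the projection system well-conditioned
        w2 <- pmax(abs(z), 1e-6 * max(abs(z), atol), atol)^2
        Aw <- Qn * w2            # = diag(w2) %*% Qn
        corr <- Aw %*% solve(crossprod(Qn, Aw), r, tol = 0)
        z <- z + as.vector(corr)
      }
      while (gi <= length(grid) && t >= grid[gi] - 1e-12 * max(grid[gi], 1)) {
        out[, gi] <- pmax(z[seq_len(n)], 0)
        outcl[, gi] <- z[n + seq_len(ncl)]
        gi <- gi + 1L
      }
    }
    # after a rejection, hold h for one step to avoid grow/reject thrash
    grow <- if (rejected) 1 else 5
    h <- h * min(grow, max(0.2, 0.9 / sqrt(max(err, 1e-10))))
  }
  structure(list(time = grid, conc = out, clamped_net = outcl, model = model,
                 n_steps = steps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d species over [0, %g] s (%d output points, %d internal steps)\n",
              nrow(x$conc), max(x$time), length(x$time), x$n_steps))
  invisible(x)
}

#' Elemental conservation audit of a trajectory
#'
#' Total moles of each element carried by dynamic species plus the
#' cumulative net amount exported to clamped pools must be constant.
#'
#' @param traj A [simulate_kinetics()] trajectory.
#' @return Named numeric vector: maximum absolute drift per element.
#' @export
conservation_drift <- function(traj) {
  m <- traj$model
  tot <- m$elements %*% traj$conc + m$clamped_elements %*% traj$clamped_net
  apply(tot, 1, function(v) max(abs(v - v[1])))
}

#' Autocatalysis and leakage metrics
#'
#' @param traj A trajectory.
#' @param c2_pool Species ids forming the autocatalytic (C2) pool.
#' @param drain_pool Species ids forming the parasitic drain
#'   (Cannizzaro products).
#' @param food_pool Species ids holding the C1 food (default `"1"`-like
#'   single id must be supplied by the caller).
#' @param pool_floor Pool concentrations below this (mol/L) are excluded
#'   from the per-capita rate (default 1e-6: in these molar-scale
#'   scenarios a sub-micromolar pool is a numerical vestige, and relative
#'   changes of such traces are not chemically meaningful growth).
#' @return List: `max_per_capita_rate` (1/s, maximum over time of
#'   `d[C2]/dt / [C2]`), `leakage_fraction` (fraction of consumed food
#'   carbon residing in the drain pool at `t_end`), and
#'   `food_half_depletion_time` (s; `NA` if the food never halves).
#' @export
autocatalysis_metrics <- function(traj, c2_pool, drain_pool, food_pool,
                                  pool_floor = 1e-6) {
  conc <- traj$conc
  for (p in list(c2_pool, drain_pool, food_pool)) {
    missing_ids <- setdiff(p, rownames(conc))
    if (length(missing_ids)) stop(sprintf("pool species absent from trajectory: %s",
                                          paste(missing_ids, collapse = ", ")),
                                  call. = FALSE)
  }
  E <- traj$model$elements
  pool_c <- function(ids) {
    if (!length(ids)) return(rep(0, ncol(conc)))
    as.vector(E["C", ids, drop = FALSE] %*% conc[ids, , drop = FALSE])
  }
  p2 <- colSums(conc[c2_pool, , drop = FALSE])
  tt <- traj$time
  # per-capita rate = slope of log(pool) between output points. Intervals
  # whose relative pool change is below resolution (1e-9, far above the
  # integrator's rounding noise) are unresolvable and treated as zero
  # growth rather than noise-amplified rates.
  nt <- length(tt)
  per_capita <- rep(NA_real_, nt - 1L)
  ok <- p2[-1] >= pool_floor & p2[-nt] >= pool_floor
  dlog <- log(p2[-1][ok] / p2[-nt][ok])
  dlog[abs(dlog) < 1e-9] <- 0
  per_capita[ok] <- dlog / diff(tt)[ok]
  max_rate <- suppressWarnings(max(per_capita, na.rm = TRUE))
  if (!is.finite(max_rate)) max_rate <- NA_real_
  food_c <- pool_c(food_pool)
  drain_c <- pool_c(drain_pool)
  consumed <- food_c[1] - food_c[length(tt)]
  leak <- if (consumed > 0) (drain_c[length(tt)] - drain_c[1]) / consumed else 0
  half_idx <- which(food_c <= food_c[1] / 2)
  list(max_per_capita_rate = max_rate,
       leakage_fraction = leak,
       food_half_depletion_time = if (length(half_idx)) tt[min(half_idx)] else NA_real_)
}
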