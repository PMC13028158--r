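# Minimal exact rational arithmetic on small integers, used so that
# stoichiometric balancing and cycle bases never suffer float drift.
# Rationals are stored as parallel numerator/denominator vectors of
# doubles holding exact integers (element counts are tiny, so no
# overflow risk in practice).

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  max(a, 1)
}

rat_new <- function(num, den = rep(1, length(num))) {
  stopifnot(all(den != 0))
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn; den <- den * sgn
  g <- mapply(rat_gcd, num, den)
  list(num = num / g, den = den / g)
}

rat_add <- function(x, y) rat_new(x$num * y$den + y$num * x$den, x$den * y$den)
rat_sub <- function(x, y) rat_new(x$num * y$den - y$num * x$den, x$den * y$den)
rat_mul <- function(x, y) rat_new(x$num * y$num, x$den * y$den)
rat_div <- function(x, y) {
  if (any(abs(y$num) < 0.5)) stop("rational division by zero", call. = FALSE)
  rat_new(x$num * y$den, x$den * y$num)
}
rat_numeric <- function(x) x$num / x$den
rat_is_zero <- function(x) abs(x$num) < 0.5

# Solve A x = b exactly by Gauss-Jordan elimination over the rationals.
# A: integer matrix (m x n), b: integer vector (m). Returns list with
# `solution` (numeric, exact rationals evaluated), `unique` flag, and
# `rank`. Errors if the system is inconsistent.
rat_solve <- function(A, b) {
  m <- nrow(A); n <- ncol(A)
  # augmented matrix as rationals, stored row-major in a list of rows
  aug <- lapply(seq_len(m), function(i) rat_new(c(A[i, ], b[i])))
  pivot_cols <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    piv <- NA_integer_
    for (r in row:m) {
      if (r <= m && abs(aug[[r]]$num[col]) > 0.5) { piv <- r; break }
    }
    if (is.na(piv)) next
    aug[c(row, piv)] <- aug[c(piv, row)]
    pr <- aug[[row]]
    pval <- rat_new(pr$num[col], pr$den[col])
    aug[[row]] <- rat_div(pr, list(num = rep(pval$num, n + 1L), den = rep(pval$den, n + 1L)))
    for (r in seq_len(m)) {
      if (r == row) next
      f <- rat_new(aug[[r]]$num[col], aug[[r]]$den[col])
      if (rat_is_zero(f)) next
      scaled <- rat_mul(aug[[row]], list(num = rep(f$num, n + 1L), den = rep(f$den, n + 1L)))
      aug[[r]] <- rat_sub(aug[[r]], scaled)
    }
    pivot_cols <- c(pivot_cols, col)
    row <- row + 1L
    if (row > m) break
  }
  rank <- length(pivot_cols)
  # consistency: any zero row with nonzero rhs?
  for (r in seq_len(m)) {
    lhs_zero <- all(abs(aug[[r]]$num[seq_len(n)]) < 0.5)
    if (lhs_zero && abs(aug[[r]]$num[n + 1L]) > 0.5) {
      stop("linear system inconsistent: target not representable in basis", call. = FALSE)
    }
  }
  x <- rep(0, n)
  for (i in seq_along(pivot_cols)) {
    x[pivot_cols[i]] <- aug[[i]]$num[n + 1L] / aug[[i]]$den[n + 1L]
  }
  list(solution = x, unique = rank == n, rank = rank, pivot_cols = pivot_cols)
}

# Exact rational null-space basis of an integer matrix A (m x n), columns
# ordered as given. Returns a matrix (n x k) of integer-scaled primitive
# basis vectors; deterministic for a fixed column order (free columns in
# ascending index, back-substituted from the RREF).
rat_nullspace <- function(A) {
  m <- nrow(A); n <- ncol(A)
  if (n == 0L) return(matrix(0, 0, 0))
  sol <- rat_solve(A, rep(0L, m))
  piv <- sol$pivot_cols
  free <- setdiff(seq_len(n), piv)
  if (length(free) == 0L) return(matrix(0, n, 0))
  # redo elimination keeping the reduced rows to express pivots in free vars
  aug <- lapply(seq_len(m), function(i) rat_new(c(A[i, ], 0)))
  row <- 1L; piv2 <- integer(0)
  for (col in seq_len(n)) {
    pr <- NA_integer_
    for (r in row:m) if (r <= m && abs(aug[[r]]$num[col]) > 0.5) { pr <- r; break }
    if (is.na(pr)) next
    aug[c(row, pr)] <- aug[c(pr, row)]
    pv <- rat_new(aug[[row]]$num[col], aug[[row]]$den[col])
    aug[[row]] <- rat_div(aug[[row]], list(num = rep(pv$num, n + 1L), den = rep(pv$den, n + 1L)))
    for (r in seq_len(m)) {
      if (r == row) next
      f <- rat_new(aug[[r]]$num[col], aug[[r]]$den[col])
      if (rat_is_zero(f)) next
      aug[[r]] <- rat_sub(aug[[r]], rat_mul(aug[[row]],
        list(num = rep(f$num, n + 1L), den = rep(f$den, n + 1L))))
    }
    piv2 <- c(piv2, col); row <- row + 1L
    if (row > m) break
  }
  basis <- matrix(0, n, length(free))
  for (j in seq_along(free)) {
    fc <- free[j]
    v_num <- rep(0, n); v_den <- rep(1, n)
    v_num[fc] <- 1
    for (i in seq_along(piv2)) {
      # pivot value = -coef of free column in reduced row i
      v_num[piv2[i]] <- -aug[[i]]$num[fc]
      v_den[piv2[i]] <- aug[[i]]$den[fc]
    }
    # scale to primitive integer vector
    L <- 1
    for (k in seq_len(n)) L <- L * v_den[k] / rat_gcd(L, v_den[k])
    vi <- v_num * (L / v_den)
    g <- 0
    for (k in seq_len(n)) if (abs(vi[k]) > 0.5) g <- rat_gcd(g, vi[k])
    if (g > 0.5) vi <- vi / g
    basis[, j] <- vi
  }
  basis
}
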