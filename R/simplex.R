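# Dense primal simplex for the box-truncated flux-cone LPs
#
#   maximize c'x   subject to   Aeq x = 0,   0 <= x <= M
#
# These LPs are tiny (tens of variables) but heavily degenerate: the
# origin is always feasible and lies on many constraint facets at once.
# General-purpose simplex routines without anti-cycling safeguards stall
# or crash on exactly this structure, so the oracle uses its own
# implementation with Bland's rule, which is guaranteed to terminate.
#
# Setup: upper bounds become slack rows (x_j + s_j = M), equality rows
# get artificial variables.  Because the equality right-hand side is 0,
# the artificial basis is already feasible at level 0 and the usual
# phase 1 reduces to driving the artificials out of the basis by
# zero-ratio pivots (rows that are entirely zero are redundant and keep
# their artificial basic at level 0 forever).

solve_bounded_lp <- function(obj, Aeq, big_m, tol = 1e-9) {
  n <- length(obj)
  m <- nrow(Aeq)
  N <- 2L * n + m  # structural, slack, artificial columns
  mm <- m + n
  T <- matrix(0, mm, N + 1L)
  if (m) {
    T[seq_len(m), seq_len(n)] <- Aeq
    T[cbind(seq_len(m), 2L * n + seq_len(m))] <- 1
  }
  T[m + seq_len(n), seq_len(n)] <- diag(n)
  T[m + seq_len(n), n + seq_len(n)] <- diag(n)
  T[m + seq_len(n), N + 1L] <- big_m
  basis <- c(if (m) 2L * n + seq_len(m), n + seq_len(n))
  zrow <- c(-obj, numeric(n + m), 0)

  do_pivot <- function(i, j) {
    piv <- T[i, j]
    T[i, ] <<- T[i, ] / piv
    for (k in seq_len(mm)) {
      if (k != i && abs(T[k, j]) > 0) T[k, ] <<- T[k, ] - T[k, j] * T[i, ]
    }
    if (abs(zrow[j]) > 0) zrow <<- zrow - zrow[j] * T[i, ]
    basis[i] <<- j
  }

  # drive artificials out of the basis (all at level 0, so any nonzero
  # entry in a structural or slack column is a valid zero-ratio pivot)
  if (m) {
    for (i in seq_len(m)) {
      if (basis[i] <= 2L * n) next
      cand <- which(abs(T[i, seq_len(2L * n)]) > tol)
      if (length(cand)) do_pivot(i, cand[1L])
      # else: redundant all-zero row; its artificial stays basic at 0
    }
  }

  # phase 2, Bland's rule; artificial columns may never enter
  allowed <- seq_len(2L * n)
  it <- 0L
  max_it <- 10000L + 200L * N
  repeat {
    it <- it + 1L
    if (it > max_it) {
      stop("internal simplex did not terminate (", max_it, " pivots)")
    }
    enter <- 0L
    for (j in allowed) {  # smallest index with negative reduced cost
      if (zrow[j] < -tol && !(j %in% basis)) { enter <- j; break }
    }
    if (!enter) break
    col <- T[, enter]
    rows <- which(col > tol)
    if (!length(rows)) {
      stop("internal simplex: unbounded direction despite box bounds")
    }
    ratios <- T[rows, N + 1L] / col[rows]
    best <- min(ratios)
    tied <- rows[ratios <= best + tol]
    leave <- tied[which.min(basis[tied])]  # Bland tie-break
    do_pivot(leave, enter)
  }

  x <- numeric(n)
  struct_rows <- which(basis <= n)
  x[basis[struct_rows]] <- T[struct_rows, N + 1L]
  list(value = zrow[N + 1L], x = x)
}
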