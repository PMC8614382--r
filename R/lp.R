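# Internal dense two-phase simplex.
#
# The envelopment problems solved per farm are small (a handful of rows, one
# column per peer farm) but frequently degenerate: ties on the frontier give
# zero right-hand sides and multiple optimal bases. Bland's anti-cycling rule
# is used throughout, trading a few extra pivots for guaranteed termination.

# Solve  max/min  obj'x  s.t.  A x (dir) b,  x >= 0.
# dir is a character vector over {"<=", ">=", "="}; b may have any sign.
# Returns list(status, x, value); status one of "optimal", "infeasible",
# "unbounded", "iteration_limit".
lp_solve <- function(obj, A, b, dir, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(dir) == m,
            all(dir %in% c("<=", ">=", "=")))

  # canonical form: nonnegative right-hand sides
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  # slack/surplus columns; artificials where no identity column arises
  n_slack <- sum(dir != "=")
  S <- matrix(0, m, n_slack)
  slack_of_row <- integer(m)
  j <- 0L
  for (i in seq_len(m)) {
    if (dir[i] != "=") {
      j <- j + 1L
      S[i, j] <- if (dir[i] == "<=") 1 else -1
      slack_of_row[i] <- n + j
    }
  }
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)
  Ar <- matrix(0, m, n_art)
  for (k in seq_along(art_rows)) Ar[art_rows[k], k] <- 1

  Tb <- cbind(A, S, Ar, b)
  ncol_tot <- n + n_slack + n_art
  basis <- integer(m)
  basis[dir == "<="] <- slack_of_row[dir == "<="]
  basis[art_rows] <- n + n_slack + seq_len(n_art)

  cmin <- if (maximize) -obj else obj

  pivot <- function(Tb, pr, pc) {
    piv <- Tb[pr, pc]
    Tb[pr, ] <- Tb[pr, ] / piv
    other <- setdiff(seq_len(nrow(Tb)), pr)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, pc], Tb[pr, ])
    Tb
  }

  # Bland's rule iteration on tableau rows 1..m with cost row appended last.
  run_phase <- function(Tb, basis, cost) {
    # reduced-cost row: d_j = c_j - c_B' B^-1 A_j, objective value in last cell
    d <- c(cost, 0) - colSums(Tb * cost[basis])
    Tb <- rbind(Tb, d)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      red <- Tb[m + 1L, seq_len(ncol_tot)]
      enter <- which(red < -tol)
      if (!length(enter)) {
        return(list(status = "optimal", Tb = Tb[seq_len(m), , drop = FALSE],
                    basis = basis, value = -Tb[m + 1L, ncol_tot + 1L]))
      }
      pc <- enter[1L]                      # Bland: lowest eligible index
      col <- Tb[seq_len(m), pc]
      rows <- which(col > tol)
      if (!length(rows)) return(list(status = "unbounded"))
      ratio <- Tb[rows, ncol_tot + 1L] / col[rows]
      cand <- rows[ratio <= min(ratio) + tol]
      pr <- cand[which.min(basis[cand])]   # Bland tie-break on leaving index
      Tb <- pivot(Tb, pr, pc)
      basis[pr] <- pc
    }
  }

  # phase 1: drive artificials to zero
  if (n_art > 0L) {
    c1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- run_phase(Tb, basis, c1)
    if (ph1$status != "optimal") return(list(status = ph1$status))
    if (ph1$value > 1e-7) return(list(status = "infeasible"))
    Tb <- ph1$Tb
    basis <- ph1$basis
    # pivot residual artificials out of the basis where possible
    for (i in which(basis > n + n_slack)) {
      row <- Tb[i, seq_len(n + n_slack)]
      pc <- which(abs(row) > tol)[1L]
      if (!is.na(pc)) {
        Tb <- pivot(Tb, i, pc)
        basis[i] <- pc
      }
    }
    # zero out artificial columns so they can never re-enter
    Tb[, n + n_slack + seq_len(n_art)] <- 0
  }

  c2 <- c(cmin, rep(0, n_slack), rep(0, n_art))
  ph2 <- run_phase(Tb, basis, c2)
  if (ph2$status != "optimal") return(list(status = ph2$status))

  x <- numeric(ncol_tot)
  x[ph2$basis] <- ph2$Tb[, ncol_tot + 1L]
  val <- sum(cmin * x[seq_len(n)])
  list(status = "optimal",
       x = x[seq_len(n)],
       value = if (maximize) -val else val)
}
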