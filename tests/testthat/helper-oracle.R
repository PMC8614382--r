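# Brute-force oracles for the envelopment problems, written independently of
# the package internals. Both phases of the DEA model reduce to maximizing a
# linear function of the intensity weights over
#   { lambda >= 0, sum lambda = 1, A lambda <= b }.
# Every vertex of that polytope solves a square system picked from one
# support set and one tight-constraint set, so exhaustive enumeration of all
# such systems is an exact oracle for small n.

oracle_lp_on_simplex <- function(cvec, A, b) {
  n <- length(cvec)
  r <- length(b)
  best <- -Inf
  best_lam <- NULL
  for (size in 1:min(n, r + 1L)) {
    for (S in utils::combn(n, size, simplify = FALSE)) {
      tight_sets <- if (size == 1L) list(integer(0)) else
        utils::combn(r, size - 1L, simplify = FALSE)
      for (Tt in tight_sets) {
        M <- rbind(rep(1, size), A[Tt, S, drop = FALSE])
        sol <- tryCatch(solve(M, c(1, b[Tt])), error = function(e) NULL)
        if (is.null(sol) || any(!is.finite(sol)) || any(sol < -1e-8)) next
        lam <- numeric(n)
        lam[S] <- pmax(sol, 0)
        if (any(A %*% lam > b + 1e-8 * pmax(abs(b), 1))) next
        v <- sum(cvec * lam)
        if (v > best) {
          best <- v
          best_lam <- lam
        }
      }
    }
  }
  list(value = best, lambda = best_lam)
}

# radial phase: theta* = max { sum lambda y : sum lambda x <= x_i } / y_i
oracle_theta <- function(X, y, i) {
  o <- oracle_lp_on_simplex(y, t(X), X[i, ])
  o$value / y[i]
}

# slack phase at fixed theta: maximal raw slack total
# sum_k (x_ki - sum lambda x_k) + (sum lambda y - theta y_i)
oracle_total_slack <- function(X, y, i, theta) {
  cvec <- y - rowSums(X)
  A <- rbind(t(X), -y)
  b <- c(X[i, ], -theta * y[i])
  o <- oracle_lp_on_simplex(cvec, A, b)
  o$value + sum(X[i, ]) - theta * y[i]
}

# random DEA instance on positive data
random_instance <- function(n, m) {
  list(X = matrix(stats::runif(n * m, 1, 10), n, m),
       y = stats::runif(n, 1, 10))
}
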