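# Output-oriented variable-returns-to-scale DEA, solved per decision-making
# unit (DMU) as two linear programs: a radial phase maximizing the output
# expansion factor theta, and a slack phase maximizing residual input excess /
# output shortfall at fixed theta. Technical efficiency is TE = 1/theta.

#' Construct a DEA problem
#'
#' Bundles the input matrix and the output vector of a set of decision-making
#' units (farms) evaluated against a common frontier. Inputs are held fixed;
#' efficiency is measured as the feasible radial expansion of output within
#' the variable-returns-to-scale production possibility set (intensity
#' weights summing to one).
#'
#' @param x either an `n x m` numeric matrix of inputs (rows = DMUs) or a
#'   farm table, in which case the inputs are ewes, labor hours, variable
#'   cost and fixed capital cost and the output is gross revenue.
#' @param y numeric vector of outputs (one per DMU, all positive). Ignored
#'   when `x` is a farm table.
#' @param ... unused.
#' @return An object of class `dea_problem` with elements `X` (n x m), `y`
#'   and `dmu_names`.
#' @export
#' @examples
#' prob <- dea_problem(matrix(c(2, 1), ncol = 1), y = c(2, 1))
#' solve_all(prob)
dea_problem <- function(x, y = NULL, ...) UseMethod("dea_problem")

#' @rdname dea_problem
#' @export
dea_problem.matrix <- function(x, y = NULL, ...) {
  X <- x
  stopifnot(is.numeric(X), is.numeric(y), nrow(X) == length(y),
            nrow(X) >= 1, ncol(X) >= 1)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("inputs and outputs must be finite", call. = FALSE)
  if (any(X < 0)) stop("inputs must be nonnegative", call. = FALSE)
  if (any(rowSums(X > 0) == 0))
    stop("every DMU needs at least one positive input", call. = FALSE)
  if (any(y <= 0)) stop("all outputs must be positive", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("input_", seq_len(ncol(X)))
  nm <- rownames(X)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(X)))
  structure(list(X = unname(X), y = unname(y), dmu_names = nm,
                 input_names = colnames(X)),
            class = "dea_problem")
}

#' @rdname dea_problem
#' @export
dea_problem.data.frame <- function(x, y = NULL, ...) {
  validate_farm_table(x)
  if (length(unique(x$farm_type)) > 1L) {
    stop("farm table mixes farm types; each type is benchmarked against ",
         "its own frontier -- split the table first", call. = FALSE)
  }
  X <- as.matrix(x[, c("ewes", "labor", "variable_cost", "fixed_cost")])
  rownames(X) <- x$farm_id
  dea_problem(X, x$gross_revenue)
}

#' @export
print.dea_problem <- function(x, ...) {
  cat(sprintf("DEA problem: %d DMUs, %d inputs (%s), single output\n",
              length(x$y), ncol(x$X), paste(x$input_names, collapse = ", ")))
  invisible(x)
}

#' Solver settings for the DEA linear programs
#'
#' @param feasibility_tol numeric feasibility/pivot tolerance of the simplex
#'   routine, in (0, 1e-3).
#' @param efficiency_eps classification tolerance: a DMU is efficient when
#'   TE >= 1 - `efficiency_eps` and all slacks vanish at scale.
#' @param slack_phase run the second-phase slack maximization (default TRUE).
#' @param slack_normalization `"raw"` maximizes the plain sum of slacks in
#'   original units (EUR, hours, head), the convention of common envelopment
#'   software; `"input-mean-scaled"` divides each input slack by the sample
#'   mean of that input, removing unit sensitivity.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(feasibility_tol = 1e-7, efficiency_eps = 1e-6,
                            slack_phase = TRUE,
                            slack_normalization = c("raw",
                                                    "input-mean-scaled")) {
  slack_normalization <- match.arg(slack_normalization)
  stopifnot(feasibility_tol > 0, feasibility_tol < 1e-3,
            efficiency_eps > 0, efficiency_eps < 1e-3,
            is.logical(slack_phase))
  structure(list(feasibility_tol = feasibility_tol,
                 efficiency_eps = efficiency_eps,
                 slack_phase = slack_phase,
                 slack_normalization = slack_normalization),
            class = "solver_settings")
}

# column scaling for LP conditioning; theta is invariant to it
.dea_scale <- function(problem) {
  sx <- apply(problem$X, 2, max)
  sx[sx == 0] <- 1
  list(Xs = sweep(problem$X, 2, sx, "/"), ys = problem$y / max(problem$y),
       sx = sx, sy = max(problem$y))
}

#' Radial phase: maximal proportional output expansion
#'
#' Solves, for one DMU, the envelopment LP
#' max theta s.t. sum_j lambda_j y_j >= theta * y_i,
#' sum_j lambda_j x_kj <= x_ki for every input k, sum_j lambda_j = 1,
#' lambda >= 0. The DMU itself (lambda_i = 1, theta = 1) is always feasible,
#' so theta >= 1 up to solver tolerance.
#'
#' @param problem a [dea_problem()].
#' @param i DMU index in 1..n.
#' @param settings a [solver_settings()].
#' @return list with `theta` and the attaining `lambda` vector.
#' @export
solve_theta <- function(problem, i, settings = solver_settings()) {
  stopifnot(inherits(problem, "dea_problem"),
            i >= 1, i <= length(problem$y))
  sc <- .dea_scale(problem)
  n <- length(problem$y)
  m <- ncol(problem$X)
  # variables: (theta, lambda_1..n)
  A <- rbind(c(sc$ys[i], -sc$ys),
             cbind(0, t(sc$Xs)),
             c(0, rep(1, n)))
  b <- c(0, sc$Xs[i, ], 1)
  dir <- c("<=", rep("<=", m), "=")
  sol <- lp_solve(c(1, rep(0, n)), A, b, dir, maximize = TRUE,
                  tol = settings$feasibility_tol)
  if (sol$status != "optimal") {
    stop("DEA radial phase failed for DMU ", i, " (", problem$dmu_names[i],
         "): solver status '", sol$status, "'", call. = FALSE)
  }
  if (sol$value < 1 - 1e-6) {
    stop("DEA radial phase for DMU ", i, " returned theta = ", sol$value,
         " < 1; self-feasibility violated", call. = FALSE)
  }
  list(theta = max(sol$value, 1), lambda = sol$x[-1L])
}

#' Slack phase: maximize residual slacks at fixed theta
#'
#' At the radial optimum theta, alternate projections can still leave input
#' excess or output shortfall. The second-phase LP maximizes the total slack
#' subject to sum_j lambda_j y_j = theta * y_i + s_out,
#' sum_j lambda_j x_kj = x_ki - s_k, sum_j lambda_j = 1, all slacks >= 0.
#'
#' @inheritParams solve_theta
#' @param theta_fixed radial expansion factor from [solve_theta()].
#' @return list with `input_slacks` (original input units), `output_slack`
#'   (output units) and `lambda`.
#' @export
maximize_slacks <- function(problem, i, theta_fixed,
                            settings = solver_settings()) {
  stopifnot(inherits(problem, "dea_problem"),
            i >= 1, i <= length(problem$y), theta_fixed >= 1 - 1e-6)
  sc <- .dea_scale(problem)
  n <- length(problem$y)
  m <- ncol(problem$X)
  # variables: (lambda_1..n, s_in_1..m, s_out), all in scaled units
  A <- rbind(cbind(rbind(sc$ys), matrix(0, 1, m), -1),
             cbind(t(sc$Xs), diag(m), 0),
             c(rep(1, n), rep(0, m + 1)))
  b <- c(theta_fixed * sc$ys[i], sc$Xs[i, ], 1)
  dir <- rep("=", m + 2)
  w_in <- switch(settings$slack_normalization,
                 "raw" = sc$sx,                       # back to original units
                 "input-mean-scaled" = sc$sx / colMeans(problem$X))
  w_out <- switch(settings$slack_normalization,
                  "raw" = sc$sy,
                  "input-mean-scaled" = sc$sy / mean(problem$y))
  obj <- c(rep(0, n), w_in, w_out)
  sol <- lp_solve(obj, A, b, dir, maximize = TRUE,
                  tol = settings$feasibility_tol)
  if (sol$status == "infeasible") {
    # numerical guard: retry with theta shrunk by the feasibility tolerance
    sol <- lp_solve(obj, A, b * c(1 - settings$feasibility_tol, rep(1, m + 1)),
                    dir, maximize = TRUE, tol = settings$feasibility_tol)
  }
  if (sol$status != "optimal") {
    stop("DEA slack phase failed for DMU ", i, " (", problem$dmu_names[i],
         "): solver status '", sol$status,
         "' at theta = ", theta_fixed, call. = FALSE)
  }
  s_in <- pmax(sol$x[n + seq_len(m)] * sc$sx, 0)
  s_out <- max(sol$x[n + m + 1L] * sc$sy, 0)
  list(input_slacks = s_in, output_slack = s_out,
       lambda = sol$x[seq_len(n)])
}

#' Technical efficiency from the radial expansion factor
#'
#' TE = 1/theta, clamped to at most 1 (theta can undershoot 1 by solver
#' tolerance for frontier units).
#'
#' @param theta numeric vector of radial expansion factors (> 0).
#' @return numeric vector of TE scores in (0, 1].
#' @export
#' @examples
#' compute_te(c(1, 1.25, 2))
compute_te <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be positive and finite", call. = FALSE)
  pmin(1 / theta, 1)
}

#' Frontier level of output
#'
#' The efficient target output of a DMU: the radially expanded output plus
#' any second-phase output slack, y* = theta * y + s_out. Always at least the
#' observed output.
#'
#' @param y observed output.
#' @param theta radial expansion factor.
#' @param output_slack second-phase output slack (default 0).
#' @return projected (frontier) output, same units as `y`.
#' @export
#' @examples
#' project_to_frontier(100, 1.372)       # 137.2
#' project_to_frontier(50, 1.2, 5)       # 65
project_to_frontier <- function(y, theta, output_slack = 0) {
  stopifnot(all(is.finite(y)), all(is.finite(theta)),
            all(is.finite(output_slack)))
  theta * y + output_slack
}

#' Solve the DEA model for every DMU
#'
#' Runs the radial phase (and, unless disabled, the slack phase) for each
#' DMU as independent linear programs and assembles per-DMU scores, slacks
#' and frontier projections. A DMU is flagged efficient when TE >= 1 -
#' `efficiency_eps` and all its slacks are zero at the scale of the data.
#'
#' @inheritParams solve_theta
#' @return A data.frame of class `dea_result` with one row per DMU: `dmu`,
#'   `theta`, `te`, `output_slack`, one `slack_<input>` column per input,
#'   `projected_output`, one `projected_<input>` column per input and
#'   `is_efficient`. The intensity-weight matrix is attached as attribute
#'   `lambda` (rows = evaluated DMUs) and peer reference sets as attribute
#'   `peers`.
#' @export
solve_all <- function(problem, settings = solver_settings()) {
  stopifnot(inherits(problem, "dea_problem"),
            inherits(settings, "solver_settings"))
  n <- length(problem$y)
  m <- ncol(problem$X)
  theta <- numeric(n)
  lambda <- matrix(0, n, n)
  s_in <- matrix(0, n, m)
  s_out <- numeric(n)
  for (i in seq_len(n)) {
    ph1 <- solve_theta(problem, i, settings)
    theta[i] <- ph1$theta
    if (settings$slack_phase) {
      ph2 <- maximize_slacks(problem, i, ph1$theta, settings)
      s_in[i, ] <- ph2$input_slacks
      s_out[i] <- ph2$output_slack
      lambda[i, ] <- ph2$lambda
    } else {
      lambda[i, ] <- ph1$lambda
    }
  }
  te <- compute_te(theta)
  scale_in <- apply(problem$X, 2, max)
  scale_out <- max(problem$y)
  zero_slack <- rowSums(sweep(s_in, 2, pmax(scale_in, 1), "/") >
                          settings$feasibility_tol * 10) == 0 &
    s_out / scale_out <= settings$feasibility_tol * 10
  res <- data.frame(dmu = problem$dmu_names,
                    theta = theta,
                    te = te,
                    output_slack = s_out,
                    stringsAsFactors = FALSE)
  for (k in seq_len(m)) res[[paste0("slack_", problem$input_names[k])]] <-
    s_in[, k]
  res$projected_output <- project_to_frontier(problem$y, theta, s_out)
  for (k in seq_len(m)) {
    res[[paste0("projected_", problem$input_names[k])]] <-
      pmax(problem$X[, k] - s_in[, k], 0)
  }
  res$is_efficient <- te >= 1 - settings$efficiency_eps & zero_slack
  class(res) <- c("dea_result", "data.frame")
  attr(res, "lambda") <- lambda
  attr(res, "peers") <- apply(lambda, 1, function(l)
    which(l > settings$feasibility_tol * 10), simplify = FALSE)
  attr(res, "settings") <- settings
  res
}

#' @export
print.dea_result <- function(x, ...) {
  cat(sprintf(
    "DEA results: %d DMUs | mean TE %.3f | %d efficient | theta in [%.3f, %.3f]\n",
    nrow(x), mean(x$te), sum(x$is_efficient), min(x$theta), max(x$theta)))
  NextMethod()
}

#' Write DEA results to disk
#'
#' @param results a `dea_result` from [solve_all()].
#' @param path output path.
#' @param format `"csv"` for a flat table or `"json"` for a structured
#'   report including peer reference sets and intensity weights above
#'   tolerance.
#' @return `path`, invisibly.
#' @export
write_dea_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(results, "dea_result"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  } else {
    lam <- attr(results, "lambda")
    peers <- attr(results, "peers")
    recs <- lapply(seq_len(nrow(results)), function(i) {
      row <- as.list(as.data.frame(results)[i, ])
      row$reference_set <- lapply(peers[[i]], function(j)
        list(dmu = results$dmu[j], lambda = lam[i, j]))
      row
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
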