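# Synthetic farm populations with known-truth efficiencies.
#
# Construction: a small set of anchor farms is placed on a strictly concave,
# increasing frontier y = c0 + a * s^b of an aggregate input s (a positive
# weighted sum of the four inputs). Strict concavity makes every anchor a
# vertex of the variable-returns-to-scale hull, so the hull of the anchors IS
# the true frontier. Every other farm sits at a convex combination of anchor
# input profiles with output scaled down multiplicatively by its true TE;
# scaled-down points never extend the hull, so DEA on the full population
# recovers TE_true exactly (up to LP tolerance). The true frontier output at
# any input profile is evaluated by exact vertex enumeration, a route fully
# independent of the simplex solver.

.syn_defaults <- list(
  french_extensive = list(
    class_counts = c(small = 80, medium = 45, large = 116),
    n_efficient = 25, te_min = 0.313, ineff_mean_te = 0.675,
    rev_pe = 178, ewes_per_alu = 399, variable_cost_pe = 71,
    fixed_cost_pe = 78,
    rev_shares = c(lambs_meat = 65.56, lambs_breeding = 9.72, culls = 4.43,
                   subsidies = 17.40, wool_other = 2.89),
    lambs_pe = 0.87, feed_kg = 378, feed_share = 45 / 71,
    purchased_share = 34 / 45,
    size_range = c(100, 1200),
    practice_rates = c(16, 15, 13, 12, 10, 12, 10, 8, 2) / 25),
  french_intensive = list(
    class_counts = c(small = 22, medium = 13, large = 26),
    n_efficient = 22, te_min = 0.576, ineff_mean_te = 0.802,
    rev_pe = 214, ewes_per_alu = 518, variable_cost_pe = 87,
    fixed_cost_pe = 76,
    rev_shares = c(lambs_meat = 69.94, lambs_breeding = 8.24, culls = 5.48,
                   subsidies = 13.32, wool_other = 3.02),
    lambs_pe = 1.07, feed_kg = 496, feed_share = 60 / 87,
    purchased_share = 45 / 60,
    size_range = c(100, 1200),
    practice_rates = c(17, 14, 18, 17, 17, 13, 6, 3, 2) / 22),
  spanish_semi_intensive = list(
    class_counts = c(small = 13, medium = 13, large = 11),
    n_efficient = 14, te_min = 0.57, ineff_mean_te = 0.798,
    rev_pe = 157, ewes_per_alu = 532, variable_cost_pe = 68,
    fixed_cost_pe = 23,
    rev_shares = c(lambs_meat = 66.48, lambs_breeding = 1.11, culls = 1.48,
                   subsidies = 26.91, wool_other = 4.05),
    lambs_pe = 1.58, feed_kg = 287, feed_share = 59 / 68,
    purchased_share = 42 / 59,
    size_range = c(250, 2400),
    practice_rates = c(6, 5, 6, 6, 2, 6, 6, 2, 0) / 14),
  uk_extensive = list(
    class_counts = c(small = 44, medium = 46, large = 29),
    n_efficient = 22, te_min = 0.31, ineff_mean_te = 0.722,
    rev_pe = 142, ewes_per_alu = 922, variable_cost_pe = 65,
    fixed_cost_pe = 64,
    rev_shares = c(lambs_meat = 38.74, lambs_breeding = 43.74, culls = 14.67,
                   subsidies = NA, wool_other = 2.85),
    lambs_pe = 0.63, feed_kg = 86.24, feed_share = 19 / 65,
    purchased_share = 12 / 19,
    size_range = c(100, 2200),
    practice_rates = rep(0, 9))
)

.alu_hours <- 1800   # one annual labor unit, hours/year
.wage <- 12          # EUR per labor hour, for the per-ewe labor cost field

#' Specification of a synthetic farm population
#'
#' Collects the parameters of the known-truth generator: the farm count per
#' size class, the number of anchor farms spanning the frontier, the
#' inefficiency distribution (a Beta law rescaled to `[te_min, 0.995]` plus a
#' fixed count of fully efficient farms), and the per-ewe revenue/cost
#' calibration the population is shaped to. Per-type defaults emulate the
#' published benchmark aggregates for the four European farm types (size
#' class counts, efficient-group counts, TE range and group means,
#' gross-revenue composition shares, per-ewe cost structure, practice
#' adoption rates).
#'
#' @param farm_type one of [farm_types()].
#' @param n_anchors number of frontier anchor farms (at least 5: the number
#'   of inputs plus one).
#' @param class_counts named vector `c(small=, medium=, large=)` of farm
#'   counts; the total population size is their sum.
#' @param n_efficient total number of farms with true TE = 1, anchors
#'   included.
#' @param te_min lower end of the true-TE range of inefficient farms.
#' @param te_concentration concentration (alpha + beta) of the Beta law for
#'   inefficient TE; its mean is set to reproduce the calibrated
#'   inefficient-group mean TE.
#' @param seed integer seed recorded in the spec and used by
#'   [generate_population()] unless overridden there.
#' @param ... overrides of the per-type calibration entries (`rev_pe`,
#'   `ewes_per_alu`, `variable_cost_pe`, `fixed_cost_pe`, `rev_shares`,
#'   `lambs_pe`, `feed_kg`, `feed_share`, `purchased_share`, `size_range`,
#'   `practice_rates`, `ineff_mean_te`).
#' @return object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec("spanish_semi_intensive", seed = 1)
#' spec$n
synthetic_spec <- function(farm_type, n_anchors = 8, class_counts = NULL,
                           n_efficient = NULL, te_min = NULL,
                           te_concentration = 6, seed = NULL, ...) {
  farm_type <- match.arg(farm_type, farm_types())
  spec <- .syn_defaults[[farm_type]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown synthetic_spec field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  spec[names(dots)] <- dots
  if (!is.null(class_counts)) spec$class_counts <- class_counts
  if (is.null(names(spec$class_counts)))
    names(spec$class_counts) <- c("small", "medium", "large")
  stopifnot(length(spec$class_counts) == 3, all(spec$class_counts >= 0))
  if (!is.null(n_efficient)) spec$n_efficient <- n_efficient
  if (!is.null(te_min)) spec$te_min <- te_min
  spec$farm_type <- farm_type
  spec$n_anchors <- n_anchors
  spec$n <- sum(spec$class_counts)
  spec$te_concentration <- te_concentration
  spec$seed <- seed
  stopifnot(spec$n >= spec$n_anchors, spec$n_anchors >= 5,
            spec$te_min > 0, spec$te_min < 1,
            spec$n_efficient >= spec$n_anchors,
            spec$n_efficient <= spec$n,
            all(spec$rev_shares >= 0, na.rm = TRUE))
  class(spec) <- "synthetic_spec"
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic population spec: %s, n = %d ",
                     "(%d/%d/%d by size), %d efficient, %d anchors, ",
                     "true TE in [%.3g, 1]\n"),
              x$farm_type, x$n, x$class_counts[1], x$class_counts[2],
              x$class_counts[3], x$n_efficient, x$n_anchors, x$te_min))
  invisible(x)
}

# evaluate max c'lambda s.t. rowsum(lambda)=1, A lambda <= b, lambda >= 0
# by exact vertex enumeration (supports of size t+1 with t tight rows).
.enum_max_on_hull <- function(cvec, A, b, tol = 1e-9) {
  K <- length(cvec)
  r <- nrow(A)
  scale_b <- pmax(abs(b), 1)
  best <- -Inf
  for (t in 0:r) {
    tights <- if (t == 0) list(integer(0)) else
      utils::combn(r, t, simplify = FALSE)
    supports <- if (t + 1 > K) list() else
      utils::combn(K, t + 1L, simplify = FALSE)
    for (S in supports) {
      for (Tset in tights) {
        M <- rbind(rep(1, t + 1L), A[Tset, S, drop = FALSE])
        rhs <- c(1, b[Tset])
        lam_s <- tryCatch(solve(M, rhs), error = function(e) NULL)
        if (is.null(lam_s) || any(!is.finite(lam_s))) next
        if (any(lam_s < -1e-8)) next
        lam <- numeric(K)
        lam[S] <- pmax(lam_s, 0)
        if (any(A %*% lam > b + tol * scale_b)) next
        val <- sum(cvec * lam)
        if (val > best) best <- val
      }
    }
  }
  best
}

#' True frontier output at an input profile
#'
#' Evaluates the variable-returns-to-scale frontier spanned by a set of
#' anchor farms at an arbitrary input profile: the maximal output of a convex
#' combination of anchors whose inputs do not exceed `x` in any dimension.
#' Computed by exact vertex enumeration, which is practical for small anchor
#' sets (the generator's use case) and fully independent of the LP solver.
#'
#' @param anchor_x `K x m` matrix of anchor input profiles.
#' @param anchor_y length-`K` vector of anchor outputs.
#' @param x input profile (length `m`).
#' @return frontier output at `x`; errors if no convex combination of anchors
#'   fits under `x`.
#' @export
frontier_output <- function(anchor_x, anchor_y, x) {
  anchor_x <- as.matrix(anchor_x)
  stopifnot(nrow(anchor_x) == length(anchor_y), ncol(anchor_x) == length(x))
  val <- .enum_max_on_hull(anchor_y, t(anchor_x), as.numeric(x))
  if (!is.finite(val))
    stop("input profile lies below every anchor combination ",
         "(infeasible calibration)", call. = FALSE)
  val
}

.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# anchor farms on the concave frontier; deterministic given the spec
.make_anchors <- function(spec) {
  K <- spec$n_anchors
  span <- c(0.8 * spec$size_range[1], 1.15 * spec$size_range[2])
  ewes <- round(exp(seq(log(span[1]), log(span[2]), length.out = K)))
  e_mid <- sqrt(prod(span))
  labor <- ewes * (.alu_hours / spec$ewes_per_alu) * (ewes / e_mid)^(-0.12)
  vcost <- ewes * spec$variable_cost_pe * (ewes / e_mid)^(-0.03)
  fcost <- ewes * spec$fixed_cost_pe * (ewes / e_mid)^(-0.15)
  X <- cbind(ewes = ewes, labor = labor,
             variable_cost = vcost, fixed_cost = fcost)
  w <- c(25, .wage, 1, 1)                      # EUR-denominated aggregate
  s <- as.numeric(X %*% w)
  bpow <- 0.88
  c0 <- 0.15 * spec$rev_pe * min(ewes)
  s_mid <- s[which.min(abs(ewes - e_mid))]
  a <- (spec$rev_pe * e_mid - c0) / s_mid^bpow
  stopifnot(a > 0)
  y <- c0 + a * s^bpow
  list(X = X, y = y)
}

#' Generate a synthetic farm population with known-truth efficiencies
#'
#' Builds the anchor farms, samples flock sizes per size class, places every
#' non-anchor farm at a convex combination of anchor input profiles (biased
#' towards the two anchors bracketing its flock size, with a small random
#' admixture of the others), evaluates the true frontier output there by
#' vertex enumeration, and scales output down by the farm's true TE. Revenue
#' components are drawn around the calibrated composition shares and sum to
#' gross revenue exactly; per-ewe techno-economic fields are derived from the
#' generated inputs so that the accounting identities hold by construction.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`. The same seed yields an
#'   identical population.
#' @return list with `records` (a validated farm table; anchors first),
#'   `te_true`, `anchor_ids` (farm ids of the anchors) and `seed`.
#' @export
#' @examples
#' pop <- generate_population(synthetic_spec("spanish_semi_intensive"),
#'                            seed = 42)
#' nrow(pop$records)
generate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed
  .with_seed(seed, function() .generate_population_impl(spec, seed))
}

.generate_population_impl <- function(spec, seed) {
  anch <- .make_anchors(spec)
  K <- spec$n_anchors
  m <- ncol(anch$X)
  scheme <- size_class_scheme(spec$farm_type)
  anchor_cls <- assign_size_class(anch$X[, "ewes"], scheme)

  # remaining farms per class after the anchors are counted
  rem <- spec$class_counts
  for (cl in levels(anchor_cls)) {
    rem[cl] <- max(0L, rem[cl] - sum(anchor_cls == cl))
  }
  short <- (spec$n - K) - sum(rem)
  rem[which.max(rem)] <- rem[which.max(rem)] + short

  ranges <- list(
    small = c(spec$size_range[1], scheme$small_upper - 1),
    medium = c(scheme$small_upper, scheme$large_lower),
    large = c(scheme$large_lower + 1, spec$size_range[2]))
  targets <- unlist(lapply(names(rem), function(cl) {
    if (rem[cl] == 0) return(integer(0))
    round(stats::runif(rem[cl], ranges[[cl]][1], ranges[[cl]][2]))
  }))
  targets <- sample(targets)

  n_other <- length(targets)
  Xg <- matrix(0, n_other, m, dimnames = list(NULL, colnames(anch$X)))
  Fg <- numeric(n_other)
  e_a <- anch$X[, "ewes"]
  for (i in seq_len(n_other)) {
    tgt <- min(max(targets[i], min(e_a)), max(e_a))
    hi <- which(e_a >= tgt)[1L]
    lo <- max(hi - 1L, 1L)
    eta <- stats::runif(1, 0, 0.12)
    g <- stats::rexp(K)
    nw <- eta * g / sum(g)
    ne <- sum(nw * e_a)
    mu <- nw
    if (lo == hi) {
      mu[hi] <- mu[hi] + (1 - eta)
    } else {
      tt <- ((tgt - ne) / (1 - eta) - e_a[hi]) / (e_a[lo] - e_a[hi])
      if (!is.finite(tt) || tt < 0 || tt > 1) {
        mu <- numeric(K)   # fall back to the pure bracket pair
        tt <- (tgt - e_a[hi]) / (e_a[lo] - e_a[hi])
        tt <- min(max(tt, 0), 1)
        mu[lo] <- tt
        mu[hi] <- 1 - tt
      } else {
        mu[lo] <- mu[lo] + (1 - eta) * tt
        mu[hi] <- mu[hi] + (1 - eta) * (1 - tt)
      }
    }
    xi <- as.numeric(mu %*% anch$X)
    er <- round(xi[1])
    xi[1] <- if (abs(er - xi[1]) < 1e-6) er else ceiling(xi[1])
    Xg[i, ] <- xi
    Fg[i] <- frontier_output(anch$X, anch$y, xi)
  }

  X <- rbind(anch$X, Xg)
  Ftrue <- c(anch$y, Fg)
  n <- nrow(X)

  te_true <- numeric(n)
  te_true[seq_len(K)] <- 1
  extra_eff <- sample(K + seq_len(n_other), spec$n_efficient - K)
  te_true[extra_eff] <- 1
  ineff <- which(te_true == 0)
  mu_te <- (spec$ineff_mean_te - spec$te_min) / (0.995 - spec$te_min)
  mu_te <- min(max(mu_te, 0.02), 0.98)
  kap <- spec$te_concentration
  te_true[ineff] <- spec$te_min +
    stats::rbeta(length(ineff), mu_te * kap, (1 - mu_te) * kap) *
    (0.995 - spec$te_min)

  y <- te_true * Ftrue
  ewes <- X[, "ewes"]

  # revenue components: jittered calibrated shares, exact sum
  shares <- spec$rev_shares
  avail <- !is.na(shares)
  comp <- matrix(NA_real_, n, length(shares),
                 dimnames = list(NULL, names(shares)))
  base <- shares[avail] / sum(shares[avail])
  for (i in seq_len(n)) {
    s_i <- base * exp(stats::rnorm(sum(avail), 0, 0.12))
    s_i <- s_i / sum(s_i)
    vals <- s_i * y[i]
    vals[length(vals)] <- y[i] - sum(vals[-length(vals)])
    comp[i, avail] <- vals
  }

  fs <- pmin(pmax(spec$feed_share * exp(stats::rnorm(n, 0, 0.05)),
                  0.05), 0.95)
  ps <- pmin(pmax(spec$purchased_share * exp(stats::rnorm(n, 0, 0.05)),
                  0.05), 0.95)
  feed_pe <- fs * X[, "variable_cost"] / ewes
  records <- data.frame(
    farm_id = sprintf("%s_%04d",
                      c(french_extensive = "frext",
                        french_intensive = "frint",
                        spanish_semi_intensive = "essemi",
                        uk_extensive = "ukext")[[spec$farm_type]],
                      seq_len(n)),
    farm_type = spec$farm_type,
    ewes = ewes,
    labor = X[, "labor"],
    variable_cost = X[, "variable_cost"],
    fixed_cost = X[, "fixed_cost"],
    gross_revenue = y,
    lambs_meat = comp[, "lambs_meat"],
    lambs_breeding = comp[, "lambs_breeding"],
    culls = comp[, "culls"],
    subsidies = comp[, "subsidies"],
    wool_other = comp[, "wool_other"],
    lambs_sold = pmax(1, round(spec$lambs_pe * ewes *
                                 exp(stats::rnorm(n, 0, 0.1)))),
    alu = X[, "labor"] / .alu_hours,
    feed_kg_dm_per_ewe = spec$feed_kg * exp(stats::rnorm(n, 0, 0.1)),
    labor_cost = .wage * X[, "labor"] / ewes,
    feed_cost = feed_pe,
    purchased_feed = ps * feed_pe,
    homegrown_feed = (1 - ps) * feed_pe,
    variable_capital_cost = (1 - fs) * X[, "variable_cost"] / ewes,
    fixed_capital_cost = X[, "fixed_cost"] / ewes,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  validate_farm_table(records)
  list(records = records, te_true = te_true,
       anchor_ids = records$farm_id[seq_len(K)], seed = seed)
}

#' Generate a synthetic practice-selection matrix for efficient farms
#'
#' Draws independent Bernoulli flags per farm and practice. The per-practice
#' rate within a category is set so that the probability of flagging at least
#' one practice of the category equals the spec's calibrated category-level
#' adoption rate.
#'
#' @param spec a [synthetic_spec()] (provides the category rates).
#' @param farm_ids ids of the efficient farms to generate selections for.
#' @param catalog a [practice_catalog()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a `practice_selection` data.frame.
#' @export
generate_practice_matrix <- function(spec, farm_ids,
                                     catalog = practice_catalog(),
                                     seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed
  rates <- spec$practice_rates
  if (length(rates) != length(unique(catalog$category)))
    stop("need one category rate per catalog category", call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("category adoption rates must lie in [0, 1]", call. = FALSE)
  names(rates) <- unique(catalog$category)
  .with_seed(seed, function() {
    nf <- length(farm_ids)
    flags <- matrix(FALSE, nf, nrow(catalog))
    for (j in seq_len(nrow(catalog))) {
      cc <- catalog$category[j]
      k <- sum(catalog$category == cc)
      p <- 1 - (1 - rates[[cc]])^(1 / k)
      flags[, j] <- stats::runif(nf) < p
    }
    practice_selection(farm_ids, flags, catalog)
  })
}
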