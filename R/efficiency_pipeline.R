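# Reporting layer: efficiency grouping, TE frequency tables, size-class
# projection summaries, gross-revenue composition and per-ewe techno-economic
# indicators. All group figures are unweighted means over farms of per-ewe
# ratios; printed-table reproductions are computed from unrounded internals.

.te_from <- function(results) {
  te <- if (inherits(results, "dea_result") || is.data.frame(results))
    results$te else results
  if (!is.numeric(te) || !length(te))
    stop("need a dea_result or a nonempty numeric TE vector", call. = FALSE)
  if (any(!is.finite(te)) || any(te <= 0) || any(te > 1 + 1e-9)) {
    stop("TE scores outside (0, 1]; upstream solver defect", call. = FALSE)
  }
  pmin(te, 1)
}

#' Partition farms into efficient and inefficient groups
#'
#' A farm is efficient when TE >= 1 - `epsilon`.
#'
#' @param results a `dea_result` or a numeric TE vector.
#' @param epsilon efficiency classification tolerance.
#' @return list with integer index vectors `efficient` and `inefficient`
#'   (a disjoint, exhaustive partition of 1..n).
#' @export
#' @examples
#' classify_groups(c(1, 0.9, 1 - 1e-9))
classify_groups <- function(results, epsilon = 1e-6) {
  te <- .te_from(results)
  eff <- which(te >= 1 - epsilon)
  list(efficient = eff, inefficient = setdiff(seq_along(te), eff))
}

#' Frequency distribution of TE scores
#'
#' Tabulates farms into TE bins (by default below 0.60, then decade bins up
#' to 0.90, near-frontier, and the fully efficient group at TE >= 1 -
#' `epsilon`), with counts, percentage shares and per-bin mean TE computed on
#' unrounded scores, plus a total row.
#'
#' @param results a `dea_result` or numeric TE vector, all values in (0, 1].
#' @param bin_edges increasing interior bin edges in (0, 1); bins are
#'   half-open `[edge, next)` with the top bin `[1 - epsilon, 1]` reserved
#'   for efficient farms.
#' @param epsilon efficiency classification tolerance defining the top bin.
#' @return data.frame of class `te_frequency_table` with columns `bin`,
#'   `n_farms`, `share_pct`, `mean_te`; the last row is the total.
#' @export
#' @examples
#' te_frequency_table(c(0.45, 0.65, 0.65, 0.95, 1, 1))
te_frequency_table <- function(results,
                               bin_edges = c(0.60, 0.70, 0.80, 0.90),
                               epsilon = 1e-6) {
  te <- .te_from(results)
  stopifnot(is.numeric(bin_edges), !is.unsorted(bin_edges, strictly = TRUE),
            all(bin_edges > 0), all(bin_edges < 1))
  edges <- c(0, bin_edges, 1 - epsilon, 1 + 1e-12)
  idx <- findInterval(te, edges, rightmost.closed = FALSE)
  k <- length(edges) - 1L
  two_dec <- function(z) formatC(z, format = "f", digits = 2)
  labels <- c(paste0("<", two_dec(bin_edges[1])),
              paste0(two_dec(edges[2:(k - 1L)]), "-",
                     two_dec(pmin(edges[3:k], 1) - 0.01)),
              "1.00")
  n <- length(te)
  counts <- tabulate(idx, nbins = k)
  means <- vapply(seq_len(k), function(b)
    if (counts[b]) mean(te[idx == b]) else NA_real_, numeric(1))
  out <- data.frame(bin = c(labels, "Total"),
                    n_farms = c(counts, n),
                    share_pct = c(100 * counts / n, 100),
                    mean_te = c(means, mean(te)),
                    stringsAsFactors = FALSE)
  class(out) <- c("te_frequency_table", "data.frame")
  out
}

#' Percent increase from existing to target output
#'
#' @param existing existing (observed) value, > 0.
#' @param target efficient-target value.
#' @param digits optional rounding of the reported percentage.
#' @return 100 * (target / existing - 1).
#' @export
#' @examples
#' percent_increase(81624, 111964)   # 37.2
percent_increase <- function(existing, target, digits = NULL) {
  stopifnot(is.numeric(existing), is.numeric(target))
  if (any(existing <= 0)) stop("existing output must be > 0", call. = FALSE)
  p <- 100 * (target / existing - 1)
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Existing versus efficient-target output by size class
#'
#' Per size class (and overall): farm count, mean observed output, mean
#' slack-adjusted frontier target and the percent increase between the two
#' means. Empty classes are kept with a zero count and NA means.
#'
#' @param records farm table aligned row-by-row with `results`.
#' @param results `dea_result` from [solve_all()] on those records.
#' @param scheme optional [size_class_scheme()]; defaults to the scheme of
#'   the table's farm type.
#' @return data.frame of class `projection_summary` with columns
#'   `size_class`, `n_farms`, `existing_output`, `target_output`,
#'   `pct_increase`.
#' @export
projection_summary <- function(records, results, scheme = NULL) {
  validate_farm_table(records)
  stopifnot(nrow(records) == nrow(results))
  if (is.null(scheme)) scheme <- size_class_scheme(records$farm_type[1])
  cls <- assign_size_class(records$ewes, scheme)
  one <- function(sel, label) {
    n <- sum(sel)
    ex <- if (n) mean(records$gross_revenue[sel]) else NA_real_
    tg <- if (n) mean(results$projected_output[sel]) else NA_real_
    data.frame(size_class = label, n_farms = n,
               existing_output = ex, target_output = tg,
               pct_increase = if (n) percent_increase(ex, tg) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(cls == "small", "small"),
               one(cls == "medium", "medium"),
               one(cls == "large", "large"),
               one(rep(TRUE, length(cls)), "all"))
  class(out) <- c("projection_summary", "data.frame")
  out
}

.group_rows <- function(te, epsilon) {
  g <- classify_groups(te, epsilon)
  list(inefficient = g$inefficient, efficient = g$efficient,
       average = seq_along(te))
}

#' Gross-revenue composition per ewe by efficiency group
#'
#' For the inefficient, efficient and average farm: the unweighted group mean
#' of each per-ewe revenue component (lambs sold for meat, lambs sold for
#' breeding, cull animals, subsidies, wool and other products), the group
#' total and each component's percentage share of that total. Components that
#' are entirely unavailable in a group (e.g. UK subsidies) are excluded from
#' the total and reported as NA; the excluded set is attached as attribute
#' `excluded_components`.
#'
#' @param records farm table with revenue-component columns.
#' @param results `dea_result` or TE vector aligned with `records`.
#' @param epsilon efficiency classification tolerance.
#' @return data.frame of class `revenue_composition`: one row per group with
#'   `group`, `mean_te`, `n_farms`, one `<component>` column (EUR/ewe) and
#'   one `pct_<component>` column per component, and `total` (EUR/ewe).
#' @export
revenue_composition <- function(records, results, epsilon = 1e-6) {
  validate_farm_table(records)
  te <- .te_from(results)
  stopifnot(nrow(records) == length(te))
  comps <- intersect(.component_cols, names(records))
  if (!length(comps) || all(vapply(records[comps], function(v) all(is.na(v)),
                                   logical(1))))
    stop("no revenue components available", call. = FALSE)
  groups <- .group_rows(te, epsilon)
  excluded <- character(0)
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    per_ewe <- vapply(comps, function(cc) {
      v <- records[[cc]][idx] / records$ewes[idx]
      if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    if (length(idx)) excluded <<- union(excluded, comps[is.na(per_ewe)])
    total <- if (length(idx)) sum(per_ewe, na.rm = TRUE) else NA_real_
    row <- data.frame(group = gname,
                      mean_te = if (length(idx)) mean(te[idx]) else NA_real_,
                      n_farms = length(idx), stringsAsFactors = FALSE)
    for (cc in comps) row[[cc]] <- per_ewe[[cc]]
    row$total <- total
    for (cc in comps) row[[paste0("pct_", cc)]] <- 100 * per_ewe[[cc]] / total
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("revenue_composition", "data.frame")
  attr(out, "excluded_components") <- excluded
  attr(out, "group_means") <- "unweighted mean over farms of per-ewe ratios"
  out
}

#' Gross margin per ewe
#'
#' Gross revenue less the variable cost, here feed cost plus variable capital
#' cost (veterinary/drugs, bedding, recording, land rent), all EUR/ewe.
#'
#' @param gross_revenue,feed_cost,variable_capital_cost EUR/ewe.
#' @return gross margin, EUR/ewe.
#' @export
#' @examples
#' gross_margin(192, 60, 27)   # 105
gross_margin <- function(gross_revenue, feed_cost, variable_capital_cost) {
  gross_revenue - feed_cost - variable_capital_cost
}

#' Production cost per ewe
#'
#' Sum of labor, feed, variable capital and fixed capital costs, EUR/ewe.
#'
#' @param labor_cost,feed_cost,variable_capital_cost,fixed_capital_cost
#'   EUR/ewe.
#' @return production cost, EUR/ewe.
#' @export
production_cost <- function(labor_cost, feed_cost, variable_capital_cost,
                            fixed_capital_cost) {
  labor_cost + feed_cost + variable_capital_cost + fixed_capital_cost
}

#' Net profit (or loss) per ewe
#'
#' Gross revenue less production cost, EUR/ewe.
#'
#' @param gross_revenue,production_cost EUR/ewe.
#' @return profit, EUR/ewe.
#' @export
#' @examples
#' net_profit(144, 121)   # 23
net_profit <- function(gross_revenue, production_cost) {
  gross_revenue - production_cost
}

#' Techno-economic indicators by efficiency group
#'
#' Per group (inefficient, efficient, average): flock size, lambs sold per
#' farm and per ewe, labor productivity (ewes per annual labor unit), feed
#' supplied, the per-ewe cost components, and the derived indicators
#' production cost, gross revenue, gross margin and profit per ewe. Derived
#' indicators are computed per farm from unrounded components and then
#' averaged (unweighted) over the group. Indicators whose ingredients are
#' absent from the table are reported as NA.
#'
#' @inheritParams revenue_composition
#' @return data.frame of class `economic_indicators`: one row per indicator
#'   with columns `indicator`, `inefficient`, `efficient`, `average`.
#' @export
economic_indicators <- function(records, results, epsilon = 1e-6) {
  validate_farm_table(records)
  te <- .te_from(results)
  stopifnot(nrow(records) == length(te))
  groups <- .group_rows(te, epsilon)

  col <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, nrow(records))
  per_farm <- list(
    n_farms             = rep(1, nrow(records)),
    ewes                = records$ewes,
    lambs_sold_per_farm = col("lambs_sold"),
    lambs_sold_per_ewe  = col("lambs_sold") / records$ewes,
    ewes_per_alu        = records$ewes / col("alu"),
    feed_kg_dm_per_ewe  = col("feed_kg_dm_per_ewe"),
    labor_cost          = col("labor_cost"),
    feed_cost           = col("feed_cost"),
    purchased_feed      = col("purchased_feed"),
    homegrown_feed      = col("homegrown_feed"),
    variable_capital_cost = col("variable_capital_cost"),
    fixed_capital_cost  = col("fixed_capital_cost"),
    production_cost     = production_cost(col("labor_cost"), col("feed_cost"),
                                          col("variable_capital_cost"),
                                          col("fixed_capital_cost")),
    gross_revenue       = records$gross_revenue / records$ewes,
    gross_margin        = gross_margin(records$gross_revenue / records$ewes,
                                       col("feed_cost"),
                                       col("variable_capital_cost")),
    profit              = net_profit(records$gross_revenue / records$ewes,
                                     production_cost(col("labor_cost"),
                                                     col("feed_cost"),
                                                     col("variable_capital_cost"),
                                                     col("fixed_capital_cost")))
  )
  gmean <- function(v, idx) {
    if (!length(idx) || all(is.na(v[idx]))) NA_real_ else mean(v[idx],
                                                               na.rm = TRUE)
  }
  out <- data.frame(indicator = names(per_farm), stringsAsFactors = FALSE)
  for (g in names(groups)) {
    out[[g]] <- vapply(per_farm, gmean, numeric(1), idx = groups[[g]])
  }
  out$inefficient[1] <- length(groups$inefficient)
  out$efficient[1] <- length(groups$efficient)
  out$average[1] <- length(groups$average)
  class(out) <- c("economic_indicators", "data.frame")
  attr(out, "group_means") <- "unweighted mean over farms of per-ewe ratios"
  out
}
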