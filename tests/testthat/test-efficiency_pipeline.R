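# grouping, frequency tables, projections, composition and indicators

te_sample <- c(0.45, 0.55, 0.62, 0.695, 0.71, 0.80, 0.85, 0.93, 1, 1)

test_that("efficiency grouping is a disjoint exhaustive partition", {
  g <- classify_groups(te_sample)
  expect_length(intersect(g$efficient, g$inefficient), 0)
  expect_setequal(c(g$efficient, g$inefficient), seq_along(te_sample))
  expect_equal(classify_groups(c(1, 0.9))$efficient, 1L)
  # threshold rule: within epsilon of 1 counts as efficient
  expect_equal(classify_groups(1 - 1e-9, epsilon = 1e-6)$efficient, 1L)
  expect_equal(length(classify_groups(1 - 1e-4, epsilon = 1e-6)$efficient), 0)
})

test_that("frequency table bins on unrounded TE and totals are consistent", {
  tab <- te_frequency_table(te_sample)
  expect_equal(tab$n_farms, c(2, 2, 1, 2, 1, 2, 10))
  expect_equal(sum(tab$n_farms[1:6]), tab$n_farms[7])
  expect_equal(sum(tab$share_pct[1:6]), 100, tolerance = 0.1)
  # weighted bin means reproduce the overall mean
  w <- tab$n_farms[1:6]
  m <- tab$mean_te[1:6]
  expect_equal(sum(w * m, na.rm = TRUE) / sum(w), tab$mean_te[7],
               tolerance = 1e-12)
  # 0.695 must land in [0.60, 0.70): binning happens before any rounding
  tab2 <- te_frequency_table(c(0.695, 1))
  expect_equal(tab2$n_farms[2], 1)
  expect_equal(tab2$bin[1:6], c("<0.60", "0.60-0.69", "0.70-0.79",
                                "0.80-0.89", "0.90-0.99", "1.00"))
})

test_that("degenerate and invalid TE inputs are handled", {
  tab <- te_frequency_table(rep(1, 7))
  expect_equal(tab$n_farms[6], 7)
  expect_equal(tab$mean_te[7], 1)
  expect_error(te_frequency_table(c(0.5, 1.2)), "outside")
  expect_error(te_frequency_table(c(0.5, -0.1)), "outside")
})

test_that("frequency counts match an independent binning pass", {
  set.seed(11)
  te <- pmin(stats::runif(300, 0.2, 1.05), 1)
  tab <- te_frequency_table(te)
  edges <- c(0, 0.6, 0.7, 0.8, 0.9, 1 - 1e-6, 1.1)
  manual <- as.integer(table(cut(te, edges, right = FALSE)))
  expect_equal(tab$n_farms[1:6], manual)
})

test_that("percent increase follows its definition", {
  expect_equal(percent_increase(81624, 111964), 37.2, tolerance = 0.05)
  expect_equal(percent_increase(50, 75), 50)
  expect_equal(percent_increase(10, 10), 0)
  expect_equal(percent_increase(100, 137.17, digits = 1), 37.2)
  expect_error(percent_increase(0, 10), "existing")
})

test_that("projection summary aggregates by size class with dominance", {
  set.seed(21)
  spec <- synthetic_spec("french_extensive",
                         class_counts = c(small = 15, medium = 10,
                                          large = 15),
                         n_efficient = 9, seed = 33)
  pop <- generate_population(spec)
  res <- solve_all(dea_problem(pop$records))
  ps <- projection_summary(pop$records, res)
  expect_equal(ps$size_class, c("small", "medium", "large", "all"))
  expect_equal(sum(ps$n_farms[1:3]), ps$n_farms[4])
  expect_true(all(ps$target_output >= ps$existing_output - 1e-9))
  expect_true(all(ps$pct_increase >= -1e-9))
  # overall row equals direct means
  expect_equal(ps$existing_output[4], mean(pop$records$gross_revenue))
  expect_equal(ps$target_output[4], mean(res$projected_output))
})

test_that("an all-efficient population projects a zero percent increase", {
  spec <- synthetic_spec("french_intensive",
                         class_counts = c(small = 4, medium = 4, large = 4),
                         n_efficient = 12, seed = 8)
  pop <- generate_population(spec)
  res <- solve_all(dea_problem(pop$records))
  ps <- projection_summary(pop$records, res)
  expect_equal(ps$pct_increase, rep(0, 4), tolerance = 1e-6)
})

test_that("revenue composition reproduces shares and respects NA components", {
  # one farm whose revenue is entirely lamb meat
  df <- data.frame(farm_id = "a", farm_type = "french_extensive", ewes = 100,
                   labor = 500, variable_cost = 1000, fixed_cost = 1000,
                   gross_revenue = 9000, lambs_meat = 9000,
                   lambs_breeding = 0, culls = 0, subsidies = 0,
                   wool_other = 0, stringsAsFactors = FALSE)
  rc <- revenue_composition(df, 1)
  expect_equal(rc$pct_lambs_meat[rc$group == "efficient"], 100)
  # published efficient-group per-ewe means reproduce the printed shares
  means <- c(lambs_meat = 109.25, lambs_breeding = 30.37, culls = 8.02,
             subsidies = 26.35, wool_other = 4.57)
  one <- data.frame(farm_id = "e", farm_type = "french_extensive", ewes = 1,
                    labor = 1, variable_cost = 1, fixed_cost = 1,
                    gross_revenue = sum(means), lambs_meat = means[1],
                    lambs_breeding = means[2], culls = means[3],
                    subsidies = means[4], wool_other = means[5],
                    stringsAsFactors = FALSE)
  rc2 <- revenue_composition(one, 1)
  eff <- rc2[rc2$group == "efficient", ]
  expect_equal(round(eff$total, 2), 178.56)
  expect_equal(round(c(eff$pct_lambs_meat, eff$pct_lambs_breeding,
                       eff$pct_culls, eff$pct_subsidies,
                       eff$pct_wool_other), 2),
               c(61.18, 17.01, 4.49, 14.76, 2.56))
  # NA subsidies (UK case) are excluded from the total, not zeroed
  uk <- one
  uk$farm_type <- "uk_extensive"
  uk$subsidies <- NA_real_
  uk$gross_revenue <- sum(means[-4])
  rc3 <- revenue_composition(uk, 1)
  eff3 <- rc3[rc3$group == "efficient", ]
  expect_true("subsidies" %in% attr(rc3, "excluded_components"))
  expect_equal(eff3$total, sum(means[-4]), tolerance = 1e-9)
  expect_true(is.na(eff3$pct_subsidies))
})

test_that("composition shares sum to 100 and match a manual recomputation", {
  set.seed(31)
  spec <- synthetic_spec("spanish_semi_intensive", seed = 41)
  pop <- generate_population(spec)
  rc <- revenue_composition(pop$records, pop$te_true)
  pct <- as.matrix(rc[, grep("^pct_", names(rc))])
  expect_equal(rowSums(pct, na.rm = TRUE), rep(100, 3), tolerance = 0.05)
  idx <- classify_groups(pop$te_true)$efficient
  manual <- mean(pop$records$lambs_meat[idx] / pop$records$ewes[idx])
  expect_equal(rc$lambs_meat[rc$group == "efficient"], manual)
  expect_error(revenue_composition(pop$records[, 1:7], pop$te_true),
               "components")
})

test_that("economic indicators honor the accounting identities", {
  expect_equal(gross_margin(192, 60, 27), 105)
  expect_equal(net_profit(144, 121), 23)
  expect_equal(gross_margin(10, 0, 0), 10)
  set.seed(51)
  spec <- synthetic_spec("uk_extensive", seed = 61)
  pop <- generate_population(spec)
  ind <- economic_indicators(pop$records, pop$te_true)
  get <- function(nm, g) ind[[g]][ind$indicator == nm]
  for (g in c("inefficient", "efficient", "average")) {
    expect_equal(get("production_cost", g),
                 production_cost(get("labor_cost", g), get("feed_cost", g),
                                 get("variable_capital_cost", g),
                                 get("fixed_capital_cost", g)),
                 tolerance = 1e-9)
    expect_equal(get("profit", g),
                 get("gross_revenue", g) - get("production_cost", g),
                 tolerance = 1e-9)
    expect_equal(get("gross_margin", g),
                 gross_margin(get("gross_revenue", g), get("feed_cost", g),
                              get("variable_capital_cost", g)),
                 tolerance = 1e-9)
    expect_equal(get("feed_cost", g),
                 get("purchased_feed", g) + get("homegrown_feed", g),
                 tolerance = 1e-9)
  }
  # overall mean of any indicator lies between the group means
  for (nm in c("gross_revenue", "gross_margin", "profit", "ewes")) {
    vals <- c(get(nm, "inefficient"), get(nm, "efficient"))
    expect_gte(get(nm, "average"), min(vals) - 1e-9)
    expect_lte(get(nm, "average"), max(vals) + 1e-9)
  }
  # missing ingredients yield NA indicators, not errors
  slim <- pop$records[, c(names(pop$records)[1:7], "lambs_sold")]
  ind2 <- economic_indicators(slim, pop$te_true)
  expect_true(is.na(ind2$average[ind2$indicator == "gross_margin"]))
  expect_false(is.na(ind2$average[ind2$indicator == "lambs_sold_per_ewe"]))
})
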