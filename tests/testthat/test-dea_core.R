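# DEA core: analytic cases, oracle equivalence and model invariants

test_that("a lone DMU envelops itself", {
  prob <- dea_problem(matrix(c(3, 2), 1, 2), y = 5)
  res <- solve_all(prob)
  expect_equal(res$theta, 1, tolerance = 1e-9)
  expect_equal(res$te, 1)
  expect_true(res$is_efficient)
})

test_that("a dominated twin doubles its output radially", {
  # identical inputs, half the output: theta = 2, TE = 0.5
  prob <- dea_problem(matrix(c(5, 5), 2, 1), y = c(100, 50))
  res <- solve_all(prob)
  expect_equal(res$theta, c(1, 2), tolerance = 1e-9)
  expect_equal(res$te, c(1, 0.5), tolerance = 1e-9)
})

test_that("the convexity constraint protects small units (VRS)", {
  # A(x=2, y=2), B(x=1, y=1): under constant returns B would be scaled from
  # A; under VRS no convex combination fits under B's input, so B is efficient
  prob <- dea_problem(matrix(c(2, 1), 2, 1), y = c(2, 1))
  res <- solve_all(prob)
  expect_equal(res$theta, c(1, 1), tolerance = 1e-9)
})

test_that("weakly efficient units keep theta = 1 but carry input slack", {
  # B matches A's output with 4 extra units of input 2
  X <- rbind(A = c(1, 1), B = c(1, 5))
  prob <- dea_problem(X, y = c(10, 10))
  th <- solve_theta(prob, 2)
  expect_equal(th$theta, 1, tolerance = 1e-9)
  sl <- maximize_slacks(prob, 2, th$theta)
  expect_equal(sl$input_slacks, c(0, 4), tolerance = 1e-8)
  expect_equal(sl$output_slack, 0, tolerance = 1e-8)
  # the frontier vertex itself has no slack anywhere
  sl_a <- maximize_slacks(prob, 1, solve_theta(prob, 1)$theta)
  expect_equal(max(sl_a$input_slacks, sl_a$output_slack), 0, tolerance = 1e-8)
})

test_that("TE and projection arithmetic follow their definitions", {
  expect_equal(compute_te(c(1, 1.25, 2)), c(1, 0.8, 0.5))
  expect_error(compute_te(0), "positive")
  expect_equal(project_to_frontier(100, 1.372), 137.2)
  expect_equal(project_to_frontier(100, 1), 100)
  expect_equal(project_to_frontier(50, 1.2, 5), 65)
})

test_that("radial phase matches the enumeration oracle on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    inst <- random_instance(sample(3:6, 1), sample(1:2, 1))
    prob <- dea_problem(inst$X, inst$y)
    i <- sample(nrow(inst$X), 1)
    th <- solve_theta(prob, i)$theta
    expect_equal(th, oracle_theta(inst$X, inst$y, i), tolerance = 1e-6)
  }
})

test_that("slack phase matches the enumeration oracle's total slack", {
  set.seed(202)
  for (rep in 1:25) {
    inst <- random_instance(sample(3:6, 1), 2)
    prob <- dea_problem(inst$X, inst$y)
    i <- sample(nrow(inst$X), 1)
    th <- solve_theta(prob, i)$theta
    sl <- maximize_slacks(prob, i, th)
    expect_equal(sum(sl$input_slacks) + sl$output_slack,
                 oracle_total_slack(inst$X, inst$y, i, th),
                 tolerance = 1e-6)
  }
})

test_that("theta is invariant to input units and output scale", {
  set.seed(303)
  inst <- random_instance(6, 2)
  base <- solve_all(dea_problem(inst$X, inst$y))$theta
  for (cc in c(0.01, 7, 1000)) {
    Xu <- inst$X
    Xu[, 1] <- Xu[, 1] * cc
    expect_equal(solve_all(dea_problem(Xu, inst$y))$theta, base,
                 tolerance = 1e-6)
    expect_equal(solve_all(dea_problem(inst$X, inst$y * cc))$theta, base,
                 tolerance = 1e-6)
  }
})

test_that("appending a DMU never raises anyone's TE, dropping an inefficient one changes nothing", {
  set.seed(404)
  for (rep in 1:10) {
    inst <- random_instance(6, 2)
    res <- solve_all(dea_problem(inst$X, inst$y))
    new <- random_instance(1, 2)
    res2 <- solve_all(dea_problem(rbind(inst$X, new$X), c(inst$y, new$y)))
    expect_true(all(res2$te[1:6] <= res$te + 1e-9))
    drop <- which(res$te < 1 - 1e-6)
    if (length(drop)) {
      d <- drop[1]
      res3 <- solve_all(dea_problem(inst$X[-d, , drop = FALSE], inst$y[-d]))
      expect_equal(res3$te, res$te[-d], tolerance = 1e-8)
    }
  }
})

test_that("re-solving with the projected point appended yields theta = 1 for it", {
  set.seed(505)
  for (rep in 1:10) {
    inst <- random_instance(5, 2)
    prob <- dea_problem(inst$X, inst$y)
    res <- solve_all(prob)
    i <- which.max(res$theta)
    proj_x <- c(res$projected_input_1[i], res$projected_input_2[i])
    proj_y <- res$projected_output[i]
    res2 <- solve_all(dea_problem(rbind(inst$X, proj_x), c(inst$y, proj_y)))
    expect_equal(res2$theta[6], 1, tolerance = 1e-7)
  }
})

test_that("identical DMUs are all efficient and the max-output DMU always is", {
  X <- matrix(rep(c(2, 3), each = 4), 4, 2)
  res <- solve_all(dea_problem(X, rep(7, 4)))
  expect_true(all(abs(res$theta - 1) < 1e-9))
  set.seed(606)
  inst <- random_instance(8, 2)
  res2 <- solve_all(dea_problem(inst$X, inst$y))
  expect_equal(res2$theta[which.max(inst$y)], 1, tolerance = 1e-9)
})

test_that("six DMUs built from frontier anchors recover their constructed TE", {
  # three anchors on a strictly concave frontier, three copies scaled down
  Xa <- rbind(c(1, 2), c(3, 4), c(6, 7))
  ya <- c(10, 16, 19)
  te_true <- c(0.8, 0.5, 1)
  X <- rbind(Xa, Xa)
  y <- c(ya, ya * te_true)
  res <- solve_all(dea_problem(X, y))
  expect_equal(res$te, c(1, 1, 1, te_true), tolerance = 1e-6)
})

test_that("invalid problems and solver failures are loud", {
  expect_error(dea_problem(matrix(1, 1, 1), y = -2), "positive")
  expect_error(dea_problem(matrix(0, 2, 1), y = c(1, 1)), "positive input")
  expect_error(dea_problem(matrix(-1, 1, 1), y = 1), "nonnegative")
  prob <- dea_problem(matrix(c(1, 2), 2, 1), y = c(1, 2))
  expect_error(solve_theta(prob, 5), "i <=")
})

test_that("solve_all is deterministic and serializes both formats", {
  set.seed(707)
  inst <- random_instance(6, 2)
  prob <- dea_problem(inst$X, inst$y)
  r1 <- solve_all(prob)
  r2 <- solve_all(prob)
  expect_identical(r1$theta, r2$theta)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_dea_results(r1, csv, "csv")
  write_dea_results(r1, js, "json")
  expect_equal(nrow(utils::read.csv(csv)), 6)
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, 6)
  expect_true(all(vapply(parsed, function(p) length(p$reference_set) >= 1,
                         logical(1))))
})
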