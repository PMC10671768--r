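surv3 <- c(70, 90, 100)
ent3 <- c(11.4332400, 11.4294941, 11.4150921)

test_that("orthogonal and ordinary fits agree on the 3-point calibration", {
  tls <- fit_survline(surv3, ent3, method = "tls")
  ols <- fit_survline(surv3, ent3, method = "ols")
  # y-scatter is tiny relative to x-scatter, so the two methods nearly match
  expect_equal(tls$slope, ols$slope, tolerance = 1e-4)
  expect_equal(tls$intercept, ols$intercept, tolerance = 1e-6)
  expect_equal(tls$n_points, 3L)
  expect_equal(coef(tls),
               c(intercept = tls$intercept, slope = tls$slope))
})

test_that("exactly collinear points return the exact line under both methods", {
  for (m in c("tls", "ols")) {
    fit <- fit_survline(c(0, 1, 2), c(1, 3, 5), method = m)
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 1, tolerance = 1e-12)
  }
  # two points: the unique interpolating line
  two <- fit_survline(c(10, 20), c(5, 3), method = "tls")
  expect_equal(two$slope, -0.2, tolerance = 1e-12)
  expect_equal(two$intercept, 7, tolerance = 1e-12)
})

test_that("degenerate calibrations are rejected", {
  expect_error(fit_survline(5, 1), "at least 2")
  expect_error(fit_survline(c(50, 50), c(1, 2)), "degenerate")
  expect_error(fit_survline(c(1, 2), c(3, Inf)), "non-finite")
})

test_that("survival prediction inverts the line, with optional capping", {
  fit <- fit_survline(surv3, ent3)
  expect_equal(predict(fit, fit$intercept + 100 * fit$slope), 100,
               tolerance = 1e-9)
  expect_equal(predict(fit, 11.4332400), 73.28, tolerance = 1e-3)
  # capping clips optimistic predictions
  low_h <- fit$intercept + 106.6 * fit$slope
  expect_gt(predict(fit, low_h), 100)
  expect_equal(predict(fit, low_h, cap_at_100 = TRUE), 100)
  expect_error(predict(survline(0, 1)), "zero|invert")
})

test_that("entropy threshold evaluates the line at the survival goal", {
  pan <- survline(-0.004, 2.507)
  expect_equal(entropy_threshold(pan, 100), 2.107, tolerance = 1e-12)
  expect_equal(entropy_threshold(pan, 0), 2.507)
  b <- hub_calibration("breast-cell-lines-2020")
  expect_equal(entropy_threshold(b, 100), 11.41867, tolerance = 1e-5)
  # prediction of the threshold entropy recovers the goal
  for (goal in c(100, 85, 60)) {
    expect_equal(predict(pan, entropy_threshold(pan, goal)), goal,
                 tolerance = 1e-9)
    expect_equal(predict(b, entropy_threshold(b, goal)), goal,
                 tolerance = 1e-9)
  }
})

test_that("built-in calibrations are available by name", {
  expect_setequal(hub_calibration(),
                  c("breast-cell-lines-2020", "pancancer-2019"))
  expect_equal(hub_calibration("pancancer-2019")$slope, -0.004)
  expect_equal(hub_calibration("pancancer-2019")$entropy_variant,
               "unspecified")
  expect_error(hub_calibration("nope"), "unknown")
})

test_that("survline round-trips through JSON", {
  fit <- fit_survline(surv3, ent3)
  f <- withr::local_tempfile(fileext = ".json")
  write_survline(fit, f)
  back <- read_survline(f)
  expect_equal(back$slope, fit$slope, tolerance = 1e-12)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(back$method, "tls")
})

test_that("calibration points read from TSV with or without header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("survival_pct\tentropy", "70\t11.4332400", "90\t11.4294941",
               "100\t11.4150921"), f)
  pts <- read_calibration_points(f)
  expect_equal(pts$survival_pct, surv3)
  expect_equal(pts$entropy, ent3)
  fit <- fit_survline(pts)
  expect_equal(fit$n_points, 3L)
})

test_that("targets_needed counts removals until the entropy threshold", {
  g <- gen_network(200, 2, seed = 21)
  calls <- fake_calls(igraph::V(g)$name, rep("up", 200))
  rk <- rank_hubs(g, up_subnetwork(g, calls), calls)
  h0 <- net_entropy(g, "degree_class", 2)$value
  # pick a goal whose threshold sits strictly inside the attack trajectory
  traj <- net_attack(g, targets = rk$gene_id[1:30], variant = "degree_class")
  thr <- (min(traj$entropy) + h0) / 2
  line <- survline(-0.004, 2.507)
  goal <- (thr - 2.507) / -0.004
  res <- targets_needed(g, rk, line, survival_goal = goal,
                        variant = "degree_class", log_base = 2)
  expect_true(res$reachable)
  expect_gte(res$count, 1)
  expect_lte(res$trajectory$entropy[res$count], res$threshold)
  if (res$count > 1) {
    expect_true(all(res$trajectory$entropy[seq_len(res$count - 1)] >
                      res$threshold))
  }
})

test_that("targets_needed handles already-met and unreachable goals", {
  s4 <- star_s4()
  line <- survline(-0.004, 2.507)
  # star degree-class entropy ~0.72 is already below the 2.107 threshold
  res0 <- targets_needed(s4, c("c", "l1"), line, survival_goal = 100,
                         variant = "degree_class", log_base = 2)
  expect_equal(res0$count, 0L)
  expect_true(res0$reachable)
  # negative threshold can never be reached: flagged, not an exception
  goal_neg <- (2.507 + 1) / 0.004  # threshold -1
  res1 <- targets_needed(s4, c("c", "l1"), line, survival_goal = goal_neg,
                         variant = "degree_class", log_base = 2)
  expect_false(res1$reachable)
  expect_equal(res1$count, 2L)
  expect_gte(res1$final_entropy, 0)
})

test_that("targets_needed count is non-increasing as the goal relaxes", {
  g <- gen_network(150, 2, seed = 33)
  calls <- fake_calls(igraph::V(g)$name, rep("up", 150))
  rk <- rank_hubs(g, up_subnetwork(g, calls), calls)
  h0 <- net_entropy(g, "degree_class", 2)$value
  line <- survline(-0.004, h0 + 0.38)  # thresholds straddle the trajectory
  goals <- c(100, 80, 60, 40, 20)
  counts <- vapply(goals, function(goal) {
    r <- targets_needed(g, rk, line, survival_goal = goal,
                        variant = "degree_class", log_base = 2)
    if (r$reachable) r$count else length(rk$gene_id) + 1L
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mixing a line with a differently-declared entropy variant is refused", {
  line <- fit_survline(surv3, ent3, entropy_variant = "vertex", log_base = 2)
  s4 <- star_s4()
  expect_error(targets_needed(s4, "c", line, variant = "degree_class"),
               "differs from the calibration")
  expect_silent(res <- targets_needed(s4, "c", line,
                                      variant = "degree_class",
                                      allow_mismatch = TRUE))
  # unspecified declarations pass without a check
  expect_silent(targets_needed(s4, "c", survline(-1, 10),
                               variant = "degree_class"))
})
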