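test_that("CNR is the mean of per-field ratios", {
  f10 <- data.frame(sample_id = "S1", field_index = 1:10,
                    n_centrosomes = 50, n_nuclei = 50)
  expect_equal(compute_cnr(f10)$cnr, 1.0)

  f2 <- data.frame(sample_id = "S1", field_index = 1:2,
                   n_centrosomes = c(20, 10), n_nuclei = c(10, 10))
  res <- compute_cnr(f2)
  expect_equal(res$cnr, 1.5)
  expect_equal(res$cnr_pooled, 30 / 20)

  # zero-nuclei fields are excluded; all-zero is an error
  f3 <- data.frame(sample_id = "S1", field_index = 1:3,
                   n_centrosomes = c(10, 10, 99), n_nuclei = c(10, 10, 0))
  expect_equal(compute_cnr(f3)$n_fields_excluded, 1L)
  f4 <- data.frame(sample_id = "S1", field_index = 1,
                   n_centrosomes = 5, n_nuclei = 0)
  expect_error(compute_cnr(f4), "zero nuclei")

  # identical fields reproduce the single ratio exactly
  f5 <- data.frame(sample_id = "S1", field_index = 1:10,
                   n_centrosomes = 17, n_nuclei = 12)
  expect_equal(compute_cnr(f5)$cnr, 17 / 12)
})

test_that("Poisson field noise still recovers the underlying ratio", {
  cfg <- simulation_config(seed = 2, cohort = list(n_samples = 200))
  sim <- simulate_cohort(cfg)
  cnr <- compute_cnr(sim$fields)
  err <- cnr$cnr - sim$cohort$true_cnr
  # per-sample standard error ~ sqrt(cnr / total nuclei)
  se <- sqrt(sim$cohort$true_cnr / (10 * 50))
  expect_gt(mean(abs(err) < 3 * se), 0.97)
})

test_that("depth-1 CART split minimizes Gini impurity with the low/high convention", {
  ct <- cart_threshold(c(1, 1, 2, 2), c(0, 0, 1, 1))
  expect_equal(ct$threshold, 1.5)
  expect_equal(ct$impurity, 0)
  expect_equal(as.character(ct$group), c("low", "low", "high", "high"))

  expect_error(cart_threshold(c(1, 2, 3, 4), c(1, 1, 1, 1)), "single outcome")

  set.seed(10)
  for (i in 1:40) {
    n <- sample(6:200, 1)
    v <- round(runif(n, 0.5, 2.5), 2)
    y <- rbinom(n, 1, plogis(3 * (v - 1.5)))
    if (length(unique(y)) < 2 || length(unique(v)) < 2) next
    got <- cart_threshold(v, y)
    want <- oracle_gini_split(v, y)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    expect_equal(got$impurity, want$impurity, tolerance = 1e-12)
  }
})

test_that("CART agrees with rpart on its chosen partition", {
  skip_if_not_installed("rpart")
  set.seed(64)
  for (i in 1:10) {
    v <- round(runif(60, 1, 2), 2)
    y <- rbinom(60, 1, plogis(6 * (v - 1.5)))
    if (length(unique(y)) < 2) next
    fit <- rpart::rpart(factor(y) ~ v, data = data.frame(v = v, y = y),
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       minbucket = 1,
                                                       cp = -1, xval = 0))
    if (nrow(fit$splits) == 0) next
    expect_equal(cart_threshold(v, y)$threshold,
                 unname(fit$splits[1, "index"]), tolerance = 1e-8)
  }
})

test_that("CART partition is invariant under strictly monotone transforms", {
  set.seed(3)
  v <- runif(40, 1, 2)
  y <- rbinom(40, 1, plogis(5 * (v - 1.4)))
  if (length(unique(y)) >= 2) {
    g1 <- cart_threshold(v, y)$group
    g2 <- cart_threshold(exp(2 * v), y)$group
    expect_identical(as.character(g1), as.character(g2))
  }
})

test_that("CNR classification uses the <= low / > high convention", {
  expect_equal(as.character(classify_cnr(1.50, 1.45)), "high")
  expect_equal(as.character(classify_cnr(1.45, 1.45)), "low")
  expect_equal(as.character(classify_cnr(1.02, 1.45)), "low")
})

test_that("Kaplan-Meier estimate equals the hand product-limit oracle", {
  km <- km_curve(c(5, 10), c(1, 0))
  expect_equal(km$survival[km$time == 5], 0.5)
  expect_equal(km$survival[km$time == 10], 0.5)

  none <- km_curve(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  set.seed(18)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    t <- round(rexp(n, 0.1), 1)
    e <- rbinom(n, 1, 0.7)
    km <- km_curve(t, e)
    o <- oracle_km(t, e)
    expect_equal(km$survival, o$survival[match(km$time, o$time)],
                 tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
  }
  # with no censoring KM equals the empirical survival function
  t <- c(1, 2, 2, 5, 7)
  km <- km_curve(t, rep(1, 5))
  expect_equal(km$survival, vapply(km$time, function(x) mean(t > x),
                                   numeric(1)))
})

test_that("log-rank matches the observed-minus-expected oracle", {
  same <- logrank(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  deg <- logrank(c(5, 6), c(0, 0), c(7, 8), c(0, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  set.seed(27)
  for (i in 1:25) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    ta <- round(rexp(na, 0.1), 1); tb <- round(rexp(nb, 0.2), 1)
    ea <- rbinom(na, 1, 0.8); eb <- rbinom(nb, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    got <- logrank(ta, ea, tb, eb)
    want <- oracle_logrank(ta, ea, tb, eb)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("Spearman association uses average ranks and the t approximation", {
  up <- spearman_assoc(1:10, (1:10)^2)
  expect_equal(up$rho, 1)
  down <- spearman_assoc(1:10, -(1:10))
  expect_equal(down$rho, -1)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "zero variance")

  set.seed(55)
  for (i in 1:15) {
    x <- sample(1:6, 30, replace = TRUE)  # heavy ties
    y <- x + sample(0:3, 30, replace = TRUE)
    got <- spearman_assoc(x, y)
    rho <- cor(rank(x), rank(y))  # Pearson on average ranks
    expect_equal(got$rho, rho, tolerance = 1e-12)
    tt <- rho * sqrt((30 - 2) / (1 - rho^2))
    expect_equal(got$p_value, 2 * pt(-abs(tt), 28), tolerance = 1e-9)
  }
})

test_that("simulated CNR cohorts recover the group structure end to end", {
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 300 + s, cohort = list(
      n_samples = 120, cnr_sd = 0.05, nuclei_per_field = 100,
      relapse_rate_low = log(2) / 0.75, hazard_ratio = 0.005,
      censoring_rate = 0.002))
    sim <- simulate_cohort(cfg)
    cnr <- compute_cnr(sim$fields)
    stopifnot(identical(cnr$sample_id, sim$cohort$sample_id))
    ct <- cart_threshold(cnr$cnr, sim$cohort$relapse_within_6mo)
    # oracle agreement must hold on every draw
    expect_equal(ct$threshold, oracle_gini_split(
      cnr$cnr, sim$cohort$relapse_within_6mo)$threshold, tolerance = 1e-12)
    recovered <- identical(
      as.character(classify_cnr(cnr$cnr, ct$threshold)),
      ifelse(sim$cohort$true_group == "low", "low", "high"))
    hits <- hits + recovered
  }
  expect_gte(hits / n_rep, 0.9)
})
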