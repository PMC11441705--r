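# configuration in which generation 1 divides exactly once on film and the
# daughters' full interphase fits inside the movie (2 x 2130 + 40 = 4300),
# so daughter deaths are never censored
one_round_config <- function(seed, n_lineages, phenos, deaths) {
  simulation_config(seed = seed, lineage = list(
    n_lineages = n_lineages,
    cycle_length = list(family = "fixed", value = 2130),
    mitosis_length = list(family = "fixed", value = 40),
    phenotype_probabilities = phenos,
    daughter_death_probability = deaths,
    death_in_mitosis_probability = 0,
    root_death_probability = 0))
}

test_that("per-lineage fate counts follow the tree structure", {
  single <- lineage_table(rec("L1.1", end = 900, fate = "DEATH_INTERPHASE"))
  lf <- lineage_fate_counts(single)
  expect_equal(lf$per_lineage$DEATH_INTERPHASE, 1)
  expect_equal(lf$per_lineage$n_cells, 1)

  lf3 <- lineage_fate_counts(three_cell_table())
  expect_equal(lf3$per_lineage$DIVIDED, 1)
  expect_equal(lf3$per_lineage$ALIVE_AT_END, 2)
  expect_equal(lf3$per_lineage$n_cells, 3)
  expect_error(lineage_fate_counts(three_cell_table()[0, ]), "empty")
})

test_that("mean deaths per lineage sit in the Monte-Carlo envelope", {
  # 200 lineages, one division round, per-daughter death probability 0.3
  cfg <- one_round_config(21, 200, c(NO_MISSEG = 1), c(NO_MISSEG = 0.3))
  tab <- simulate_lineages(cfg)
  lf <- lineage_fate_counts(tab)
  mean_deaths <- mean(lf$per_lineage$DEATH_INTERPHASE +
                        lf$per_lineage$DEATH_MITOSIS)
  # Monte-Carlo oracle at 10x replicates: each lineage contributes
  # Binomial(2, 0.3) deaths
  set.seed(91)
  oracle_means <- replicate(2000, mean(rbinom(200, 2, 0.3)))
  expect_gt(mean_deaths, quantile(oracle_means, 0.025) - 1e-9)
  expect_lt(mean_deaths, quantile(oracle_means, 0.975) + 1e-9)
})

test_that("generation fate percentages match direct enumeration", {
  tab <- lineage_table(rbind(
    rec("L1.1", end = 900, fate = "DEATH_INTERPHASE"),
    rec("L2.1", mitosis = 800, end = 900, fate = "DEATH_MITOSIS"),
    rec("L3.1", mitosis = 1000, end = 1040, phenotype = "NO_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L3.1.1", parent_id = "L3.1", generation = 2, birth = 1040),
    rec("L3.1.2", parent_id = "L3.1", generation = 2, birth = 1040),
    rec("L4.1", mitosis = 2000, end = 2040, phenotype = "SLIGHT_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L4.1.1", parent_id = "L4.1", generation = 2, birth = 2040),
    rec("L4.1.2", parent_id = "L4.1", generation = 2, birth = 2040)))
  fd <- generation_fate_percent(tab, 1)
  expect_equal(unname(fd$percent[c("DEATH_INTERPHASE", "DEATH_MITOSIS",
                                   "DIVIDED", "ALIVE_AT_END")]),
               c(25, 25, 50, 0))
  fd2 <- generation_fate_percent(tab, 2)
  expect_equal(unname(fd2$percent["ALIVE_AT_END"]), 100)
  expect_error(generation_fate_percent(tab, 5), "available")

  # brute-force recount on a simulated table
  sim <- simulate_lineages(simulation_config(seed = 13,
                                             lineage = list(n_lineages = 15)))
  for (g in sort(unique(sim$generation))) {
    fd <- generation_fate_percent(sim, g)
    r <- as.data.frame(sim)
    manual <- vapply(CELL_FATES, function(f) {
      k <- 0
      for (i in seq_len(nrow(r)))
        if (r$generation[i] == g && r$fate[i] == f) k <- k + 1
      k
    }, numeric(1))
    expect_equal(unname(fd$percent), unname(manual / sum(manual) * 100))
    expect_equal(sum(fd$percent), 100)
  }
})

test_that("mitosis-fate crosstab conditions progeny fate on mother phenotype", {
  tab <- lineage_table(rbind(
    rec("L1.1", mitosis = 500, end = 560, phenotype = "MULTIPOLAR",
        fate = "DIVIDED", n_daughters = 3),
    rec("L1.1.1", parent_id = "L1.1", generation = 2, birth = 560, end = 900,
        fate = "DEATH_INTERPHASE"),
    rec("L1.1.2", parent_id = "L1.1", generation = 2, birth = 560, end = 1200,
        fate = "DEATH_INTERPHASE"),
    rec("L1.1.3", parent_id = "L1.1", generation = 2, birth = 560)))
  ct <- mitosis_fate_crosstab(tab)
  row <- ct$rows[ct$rows$phenotype == "MULTIPOLAR", ]
  expect_equal(row$DEATH_INTERPHASE, 2 / 3)
  expect_equal(row$ALIVE_AT_END, 1 / 3)
  expect_equal(sum(ct$marginal$freq_divisions), 1)

  # only deaths in mitosis: a marginal class with no conditional rows
  dm <- lineage_table(rbind(
    rec("L1.1", mitosis = 700, end = 800, fate = "DEATH_MITOSIS"),
    rec("L2.1", mitosis = 900, end = 1000, fate = "DEATH_MITOSIS")))
  ct2 <- mitosis_fate_crosstab(dm)
  expect_equal(ct2$marginal$freq_divisions[ct2$marginal$class == "DEATH_MITOSIS"], 1)
  expect_null(ct2$rows)

  # no divisions at all: empty crosstab, not an error
  ct3 <- mitosis_fate_crosstab(lineage_table(rec("L1.1")))
  expect_equal(ct3$n_divisions, 0L)
})

test_that("crosstab recovers generator death probabilities", {
  cfg <- one_round_config(5, 600, c(NO_MISSEG = 0.7, MULTIPOLAR = 0.3),
                          c(NO_MISSEG = 0.12, MULTIPOLAR = 0.5))
  tab <- simulate_lineages(cfg)
  ct <- mitosis_fate_crosstab(tab, mother_generation = 1)
  for (case in list(c("NO_MISSEG", 0.12), c("MULTIPOLAR", 0.5))) {
    row <- ct$rows[ct$rows$phenotype == case[1], ]
    p <- as.numeric(case[2])
    phat <- row$DEATH_INTERPHASE + row$DEATH_MITOSIS
    se <- sqrt(p * (1 - p) / row$n_daughters)
    expect_lt(abs(phat - p), 3 * se)
    expect_equal(row$DIVIDED + row$DEATH_INTERPHASE + row$DEATH_MITOSIS +
                   row$ALIVE_AT_END, 1)
  }
})

test_that("durations extract interphase and mitosis lengths with censoring rules", {
  tab <- lineage_table(rbind(
    rec("L1.1", mitosis = 540, end = 600, phenotype = "NO_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L1.1.1", parent_id = "L1.1", generation = 2, birth = 600,
        mitosis = 1800, end = 1860, phenotype = "NO_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L1.1.1.1", parent_id = "L1.1.1", generation = 3, birth = 1860),
    rec("L1.1.1.2", parent_id = "L1.1.1", generation = 3, birth = 1860),
    rec("L1.1.2", parent_id = "L1.1", generation = 2, birth = 600)))
  d <- durations(tab)
  cell <- d$interphase[d$interphase$cell_id == "L1.1.1", ]
  expect_equal(cell$minutes, 1200)
  expect_equal(d$mitosis$minutes[d$mitosis$cell_id == "L1.1.1"], 60)
  # the root is excluded from interphase statistics
  expect_false("L1.1" %in% d$interphase$cell_id)
  expect_equal(unname(d$exclusions["interphase_root_censored"]), 1L)
})

test_that("lognormal cycle-length median is recovered within 5%", {
  cfg <- simulation_config(seed = 3, lineage = list(
    n_lineages = 150,
    cycle_length = list(family = "lognormal", meanlog = log(1200),
                        sdlog = 0.2),
    root_death_probability = 0, death_in_mitosis_probability = 0,
    daughter_death_probability = c(NO_MISSEG = 0),
    phenotype_probabilities = c(NO_MISSEG = 1)))
  d <- durations(simulate_lineages(cfg))
  expect_gt(nrow(d$interphase), 300)
  expect_lt(abs(median(d$interphase$minutes) - 1200) / 1200, 0.05)
})

test_that("mitotic entry times are grouped by first-mitosis phenotype", {
  tab <- lineage_table(rbind(
    rec("L1.1", mitosis = 300, end = 360, phenotype = "SLIGHT_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L1.1.1", parent_id = "L1.1", generation = 2, birth = 360),
    rec("L1.1.2", parent_id = "L1.1", generation = 2, birth = 360),
    rec("L2.1")))
  met <- mitotic_entry_times(tab)
  expect_equal(met$samples$entry_min[met$samples$group == "SLIGHT_MISSEG"], 300)
  expect_equal(unname(met$exclusions["no_mitotic_entry"]), 1L)
})

test_that("a programmed late switch to high mis-segregation is visible in entry times", {
  cfg <- simulation_config(seed = 17, lineage = list(
    n_lineages = 300,
    cycle_length = list(family = "lognormal", meanlog = log(1400),
                        sdlog = 0.35),
    phenotype_probabilities = c(NO_MISSEG = 1, HIGH_MISSEG = 0),
    phenotype_probabilities_late = c(NO_MISSEG = 0, HIGH_MISSEG = 1),
    t_switch_min = 1440,
    root_death_probability = 0, death_in_mitosis_probability = 0,
    daughter_death_probability = c(NO_MISSEG = 0.1, HIGH_MISSEG = 0.4)))
  met <- mitotic_entry_times(simulate_lineages(cfg))
  hi <- met$samples$entry_min[met$samples$group == "HIGH_MISSEG"]
  no <- met$samples$entry_min[met$samples$group == "NO_MISSEG"]
  expect_gt(length(hi), 20)
  expect_gt(length(no), 20)
  expect_true(all(hi >= 1440))
  expect_true(all(no < 1440))
  expect_gt(median(hi), median(no))
})

test_that("Fisher engine matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  m <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(fisher_exact_2x2(m)$p_value, oracle_fisher_two_sided(m),
               tolerance = 1e-12)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  set.seed(8)
  for (i in 1:60) {
    m <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact_2x2(m)$p_value
    expect_equal(p, oracle_fisher_two_sided(m), tolerance = 1e-12)
    # symmetric under swapping conditions and rows
    expect_equal(fisher_exact_2x2(m[, 2:1])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m[2:1, ])$p_value, p, tolerance = 1e-12)
  }
})

test_that("pooled-death Fisher test counts cells, not lineages", {
  a <- lineage_table(rbind(rec("L1.1", end = 600, fate = "DEATH_INTERPHASE"),
                           rec("L2.1")))
  b <- lineage_table(rbind(rec("L1.1"), rec("L2.1")))
  res <- fisher_pooled_death(a, b)
  expect_equal(unname(res$table["died", ]), c(1, 0))
  expect_equal(res$p_value, 1)  # 1/2 vs 0/2 is not distinguishable
})

test_that("chi-square phenotype comparison matches the textbook formula", {
  a <- lineage_table(rbind(
    rec("L1.1", mitosis = 500, end = 560, phenotype = "NO_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L1.1.1", parent_id = "L1.1", generation = 2, birth = 560),
    rec("L1.1.2", parent_id = "L1.1", generation = 2, birth = 560),
    rec("L2.1", mitosis = 700, end = 760, phenotype = "SLIGHT_MISSEG",
        fate = "DIVIDED", n_daughters = 2),
    rec("L2.1.1", parent_id = "L2.1", generation = 2, birth = 760),
    rec("L2.1.2", parent_id = "L2.1", generation = 2, birth = 760)))
  expect_equal(chi_square_phenotypes(a, a)$statistic, 0)
  expect_equal(chi_square_phenotypes(a, a)$p_value, 1)
  expect_error(chi_square_phenotypes(
    lineage_table(rec("L1.1")), lineage_table(rec("L2.1"))), "non-empty")

  m <- matrix(c(10, 0, 0, 10), 2)
  o <- oracle_chisq(m)
  expect_equal(o$statistic, 20)
  set.seed(30)
  for (i in 1:20) {
    m <- matrix(sample(1:30, 6, replace = TRUE), 3)
    got <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(unname(got$statistic), oracle_chisq(m)$statistic,
                 tolerance = 1e-12)
  }
  # end-to-end on simulated tables
  t1 <- simulate_lineages(simulation_config(seed = 4,
                                            lineage = list(n_lineages = 30)))
  t2 <- simulate_lineages(simulation_config(seed = 44,
                                            lineage = list(n_lineages = 30)))
  res <- chi_square_phenotypes(t1, t2)
  expect_equal(res$statistic, oracle_chisq(res$table)$statistic,
               tolerance = 1e-10)
})

test_that("profile matrix codes states per frame and conserves cells", {
  root <- lineage_table(rec("L1.1"))
  pm <- profile_matrix(root)
  expect_equal(ncol(pm), 432L)
  expect_true(all(pm == "INTER"))

  dead <- lineage_table(rec("L1.1", end = 1000, fate = "DEATH_INTERPHASE"))
  pm2 <- profile_matrix(dead)
  expect_true(all(pm2[1, 1:100] == "INTER"))
  expect_true(all(pm2[1, 101:432] == "DEAD"))

  sim <- simulate_lineages(simulation_config(seed = 6,
                                             lineage = list(n_lineages = 12)))
  expect_equal(nrow(profile_matrix(sim)), nrow(sim))
})
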