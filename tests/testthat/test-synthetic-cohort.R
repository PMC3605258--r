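test_that("expression simulation is reproducible and respects gene specs", {
  specs <- list(gene_spec("BAALC"),
                gene_spec("EVI1", "spike-mixture", spike_fraction = 12 / 215))
  m1 <- simulate_expression(215, specs, seed = 4)
  m2 <- simulate_expression(215, specs, seed = 4)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(2L, 215L))
  expect_false(identical(m1, simulate_expression(215, specs, seed = 5)))

  # law-of-large-numbers check on the standard-normal family
  big <- simulate_expression(10000, list(gene_spec("G")), seed = 1)
  expect_lt(abs(mean(big)), 0.05)
  expect_lt(abs(sd(big) - 1), 0.05)

  # degenerate mixture: zero spike weight draws everything from baseline
  base_only <- simulate_expression(
    5000, list(gene_spec("EVI1", "spike-mixture", spike_fraction = 0,
                         baseline_location = -0.2, baseline_scale = 0.35)),
    seed = 2)
  expect_lt(max(base_only), 2)   # no spike component near +3

  expect_error(simulate_expression(1, specs, 1), "at least 2")
  expect_error(gene_spec("EVI1", "spike-mixture", spike_fraction = 0.6),
               "spike_fraction")
  expect_error(gene_spec("EVI1", "spike-mixture", spike_location = -1,
                         baseline_location = 0), "spike_location")
})

test_that("spike count matches its binomial expectation (12 of 215)", {
  specs <- list(gene_spec("EVI1", "spike-mixture", spike_fraction = 12 / 215))
  counts <- vapply(1:200, function(s) {
    sum(simulate_expression(215, specs, seed = 300 + s)["EVI1", ] > 1.5)
  }, numeric(1))
  # mean spike count ~ Binomial(215, 12/215): expectation 12, se of the
  # mean over 200 cohorts ~ 0.24
  expect_lt(abs(mean(counts) - 12), 1)
})

test_that("planted survival effect has the closed-form exponential structure", {
  # hazard_ratio 4, no censoring: stratum median-survival ratio ~ 4
  expr <- simulate_expression(2000, list(gene_spec("G")), seed = 8)
  truth <- survival_truth("G", percentile = 50, hazard_ratio = 4,
                          direction = "high", censor_rate = 0,
                          max_followup = 1e6)
  s <- simulate_survival(expr, truth, seed = 8)
  med <- tapply(s$time, s$stratum, median)
  expect_equal(unname(med[["low"]] / med[["high"]]), 4, tolerance = 0.25)
  expect_true(all(s$event == 1))
  expect_true(all(s$time > 0))

  # null effect: logrank type-I close to alpha over repetitions
  rej <- 0
  for (r in 1:100) {
    e2 <- simulate_expression(100, list(gene_spec("G")), seed = 900 + r)
    s2 <- simulate_survival(e2, survival_truth("G", 50, hazard_ratio = 1),
                            seed = 900 + r)
    p <- logrank_test(s2$time, s2$event, s2$stratum)$p_two_sided
    if (p < 0.05) rej <- rej + 1
  }
  expect_lt(rej / 100, 0.12)

  expect_error(simulate_survival(expr, survival_truth("NOPE"), 1), "missing")
})

test_that("univariate Cox on true strata recovers the planted hazard ratio", {
  hits <- 0
  for (r in 1:100) {
    expr <- simulate_expression(300, list(gene_spec("G")), seed = 5000 + r)
    truth <- survival_truth("G", percentile = 50, hazard_ratio = 2,
                            direction = "high", baseline_hazard = 0.02)
    s <- simulate_survival(expr, truth, seed = 5000 + r)
    fit <- univariate_hr(s$time, s$event, s$stratum)
    if (fit$ci_lower <= 2 && 2 <= fit$ci_upper) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.90)
})

test_that("mutation frequencies follow their stratum rates", {
  strata <- rep(c("low", "high"), c(81, 134))
  specs <- list(mutation_spec("npm1", c(low = 49 / 81, high = 36 / 134)),
                mutation_spec("zero", c(low = 0, high = 0.2)))
  counts_l <- counts_h <- 0
  for (r in 1:100) {
    mut <- simulate_mutations(strata, specs, seed = r)
    counts_l <- counts_l + sum(mut$npm1[strata == "low"])
    counts_h <- counts_h + sum(mut$npm1[strata == "high"])
    expect_equal(sum(mut$zero[strata == "low"]), 0)
  }
  expect_lt(abs(counts_l / 100 - 49), 2)  # expected count 49 per cohort
  expect_lt(abs(counts_h / 100 - 36), 2)  # expected count 36 per cohort

  big <- simulate_mutations(rep(c("low", "high"), each = 5000),
                            list(mutation_spec("m", c(low = 0.3, high = 0.3))),
                            seed = 9)
  expect_lt(abs(mean(big$m) - 0.3), 0.02)

  expect_error(simulate_mutations(c("low", "odd"), specs, 1), "odd")
})

test_that("cohorts are deterministic, aligned, and preset dimensions match", {
  c1 <- simulate_cohort("validation-like", seed = 77)
  c2 <- simulate_cohort("validation-like", seed = 77)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$clinical, c2$clinical)

  expect_equal(ncol(c1$expression), 215L)
  expect_equal(nrow(c1$expression), 4L)
  expect_setequal(rownames(c1$expression), c("BAALC", "ERG", "MN1", "EVI1"))
  expect_true(all(c("npm1", "cebpa_dm", "flt3_itd") %in% names(c1$clinical)))
  expect_equal(c1$clinical$sample_id, colnames(c1$expression))
  expect_true(all(c1$clinical$os_months > 0))
  expect_true(all(c1$clinical$efs_months > 0))
  expect_true(all(c1$clinical$os_event %in% 0:1))
  # EFS adds an earlier event process: never later than OS
  expect_true(all(c1$clinical$efs_months <= c1$clinical$os_months))
  expect_true(all(c1$clinical$efs_event >= c1$clinical$os_event))
})

test_that("event fraction is monotone in baseline hazard", {
  frac <- vapply(c(0.01, 0.03, 0.09), function(h) {
    cfg <- cohort_config(400, list(gene_spec("G")),
                         survival_truth("G", 50, 2, "high", baseline_hazard = h))
    mean(simulate_cohort(cfg, seed = 12)$clinical$os_event)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("confounding knob induces bias that adjustment removes", {
  # age is both stratum-linked and prognostic; the adjusted marker HR
  # should land nearer the planted value than the unadjusted one
  closer <- 0; reps <- 50
  for (r in seq_len(reps)) {
    truth <- survival_truth("G", 50, hazard_ratio = 2, direction = "high",
                            covariate_log_hr = 0.04)
    cfg <- cohort_config(300, list(gene_spec("G")), truth, confounding = 1.2)
    co <- simulate_cohort(cfg, seed = 7000 + r)
    g <- as.integer(co$stratum == "high")
    unadj <- cox_ph(data.frame(g = g), co$clinical$os_months, co$clinical$os_event)
    adj <- cox_ph(data.frame(g = g, age = co$clinical$age),
                  co$clinical$os_months, co$clinical$os_event)
    if (abs(adj$coef[1] - log(2)) < abs(unadj$coef[1] - log(2))) closer <- closer + 1
  }
  expect_gte(closer / reps, 0.8)
})

test_that("cohorts round-trip through the on-disk dialect", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_preset("validation-like", n = 40), seed = 3)
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  expr <- read_gene_table(paths["expression"])
  clin <- read_clinical(paths["clinical"])
  expect_equal(expr, co$expression, tolerance = 1e-12)
  expect_equal(clin$os_months, co$clinical$os_months, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, 3)
  expect_equal(truth$config$truth[[1]]$gene, "BAALC")
})
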