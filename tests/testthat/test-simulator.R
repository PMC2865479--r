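batch <- sexconstraint:::simulate_tips_batch
tip_cor <- sexconstraint:::tip_correlations

test_that("the per-branch steps evaluate the model formulas exactly", {
  expect_equal(brownian_step(c(1, 1), increments = c(0.5, -0.2)), c(1.5, 0.8))

  # block of reversed dimorphism, per model
  expect_equal(block_reversal("constraint_on_females", c(1, 2)), c(1, 1))
  expect_equal(block_reversal("constraint_on_males", c(1, 2)), c(2, 2))
  expect_equal(block_reversal("mutual_constraint", c(1, 2)), c(1.5, 1.5))
  for (m in c("constraint_on_females", "constraint_on_males", "mutual_constraint")) {
    expect_equal(block_reversal(m, c(2, 1)), c(2, 1))
  }

  # pull towards the other sex
  expect_equal(constraint_pull("constraint_on_females", c(2, 0), 0.5), c(2, 1))
  expect_equal(constraint_pull("constraint_on_males", c(2, 0), 0.5), c(1, 0))
  expect_equal(constraint_pull("mutual_constraint", c(2, 0), 0.25), c(1.5, 0.5))
  expect_equal(constraint_pull("mutual_constraint", c(2, 0), 0.5), c(1, 1))
  for (m in c("constraint_on_females", "constraint_on_males", "mutual_constraint")) {
    expect_equal(constraint_pull(m, c(1.3, -0.4), 0), c(1.3, -0.4))
  }
  expect_error(constraint_pull("constraint_on_females", c(1, 0), 1.2), "pull constant")
  expect_error(constraint_pull("mutual_constraint", c(1, 0), 0.7), "pull constant")
})

test_that("a one-tip branch reproduces the three-step hand trace", {
  tr <- read_newick("(A);")
  inc <- list(male = matrix(1.0), female = matrix(0.2))
  # brownian: (1.0, 0.2); block: no-op; pull F by 0.3 * 0.8
  out <- batch(tr, "constraint_on_females", 0.3, 1, increments = inc)
  expect_equal(c(out$male, out$female), c(1.0, 0.44))

  inc2 <- list(male = matrix(0.2), female = matrix(1.0))
  # brownian: (0.2, 1.0); block resets F to 0.2; pull is then a no-op
  out2 <- batch(tr, "constraint_on_females", 0.3, 1, increments = inc2)
  expect_equal(c(out2$male, out2$female), c(0.2, 0.2))
  # under male constraint the male is raised instead, then pulled (no-op at F==M)
  out3 <- batch(tr, "constraint_on_males", 0.3, 1, increments = inc2)
  expect_equal(c(out3$male, out3$female), c(1.0, 1.0))
  # mutual: both to the mean 0.6
  out4 <- batch(tr, "mutual_constraint", 0.2, 1, increments = inc2)
  expect_equal(c(out4$male, out4$female), c(0.6, 0.6))
})

test_that("no simulated tip ever shows reversed dimorphism", {
  tr <- study_tree()
  for (model in c("constraint_on_females", "constraint_on_males", "mutual_constraint")) {
    for (C in c(0, 0.2, pull_max(model))) {
      sim <- batch(tr, model, C, 200, seed = 17)
      expect_true(all(sim$female <= sim$male),
                  label = paste("female <= male under", model, "C =", C))
    }
  }
})

test_that("a full pull forces identical sexes and perfect correlation", {
  tr <- study_tree()
  for (model in c("constraint_on_females", "constraint_on_males", "mutual_constraint")) {
    sim <- batch(tr, model, pull_max(model), 50, seed = 4)
    expect_equal(sim$female, sim$male)
    expect_true(all(abs(tip_cor(sim) - 1) < 1e-12))
  }
})

test_that("mutual constraint conserves the sex mean along every branch", {
  tr <- study_tree()
  n_edges <- nrow(tr$edge)
  set.seed(8)
  inc <- list(male = matrix(rnorm(n_edges * 100), n_edges),
              female = matrix(rnorm(n_edges * 100), n_edges))
  mut <- batch(tr, "mutual_constraint", 0.3, 100, increments = inc)
  pure <- batch(tr, "mutual_constraint", 0.3, 100, increments = inc,
                pure_brownian = TRUE)
  # steps 2-3 never move (M + F)/2, so the tip means match pure Brownian
  expect_equal((mut$male + mut$female) / 2, (pure$male + pure$female) / 2)
})

test_that("the one-sided models are exact mirrors of each other", {
  tr <- study_tree()
  n_edges <- nrow(tr$edge)
  set.seed(21)
  A <- matrix(rnorm(n_edges * 200), n_edges)
  B <- matrix(rnorm(n_edges * 200), n_edges)
  fem <- batch(tr, "constraint_on_females", 0.35, 200,
               increments = list(male = A, female = B))
  mal <- batch(tr, "constraint_on_males", 0.35, 200,
               increments = list(male = -B, female = -A))
  expect_equal(mal$male, -fem$female)
  expect_equal(mal$female, -fem$male)
  # hence |DSD| and |DRS| are distributed identically across the two models
  sf <- sexconstraint:::batch_statistics(fem)
  sm <- sexconstraint:::batch_statistics(mal)
  expect_equal(abs(sm$DSD), abs(sf$DSD))
  expect_equal(abs(sm$DRS), abs(sf$DRS))
})

test_that("pure Brownian motion leaves the sexes uncorrelated", {
  tr <- study_tree()
  sim <- batch(tr, "constraint_on_females", 0, 2000, seed = 33,
               pure_brownian = TRUE)
  r <- tip_cor(sim)
  expect_lt(abs(mean(r)), 3 / sqrt(2000) * sd(r) + 0.02)
})

test_that("simulation is deterministic given the seed and rejects bad trees", {
  tr <- study_tree()
  expect_identical(simulate_tips(tr, "mutual_constraint", 0.2, seed = 5),
                   simulate_tips(tr, "mutual_constraint", 0.2, seed = 5))
  raw <- read_newick("((A:0.2,B:3):1,C:0.7);")
  expect_error(simulate_tips(raw, "constraint_on_females", 0.3, seed = 1),
               "speciational")
})

test_that("calibration hits forced, baseline and ordered targets", {
  tr <- study_tree()
  for (model in c("constraint_on_females", "mutual_constraint")) {
    expect_equal(calibrate_pull_constant(tr, model, 1, seed = 2), pull_max(model))
  }
  # measure the C = 0 baseline with the calibration's own seed stream, then
  # ask for exactly that: the answer must be (near) zero
  set.seed(3)
  n_edges <- nrow(tr$edge)
  inc <- list(male = matrix(rnorm(n_edges * 500), n_edges),
              female = matrix(rnorm(n_edges * 500), n_edges))
  baseline <- mean(tip_cor(batch(tr, "constraint_on_females", 0, 500,
                                 increments = inc)))
  expect_equal(calibrate_pull_constant(tr, "constraint_on_females", baseline,
                                       seed = 3), 0)
  expect_error(calibrate_pull_constant(tr, "constraint_on_females",
                                       baseline / 4, seed = 3),
               "unachievable")
  expect_error(calibrate_pull_constant(tr, "constraint_on_females", 1.2), "target_r")

  c_low <- calibrate_pull_constant(tr, "constraint_on_females", 0.6, seed = 3)
  c_high <- calibrate_pull_constant(tr, "constraint_on_females", 0.9, seed = 3)
  expect_gt(c_high, c_low)
})

test_that("mean tip correlation is nondecreasing in C under common random numbers", {
  tr <- study_tree()
  n_edges <- nrow(tr$edge)
  set.seed(12)
  inc <- list(male = matrix(rnorm(n_edges * 400), n_edges),
              female = matrix(rnorm(n_edges * 400), n_edges))
  for (model in c("constraint_on_females", "constraint_on_males", "mutual_constraint")) {
    grid <- seq(0, pull_max(model), length.out = 9)
    curve <- vapply(grid, function(C) {
      mean(tip_cor(batch(tr, model, C, 400, increments = inc)))
    }, numeric(1))
    expect_true(all(diff(curve) >= -1e-10), label = paste("monotone under", model))
  }
})
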