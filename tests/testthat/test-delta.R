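test_that("delta keeps the overestimation sign convention", {
  expect_equal(compute_delta(c(50, 60), c(50, 55)), c(0, 5))
  set.seed(1)
  p <- rnorm(20, 50, 10)
  a <- rnorm(20, 50, 10)
  loop <- numeric(20)
  for (i in 1:20) loop[i] <- p[i] - a[i]
  expect_equal(compute_delta(p, a), loop)
  expect_error(compute_delta(1:3, 1:2), "misaligned")
})

test_that("residualization removes exactly the cubic age trend", {
  set.seed(2)
  age <- runif(500, 18, 88)
  # exact cubic: nothing left
  score <- 3 + 0.5 * age - 0.01 * age^2 + 1e-4 * age^3
  expect_lt(sqrt(sum(residualize_score(score, age)^2)), 1e-8)

  # age-independent score: residual ~ the centered score
  s2 <- rnorm(2000)
  age2 <- runif(2000, 18, 88)
  r2 <- residualize_score(s2, age2)
  expect_gt(cor(r2, s2), 0.999)

  # orthogonality to the polynomial basis
  s3 <- rnorm(500) + 0.05 * age
  r3 <- residualize_score(s3, age)
  for (k in 1:3) expect_lt(abs(sum(r3 * scale(age)^k)), 1e-8)
})

test_that("two-step beta equals the residual-delta correlation", {
  set.seed(3)
  age <- runif(400, 18, 88)
  delta <- rnorm(400, sd = 5)
  score <- 0.2 * scale(age) + rnorm(400)
  row <- delta_association(score, delta, age, spec = "two_step")
  resid <- residualize_score(score, age)
  expect_equal(row$beta, cor(scale(resid)[, 1], scale(delta)[, 1]),
               tolerance = 1e-10)
})

test_that("joint model beta ignores added linear-in-age components", {
  set.seed(4)
  age <- runif(600, 18, 88)
  delta <- rnorm(600, sd = 4)
  score <- 0.3 * scale(delta)[, 1] + rnorm(600, sd = 0.5)
  b0 <- delta_association(score, delta, age, spec = "joint")$beta
  # adding any linear function of age changes nothing once age terms are in
  shifted <- score + 0.04 * (age - 50)
  # standardization rescales the score; compare after the same scaling
  b1 <- delta_association(shifted, delta, age, spec = "joint")$beta
  expect_equal(b1 * sd(shifted), b0 * sd(score), tolerance = 1e-6)
})

test_that("planted delta-score associations are recovered", {
  # null: no association, coefficients near zero and p roughly uniform
  set.seed(5)
  betas <- replicate(20, {
    age <- runif(2000, 18, 88)
    delta <- rnorm(2000, sd = 5)
    score <- rnorm(2000)
    delta_association(score, delta, age, spec = "two_step")$beta
  })
  expect_lt(max(abs(betas)), 0.05)

  # planted: score and delta share the latent health factor
  est <- sapply(1:20, function(seed) {
    set.seed(seed)
    n <- 2000
    age <- runif(n, 18, 88)
    health <- rnorm(n)
    delta <- 2 * health + rnorm(n, sd = 2)       # brain age reads health
    score <- 0.3 * health + rnorm(n, sd = 1)
    delta_association(score, delta, age, spec = "two_step")$beta
  })
  # induced correlation: 0.3*2 / (sd(score) * sd(delta))
  truth <- 0.6 / (sqrt(0.09 + 1) * sqrt(4 + 4))
  expect_lt(abs(mean(est) - truth), 0.05)

  # two-step and joint agree when the delta is age-independent
  set.seed(6)
  age <- runif(2000, 18, 88)
  delta <- rnorm(2000, sd = 5)
  score <- 0.2 * scale(delta)[, 1] + rnorm(2000)
  b_two <- delta_association(score, delta, age, spec = "two_step")$beta
  b_joint <- delta_association(score, delta, age, spec = "joint")$beta
  expect_lt(abs(b_two - b_joint), 0.02)
})

test_that("extended specification demands and uses confounds", {
  set.seed(7)
  n <- 300
  age <- runif(n, 18, 88)
  delta <- rnorm(n, sd = 5)
  score <- rnorm(n)
  conf <- tibble::tibble(gender = rbinom(n, 1, 0.5),
                         handedness = rbinom(n, 1, 0.9),
                         motion_log = log(rexp(n) + 0.1))
  row <- delta_association(score, delta, age, conf, spec = "extended")
  expect_equal(row$spec, "extended")
  expect_true(row$p_value > 0 && row$p_value <= 1)
  expect_error(delta_association(score, delta, age, spec = "extended"),
               "confounds")
  # collinearity is reported with column names
  conf2 <- conf
  conf2$motion_log <- conf2$gender
  expect_error(
    delta_association(score, delta, age, conf2, spec = "extended"),
    "collinear")
})

test_that("the score catalog enumerates and aggregates correctly", {
  cat38 <- default_score_catalog()
  expect_s3_class(cat38, "score_catalog")
  expect_equal(attr(cat38, "total_variables"), 38L)
  expect_equal(nrow(cat38), 23L)

  # a catalog of two totals counts two variables
  small <- build_score_catalog(tibble::tibble(
    name = c("a", "b"), type = "questionnaire",
    aggregation = "total", n_variables = c(1L, 1L)))
  expect_equal(attr(small, "total_variables"), 2L)
  expect_error(build_score_catalog(tibble::tibble(
    name = "x", type = "questionnaire", aggregation = "median",
    n_variables = 1L)), "unknown aggregation")

  # PC1 of two perfectly correlated standardized sub-scores explains all
  set.seed(8)
  a <- rnorm(100)
  pc <- aggregate_score(cbind(a, 2 * a + 3), "PC1")
  expect_equal(attr(pc, "explained_variance"), 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive => PC1 tracks a
  expect_gt(cor(pc, a), 0.999)

  expect_equal(aggregate_score(cbind(1:3, 4:6), "ratio"), (1:3) / (4:6))
  expect_equal(aggregate_score(cbind(4:6, 1:3), "difference"), rep(3, 3))
  expect_equal(aggregate_score(cbind(1:3, 4:6), "total"), c(5, 7, 9))
})
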