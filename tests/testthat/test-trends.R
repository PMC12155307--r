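test_that("a perfect linear response is fit exactly", {
  x <- 1:10
  fit <- fit_trend(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p, 1e-12)
  expect_false(fit$degenerate)
})

test_that("fit_trend matches the closed-form least-squares solution", {
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    fit <- fit_trend(x, y)
    slope_cf <- cov(x, y) / var(x)
    intercept_cf <- mean(y) - slope_cf * mean(x)
    expect_equal(fit$slope, slope_cf, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept_cf, tolerance = 1e-10)
    # and the t-test against the closed form
    res <- y - intercept_cf - slope_cf * x
    se_cf <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
    expect_equal(fit$se, se_cf, tolerance = 1e-10)
    expect_equal(fit$p, 2 * pt(abs(slope_cf / se_cf), n - 2,
                               lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("degenerate inputs are handled as documented", {
  expect_error(fit_trend(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(fit_trend(1:2, 1:2), "at least 3")
  flat <- fit_trend(1:8, rep(0.25, 8))
  expect_true(flat$degenerate)
  expect_identical(flat$slope, 0)
  expect_identical(flat$r_squared, 0)
  expect_identical(flat$p, 1)
  expect_message(fit_trend(c(1:5, NA), c(2:6, 3)), "dropping 1")
})

test_that("null slope test keeps its nominal type-I error rate", {
  set.seed(16)
  reps <- 400
  p <- replicate(reps, {
    fit_trend(rnorm(30), rnorm(30))$p
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / reps) + 1e-9)
})

test_that("bridge-based yield adjustment follows the worked arithmetic", {
  # equal ratios: both candidates give 49.5
  bridges <- data.frame(yield_b = c(50, 40), yield_a = c(55, 44))
  expect_equal(adjust_yield(45, bridges), 49.5)
  # single bridge: proportional scaling
  expect_equal(adjust_yield(25, data.frame(yield_b = 50, yield_a = 55)), 27.5)
  # target equal to the bridge recovers the bridge's source-A yield
  expect_equal(adjust_yield(50, data.frame(yield_b = 50, yield_a = 55)), 55)
  # both aggregation rules agree when ratios are equal
  expect_equal(adjust_yield(45, bridges, method = "ratio_of_means"),
               adjust_yield(45, bridges))
})

test_that("yield adjustment is scale-equivariant in the source-B scale", {
  set.seed(17)
  bridges <- data.frame(yield_b = runif(3, 30, 80), yield_a = runif(3, 30, 80))
  target <- 52
  a1 <- adjust_yield(target, bridges)
  k <- 3.7
  bridges2 <- transform(bridges, yield_b = yield_b * k)
  expect_equal(adjust_yield(target * k, bridges2), a1, tolerance = 1e-12)
})

test_that("yield adjustment rejects bad bridges", {
  expect_error(adjust_yield(45, data.frame()), "empty bridge set")
  expect_error(adjust_yield(45, data.frame(yield_b = 0, yield_a = 5)),
               "positive")
  expect_error(adjust_yield(-1, data.frame(yield_b = 5, yield_a = 5)),
               "positive")
})

test_that("bushel conversions use the crop's standard weight", {
  expect_equal(convert_yield_unit(3200, "oat", "lb/ac"), 100)
  expect_equal(convert_yield_unit(6000, "wheat", "lb/ac"), 100)
  expect_equal(convert_yield_unit(100, "oat", "bu/ac"), 3200)
})

test_that("trend_suite runs the six burden regressions", {
  b <- simulate_cohort(simulation_config(
    n_samples = 80L, n_chromosomes = 3L, sites_per_chromosome = 300L,
    deleterious_fraction = 0.05, seed = 19L
  ))
  catg <- identify_dsnps(b$cohort, b$annotations, b$track, filter_config())
  bu <- estimate_burdens(b$cohort, catg, b$metadata)
  ts <- trend_suite(bu, b$metadata)
  expect_identical(nrow(ts), 6L)
  expect_setequal(unique(ts$predictor), c("year", "yield"))
  expect_setequal(unique(ts$response),
                  c("total_burden", "het_burden", "hom_burden"))
  # planted positive slope and year-coupled yield: both positive
  expect_gt(ts$slope[ts$response == "total_burden" & ts$predictor == "year"], 0)
  expect_gt(ts$slope[ts$response == "total_burden" & ts$predictor == "yield"], 0)
})

test_that("null planted slope is rarely declared significant", {
  hits <- vapply(1:20, function(seed) {
    b <- simulate_cohort(simulation_config(
      n_samples = 60L, n_chromosomes = 2L, sites_per_chromosome = 150L,
      deleterious_fraction = 0.1, burden_slope_per_year = 0, seed = seed
    ))
    catg <- identify_dsnps(b$cohort, b$annotations, b$track, filter_config())
    bu <- estimate_burdens(b$cohort, catg, b$metadata)
    fit <- fit_trend(bu$registration_year, bu$total_burden)
    fit$p < 0.05
  }, logical(1))
  expect_lte(sum(hits), 4)  # ~5% nominal; allow wide Monte-Carlo slack
})

test_that("expression trend averages TPM per sample and regresses on year", {
  b <- small_bundle()
  md <- b$metadata
  genes <- paste0("g", 1:5)
  # constant matrix: flat, degenerate fit
  tpm <- matrix(3, 5, nrow(md), dimnames = list(genes, md$cultivar))
  flat <- expression_trend(tpm, md)
  expect_true(flat$degenerate)
  expect_identical(flat$slope, 0)
  # one-gene matrix equals that gene's row
  one <- tpm[1, , drop = FALSE]
  one[1, ] <- rnorm(ncol(one), 5)
  fit1 <- expression_trend(one, md)
  fit2 <- fit_trend(md$registration_year, as.numeric(one[1, ]))
  expect_equal(fit1$slope, fit2$slope, tolerance = 1e-12)
  # planted increase with year is detected
  set.seed(20)
  base <- matrix(rnorm(5 * nrow(md), 5, 0.2), 5, nrow(md),
                 dimnames = list(genes, md$cultivar))
  trendy <- sweep(base, 2, 0.02 * (md$registration_year - 1900), "+")
  fit3 <- expression_trend(trendy, md)
  expect_gt(fit3$slope, 0)
  expect_lt(fit3$p, 0.01)
  expect_error(expression_trend(tpm[0, ], md), "empty gene set")
})
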