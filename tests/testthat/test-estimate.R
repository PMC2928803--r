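# small birth-death dataset used across the pipeline tests
make_bd_dataset <- function(m, seed, times = c(2, 10)) {
  net <- builtin_model("birth_death_test")
  ens <- simulate_ensemble(net, net$true_params, 0, times, m, seed = seed)
  cme_dataset(ens$states[, , 1], times, species = "X",
              provenance = list(model = "birth_death_test",
                                true_params = net$true_params, sigma2 = 0,
                                x0 = list(X = 0), t0 = 0))
}

test_that("histogram criteria refuse sparse datasets", {
  net <- builtin_model("birth_death_test")
  ds <- make_bd_dataset(10, seed = 1)
  spec <- objective_spec("dfd_pdf", n_ssa = 200)
  expect_error(objective_function(ds, net, spec, seed = 1),
               "at least 1000 replicates")
  # the override flag and the sparse CDF mode both work
  spec2 <- objective_spec("dfd_pdf", n_ssa = 200, allow_sparse_pdf = TRUE)
  expect_silent(obj <- objective_function(ds, net, spec2, seed = 1))
  spec3 <- objective_spec("dfd_cdf", n_ssa = 200)
  obj3 <- objective_function(ds, net, spec3, seed = 1)
  expect_true(is.finite(obj3(net$true_params)))
})

test_that("objective closures honour common random numbers", {
  net <- builtin_model("birth_death_test")
  ds <- make_bd_dataset(2000, seed = 2)
  spec <- objective_spec("dfd_cdf", n_ssa = 300)
  obj <- objective_function(ds, net, spec, seed = 5)
  p <- net$true_params
  expect_identical(obj(p), obj(p))
  obj_fresh <- objective_function(ds, net, spec, seed = 5, crn = FALSE)
  expect_false(identical(obj_fresh(p), obj_fresh(p)))
})

test_that("objective evaluation does not disturb the caller's RNG stream", {
  net <- builtin_model("birth_death_test")
  ds <- make_bd_dataset(1200, seed = 3)
  spec <- objective_spec("ml", n_ssa = 200)
  obj <- objective_function(ds, net, spec, seed = 7)
  set.seed(42)
  a <- stats::runif(3)
  set.seed(42)
  invisible(obj(net$true_params))
  b <- stats::runif(3)
  expect_identical(a, b)
})

test_that("estimation runs are replayable bit-for-bit", {
  net <- builtin_model("birth_death_test")
  ds <- make_bd_dataset(300, seed = 4)  # sparse -> CDF order-statistic mode
  spec <- objective_spec("dfd_cdf", n_ssa = 200)
  de <- de_config(net$bounds, generations = 8, np = 8, seed = 11)
  r1 <- estimate(ds, net, spec, de)
  r2 <- estimate(ds, net, spec, de)
  expect_identical(r1$result$best_params, r2$result$best_params)
  expect_identical(r1$result$history, r2$result$history)
  expect_s3_class(tidy(r1), "tbl_df")
  expect_true(all(c("method", "best_value", "median_error") %in%
                  names(glance(r1))))
})

test_that("a short end-to-end run recovers birth-death rates roughly", {
  net <- builtin_model("birth_death_test")
  ds <- make_bd_dataset(3000, seed = 6, times = c(1, 3, 10))
  spec <- objective_spec("dfd_cdf", n_ssa = 500)
  de <- de_config(net$bounds, generations = 40, np = 20, seed = 12)
  run <- estimate(ds, net, spec, de)
  expect_true(all(run$recovery$error < 0.35))
  expect_true(all(run$result$best_params >= net$bounds$lower &
                  run$result$best_params <= net$bounds$upper))
})

test_that("objective landscapes normalise to a unit minimum", {
  net <- builtin_model("birth_death_test")
  ds <- make_bd_dataset(1500, seed = 8)
  spec <- objective_spec("dfd_cdf", n_ssa = 300)
  scan <- scan_objective(net, ds, spec,
                         grid = list(k = seq(3, 7, by = 1)),
                         fixed = c(gamma = 1), seed = 9)
  expect_equal(min(scan$normalized), 1)
  expect_true(all(scan$normalized >= 1))
  expect_equal(nrow(scan), 5)

  single <- scan_objective(net, ds, spec, grid = list(k = 5),
                           fixed = c(gamma = 1), seed = 9)
  expect_equal(single$normalized, 1)

  expect_error(
    scan_objective(net, ds, spec, grid = list(k = numeric(0)),
                   fixed = c(gamma = 1), seed = 9),
    "empty grid"
  )

  two_d <- scan_objective(net, ds, spec,
                          grid = list(k = c(4, 5, 6), gamma = c(0.5, 1, 2)),
                          seed = 9)
  expect_equal(nrow(two_d), 9)
  expect_s3_class(autoplot(two_d), "ggplot")
})

test_that("multi-species datasets sum objectives across species", {
  net <- builtin_model("yegfp_reduced")
  ds <- generate_case_study("yegfp_reduced", m = 1200, seed = 10)
  spec <- objective_spec("dfd_cdf", n_ssa = 200)
  obj_both <- objective_function(ds, net, spec, seed = 13)
  v_both <- obj_both(net$true_params)
  ds1 <- generate_case_study("yegfp_reduced", m = 1200, seed = 10,
                             observe_tetr = FALSE)
  obj_one <- objective_function(ds1, net, spec, seed = 13)
  v_one <- obj_one(net$true_params)
  expect_true(is.finite(v_both) && is.finite(v_one))
  expect_gt(v_both, v_one)  # extra observed species adds its terms
})

test_that("autoplot methods return ggplot objects", {
  withr::local_seed(30)
  x <- stats::rpois(300, 5)
  pdf <- pdf_from_samples(x, build_bins(x))
  expect_s3_class(autoplot(pdf), "ggplot")
  cfg <- de_config(list(a = c(-1, 1)), generations = 10, np = 8, seed = 1)
  r <- de_minimize(function(x) sum(x^2), cfg)
  expect_s3_class(autoplot(r), "ggplot")
})
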