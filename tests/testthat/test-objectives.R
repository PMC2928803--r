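# fabricate a binned density without going through samples (probabilities
# need not normalise, which lets us isolate single-bin discrepancies)
make_density <- function(probs, n, kind = "pdf", edges = NULL) {
  if (is.null(edges)) edges <- as.numeric(seq_len(length(probs) + 1L) - 1L)
  scheme <- structure(
    list(edges = edges,
         centers = (edges[-length(edges)] + edges[-1L]) / 2,
         min_count = 10L, reference = "experimental"),
    class = "binning_scheme"
  )
  structure(
    list(kind = kind, prob = probs, var = probs * (1 - probs) / n, n = n,
         scheme = scheme),
    class = "binned_density"
  )
}

test_that("two-bin hand computations match the weighted distances", {
  data_pdf <- make_density(c(0.6, 0.4), n = 100)
  model_pdf <- make_density(c(0.5, 0.5), n = 1000)
  # only bin 1 counts: (0.1)^2 / (0.6 * 0.4 / 100) = 25/6
  expect_equal(dfd_pdf(data_pdf, model_pdf), 25 / 6, tolerance = 1e-9)
  expect_equal(dfd_max(data_pdf, model_pdf, "pdf"), 0.1 / sqrt(0.0024),
               tolerance = 1e-9)

  data_cdf <- make_density(c(0.6, 1), n = 100, kind = "cdf")
  model_cdf <- make_density(c(0.5, 1), n = 1000, kind = "cdf")
  expect_equal(dfd_cdf(data_cdf, model_cdf), 25 / 6, tolerance = 1e-9)
  expect_equal(dfd_max(data_cdf, model_cdf, "cdf"), 0.1 / sqrt(0.0024),
               tolerance = 1e-9)
})

test_that("identical densities give exactly zero for every criterion", {
  withr::local_seed(21)
  x <- stats::rpois(400, 7)
  pdf <- pdf_from_samples(x, build_bins(x))
  cdf <- cdf_from_pdf(pdf)
  expect_identical(dfd_pdf(pdf, pdf), 0)
  expect_identical(dfd_cdf(cdf, cdf), 0)
  expect_identical(dfd_max(pdf, pdf, "pdf"), 0)
  expect_identical(dfd_max(cdf, cdf, "cdf"), 0)
})

test_that("the last bin is excluded from the distance sums", {
  d <- make_density(c(0.3, 0.3, 0.4), n = 100)
  m <- make_density(c(0.3, 0.3, 0.2), n = 100)  # differs only in bin 3
  expect_equal(dfd_pdf(d, m), 0)
  expect_equal(dfd_max(d, m, "pdf"), 0)
  # multiple timepoints: per-timepoint maxima are summed
  d2 <- make_density(c(0.6, 0.4), n = 100)
  m2 <- make_density(c(0.5, 0.5), n = 100)
  expect_equal(dfd_max(list(d2, d2), list(m2, m2), "pdf"),
               2 * 0.1 / sqrt(0.0024))
  expect_error(dfd_pdf(d, m2), "same binning")
})

test_that("negative log-likelihood sums -log P over all observations", {
  # observation in a probability-1 bin contributes 0
  s <- rep(5L, 100)
  pdf1 <- pdf_from_samples(s, build_bins(s))
  ds <- cme_dataset(matrix(rep(5L, 4), ncol = 1), sample_times = 1)
  expect_equal(neg_log_likelihood(ds, pdf1), 0)

  # single observation in a bin with P = 0.1
  s2 <- c(rep(0L, 900), rep(1L, 100))
  pdf2 <- pdf_from_samples(s2, build_bins(s2))
  ds2 <- cme_dataset(matrix(1L, 1, 1), sample_times = 1)
  expect_equal(neg_log_likelihood(ds2, pdf2), -log(0.1), tolerance = 1e-9)

  # m = 2, n = 1 with P-values 0.5 and 0.25
  s3 <- c(rep(0L, 500), rep(1L, 250), rep(2L, 250))
  pdf3 <- pdf_from_samples(s3, build_bins(s3))
  ds3 <- cme_dataset(matrix(c(0L, 1L), 2, 1), sample_times = 1)
  expect_equal(neg_log_likelihood(ds3, pdf3), log(2) + log(4),
               tolerance = 1e-9)
})

test_that("sparse CDF distance matches direct evaluation of the formula", {
  # all model mass below the smallest datum: model CDF = 1 at every datum
  model_samples <- rep(10:11, each = 50)
  model_cdf <- cdf_from_pdf(
    pdf_from_samples(model_samples,
                     build_bins(model_samples, reference = "simulation"))
  )
  se <- sparse_ecdf(100:109)
  m <- 10
  fe <- (1:9 - 0.5) / m
  expected <- sum((fe - 1)^2 / (fe * (1 - fe) / m))
  expect_equal(dfd_cdf(se, model_cdf), expected, tolerance = 1e-9)
  expect_true(is.finite(expected) && expected > 0)
})

test_that("all criteria are non-negative and vanish only near coincidence", {
  withr::local_seed(22)
  for (i in 1:5) {
    x <- stats::rpois(1000, 6)
    y <- stats::rpois(1000, 6 + i)
    scheme <- build_bins(x)
    dp <- pdf_from_samples(x, scheme)
    mp <- pdf_from_samples(y, scheme)
    expect_gte(dfd_pdf(dp, mp), 0)
    expect_gte(dfd_cdf(cdf_from_pdf(dp), cdf_from_pdf(mp)), 0)
    expect_gte(dfd_max(dp, mp, "pdf"), 0)
    expect_gt(dfd_pdf(dp, mp), dfd_pdf(dp, dp))
  }
})

test_that("objective evaluations append to a JSON-lines log", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  log_objective_eval(path, "dfd_cdf", c(k = 5, gamma = 1), 12.5,
                     seed = 3, n_ssa = 100)
  log_objective_eval(path, "ml", c(k = 4, gamma = 2), 99, seed = 4,
                     n_ssa = 200)
  lines <- readLines(path)
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$method, "dfd_cdf")
  expect_equal(rec$params$k, 5)
  expect_equal(rec$value, 12.5)
})

test_that("every criterion prefers the true parameters on average", {
  net <- builtin_model("birth_death_test")
  truth <- net$true_params
  methods <- c("ml", "dfd_pdf", "dfd_cdf", "dfd_pdf_max", "dfd_cdf_max")
  vals <- array(0, dim = c(20, 3, length(methods)),
                dimnames = list(NULL, c("truth", "double", "half"), methods))
  for (s in 1:20) {
    ds <- local({
      ens <- simulate_ensemble(net, truth, 0, c(2, 10), 2000, seed = 1000 + s)
      cme_dataset(ens$states[, , 1], c(2, 10), species = "X",
                  provenance = list(model = "birth_death_test",
                                    true_params = truth, sigma2 = 0,
                                    x0 = list(X = 0), t0 = 0))
    })
    for (mi in seq_along(methods)) {
      spec <- objective_spec(methods[mi], n_ssa = 500)
      obj <- objective_function(ds, net, spec, seed = 2000 + s)
      vals[s, , mi] <- c(obj(truth), obj(truth * 2), obj(truth * 0.5))
    }
  }
  for (mi in seq_along(methods)) {
    expect_lt(mean(vals[, "truth", mi]), mean(vals[, "double", mi]),
              label = methods[mi])
    expect_lt(mean(vals[, "truth", mi]), mean(vals[, "half", mi]),
              label = methods[mi])
  }
})
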