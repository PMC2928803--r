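bd_net <- builtin_model("birth_death_test")

test_that("a system with zero total propensity stays frozen", {
  ens <- simulate_ensemble(bd_net, c(k = 0, gamma = 1), x0 = 0,
                           sample_times = c(0, 1, 5, 50),
                           n_realizations = 20, seed = 1)
  expect_true(all(ens$states == 0))
})

test_that("pure birth process matches Poisson(k t) moments", {
  birth <- reaction_network(
    species = "X",
    reactions = list(reaction("birth", c(X = 1L), prop_mass_action("k"))),
    parameters = list(k = c(0, 10))
  )
  n <- 1e4
  ens <- simulate_ensemble(birth, c(k = 1), x0 = 0, sample_times = 10,
                           n_realizations = n, seed = 2)
  x <- ens$states[, 1, 1]
  se_mean <- sqrt(10 / n)
  expect_lt(abs(mean(x) - 10), 3 * se_mean)
  # Poisson: Var[s^2] ~ (mu4 - sigma^4)/n with mu4 = 3 lambda^2 + lambda
  se_var <- sqrt((3 * 100 + 10 - 100) / n)
  expect_lt(abs(stats::var(x) - 10), 3 * se_var)
})

test_that("immigration-death equilibrates to the Poisson(k/gamma) law", {
  n <- 1e4
  ens <- simulate_ensemble(bd_net, c(k = 5, gamma = 1), x0 = 0,
                           sample_times = 20, n_realizations = n, seed = 3)
  x <- ens$states[, 1, 1]
  counts <- tabulate(x + 1L, nbins = max(x) + 1L)
  expected <- stats::dpois(0:max(x), 5) * n
  # pool the right tail so every expected count is >= 5
  cut <- max(which(expected >= 5))
  obs <- c(counts[1:cut], sum(counts[-(1:cut)]))
  exp_p <- c(expected[1:cut], n - sum(expected[1:cut])) / n
  gof <- stats::chisq.test(obs, p = exp_p)
  expect_gt(gof$p.value, 0.01)
})

test_that("ensembles are reproducible and realizations are sub-streams", {
  p <- c(k = 5, gamma = 1)
  e1 <- simulate_ensemble(bd_net, p, 0, c(1, 5), 50, seed = 7)
  e2 <- simulate_ensemble(bd_net, p, 0, c(1, 5), 50, seed = 7)
  expect_identical(e1$states, e2$states)

  single <- ssa_simulate(bd_net, p, 0, c(1, 5), seed = 7)
  expect_identical(single[, "X"], e1$states[1, , 1])

  # disjoint seeds: different draws, same law (z-test on the mean at t = 5)
  e3 <- simulate_ensemble(bd_net, p, 0, c(1, 5), 2000, seed = 8)
  e4 <- simulate_ensemble(bd_net, p, 0, c(1, 5), 2000, seed = 9)
  expect_false(identical(e3$states, e4$states))
  z <- (mean(e3$states[, 2, 1]) - mean(e4$states[, 2, 1])) /
    sqrt(5 / 2000 + 5 / 2000)
  expect_lt(abs(z), 4)
})

test_that("ensemble mean follows the birth-death ODE mean within MC error", {
  k <- 4; g <- 0.5
  times <- c(0.5, 1, 2, 4, 8)
  n <- 4000
  ens <- simulate_ensemble(bd_net, c(k = k, gamma = g), 0, times, n,
                           seed = 10)
  mu <- k / g * (1 - exp(-g * times))  # transient Poisson mean
  for (i in seq_along(times)) {
    se <- sqrt(mu[i] / n)
    expect_lt(abs(mean(ens$states[, i, 1]) - mu[i]), 3 * se)
  }
})

test_that("firing counts reconcile with the final state (R engine)", {
  net <- builtin_model("ecoli_rna")
  x0 <- c(DNA_S = 1, DNA_A = 0, RNA = 0)
  states <- cmefit:::ssa_ensemble_r(
    net, net$true_params, x0, t0 = 0, sample_times = 75,
    n_realizations = 5, seed = 21, record_firings = TRUE
  )
  firings <- attr(states, "firings")
  for (r in 1:5) {
    reconstructed <- x0 + as.vector(t(net$stoichiometry) %*% firings[r, ])
    expect_equal(unname(states[r, 1, ]), unname(reconstructed))
  }
})

test_that("compiled and pure-R engines sample the same distribution", {
  p <- c(k = 5, gamma = 1)
  n <- 1500
  ec <- simulate_ensemble(bd_net, p, 0, 10, n, seed = 31, engine = "cpp")
  er <- simulate_ensemble(bd_net, p, 0, 10, n, seed = 31, engine = "r")
  # same stationary law, independent RNGs: two-sample chi-square
  xc <- ec$states[, 1, 1]; xr <- er$states[, 1, 1]
  hi <- max(xc, xr)
  tab <- rbind(tabulate(pmin(xc, 12) + 1L, 13), tabulate(pmin(xr, 12) + 1L, 13))
  keep <- colSums(tab) > 0
  expect_gt(stats::chisq.test(tab[, keep])$p.value, 0.01)
})

test_that("expression-propensity networks run through the R engine", {
  net <- reaction_network(
    species = "X",
    reactions = list(
      reaction("birth", c(X = 1L), prop_expression("k / (1 + X)")),
      reaction("death", c(X = -1L), prop_mass_action("gamma", "X"))
    ),
    parameters = list(k = c(0, 20), gamma = c(0, 5))
  )
  ens <- simulate_ensemble(net, c(k = 10, gamma = 1), 0, c(2, 5), 50,
                           seed = 41)
  expect_identical(ens$seed_info$engine, "r")
  expect_true(all(ens$states >= 0))
  expect_error(
    simulate_ensemble(net, c(k = 10, gamma = 1), 0, 1, 2, seed = 1,
                      engine = "cpp"),
    "expression"
  )
})

test_that("measurement noise rounds, preserves the mean, keeps negatives", {
  frozen <- reaction_network(
    species = "X",
    reactions = list(reaction("none", c(X = 1L), prop_mass_action(0))),
    parameters = list(unused = c(0, 1))
  )
  ens10 <- simulate_ensemble(frozen, c(unused = 0), 10, 1, 1e4, seed = 51)

  expect_identical(add_measurement_noise(ens10, 0)$states, ens10$states)

  noisy <- add_measurement_noise(ens10, 0.25, seed = 52)
  x <- noisy$states[, 1, 1]
  expect_true(all(x == round(x)))
  expect_lt(abs(mean(x) - 10), 3 * 0.5 / sqrt(1e4))

  ens0 <- simulate_ensemble(frozen, c(unused = 0), 0, 1, 1e4, seed = 53)
  noisy0 <- add_measurement_noise(ens0, 0.25, seed = 54)
  expect_true(any(noisy0$states < 0))  # negatives retained, not clipped

  expect_error(add_measurement_noise(ens0, -1, seed = 1), ">= 0")
  expect_error(add_measurement_noise(noisy0, 0.25, seed = 1), "already")
})

test_that("ensembles round-trip through long-format CSV", {
  ens <- simulate_ensemble(bd_net, c(k = 5, gamma = 1), 0, c(1, 5), 30,
                           seed = 61)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(ens, path)
  back <- read_ensemble_csv(path)
  expect_equal(back$sample_times, ens$sample_times)
  expect_equal(unname(back$states[, , 1]), unname(ens$states[, , 1]))
})
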