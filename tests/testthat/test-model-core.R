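test_that("mass-action propensities follow the combinatorial rate law", {
  net <- builtin_model("birth_death_test")
  expect_equal(evaluate_propensities(net, state = 10,
                                     params = c(k = 2, gamma = 0.5)),
               c(2, 5))
  # dimerisation: a = k * x (x - 1) / 2
  dimer <- reaction_network(
    species = "A",
    reactions = list(reaction("dim", c(A = -2L),
                              prop_mass_action("k", c("A", "A")))),
    parameters = list(k = c(0, 1))
  )
  expect_equal(evaluate_propensities(dimer, 5, c(k = 0.1)), 0.1 * 5 * 4 / 2)
})

test_that("toggle-switch Hill propensity reduces to alpha1 at zero repressor", {
  net <- builtin_model("toggle_switch")
  a <- evaluate_propensities(net, c(LacI = 0, GFP = 0), net$true_params)
  expect_equal(a[[1]], 156.25)  # denominator 1 + 0^beta = 1
  expect_equal(a[[2]], 0)
  expect_equal(a[[3]], 15.6)
})

test_that("propensity evaluation validates dimensions and expressions", {
  net <- builtin_model("birth_death_test")
  expect_error(evaluate_propensities(net, c(1, 2), c(k = 1, gamma = 1)),
               "length")
  expect_error(evaluate_propensities(net, 1, c(k = 1)), "length")
  # division by zero in an expression names the reaction
  bad <- reaction_network(
    species = "A",
    reactions = list(reaction("blowup", c(A = 1L),
                              prop_expression("k / (A - A)"))),
    parameters = list(k = c(0, 1))
  )
  expect_error(evaluate_propensities(bad, 3, c(k = 1)), "blowup")
})

test_that("expression propensities are parsed through a whitelist", {
  expect_s3_class(prop_expression("k1 * A / (1 + B)"), "propensity_spec")
  expect_error(prop_expression("system('ls')"), "not allowed")
  expect_error(prop_expression("eval(parse(text = 'x'))"), "not allowed")
})

test_that("built-in models have the documented dimensions", {
  red <- builtin_model("yegfp_reduced")
  expect_equal(nrow(red$stoichiometry), 8)
  expect_length(red$species, 4)
  expect_length(red$parameter_names, 8)

  full <- builtin_model("yegfp_full")
  expect_equal(nrow(full$stoichiometry), 18)
  expect_length(full$species, 9)
  expect_length(full$parameter_names, 15)

  tg <- builtin_model("toggle_switch")
  expect_equal(nrow(tg$stoichiometry), 4)
  expect_setequal(tg$parameter_names,
                  c("alpha1", "alpha2", "beta", "gamma", "eta", "K"))

  eco <- builtin_model("ecoli_rna")
  expect_equal(nrow(eco$stoichiometry), 3)
  expect_true(all(eco$bounds$lower == 0) && all(eco$bounds$upper == 5))

  expect_error(builtin_model("schlogl"), "available models")
})

test_that("built-in propensities are finite and non-negative on a state grid", {
  withr::local_seed(11)
  for (nm in c("ecoli_rna", "yegfp_reduced", "yegfp_full", "toggle_switch",
               "birth_death_test")) {
    net <- builtin_model(nm)
    N <- length(net$species)
    for (i in 1:40) {
      state <- sample(0:50, N, replace = TRUE)
      a <- evaluate_propensities(net, state, net$true_params)
      expect_true(all(is.finite(a)) && all(a >= 0))
    }
  }
})

test_that("positive-propensity reactions never drive a species negative", {
  withr::local_seed(12)
  for (nm in c("ecoli_rna", "yegfp_reduced", "yegfp_full", "toggle_switch",
               "birth_death_test")) {
    net <- builtin_model(nm)
    N <- length(net$species)
    for (i in 1:40) {
      state <- sample(0:3, N, replace = TRUE)  # small counts stress clamping
      a <- evaluate_propensities(net, state, net$true_params)
      for (j in which(a > 0)) {
        expect_true(all(state + net$stoichiometry[j, ] >= 0),
                    label = paste(nm, "reaction", j, "state",
                                  paste(state, collapse = ",")))
      }
    }
  }
})

test_that("networks round-trip losslessly through YAML", {
  withr::local_seed(13)
  for (nm in c("ecoli_rna", "toggle_switch", "yegfp_full")) {
    net <- builtin_model(nm)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_network_yaml(net, path)
    back <- read_network_yaml(path)
    expect_equal(back$species, net$species)
    expect_equal(back$stoichiometry, net$stoichiometry)
    expect_equal(back$bounds, net$bounds)
    expect_equal(back$true_params, net$true_params)
    expect_equal(back$observables, net$observables)
    for (i in 1:10) {
      state <- sample(0:20, length(net$species), replace = TRUE)
      expect_equal(evaluate_propensities(back, state, net$true_params),
                   evaluate_propensities(net, state, net$true_params))
    }
  }
  # expression propensities survive the round trip too
  ex <- reaction_network(
    species = c("A", "B"),
    reactions = list(reaction("r1", c(A = 1L),
                              prop_expression("k1 * B / (1 + B)"))),
    parameters = list(k1 = c(0, 2))
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_yaml(ex, path)
  expect_equal(evaluate_propensities(read_network_yaml(path), c(0, 4),
                                     c(k1 = 1)),
               0.8)
})
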