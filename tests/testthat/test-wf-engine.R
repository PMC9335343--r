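make_state <- function(p) {
  structure(list(p = p, generation = 0L), class = "population_state")
}

test_that("selection vanishes at the symmetric fixed point and has the right signs", {
  arch <- sample_architecture(20, seed = 1)
  st <- initial_state(arch, sim_params(), mode = "half")
  for (m in c("gaussian", "first_order")) {
    # mean at optimum (centered => 0) and p = 1/2: both terms vanish
    expect_equal(selection_delta(st, arch, zopt = 0, Vs = 20, method = m),
                 rep(0, 20))
    # mean below optimum: '+' alleles pushed up at every locus
    expect_true(all(selection_delta(st, arch, zopt = 5, Vs = 20, method = m) > 0))
  }
  # mean at optimum, p away from 1/2: selection against heterozygosity
  p <- c(0.9, 0.1)
  arch2 <- genetic_architecture(c(0.3, 0.3))
  # zopt chosen equal to the realized mean so only the p-dependent term acts
  zbar <- sum(arch2$gamma * (p - 0.5))
  d <- selection_delta(make_state(p), arch2, zopt = zbar, Vs = 20)
  expect_gt(d[1], 0)
  expect_lt(d[2], 0)
  expect_error(selection_delta(st, arch, zopt = 0, Vs = -1),
               class = "polyadapt_invalid_parameter")
})

test_that("single-locus selection matches the exact two-genotype expectation", {
  gamma <- 0.5; p <- 0.3; Vs <- 20
  arch <- genetic_architecture(gamma)
  st <- make_state(p)
  for (zopt in c(-1, 0, 0.7, 3)) {
    exact <- single_locus_expected_change(p, gamma, zopt, Vs)
    # with no background variance the Gaussian closure is the exact map
    expect_equal(selection_delta(st, arch, zopt, Vs, method = "gaussian"),
                 exact, tolerance = 1e-12)
    # first-order form agrees to leading order in 1/Vs
    fo <- selection_delta(st, arch, zopt, Vs, method = "first_order")
    expect_equal(fo, exact, tolerance = 0.05)
  }
})

test_that("mutation has the advertised fixed point and boundary behavior", {
  expect_equal(mutation_delta(0.5, 0.1), 0.5)
  expect_equal(mutation_delta(0, 2.5e-5), 2.5e-5)
  expect_equal(mutation_delta(1, 2.5e-5), 1 - 2.5e-5)
  expect_error(mutation_delta(0.5, 0.6), class = "polyadapt_invalid_parameter")
})

test_that("drift is unbiased binomial resampling with absorbing boundaries", {
  expect_equal(drift_sample(c(0, 1), 100), c(0, 1))
  expect_error(drift_sample(0.5, 0), class = "polyadapt_invalid_parameter")
  set.seed(31)
  n <- 100; p <- 0.3
  draws <- replicate(4000, drift_sample(p, n))
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / n / 4000))
  expect_lt(abs(var(draws) - p * (1 - p) / n), 0.1 * p * (1 - p) / n)
})

test_that("a step with no forces leaves the state unchanged; steps are reproducible", {
  arch <- sample_architecture(50, seed = 2)
  par <- sim_params(n = 1000, mu = 0, Vs = 1e12, generations = 1,
                    selection = "directional", beta = 0)
  st <- initial_state(arch, par, mode = "near_fixed_random", seed = 4)
  st2 <- wf_step(st, arch, par)
  expect_equal(st2$p, st$p)  # p in {0,1}, no mutation, s = 0
  expect_equal(st2$generation, 1L)

  par2 <- sim_params(n = 500, mu = 1e-3, Vs = 5, generations = 50, seed = 77)
  t1 <- wf_run(initial_state(arch, par2, seed = 9), arch, par2)
  t2 <- wf_run(initial_state(arch, par2, seed = 9), arch, par2)
  expect_identical(t1$summary, t2$summary)
  expect_identical(t1$final_state$p, t2$final_state$p)
})

test_that("frequencies stay in [0,1] through a full run at study scale", {
  arch <- sample_architecture(1000, seed = 5)
  par <- sim_params(generations = 3, seed = 6)
  st <- initial_state(arch, par, mode = "near_fixed_random", seed = 6)
  traj <- wf_run(st, arch, par, checkpoints = 0:3)
  expect_true(all(traj$checkpoints$freq >= 0 & traj$checkpoints$freq <= 1))
})

test_that("a zero-generation run returns only the initial record", {
  arch <- sample_architecture(10, seed = 1)
  par <- sim_params(n = 100, generations = 0)
  traj <- wf_run(initial_state(arch, par, mode = "half"), arch, par)
  expect_equal(nrow(traj$summary), 1L)
  expect_equal(traj$summary$trait_mean, 0)
})

test_that("neutral equilibrium variance matches the Beta(theta,theta) closed form", {
  # theta = 2 n mu = 0.5: stationary E[pq] = theta/(2(2 theta + 1)) = 1/8
  n <- 100; mu <- 2.5e-3; L <- 100
  arch <- sample_architecture(L, mean_effect = 0.12, seed = 21)
  target <- sum(arch$gamma^2) / 8
  vals <- vapply(1:8, function(r) {
    par <- sim_params(n = n, mu = mu, Vs = 1, generations = 1500,
                      selection = "directional", beta = 0, seed = 1000 + r)
    st <- initial_state(arch, par, mode = "near_fixed_random", seed = 1000 + r)
    traj <- wf_run(st, arch, par)
    mean(traj$summary$var_genetic[750:1501])
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - target), 3 * se)
})

test_that("individual engine drifts at rate pq/n when neutral", {
  arch <- sample_architecture(20, mean_effect = 0.12, seed = 22)
  par <- sim_params(n = 200, mu = 0, Vs = 1, generations = 1,
                    engine = "individual", selection = "directional", beta = 0)
  set.seed(61)
  st <- initial_state(arch, par, mode = "half")
  # one neutral generation from p = 1/2 across replicates
  freqs <- replicate(300, {
    traj <- wf_run_individual(st, arch, par)
    state_freq <- traj$checkpoints$freq[traj$checkpoints$generation == 1]
  })
  v <- apply(freqs, 1, var)
  expected <- 0.5 * 0.5 / 200
  expect_lt(abs(mean(v) - expected), 3 * sd(v) / sqrt(length(v)))
})

test_that("individual-engine offspring mean equals the selection-weighted parental mean", {
  arch <- sample_architecture(20, mean_effect = 0.2, seed = 23)
  par <- sim_params(n = 400, mu = 0, Vs = 2, generations = 1,
                    engine = "individual", optimum = 1)
  set.seed(62)
  st0 <- initial_state(arch, par, mode = "half")
  gamma <- arch$gamma
  z <- as.vector(st0$genotypes %*% gamma) - sum(gamma) / 2
  w <- exp(-(z - 1)^2 / (2 * 2))
  parental_weighted_mean <- sum(w * z) / sum(w)
  offspring_means <- replicate(300, {
    traj <- wf_run_individual(st0, arch, par)
    tail(traj$summary$trait_mean, 1)
  })
  se <- sd(offspring_means) / sqrt(length(offspring_means))
  expect_lt(abs(mean(offspring_means) - parental_weighted_mean), 3 * se)
})
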