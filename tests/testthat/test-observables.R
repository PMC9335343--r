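test_that("trait moments follow the closed forms at degenerate states", {
  arch <- sample_architecture(10, seed = 1)
  par <- sim_params(n = 100)
  fixed <- initial_state(arch, par, mode = "near_fixed_random", seed = 2)
  expect_equal(trait_moments(fixed, arch)$var_genetic, 0)
  half <- initial_state(arch, par, mode = "half")
  m <- trait_moments(half, arch)
  expect_equal(m$trait_mean, 0)
  expect_equal(m$var_genetic, sum(arch$gamma^2) / 4)
})

test_that("the contribution decomposition conserves the change in mean exactly", {
  arch <- sample_architecture(200, seed = 3)
  par <- sim_params(n = 500, mu = 1e-3, Vs = 2, generations = 300,
                    optimum = 2, seed = 13)
  st <- initial_state(arch, par, mode = "near_fixed_random", seed = 13)
  traj <- wf_run(st, arch, par, checkpoints = c(0, 100, 300))

  d <- contribution_decomposition(traj, arch, 0, 300)
  dz <- with(traj$summary, trait_mean[generation == 300] - trait_mean[generation == 0])
  expect_equal(sum(d$contribution), dz, tolerance = 1e-10)

  d2 <- contribution_decomposition(traj, arch, 100, 300)
  dz2 <- with(traj$summary, trait_mean[generation == 300] - trait_mean[generation == 100])
  expect_equal(sum(d2$contribution), dz2, tolerance = 1e-10)

  # degenerate interval: all contributions vanish
  expect_equal(contribution_decomposition(traj, arch, 100, 100)$contribution,
               rep(0, 200))
  expect_error(contribution_decomposition(traj, arch, 0, 57),
               class = "polyadapt_missing_checkpoint")
})

test_that("substituted and returned loci are classified as disjoint sets", {
  arch <- genetic_architecture(c(0.5, 0.4, 0.3, 0.05))
  paths <- tidyr::expand_grid(generation = c(0, 50, 100),
                              locus = 1:4) |>
    dplyr::arrange(locus, generation)
  # locus 1 fixes; locus 2 rises then collapses; locus 3 stays low;
  # locus 4 fixes but is below the effect threshold
  paths$freq <- c(0.1, 0.9, 1.0,
                  0.1, 0.8, 0.01,
                  0.05, 0.2, 0.1,
                  0.2, 0.9, 1.0)
  traj <- fake_trajectory(paths)
  cls <- classify_outcomes(traj, arch, effect_threshold = 0.2)
  expect_equal(cls$substituted, 1L)
  expect_equal(cls$returned, 2L)
  expect_length(intersect(cls$substituted, cls$returned), 0)

  # a path ending at 1 is substituted regardless of thresholds
  cls99 <- classify_outcomes(traj, arch, effect_threshold = 0.2,
                             fix_threshold = 1, return_threshold = 0.5)
  expect_true(1L %in% cls99$substituted)
  expect_false(1L %in% cls99$returned)
})

test_that("time to optimum handles degenerate tolerances and unreached optima", {
  summary <- tibble::tibble(generation = 0:100,
                            trait_mean = seq(0, 5, length.out = 101),
                            var_genetic = 1)
  traj <- fake_trajectory(tibble::tibble(), summary = summary)
  # shift of size zero: already at the optimum
  expect_equal(time_to_optimum(traj, 0, tol = 1), 0L)
  expect_equal(time_to_optimum(traj, 100, tol = Inf), 0L)
  expect_true(is.na(time_to_optimum(traj, 100, tol = 1)))
  # default tolerance is one genetic SD at the shift generation
  expect_equal(time_to_optimum(traj, 5), which(abs(summary$trait_mean - 5) <= 1)[1] - 1L)
})

test_that("logit paths are clamped, finite, and monotone", {
  paths <- tibble::tibble(generation = 0L, locus = 1:5,
                          freq = c(0, 0.25, 0.5, 0.75, 1))
  traj <- fake_trajectory(paths, n = 100)
  lp <- logit_paths(traj)
  expect_true(all(is.finite(lp$logit)))
  expect_equal(lp$logit[3], 0)
  expect_equal(lp$logit[1], log((1 / 200) / (1 - 1 / 200)))
  expect_true(all(diff(lp$logit) > 0))  # strictly increasing in p
})

test_that("the mutational-variance diagnostic matches its closed forms", {
  arch <- sample_architecture(50, seed = 9)
  par <- sim_params(n = 100, mu = 1e-3)
  st <- initial_state(arch, par, mode = "near_fixed_random", seed = 9)

  after0 <- st; after0$p <- mutation_delta(st$p, 0)
  expect_equal(mutational_variance(st, after0, arch), 0)

  mu <- 1e-3
  after <- st; after$p <- mutation_delta(st$p, mu)
  vm <- mutational_variance(st, after, arch)
  # from fixation, one mutation round gives Vg = sum gamma^2 mu(1-mu)
  expect_equal(vm, sum(arch$gamma^2) * mu * (1 - mu), tolerance = 1e-12)
  expect_gt(vm, 0)
})

test_that("wf_run records the per-generation mutational variance on request", {
  arch <- sample_architecture(30, seed = 10)
  par <- sim_params(n = 200, mu = 2e-3, Vs = 5, generations = 50, seed = 10)
  st <- initial_state(arch, par, mode = "near_fixed_random", seed = 10)
  traj <- wf_run(st, arch, par, record_vm = TRUE)
  expect_equal(nrow(traj$vm), 50)
  # from a near-fixed start every mutation round adds variance
  expect_gt(traj$vm$vm[1], 0)
})
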