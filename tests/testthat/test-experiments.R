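# a scaled-down system with the same scaled mutation (theta = 0.5) and
# selection (n gamma^2 / Vs) as the study conditions; cheap enough for unit tests
small_config <- function(...) {
  shift_config(L = 100, mean_effect = 0.12, n = 1000, mu = 2.5e-4, Vs = 2,
               burn_in_generations = 600, post_shift_generations = 600,
               shift_to = 3, replicates = 2, record_every = 5, ...)
}

test_that("the shift experiment produces a complete, deterministic result", {
  res <- run_shift_experiment(small_config(), seed = 5)
  expect_s3_class(res, "shift_experiment")
  reps <- res$replicates
  expect_equal(nrow(reps), 2)
  expect_true(all(c("vg_eq", "time_to_optimum", "dz_ultimate",
                    "n_substituted", "contrib_substituted",
                    "contrib_large_100", "total_100") %in% names(reps)))
  expect_true(all(reps$vg_eq > 0))
  expect_true(all(!is.na(reps$time_to_optimum)))
  # the response moved the mean toward the new optimum
  expect_true(all(reps$dz_ultimate > 1))
  # stored trajectory covers the post-shift phase with locus paths
  expect_gt(nrow(res$trajectory$locus_paths), 0)

  res2 <- run_shift_experiment(small_config(), seed = 5, keep_trajectory = FALSE,
                               diffusion = FALSE)
  expect_identical(reps, res2$replicates)
})

test_that("a run manifest reproduces the identical experiment", {
  res <- run_shift_experiment(small_config(), seed = 11,
                              keep_trajectory = FALSE, diffusion = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(res, path)
  m <- read_run_manifest(path)
  expect_s3_class(m$config, "shift_config")
  res2 <- run_shift_experiment(m$config, seed = m$seed,
                               keep_trajectory = FALSE, diffusion = FALSE)
  expect_identical(res$replicates, res2$replicates)
})

test_that("fixed-architecture mode shares one effect draw across replicates", {
  cfg <- small_config(fresh_effects_per_replicate = FALSE)
  res <- run_shift_experiment(cfg, seed = 3, keep_trajectory = FALSE,
                              diffusion = FALSE)
  # same architecture => identical large-effect locus count in every replicate
  expect_equal(length(unique(res$replicates$n_large)), 1L)
  # but independent dynamics
  expect_gt(length(unique(res$replicates$vg_eq)), 1L)
})

test_that("tidiers and plots expose the result surfaces", {
  res <- run_shift_experiment(small_config(), seed = 7)
  expect_identical(tidy(res), res$replicates)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$vg_pred))

  traj <- res$trajectory
  expect_identical(tidy(traj), traj$summary)
  expect_equal(glance(traj)$n_loci, 100)

  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_locus_paths(traj), "ggplot")
  d <- contribution_decomposition(traj, res$arch,
                                  min(traj$checkpoints$generation),
                                  max(traj$checkpoints$generation))
  expect_s3_class(plot_contributions(d), "ggplot")
  scan <- efficiency_scan(c(10, 100), fitness_variance = 0.01, n = 100)
  expect_s3_class(autoplot(scan), "ggplot")

  pred <- predict_equilibrium_vg(res$arch, sim_params(n = 1000, mu = 2.5e-4,
                                                      Vs = 2))
  expect_equal(glance(pred)$vg_pred, pred$vg_pred)
  expect_equal(nrow(tidy(pred)), nrow(res$arch))
})

test_that("trajectory tables round-trip through TSV", {
  res <- run_shift_experiment(small_config(), seed = 13)
  dir <- withr::local_tempdir()
  write_trajectory(res$trajectory, dir)
  back <- read_trajectory_tables(dir)
  expect_equal(back$summary$var_genetic, res$trajectory$summary$var_genetic)
  expect_equal(nrow(back$locus_paths), nrow(res$trajectory$locus_paths))
  expect_equal(back$manifest$n, 1000)
})
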