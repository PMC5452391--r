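test_that("simulators are deterministic given config and seed", {
  for (s in c("cpf", "territorial", "nomad", "migrant")) {
    cfg <- syndrome_config(s, n_steps = if (s == "migrant") 1200 else 600)
    fn <- switch(s, cpf = simulate_cpf, territorial = simulate_territorial,
                 nomad = simulate_nomad, migrant = simulate_migrant)
    a <- fn(cfg, seed = 123); b <- fn(cfg, seed = 123); c <- fn(cfg, seed = 124)
    expect_identical(a$trajectory$x, b$trajectory$x)
    expect_identical(a$state_sequence, b$state_sequence)
    expect_false(identical(a$trajectory$x, c$trajectory$x))
    expect_equal(nrow(a$trajectory), cfg$n_steps)
  }
})

test_that("range-resident paths are bounded, unbounded movers are not", {
  for (s in c("cpf", "territorial")) {
    cfg <- syndrome_config(s, n_steps = 2000)
    fn <- if (s == "cpf") simulate_cpf else simulate_territorial
    for (seed in 1:3) {
      res <- fn(cfg, seed = seed)
      d <- sqrt(res$trajectory$x^2 + res$trajectory$y^2)
      max_step <- 2 * cfg$base_step * max(cfg$step_scalars[c("range", "attend")])
      expect_lte(max(d), cfg$home_range_radius + 3 * max_step)
      expect_lte(mnsd(res$trajectory),
                 (2 * cfg$home_range_radius + 2 * max_step)^2)
    }
  }
  # migrant reaches far beyond any home-range scale and comes back
  mig <- simulate_migrant(seed = 2)
  d <- sqrt(mig$trajectory$x^2 + mig$trajectory$y^2)
  expect_gt(sqrt(mnsd(mig$trajectory)), 50 * 5000)
  expect_lt(d[length(d)], 0.1 * max(d))  # return migration ends near origin
  # farthest point sits in the second sedentary phase, not at the end
  expect_equal(unname(mig$state_sequence[which.max(d)]), "sedentary")
})

test_that("nomad switching is symmetric with the configured rate", {
  cfg <- syndrome_config("nomad")
  res <- simulate_nomad(cfg, seed = 31)
  st <- res$state_sequence
  switches <- sum(st[-1] != st[-length(st)])
  n <- length(st) - 1
  # observed switch frequency within 4 binomial SDs of 0.05
  expect_lt(abs(switches / n - cfg$switch_prob),
            4 * sqrt(0.05 * 0.95 / n))
  # long-run occupancy near 1/2 under symmetric switching (across seeds)
  occ <- mean(sapply(1:6, function(sd)
    mean(simulate_nomad(cfg, seed = sd)$state_sequence == "foraging")))
  expect_lt(abs(occ - 0.5), 0.1)
})

test_that("a no-switch nomad started foraging is a diffusive random walk", {
  cfg <- syndrome_config("nomad", switch_prob = 1e-12, n_steps = 2000)
  set.seed(77)
  seeds <- sample(1e6, 12)
  # ensemble MSD at a ladder of lags; log-log slope ~ 1 for diffusion
  lags <- c(8, 16, 32, 64, 128, 256)
  msd <- matrix(0, length(seeds), length(lags))
  for (i in seq_along(seeds)) {
    r <- simulate_nomad(cfg, seed = seeds[i])
    if (r$state_sequence[1] != "foraging") next
    x <- r$trajectory$x; y <- r$trajectory$y
    msd[i, ] <- sapply(lags, function(L)
      mean((x[-(1:L)] - head(x, -L))^2 + (y[-(1:L)] - head(y, -L))^2))
  }
  keep <- rowSums(msd) > 0
  slope <- coef(lm(log(colMeans(msd[keep, ])) ~ log(lags)))[2]
  expect_gt(slope, 0.85); expect_lt(slope, 1.15)
})

test_that("migration schedule is honoured exactly", {
  cfg <- syndrome_config("migrant")
  expect_equal(sum(cfg$migration_schedule), 7200)
  expect_equal(unname(cfg$migration_schedule),
               c(2400, 1200, 2400, 1200))
  res <- simulate_migrant(cfg, seed = 5)
  r <- rle(res$state_sequence)
  expect_equal(r$values, c("sedentary", "migratory", "sedentary", "migratory"))
  expect_equal(r$lengths, unname(cfg$migration_schedule))
  expect_error(syndrome_config("migrant",
                               migration_schedule = c(a = 100, b = 100)),
               "sum to n_steps")
})

test_that("cohorts are labelled, distinct, and reproducible", {
  cfg <- syndrome_config("nomad", n_steps = 300)
  coh <- simulate_cohort("nomad", 3, seeds = c(5, 6, 7), cfg = cfg)
  expect_equal(length(coh), 3L)
  expect_equal(vapply(coh, function(s) attr(s$trajectory, "species"), ""),
               rep("nomad", 3))
  expect_false(identical(coh[[1]]$trajectory$x, coh[[2]]$trajectory$x))
  expect_warning(simulate_cohort("nomad", 2, seeds = c(5, 5), cfg = cfg),
                 "duplicate")
  again <- simulate_cohort("nomad", 3, seeds = c(5, 6, 7), cfg = cfg)
  expect_identical(coh[[2]]$trajectory$y, again[[2]]$trajectory$y)
})
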