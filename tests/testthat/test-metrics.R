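test_that("turn angle correlation matches its closed forms and a direct oracle", {
  # straight path: all turns 0 -> S_A = 0
  expect_equal(tac(rep(0, 25)), 0)
  # alternating 0, pi: every chord distance is 2 -> S_A = 4(N-1)/N
  for (N in c(2, 7, 50)) {
    rho <- rep(c(0, pi), length.out = N)
    expect_equal(tac(rho), 4 * (N - 1) / N)
  }
  expect_error(tac(0.3), "at least 2")
  # random angles against independent term-by-term summation
  set.seed(42)
  for (i in 1:10) {
    rho <- runif(50, -pi, pi)
    expect_equal(tac(rho), tac_oracle(rho), tolerance = 1e-12)
  }
  # rotation of the frame leaves S_A unchanged
  set.seed(1)
  x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
  th <- 1.1
  a <- tac(steps_and_turns(make_traj(x, y)))
  b <- tac(steps_and_turns(make_traj(x * cos(th) - y * sin(th),
                                     x * sin(th) + y * cos(th))))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("residence time and time-to-return have their analytic values", {
  # stationary for 48 h: never leaves any circle -> RT = full duration
  stat <- make_traj(rep(0, 48), rep(0, 48))
  p <- timeuse_params(radius = 10, cutoff_h = 12)
  expect_equal(residence_time(stat, p), 48)
  expect_message(t2r <- time_to_return(stat, p), "no absence")
  expect_equal(t2r, 0)
  # straight path with constant step 2R: each circle holds only its centre
  line <- make_traj(seq(0, by = 20, length.out = 30), rep(0, 30))
  expect_equal(residence_time(line, timeuse_params(radius = 10, cutoff_h = 12)), 1)
  # constructed 20-h absence then return, cutoff 12 -> T2R = 20 at the origin
  x <- c(0, rep(100, 20), 0, rep(100, 5))
  tr <- make_traj(x, rep(0, length(x)))
  v <- movesyndromes:::.t2r_core(tr$x, tr$y, 1, 10, 12)
  expect_equal(v[1], 20)
})

test_that("optimized RT/T2R equal the O(n^2) brute-force scan exactly", {
  set.seed(99)
  trajs <- mini_cohort_trajs()
  for (tr in trajs[c(1, 3, 5, 7)]) {
    short <- make_traj(tr$x[1:400], tr$y[1:400])
    sl <- steps_and_turns(short)$mean_SL
    p <- timeuse_params(radius = sl, cutoff_h = 12)
    expect_identical(residence_time(short, p),
                     rt_oracle(short$x, short$y, 1, sl, 12))
    expect_identical(suppressMessages(time_to_return(short, p)),
                     t2r_oracle(short$x, short$y, 1, sl, 12))
  }
  # and on pure-noise walks, including with missing slots
  for (i in 1:6) {
    n <- 300
    x <- cumsum(rnorm(n, sd = 40)); y <- cumsum(rnorm(n, sd = 40))
    x[sample(n, 25)] <- NA
    y[is.na(x)] <- NA
    tr <- make_traj(x, y)
    expect_equal(residence_time(tr, timeuse_params(60, 12)),
                 rt_oracle(x, y, 1, 60, 12))
    expect_equal(suppressMessages(time_to_return(tr, timeuse_params(60, 12))),
                 t2r_oracle(x, y, 1, 60, 12))
  }
})

test_that("MNSD is the farthest-point squared displacement, scaled per group", {
  expect_equal(mnsd(make_traj(rep(0, 5), rep(0, 5))), 0)
  expect_equal(mnsd(make_traj(0:10, rep(0, 11))), 100)
  # out-and-back: the apex counts, not the final displacement
  out_back <- make_traj(c(0:5, 4:0), rep(0, 11))
  expect_equal(mnsd(out_back), 25)
  pr <- data.frame(individual_id = letters[1:4],
                   species = c("s1", "s1", "s1", "s2"),
                   mnsd_raw = c(4, 8, 16, 3))
  sc <- scale_mnsd(pr)
  expect_equal(sc$mnsd_scaled, c(1, 2, 4, 1))
  # unit invariance
  pr2 <- pr; pr2$mnsd_raw <- pr$mnsd_raw * 1e6
  expect_equal(scale_mnsd(pr2)$mnsd_scaled, sc$mnsd_scaled)
  pr$mnsd_raw[1] <- 0
  expect_error(scale_mnsd(pr), "degenerate")
})

test_that("metric_table is complete, order-equivariant and reproducible", {
  trajs <- mini_cohort_trajs()
  mt <- metric_table(trajs, mnsd_group = NULL)
  expect_equal(nrow(mt), length(trajs))
  expect_false(anyNA(mt[, c("tac_sa", "rt_h", "t2r_h", "vi", "mnsd_scaled")]))
  expect_true(all(mt$vi >= 0 & mt$vi <= 1))
  expect_true(all(mt$mnsd_scaled >= 1))
  mt2 <- metric_table(rev(trajs), mnsd_group = NULL)
  expect_equal(mt2[order(mt2$individual_id), -1],
               mt[order(mt$individual_id), -1], tolerance = 1e-12,
               ignore_attr = TRUE)
  mt3 <- metric_table(trajs, mnsd_group = NULL)
  expect_identical(mt, mt3)
})
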