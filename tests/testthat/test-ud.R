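fake_ud <- function(mass, x = seq_len(nrow(mass)), y = seq_len(ncol(mass))) {
  structure(list(x = x, y = y, mass = mass / sum(mass), month = "m", level = 1),
            class = "ud")
}

test_that("volume of intersection has its boundary values and is symmetric", {
  m <- matrix(runif(25), 5)
  u <- fake_ud(m)
  expect_equal(volume_of_intersection(list(u, u)), 1)
  a <- matrix(0, 5, 5); a[1:2, ] <- 1
  b <- matrix(0, 5, 5); b[4:5, ] <- 1
  expect_equal(volume_of_intersection(list(fake_ud(a), fake_ud(b))), 0)
  u1 <- fake_ud(matrix(runif(25), 5)); u2 <- fake_ud(matrix(runif(25), 5))
  expect_equal(volume_of_intersection(list(u1, u2)),
               volume_of_intersection(list(u2, u1)))
  # three months with pairwise overlaps {1, .5, .5} -> mean 2/3
  h <- matrix(0, 4, 1); h[1:2] <- 0.5
  g <- matrix(0, 4, 1); g[c(1, 3)] <- 0.5
  expect_equal(volume_of_intersection(list(fake_ud(h), fake_ud(h), fake_ud(g))),
               2 / 3)
  expect_error(volume_of_intersection(list(u1)), "at least 2")
  u3 <- fake_ud(matrix(runif(16), 4))
  expect_error(volume_of_intersection(list(u1, u3)), "shared grid")
})

test_that("monthly UDs qualify months, share a grid, and normalize", {
  set.seed(3)
  # two months of fixes from the same cloud
  n <- 1400
  tr <- make_traj(rnorm(n, sd = 200), rnorm(n, sd = 200))
  uds <- monthly_uds(tr, min_fixes = 100)
  expect_equal(length(uds), 2L)   # Jan (744) + Feb (656)
  for (u in uds) expect_equal(sum(u$mass), 1)
  expect_identical(uds[[1]]$x, uds[[2]]$x)
  # truncation keeps at least the isopleth mass before renormalizing
  ud95 <- monthly_uds(tr, min_fixes = 100, level = 0.95)
  expect_gte(mean(ud95[[1]]$mass > 0), 0)
  expect_equal(sum(ud95[[1]]$mass), 1)
  expect_lte(sum(ud95[[1]]$mass > 0), sum(uds[[1]]$mass > 0))
  # a single qualifying month is an error naming the individual
  short <- make_traj(rnorm(800), rnorm(800))
  expect_error(monthly_uds(short, min_fixes = 700), "fewer than 2")
})

test_that("VI of two shifted Gaussian months matches the closed form", {
  set.seed(8)
  sigma <- 300; d <- 400
  n1 <- 744; n2 <- 700
  x <- c(rnorm(n1, 0, sigma), rnorm(n2, d, sigma))
  y <- rnorm(n1 + n2, 0, sigma)
  tr <- make_traj(x, y)
  uds <- monthly_uds(tr, min_fixes = 100, level = 1, grid_frac = 1 / 80)
  vi <- volume_of_intersection(uds)
  # overlap of two unit-mass isotropic Gaussians distance d apart is
  # 2*pnorm(-d/(2*sigma_eff)); the kernel convolution widens sigma
  bw <- MASS::bandwidth.nrd(x[1:n1]) / 4
  sigma_eff <- sqrt(sigma^2 + bw^2)
  expect_equal(vi, 2 * pnorm(-d / (2 * sigma_eff)), tolerance = 0.08)
})
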