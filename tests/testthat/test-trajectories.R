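test_that("regularization snaps fixes to the anchored grid and is idempotent", {
  t0 <- as.POSIXct("2001-03-01 00:00:00", tz = "UTC")
  # fixes at 0, 30, 60, 90, 120 min on a 1-h grid -> slots at 0, 60, 120
  raw <- trajectory(t0 + c(0, 30, 60, 90, 120) * 60, 1:5, 5:1, id = "a")
  reg <- regularize(raw, 1)
  expect_equal(nrow(reg), 3L)
  expect_equal(reg$x, c(1, 3, 5))   # nearest fix wins each slot
  # hourly fixes already on grid -> identity
  clean <- make_traj(1:10, rep(0, 10))
  expect_equal(regularize(clean, 1)$x, clean$x)
  expect_equal(as.numeric(regularize(clean, 1)$t), as.numeric(clean$t))
  # idempotence on gappy data
  gap <- trajectory(t0 + c(0, 1, 2, 5, 6) * 3600, 1:5, rep(0, 5), id = "g")
  r1 <- regularize(gap, 1); r2 <- regularize(r1, 1)
  expect_identical(r1$x, r2$x)
  expect_equal(sum(is.na(r1$x)), 2L)
  expect_error(trajectory(as.POSIXct(character(), tz = "UTC"),
                          numeric(0), numeric(0)), "empty")
})

test_that("90-min fixes regularized to 1 h leave every third slot empty", {
  t0 <- as.POSIXct("2001-03-01 00:00:00", tz = "UTC")
  raw <- trajectory(t0 + seq(0, by = 90, length.out = 21) * 60,
                    seq_len(21), rep(0, 21), id = "albatross")
  reg <- regularize(raw, 1)
  # 90-min cadence on a 60-min grid: fixes land on slots 0, 1.5->NA?, 3, ...
  # slots at odd multiples of 1 h that are 30 min from both neighbours are
  # filled (tolerance is 30 min inclusive); gap fraction is 1/3
  expect_equal(mean(is.na(reg$x)), 1 / 3, tolerance = 0.05)
})

test_that("subsampling keeps every k-th fix and composes multiplicatively", {
  tr <- make_traj(cumsum(runif(3600)), cumsum(runif(3600)))
  s3 <- subsample(tr, 3)
  expect_equal(nrow(s3), 1200L)
  expect_equal(attr(s3, "interval_h"), 3)
  expect_identical(subsample(tr, 1)$x, tr$x)
  expect_identical(subsample(tr, 6)$x, subsample(subsample(tr, 2), 3)$x)
  expect_error(subsample(tr, 0))
  # path straightening: subsampled mean step is never shorter per unit hop
  set.seed(11)
  for (i in 1:5) {
    w <- make_traj(cumsum(rnorm(200)), cumsum(rnorm(200)))
    expect_gte(3 * steps_and_turns(subsample(w, 3))$mean_SL + 1e-9,
               steps_and_turns(w)$mean_SL)
  }
})

test_that("steps and turns follow the geometry of the path", {
  sq <- make_traj(c(0, 1, 1, 0), c(0, 0, 1, 1))
  st <- steps_and_turns(sq)
  expect_equal(st$step_lengths, rep(1, 3))
  expect_equal(st$mean_SL, 1)
  expect_equal(st$turn_angles, c(pi / 2, pi / 2))
  # collinear equally spaced -> zero turns
  line <- make_traj(seq(0, 900, 100), rep(2, 10))
  expect_equal(steps_and_turns(line)$turn_angles, rep(0, 8))
  # zero-length steps carry the previous heading: turn angle 0
  zl <- make_traj(c(0, 1, 1, 2), c(0, 0, 0, 0))
  expect_equal(steps_and_turns(zl)$turn_angles, rep(0, 2))
  expect_error(steps_and_turns(make_traj(0:1, 0:1)), "at least 3")
})

test_that("headings recompose from turns and are rigid-motion covariant", {
  set.seed(5)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  st <- steps_and_turns(make_traj(x, y))
  rebuilt <- st$headings[1] + cumsum(c(0, st$turn_angles))
  wrap <- function(a) atan2(sin(a), cos(a))
  expect_equal(wrap(rebuilt), wrap(st$headings), tolerance = 1e-12)
  # rotation + translation leave step lengths and turns unchanged
  th <- 0.7
  xr <- 100 + x * cos(th) - y * sin(th)
  yr <- -50 + x * sin(th) + y * cos(th)
  str <- steps_and_turns(make_traj(xr, yr))
  expect_equal(str$step_lengths, st$step_lengths, tolerance = 1e-10)
  expect_equal(str$turn_angles, st$turn_angles, tolerance = 1e-10)
})
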