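# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with the most literal possible scan, and are
# kept free of any code shared with the package implementation.

# turn angle correlation by direct term-by-term summation
tac_oracle <- function(rho) {
  n <- length(rho)
  s <- 0
  for (k in 1:(n - 1)) {
    s <- s + (cos(rho[k + 1]) - cos(rho[k]))^2 + (sin(rho[k + 1]) - sin(rho[k]))^2
  }
  s / n
}

# residence time: per-location O(n^2) scan. A located fix inside the circle
# contributes one interval; missing fixes count as outside; an excursion of
# more than cutoff hours ends accumulation in that direction.
rt_oracle <- function(x, y, interval_h, radius, cutoff_h) {
  n <- length(x)
  maxout <- floor(cutoff_h / interval_h)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    total <- 1
    for (dir in c(1L, -1L)) {
      run_out <- 0
      j <- i + dir
      while (j >= 1 && j <= n) {
        inside <- !is.na(x[j]) &&
          (x[j] - x[i])^2 + (y[j] - y[i])^2 <= radius^2
        if (inside) {
          total <- total + 1
          run_out <- 0
        } else {
          run_out <- run_out + 1
          if (run_out > maxout) break
        }
        j <- j + dir
      }
    }
    out[i] <- total * interval_h
  }
  mean(out, na.rm = TRUE)
}

# time-to-return: first absence exceeding cutoff that is followed by re-entry
t2r_oracle <- function(x, y, interval_h, radius, cutoff_h) {
  n <- length(x)
  minout <- floor(cutoff_h / interval_h)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    run_out <- 0
    for (j in seq_len(n)[-seq_len(i)]) {
      inside <- !is.na(x[j]) &&
        (x[j] - x[i])^2 + (y[j] - y[i])^2 <= radius^2
      if (inside) {
        if (run_out > minout) { vals[i] <- run_out * interval_h; break }
        run_out <- 0
      } else {
        run_out <- run_out + 1
      }
    }
  }
  if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
}

# exhaustive minimum-variance (Ward) agglomeration: at every stage evaluate
# every candidate merge's increase in total within-cluster sum of squares and
# take the smallest (ties: lexicographically smallest member pair).
ward_oracle <- function(X) {
  X <- as.matrix(X)
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  merges <- list()
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr, "-")^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL; best_inc <- Inf
    for (a in 1:(length(clusters) - 1L)) for (b in (a + 1):length(clusters)) {
      inc <- ess(c(clusters[[a]], clusters[[b]])) -
        ess(clusters[[a]]) - ess(clusters[[b]])
      if (inc < best_inc - 1e-12) { best <- c(a, b); best_inc <- inc }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges   # list of leaf-index sets, in merge order
}

# leaf sets of an hclust tree in merge order
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    members <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[m, j]
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[m]] <- sort(members)
  }
  sets
}

# small regular trajectory builder
make_traj <- function(x, y, id = "t", species = "sp", start = "2001-01-01",
                      interval_h = 1) {
  t0 <- as.POSIXct(start, tz = "UTC")
  trajectory(t0 + (seq_along(x) - 1) * interval_h * 3600, x, y,
             id = id, species = species, interval_h = interval_h)
}

# shared small simulated cohort for metric tests (cached across test files)
mini_cohort_trajs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_fixtures(seed = 7)
      cache <<- lapply(fx$mini_cohort, function(s) s$trajectory)
    }
    cache
  }
})
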