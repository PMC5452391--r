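#' Configuration for an idealized-mover simulation
#'
#' Defaults define the reference study conditions for the four movement
#' syndromes: 3600 hourly steps (7200 for migrants, to include a return
#' migration), a 500 m base step, a 2.5 km foraging range (2 km territory)
#' for the range-resident syndromes, central-place attendance with 0.1-scaled
#' steps and trip departures at 0.02 per hour, nomad state switching at 0.05
#' per hour between short-step foraging and correlated-walk exploration, and
#' a migratory state with 3-scaled steps and tightly correlated headings.
#' Step lengths are drawn uniformly on (0, 2 * base_step * scalar) so the
#' mean step is base_step * scalar. The rationale for each value is laid out
#' in the package vignette.
#'
#' @param syndrome one of `"cpf"`, `"territorial"`, `"nomad"`, `"migrant"`.
#' @param n_steps number of hourly steps (default 3600; migrant 7200).
#' @param interval_h sampling interval in hours (1).
#' @param home_range_radius home-range radius R in metres (cpf/territorial).
#'   Defaults to 2500 m for central-place foragers and 2000 m for
#'   territorialists (a defended territory is compact relative to a foraging
#'   range).
#' @param core_radius radius of the central place (default R/5): a
#'   boundary-triggered CPF return ends when the mover is back within this
#'   distance of the centre, and inside it the forager moves with the
#'   `foraging` step scalar (attendance at the central place).
#' @param base_step mean step length scale in metres.
#' @param step_scalars named per-state step multipliers.
#' @param turn_sd named per-state SDs (rad) of the normal heading/turn
#'   distributions (`return` for boundary-triggered returns, `trip` for CPF
#'   outbound forays, `exploratory`, `migratory`).
#' @param switch_prob nomad per-step probability of switching state.
#' @param trip_prob CPF per-step probability of leaving the central place on
#'   a foraging trip (default 0.02, within the empirically reported
#'   behavioural switching range; mean attendance bout 50 h).
#' @param migration_schedule named integer vector of phase durations in steps
#'   (sedentary, migratory, sedentary2, return); must sum to `n_steps`.
#' @param max_tries proposals per step before the rejection sampler accepts
#'   the final proposal regardless of weight. The default (3) keeps the
#'   confinement bias soft enough that a range-resident mover contacts its
#'   home-range boundary a few times per month, which the out-and-return
#'   construction requires; large values confine central-place foragers so
#'   strongly that boundary trips never occur.
#' @param start UTC start timestamp; the default (first hour of a 31-day
#'   month) makes 3600 hourly steps span 5 calendar months.
#' @return A list of class `syndrome_config`.
#' @export
syndrome_config <- function(syndrome = c("cpf", "territorial", "nomad", "migrant"),
                            n_steps = NULL,
                            interval_h = 1,
                            home_range_radius = NULL,
                            core_radius = NULL,
                            base_step = 500,
                            step_scalars = c(range = 1, attend = 0.1,
                                             foraging = 0.3,
                                             exploratory = 1, sedentary = 1,
                                             migratory = 3),
                            turn_sd = c(return = 0.3, trip = 0.3, exploratory = 1.5,
                                        migratory = 0.15),
                            switch_prob = 0.05,
                            trip_prob = 0.02,
                            migration_schedule = NULL,
                            max_tries = 3L,
                            start = as.POSIXct("2001-01-01 00:00:00", tz = "UTC")) {
  syndrome <- match.arg(syndrome)
  if (is.null(n_steps)) n_steps <- if (syndrome == "migrant") 7200L else 3600L
  n_steps <- as.integer(n_steps)
  # defended territories are compact relative to a central-place foraging
  # range, so the territorial radius defaults smaller
  if (is.null(home_range_radius))
    home_range_radius <- if (syndrome == "territorial") 2000 else 2500
  if (is.null(core_radius)) core_radius <- home_range_radius / 5
  if (syndrome == "migrant" && is.null(migration_schedule)) {
    # 4:2:4:2-month proportions of the residence/migration/residence/return
    # cycle, scaled to n_steps
    u <- n_steps / 6
    migration_schedule <- c(sedentary = round(2 * u), migratory = round(u),
                            sedentary2 = round(2 * u))
    migration_schedule <- c(migration_schedule,
                            ret = n_steps - sum(migration_schedule))
    names(migration_schedule)[4] <- "return"
  }
  if (!is.null(migration_schedule) && sum(migration_schedule) != n_steps)
    stop("migration_schedule durations must sum to n_steps")
  if (switch_prob <= 0 || switch_prob >= 1) stop("switch_prob must be in (0, 1)")
  if (any(step_scalars <= 0)) stop("step scalars must be > 0")
  structure(list(syndrome = syndrome, n_steps = n_steps, interval_h = interval_h,
                 home_range_radius = home_range_radius,
                 core_radius = core_radius, base_step = base_step,
                 step_scalars = step_scalars, turn_sd = turn_sd,
                 switch_prob = switch_prob, trip_prob = trip_prob,
                 migration_schedule = migration_schedule,
                 max_tries = as.integer(max_tries), start = start),
            class = "syndrome_config")
}

sim_result <- function(xs, ys, states, cfg, id, species) {
  t <- cfg$start + (seq_along(xs) - 1) * cfg$interval_h * 3600
  structure(list(
    trajectory = trajectory(t, xs, ys, id = id, species = species,
                            interval_h = cfg$interval_h),
    state_sequence = states,
    config = cfg), class = "sim_result")
}

# Rejection-sampled step for the range-resident syndromes. `weight_fn` maps
# the proposed endpoint's distance from the home-range centre to an
# acceptance weight in [0, 1]; after max_tries failures the last proposal is
# taken, which is how boundary crossings occur for weights vanishing at the
# edge.
propose_step <- function(x, y, base_step, weight_fn, max_tries) {
  for (k in seq_len(max_tries)) {
    h <- stats::runif(1, -pi, pi)
    len <- stats::runif(1, 0, 2 * base_step)
    nx <- x + len * cos(h); ny <- y + len * sin(h)
    if (stats::runif(1) < weight_fn(sqrt(nx^2 + ny^2))) break
  }
  c(x = nx, y = ny, heading = h)
}

# Territorial engine: uniform step proposals accepted with a weight that
# grows with distance from the range centre, plus the boundary-return rule.
simulate_range_resident <- function(cfg, seed, weight_fn, id, species) {
  set.seed(seed)
  n <- cfg$n_steps
  R <- cfg$home_range_radius
  bs <- cfg$base_step * cfg$step_scalars[["range"]]
  sd_ret <- cfg$turn_sd[["return"]]
  xs <- numeric(n); ys <- numeric(n); states <- character(n)
  x <- 0; y <- 0; heading <- stats::runif(1, -pi, pi)
  returning <- FALSE
  xs[1] <- x; ys[1] <- y; states[1] <- "range"
  for (i in 2:n) {
    d <- sqrt(x^2 + y^2)
    if (!returning && d > R) returning <- TRUE
    else if (returning && d <= R) returning <- FALSE
    if (returning) {
      # turn drawn around 180 degrees from the travel direction at the
      # boundary crossing; subsequent return steps head for the range centre
      # with the same angular noise, so the return always completes
      heading <- if (states[i - 1L] == "return")
        atan2(-y, -x) + stats::rnorm(1, 0, sd_ret)
      else heading + pi + stats::rnorm(1, 0, sd_ret)
      len <- stats::runif(1, 0, 2 * bs)
      x <- x + len * cos(heading); y <- y + len * sin(heading)
      states[i] <- "return"
    } else {
      s <- propose_step(x, y, bs, weight_fn, cfg$max_tries)
      x <- s[["x"]]; y <- s[["y"]]; heading <- s[["heading"]]
      states[i] <- "range"
    }
    xs[i] <- x; ys[i] <- y
  }
  sim_result(xs, ys, states, cfg, id, species)
}

# Central-place forager engine: attendance at the central place (short
# foraging steps inside the core) alternating with foraging trips — a
# persistent outbound foray that ends at the home-range boundary, where the
# turning angle flips ~180 degrees and the mover homes back to the core.
simulate_cpf_engine <- function(cfg, seed, id, species) {
  set.seed(seed)
  n <- cfg$n_steps
  R <- cfg$home_range_radius
  core <- cfg$core_radius
  bs <- cfg$base_step * cfg$step_scalars[["range"]]
  bs_att <- cfg$base_step * cfg$step_scalars[["attend"]]
  sd_ret <- cfg$turn_sd[["return"]]
  sd_trip <- cfg$turn_sd[["trip"]]
  xs <- numeric(n); ys <- numeric(n); states <- character(n)
  x <- 0; y <- 0; heading <- stats::runif(1, -pi, pi)
  state <- "attend"
  xs[1] <- x; ys[1] <- y; states[1] <- state
  for (i in 2:n) {
    d <- sqrt(x^2 + y^2)
    state <- switch(state,
      attend = if (stats::runif(1) < cfg$trip_prob) "trip" else "attend",
      trip = if (d > R) "return" else "trip",
      `return` = if (d <= core / 5) "attend" else "return")
    if (state == "attend") {
      heading <- heading + stats::runif(1, -pi, pi)
      len <- stats::runif(1, 0, 2 * bs_att)
    } else if (state == "trip") {
      heading <- heading + stats::rnorm(1, 0, sd_trip)
      len <- stats::runif(1, 0, 2 * bs)
    } else {
      heading <- if (states[i - 1L] == "return")
        atan2(-y, -x) + stats::rnorm(1, 0, sd_ret)
      else heading + pi + stats::rnorm(1, 0, sd_ret)
      len <- stats::runif(1, 0, 2 * bs)
    }
    x <- x + len * cos(heading); y <- y + len * sin(heading)
    xs[i] <- x; ys[i] <- y; states[i] <- state
  }
  sim_result(xs, ys, states, cfg, id, species)
}

#' Simulate a central-place forager
#'
#' Bounded home-range movement organized around a central place: inside the
#' core (radius `core_radius`) the forager moves with short foraging steps
#' and uniform turn angles (attendance, concentrating use at the centre);
#' leaving the core starts a foraging trip with persistent headings; on
#' reaching the home-range boundary the turning angle is drawn from a normal
#' distribution centred 180 degrees from the travel direction and the mover
#' homes back to its central place. The result is the repeated out-and-return
#' trip structure characteristic of central-place foraging.
#'
#' @param cfg a [syndrome_config()] with `syndrome = "cpf"`.
#' @param seed integer RNG seed; the simulation is fully deterministic given
#'   `(cfg, seed)`.
#' @param id,species labels for the resulting trajectory.
#' @return A `sim_result`: `trajectory` (a `traj`) plus `state_sequence`.
#' @export
simulate_cpf <- function(cfg = syndrome_config("cpf"), seed = 1,
                         id = "cpf_1", species = "cpf") {
  stopifnot(cfg$syndrome == "cpf")
  simulate_cpf_engine(cfg, seed, id, species)
}

#' Simulate a territorial mover
#'
#' Identical boundary-return machinery to [simulate_cpf()], but step
#' proposals are weighted by distance *to* the home-range centre (weight
#' d/R, capped at 1), concentrating use at the periphery of the territory.
#'
#' @inheritParams simulate_cpf
#' @export
simulate_territorial <- function(cfg = syndrome_config("territorial"), seed = 1,
                                 id = "territorial_1", species = "territorial") {
  stopifnot(cfg$syndrome == "territorial")
  R <- cfg$home_range_radius
  simulate_range_resident(cfg, seed, function(d) min(1, d / R), id, species)
}

#' Simulate a nomad
#'
#' Two-state movement with symmetric per-step switching (default probability
#' 0.05) between a foraging state (short steps, uniform turn angles) and an
#' exploratory state (full-length steps, correlated turning angles with zero
#' mean, so each bout drifts around the direction held when it began). The
#' path is not bounded.
#'
#' @inheritParams simulate_cpf
#' @param cfg a [syndrome_config()] with `syndrome = "nomad"`.
#' @export
simulate_nomad <- function(cfg = syndrome_config("nomad"), seed = 1,
                           id = "nomad_1", species = "nomad") {
  stopifnot(cfg$syndrome == "nomad")
  set.seed(seed)
  n <- cfg$n_steps
  bs_f <- cfg$base_step * cfg$step_scalars[["foraging"]]
  bs_e <- cfg$base_step * cfg$step_scalars[["exploratory"]]
  sd_e <- cfg$turn_sd[["exploratory"]]
  xs <- numeric(n); ys <- numeric(n); states <- character(n)
  x <- 0; y <- 0
  heading <- stats::runif(1, -pi, pi)
  state <- sample(c("foraging", "exploratory"), 1)
  xs[1] <- x; ys[1] <- y; states[1] <- state
  for (i in 2:n) {
    if (stats::runif(1) < cfg$switch_prob) {
      state <- if (state == "foraging") "exploratory" else "foraging"
    }
    if (state == "foraging") {
      heading <- heading + stats::runif(1, -pi, pi)
      len <- stats::runif(1, 0, 2 * bs_f)
    } else {
      # correlated walk: zero-mean turns, so the expected direction of an
      # exploratory bout is the direction held when the bout began
      heading <- heading + stats::rnorm(1, 0, sd_e)
      len <- stats::runif(1, 0, 2 * bs_e)
    }
    x <- x + len * cos(heading); y <- y + len * sin(heading)
    xs[i] <- x; ys[i] <- y; states[i] <- state
  }
  sim_result(xs, ys, states, cfg, id, species)
}

#' Simulate a migrant
#'
#' A sedentary-migratory-sedentary-return schedule (4:2:4:2-month
#' proportions over `n_steps`, default 7200 hourly steps). Sedentary phases
#' use uniform step and turn distributions; migratory phases use long steps
#' (scalar 3) with headings tightly concentrated (SD 0.15 rad) around a
#' persistent migration direction drawn once per individual; the return leg
#' homes on the origin location, so the migration ends where it began.
#'
#' @inheritParams simulate_cpf
#' @param cfg a [syndrome_config()] with `syndrome = "migrant"`.
#' @export
simulate_migrant <- function(cfg = syndrome_config("migrant"), seed = 1,
                             id = "migrant_1", species = "migrant") {
  stopifnot(cfg$syndrome == "migrant")
  set.seed(seed)
  n <- cfg$n_steps
  sched <- cfg$migration_schedule
  phase_of <- rep(names(sched), times = sched)
  state_of <- ifelse(phase_of %in% c("migratory", "return"), "migratory", "sedentary")
  bs_s <- cfg$base_step * cfg$step_scalars[["sedentary"]]
  bs_m <- cfg$base_step * cfg$step_scalars[["migratory"]]
  sd_m <- cfg$turn_sd[["migratory"]]
  out_heading <- stats::runif(1, -pi, pi)
  xs <- numeric(n); ys <- numeric(n)
  x <- 0; y <- 0; heading <- out_heading
  xs[1] <- x; ys[1] <- y
  for (i in 2:n) {
    if (state_of[i] == "sedentary") {
      heading <- heading + stats::runif(1, -pi, pi)
      len <- stats::runif(1, 0, 2 * bs_s)
    } else {
      # outbound legs hold a persistent heading; the return leg homes on the
      # origin so the migration ends where it began
      mu <- if (phase_of[i] == "migratory") out_heading else atan2(-y, -x)
      heading <- stats::rnorm(1, mu, sd_m)
      len <- stats::runif(1, 0, 2 * bs_m)
    }
    x <- x + len * cos(heading); y <- y + len * sin(heading)
    xs[i] <- x; ys[i] <- y
  }
  sim_result(xs, ys, state_of, cfg, id, species)
}

#' Simulate a cohort of one syndrome
#'
#' Independent replicates of one idealized mover (default six individuals per
#' syndrome). The species label of each trajectory is set to the syndrome
#' name.
#'
#' @param syndrome one of `"cpf"`, `"territorial"`, `"nomad"`, `"migrant"`.
#' @param n_individuals number of replicates.
#' @param seeds one integer seed per individual.
#' @param cfg optional [syndrome_config()] override.
#' @return A list of `sim_result` objects.
#' @export
simulate_cohort <- function(syndrome, n_individuals = 6,
                            seeds = seq_len(n_individuals), cfg = NULL) {
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (length(seeds) != n_individuals) stop("one seed per individual required")
  if (anyDuplicated(seeds)) warning("duplicate seeds: replicates will be identical")
  if (is.null(cfg)) cfg <- syndrome_config(syndrome)
  fn <- switch(syndrome,
               cpf = simulate_cpf, territorial = simulate_territorial,
               nomad = simulate_nomad, migrant = simulate_migrant,
               stop("unknown syndrome: ", syndrome))
  lapply(seq_len(n_individuals), function(i)
    fn(cfg, seed = seeds[i], id = sprintf("%s_%d", syndrome, i), species = syndrome))
}

#' Simulate the full four-syndrome reference set
#'
#' Six individuals for each of the four syndromes (24 movers), with seeds
#' derived reproducibly from one master seed.
#'
#' @param master_seed integer master seed.
#' @param n_per_syndrome individuals per syndrome (default 6).
#' @param cfgs optional named list of per-syndrome [syndrome_config()]s.
#' @return A flat list of 24 `sim_result` objects.
#' @export
simulate_reference_set <- function(master_seed = 1, n_per_syndrome = 6,
                                   cfgs = NULL) {
  syndromes <- c("cpf", "territorial", "nomad", "migrant")
  out <- list()
  for (k in seq_along(syndromes)) {
    s <- syndromes[k]
    seeds <- (master_seed * 1000L + k * 100L + seq_len(n_per_syndrome)) %% .Machine$integer.max
    cfg <- if (!is.null(cfgs)) cfgs[[s]] else NULL
    out <- c(out, simulate_cohort(s, n_per_syndrome, seeds = seeds, cfg = cfg))
  }
  out
}
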