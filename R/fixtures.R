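#' Deterministic analytic and seeded fixtures
#'
#' Small named datasets with known metric values, used by the test-suite and
#' examples: a stationary path, a straight line, a unit-square loop, and a
#' fast seeded mini-cohort (all four syndromes at reduced length). All are
#' regenerated bitwise-identically from the seed.
#'
#' @param seed integer seed for the mini-cohort.
#' @param mini_steps steps per mini-cohort individual (default 1500, the
#'   minimum that spans two full calendar months so monthly overlap is
#'   defined; migrants get twice as many).
#' @return Named list: `stationary`, `straight`, `square` (traj objects) and
#'   `mini_cohort` (list of `sim_result`).
#' @export
make_fixtures <- function(seed = 42, mini_steps = 1500) {
  t0 <- as.POSIXct("2001-01-01 00:00:00", tz = "UTC")
  hours <- function(n) t0 + (seq_len(n) - 1) * 3600
  stationary <- trajectory(hours(48), rep(0, 48), rep(0, 48),
                           id = "stationary", species = "fixture")
  straight <- trajectory(hours(11), seq(0, 1000, by = 100), rep(0, 11),
                         id = "straight", species = "fixture")
  square <- trajectory(hours(4), c(0, 1, 1, 0), c(0, 0, 1, 1),
                       id = "square", species = "fixture")
  syndromes <- c("cpf", "territorial", "nomad", "migrant")
  mini <- list()
  for (k in seq_along(syndromes)) {
    s <- syndromes[k]
    n <- if (s == "migrant") 2L * mini_steps else mini_steps
    cfg <- syndrome_config(s, n_steps = n)
    mini <- c(mini, simulate_cohort(s, 2, seeds = seed + k * 10 + 1:2, cfg = cfg))
  }
  list(stationary = stationary, straight = straight, square = square,
       mini_cohort = mini)
}
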