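#' Time-use parameters for residence time and time-to-return
#'
#' @param radius circle radius in metres. The default (`NULL`) uses each
#'   individual's mean step length, the standard choice for these metrics.
#' @param cutoff_h excursion cut-off in hours (default 12): an absence from
#'   the focal circle longer than this ends residence (RT) or qualifies as a
#'   departure whose duration-until-return is measured (T2R).
#' @return A list of class `timeuse_params`.
#' @export
timeuse_params <- function(radius = NULL, cutoff_h = 12) {
  if (!is.null(radius) && radius <= 0) stop("radius must be > 0")
  if (cutoff_h <= 0) stop("cutoff must be > 0")
  structure(list(radius = radius, cutoff_h = cutoff_h), class = "timeuse_params")
}

#' Turn angle correlation S_A
#'
#' Mean of squared chord distances between successive turn angles:
#' \deqn{S_A = \frac{1}{N} \sum_{n=1}^{N-1} [(\cos\rho_{n+1}-\cos\rho_n)^2 +
#'   (\sin\rho_{n+1}-\sin\rho_n)^2]}
#' where the \eqn{\rho_n} are the N turn angles. Low values indicate high
#' turn-angle correlation (directional persistence); the maximum is 4(N-1)/N
#' for turn angles alternating between opposite directions.
#'
#' @param steps a `step_series` from [steps_and_turns()], or a numeric vector
#'   of turn angles in radians.
#' @return S_A, a dimensionless value in \[0, 4).
#' @export
tac <- function(steps) {
  rho <- if (inherits(steps, "step_series")) steps$turn_angles else as.numeric(steps)
  n <- length(rho)
  if (n < 2L) stop("need at least 2 turn angles for S_A")
  sum((cos(rho[-1]) - cos(rho[-n]))^2 + (sin(rho[-1]) - sin(rho[-n]))^2) / n
}

resolve_radius <- function(traj, params) {
  if (!is.null(params$radius)) return(params$radius)
  r <- steps_and_turns(traj)$mean_SL
  if (r <= 0) stop("mean step length is 0; supply an explicit radius")
  r
}

#' Mean residence time (hours)
#'
#' For every located relocation, the hours the animal spends inside the circle
#' of radius `radius` centred there (forward and backward along the path),
#' residence ending in each direction at the first excursion outside the
#' circle longer than the cut-off. Each located fix inside the circle counts
#' one sampling interval; missing slots count as time outside, so data gaps
#' longer than the cut-off terminate residence. Returns the mean over all
#' located relocations.
#'
#' @inheritParams time_to_return
#' @return Mean residence time in hours.
#' @seealso [time_to_return()]
#' @export
residence_time <- function(traj, params = timeuse_params()) {
  radius <- resolve_radius(traj, params)
  v <- .rt_core(traj$x, traj$y, traj_interval(traj), radius, params$cutoff_h)
  mean(v, na.rm = TRUE)
}

#' Mean time-to-return (hours)
#'
#' For every located relocation, the duration of the first absence from its
#' circle that exceeds the cut-off time and is followed by a re-entry.
#' Relocations with no qualifying absence-then-return contribute nothing; if
#' no relocation contributes the result is 0 (with a message).
#'
#' @param traj a regularized `traj`.
#' @param params a [timeuse_params()] object.
#' @return Mean time-to-return in hours over contributing relocations.
#' @export
time_to_return <- function(traj, params = timeuse_params()) {
  radius <- resolve_radius(traj, params)
  v <- .t2r_core(traj$x, traj$y, traj_interval(traj), radius, params$cutoff_h)
  if (all(is.na(v))) {
    message(sprintf("trajectory %s: no absence-and-return events; T2R = 0", traj_id(traj)))
    return(0)
  }
  mean(v, na.rm = TRUE)
}

#' Maximum net squared displacement (m^2)
#'
#' Maximum squared Euclidean displacement from the first located relocation
#' over the full trajectory.
#'
#' @param traj a `traj` with at least 2 located relocations.
#' @return MNSD in square metres.
#' @export
mnsd <- function(traj) {
  keep <- !is.na(traj$x) & !is.na(traj$y)
  x <- traj$x[keep]; y <- traj$y[keep]
  if (length(x) < 2L) stop("need at least 2 located relocations")
  max((x - x[1])^2 + (y - y[1])^2)
}

#' Scale MNSD by the within-group minimum
#'
#' Divides each individual's raw MNSD by the smallest MNSD in its scaling
#' group (by default the species), making displacements comparable across
#' groups with very different motion capacities. The group minimum maps to
#' exactly 1.
#'
#' @param profiles a data.frame with columns `mnsd_raw` and the grouping
#'   column.
#' @param group name of the grouping column (default `"species"`), or `NULL`
#'   to scale by the pooled minimum over all rows.
#' @return `profiles` with an added/overwritten `mnsd_scaled` column.
#' @export
scale_mnsd <- function(profiles, group = "species") {
  g <- if (is.null(group)) rep("all", nrow(profiles)) else as.character(profiles[[group]])
  mins <- tapply(profiles$mnsd_raw, g, min)
  if (any(mins <= 0))
    stop("degenerate stationary individual: group minimum MNSD is 0 in group(s) ",
         paste(names(mins)[mins <= 0], collapse = ", "))
  profiles$mnsd_scaled <- profiles$mnsd_raw / as.numeric(mins[g])
  profiles
}

#' Assemble the five-metric table for a set of trajectories
#'
#' Computes turn angle correlation (S_A), mean residence time, mean
#' time-to-return, mean monthly home-range overlap (VI) and scaled maximum net
#' squared displacement for each individual. Individuals lacking two
#' qualifying calendar months of data (VI undefined) are excluded with a
#' message.
#'
#' @param trajs a list of regularized `traj` objects (common interval).
#' @param params a [timeuse_params()]; a `NULL` radius uses each individual's
#'   mean step length.
#' @param mnsd_group grouping column for MNSD scaling: `"species"` (default)
#'   or `NULL` for a single pooled group.
#' @param ud_opts options passed to [monthly_uds()]. The default computes VI
#'   on full (untruncated) utilization distributions, the standard
#'   volume-of-intersection construction; pass `list(level = 0.95)` for the
#'   isopleth-truncated variant.
#' @return A data.frame with columns `individual_id`, `species`, `tac_sa`,
#'   `rt_h`, `t2r_h`, `vi`, `mnsd_raw`, `mnsd_scaled`, `mean_sl_m`.
#' @export
metric_table <- function(trajs, params = timeuse_params(),
                         mnsd_group = "species", ud_opts = list(level = 1)) {
  if (length(trajs) == 0L) stop("no trajectories supplied")
  rows <- lapply(trajs, function(tr) {
    st <- steps_and_turns(tr)
    vi <- tryCatch({
      uds <- do.call(monthly_uds, c(list(tr), ud_opts))
      volume_of_intersection(uds)
    }, error = function(e) {
      message(sprintf("individual %s excluded: %s", traj_id(tr), conditionMessage(e)))
      NA_real_
    })
    data.frame(individual_id = traj_id(tr), species = traj_species(tr),
               tac_sa = tac(st),
               rt_h = residence_time(tr, params),
               t2r_h = time_to_return(tr, params),
               vi = vi,
               mnsd_raw = mnsd(tr),
               mean_sl_m = st$mean_SL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$vi), , drop = FALSE]
  if (nrow(out) == 0L) stop("no individual satisfied the VI preconditions")
  rownames(out) <- NULL
  scale_mnsd(out, group = mnsd_group)
}

#' Write / read a metric table as TSV
#' @param profiles a metric table from [metric_table()].
#' @param path file path.
#' @export
write_metric_table <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
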