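#' Read trajectories from CSV
#'
#' Reads a Movebank-flavoured relocation CSV: columns `individual_id`,
#' `timestamp` (ISO-8601, assumed UTC when unzoned) and either planar `x`,`y`
#' in metres or `lon`,`lat` in degrees. One file may hold many individuals.
#' Longitude/latitude are projected to planar metres at ingest with a local
#' azimuthal equidistant projection centred on each individual's centroid
#' (all downstream metrics are Euclidean). Rows with unparseable timestamps
#' or coordinates are rejected and counted in the `rejected_rows` attribute.
#'
#' @param path CSV file path.
#' @param species optional named vector individual_id -> species; defaults to
#'   a `species` column if present, else `"unknown"`.
#' @return A list of `traj` objects (not yet regularized).
#' @export
read_trajectories <- function(path, species = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp")
  if (!all(need %in% names(d)))
    stop("missing required columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  geographic <- all(c("lon", "lat") %in% names(d))
  if (!geographic && !all(c("x", "y") %in% names(d)))
    stop("need either x,y or lon,lat columns")
  ts <- parse_iso8601(d$timestamp)
  bad <- is.na(ts)
  n_rejected <- sum(bad)
  if (n_rejected) warning(sprintf("%d row(s) with unparseable timestamps rejected", n_rejected))
  d <- d[!bad, , drop = FALSE]; ts <- ts[!bad]
  out <- lapply(split(seq_len(nrow(d)), d$individual_id), function(idx) {
    di <- d[idx, , drop = FALSE]; ti <- ts[idx]
    if (geographic) {
      xy <- project_aeqd(di$lon, di$lat)
    } else {
      xy <- cbind(x = di$x, y = di$y)
    }
    sp <- if (!is.null(species)) species[[di$individual_id[1]]]
          else if ("species" %in% names(di)) di$species[1] else "unknown"
    trajectory(ti, xy[, 1], xy[, 2], id = di$individual_id[1],
               species = sp %||% "unknown", interval_h = NA_real_)
  })
  attr(out, "rejected_rows") <- n_rejected
  out
}

# ISO-8601 parser tolerant of malformed rows: tries each format, returns NA
# where none matches (assumes UTC when unzoned)
parse_iso8601 <- function(s) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(s)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(s[todo], f, tz = "UTC"))
  }
  out
}

# local azimuthal equidistant projection centred on the centroid:
# x = geodesic distance * sin(bearing), y = distance * cos(bearing)
project_aeqd <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon, na.rm = TRUE), mean(lat, na.rm = TRUE))
  pts <- cbind(lon, lat)
  dst <- geosphere::distGeo(center, pts)
  brg <- geosphere::bearing(center, pts) * pi / 180
  out <- cbind(x = dst * sin(brg), y = dst * cos(brg))
  out[dst == 0, ] <- 0
  out
}

#' Write trajectories to CSV
#'
#' Emits the same dialect [read_trajectories()] reads (`individual_id,
#' timestamp,x,y,species`); missing slots are written with empty coordinate
#' fields.
#'
#' @param trajs a list of `traj` objects (or a single `traj`).
#' @param path output CSV path.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "traj")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr)
    data.frame(individual_id = attr(tr, "id"), species = attr(tr, "species"),
               timestamp = format(tr$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               x = tr$x, y = tr$y, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write and read a run configuration (YAML)
#'
#' Round-trips the pipeline configuration losslessly. Defaults match the
#' reference study conditions: 1-h interval, 12-h cut-off, radius = mean step
#' length (`NULL`), 1000 bootstrap replicates, 3600/7200 simulation steps,
#' nomad switch probability 0.05.
#'
#' @param cfg a named list of options.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Default run configuration
#' @return Named list of the default study conditions.
#' @export
default_run_config <- function() {
  list(interval_h = 1, cutoff_h = 12, radius = NULL, n_boot = 1000,
       n_steps = 3600, n_steps_migrant = 7200, switch_prob = 0.05,
       n_per_syndrome = 6, scale_mode = "sd", cut = "gap", master_seed = 1)
}
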