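#' Construct a trajectory object
#'
#' A trajectory is a time-ordered set of relocations for one individual at a
#' (nominally) fixed sampling interval. Coordinates are planar metres;
#' longitude/latitude input must be projected at ingest (see
#' [read_trajectories()]). Missing grid slots created by [regularize()] are
#' represented by `NA` coordinates.
#'
#' @param t `POSIXct` timestamps (UTC), strictly increasing.
#' @param x,y easting / northing in metres; `NA` marks a missing slot.
#' @param id individual identifier.
#' @param species group label used for between-individual MNSD scaling.
#' @param interval_h sampling interval in hours.
#' @return An object of class `traj`: a `data.frame` with columns `t`, `x`,
#'   `y` and attributes `id`, `species`, `interval_h`.
#' @export
trajectory <- function(t, x, y, id = "ind1", species = "sp1", interval_h = 1) {
  if (length(t) == 0L) stop("empty trajectory")
  if (!inherits(t, "POSIXct")) t <- as.POSIXct(t, tz = "UTC")
  attr(t, "tzone") <- "UTC"
  stopifnot(length(t) == length(x), length(x) == length(y))
  o <- order(t)
  t <- t[o]; x <- x[o]; y <- y[o]
  if (anyDuplicated(as.numeric(t))) stop("duplicate timestamps in trajectory")
  if (any(!is.finite(x) & !is.na(x)) || any(!is.finite(y) & !is.na(y)))
    stop("non-finite coordinates")
  out <- data.frame(t = t, x = as.numeric(x), y = as.numeric(y))
  structure(out, class = c("traj", "data.frame"),
            id = as.character(id), species = as.character(species),
            interval_h = as.numeric(interval_h))
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("<traj> id=%s species=%s n=%d interval=%gh missing=%d\n",
              attr(x, "id"), attr(x, "species"), nrow(x),
              attr(x, "interval_h"), sum(is.na(x$x))))
  invisible(x)
}

traj_id      <- function(traj) attr(traj, "id")
traj_species <- function(traj) attr(traj, "species")
traj_interval <- function(traj) attr(traj, "interval_h")

#' Regularize a trajectory onto a uniform time grid
#'
#' Relocations are snapped onto a grid of spacing `interval_h` hours anchored
#' at the first fix. Each grid slot is filled by the nearest raw fix within
#' half an interval; slots with no such fix become missing (`NA` coordinates).
#' Leading/trailing missing slots are trimmed (the anchor guarantees the first
#' slot is filled). No interpolation is performed: downstream time-use metrics
#' treat long gaps as excursions rather than fabricating residence.
#'
#' @param traj a `traj` object (or a data.frame with `t`, `x`, `y`).
#' @param interval_h target interval in hours.
#' @return A regularized `traj`; missing slots have `NA` coordinates.
#' @export
regularize <- function(traj, interval_h = 1) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  keep <- !is.na(traj$x) & !is.na(traj$y)
  tt <- as.numeric(traj$t[keep]); xx <- traj$x[keep]; yy <- traj$y[keep]
  if (length(tt) == 0L) stop("trajectory has no located fixes")
  step <- interval_h * 3600
  t0 <- tt[1]
  nslot <- floor((tt[length(tt)] - t0) / step) + 1L
  slot_t <- t0 + (seq_len(nslot) - 1L) * step
  # nearest slot for each raw fix, then nearest fix for each slot
  slot_of <- as.integer(round((tt - t0) / step)) + 1L
  off <- abs(tt - (t0 + (slot_of - 1L) * step))
  ok <- slot_of >= 1L & slot_of <= nslot & off <= step / 2
  xs <- rep(NA_real_, nslot); ys <- rep(NA_real_, nslot)
  if (any(ok)) {
    d <- data.frame(slot = slot_of[ok], off = off[ok], x = xx[ok], y = yy[ok])
    d <- d[order(d$slot, d$off), ]
    d <- d[!duplicated(d$slot), ]
    xs[d$slot] <- d$x; ys[d$slot] <- d$y
  }
  filled <- which(!is.na(xs))
  lo <- filled[1]; hi <- filled[length(filled)]
  xs <- xs[lo:hi]; ys <- ys[lo:hi]; slot_t <- slot_t[lo:hi]
  gap_frac <- mean(is.na(xs))
  if (gap_frac > 0.5)
    warning(sprintf("trajectory %s: %.0f%% of grid slots missing after regularization",
                    attr(traj, "id"), 100 * gap_frac))
  trajectory(as.POSIXct(slot_t, tz = "UTC", origin = "1970-01-01"),
             xs, ys,
             id = attr(traj, "id") %||% "ind1",
             species = attr(traj, "species") %||% "sp1",
             interval_h = interval_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subsample a regularized trajectory
#'
#' Keeps every `factor`-th relocation starting at the first, multiplying the
#' sampling interval accordingly (e.g. hourly fixes with `factor = 3` become
#' 3-hourly fixes). Used for temporal-resolution sensitivity analyses.
#'
#' @param traj a regularized `traj`.
#' @param factor integer >= 1.
#' @return A `traj` at the coarser interval.
#' @export
subsample <- function(traj, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("subsample factor must be >= 1")
  idx <- seq(1L, nrow(traj), by = factor)
  trajectory(traj$t[idx], traj$x[idx], traj$y[idx],
             id = attr(traj, "id"), species = attr(traj, "species"),
             interval_h = attr(traj, "interval_h") * factor)
}

wrap_angle <- function(a) {
  r <- (a + pi) %% (2 * pi) - pi   # [-pi, pi)
  r[r <= -pi] <- pi                # convention: (-pi, pi]
  r
}

#' Step lengths, headings and turn angles of a trajectory
#'
#' Steps connect successive located relocations (missing slots are skipped).
#' Headings are absolute directions (`atan2` of the displacement); turn angles
#' are successive heading differences wrapped to (-pi, pi]. A zero-length step
#' carries the previous heading forward so its turn angle is 0 rather than
#' undefined.
#'
#' @param traj a `traj` with at least 3 located relocations.
#' @return A list of class `step_series`: `step_lengths` (m), `headings`
#'   (rad), `turn_angles` (rad, one fewer than steps), `mean_SL` (m).
#' @export
steps_and_turns <- function(traj) {
  keep <- !is.na(traj$x) & !is.na(traj$y)
  x <- traj$x[keep]; y <- traj$y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 located relocations for steps and turns")
  dx <- diff(x); dy <- diff(y)
  sl <- sqrt(dx^2 + dy^2)
  h <- atan2(dy, dx)
  # carry heading across zero-length steps
  for (i in seq_along(h)) {
    if (sl[i] == 0) h[i] <- if (i == 1L) 0 else h[i - 1L]
  }
  turns <- wrap_angle(diff(h))
  structure(list(step_lengths = sl, headings = h, turn_angles = turns,
                 mean_SL = mean(sl)),
            class = "step_series")
}
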