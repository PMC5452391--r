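#' Monthly kernel utilization distributions on a shared grid
#'
#' Splits a trajectory by UTC calendar month, keeps months with at least
#' `min_fixes` located relocations, and estimates one bivariate kernel
#' utilization distribution (UD) per qualifying month. All months share one
#' grid covering every month's extent so their overlap can be integrated
#' cell-by-cell. Each UD is truncated at its `level` isopleth (default the
#' 95% kernel home range) and renormalized to unit mass.
#'
#' Bandwidth is the reference ("normal rule") bandwidth per axis and month
#' (as in standard home-range kernel estimation); grid spacing defaults to
#' 1/50 of the largest monthly extent, with the cell count capped for very
#' elongated trajectories.
#'
#' @param traj a regularized `traj` spanning at least 2 qualifying months.
#' @param min_fixes minimum located fixes for a month to qualify (default 100).
#' @param level isopleth level for truncation (default 0.95; 1 disables
#'   truncation).
#' @param grid_frac grid spacing as a fraction of the largest monthly extent.
#' @param max_cells cap on grid cells per axis.
#' @return A list of `ud` objects (fields `x`, `y`, `mass`, `month`), one per
#'   qualifying month, on a common grid.
#' @export
monthly_uds <- function(traj, min_fixes = 100, level = 0.95,
                        grid_frac = 1 / 50, max_cells = 256) {
  keep <- !is.na(traj$x) & !is.na(traj$y)
  d <- traj[keep, , drop = FALSE]
  mon <- format(d$t, "%Y-%m", tz = "UTC")
  tab <- table(mon)
  months <- names(tab)[tab >= min_fixes]
  if (length(months) < 2L)
    stop(sprintf("individual %s: fewer than 2 calendar months with >= %d fixes; VI undefined",
                 attr(traj, "id"), min_fixes))
  by_m <- lapply(months, function(m) d[mon == m, c("x", "y")])

  # largest monthly extent sets the grid spacing; shared bounding box + pad
  ext <- vapply(by_m, function(p) max(diff(range(p$x)), diff(range(p$y))), 0)
  spacing <- max(ext) * grid_frac
  if (spacing <= 0) spacing <- 1
  bw <- lapply(by_m, function(p) {
    c(x = nrd_bandwidth(p$x), y = nrd_bandwidth(p$y))
  })
  pad <- max(unlist(bw)) * 3
  xr <- range(d$x) + c(-pad, pad)
  yr <- range(d$y) + c(-pad, pad)
  nx <- min(max_cells, max(25L, ceiling(diff(xr) / spacing) + 1L))
  ny <- min(max_cells, max(25L, ceiling(diff(yr) / spacing) + 1L))

  lapply(seq_along(months), function(i) {
    p <- by_m[[i]]
    k <- MASS::kde2d(p$x, p$y, h = pmax(bw[[i]], spacing / 10),
                     n = c(nx, ny), lims = c(xr, yr))
    mass <- k$z / sum(k$z)
    mass <- truncate_ud(mass, level)
    structure(list(x = k$x, y = k$y, mass = mass, month = months[i],
                   level = level), class = "ud")
  })
}

# MASS::bandwidth.nrd with a floor for (near-)degenerate coordinates
nrd_bandwidth <- function(v) {
  b <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
  if (!is.finite(b) || b <= 0) b <- max(stats::sd(v), 1e-6)
  if (!is.finite(b) || b <= 0) b <- 1e-6
  b
}

truncate_ud <- function(mass, level) {
  if (level >= 1) return(mass / sum(mass))
  o <- order(mass, decreasing = TRUE)
  cs <- cumsum(mass[o])
  cut_idx <- which(cs >= level)[1]
  thr <- mass[o][cut_idx]
  mass[mass < thr] <- 0
  mass / sum(mass)
}

#' Volume of intersection between utilization distributions
#'
#' VI(a, b) is the integral of the pointwise minimum of two UDs: 0 for
#' disjoint ranges, 1 for identical ones. For more than two UDs the mean over
#' all distinct pairs is returned (a measure of monthly home-range
#' stability).
#'
#' @param uds a list of `ud` objects on a shared grid (from [monthly_uds()]).
#' @param pairs `"all"` (default) or `"consecutive"` months.
#' @return Mean pairwise VI in \[0, 1\].
#' @export
volume_of_intersection <- function(uds, pairs = c("all", "consecutive")) {
  pairs <- match.arg(pairs)
  if (length(uds) < 2L) stop("need at least 2 UDs")
  same_grid <- function(a, b)
    length(a$x) == length(b$x) && length(a$y) == length(b$y) &&
      isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
  for (i in seq_along(uds)[-1])
    if (!same_grid(uds[[1]], uds[[i]])) stop("UDs are not on a shared grid")
  idx <- if (pairs == "all") utils::combn(length(uds), 2, simplify = FALSE)
         else lapply(seq_len(length(uds) - 1L), function(i) c(i, i + 1L))
  mean(vapply(idx, function(ij)
    sum(pmin(uds[[ij[1]]]$mass, uds[[ij[2]]]$mass)), 0))
}

#' Export a UD as an ASCII grid raster
#' @param ud a `ud` object.
#' @param path output file path.
#' @export
write_ud_ascii <- function(ud, path) {
  nx <- length(ud$x); ny <- length(ud$y)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.6f", min(ud$x)), sprintf("yllcorner %.6f", min(ud$y)),
           sprintf("cellsize %.6f", ud$x[2] - ud$x[1]), "NODATA_value -9999")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  for (j in ny:1) writeLines(paste(signif(ud$mass[, j], 6), collapse = " "), con)
  invisible(path)
}
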