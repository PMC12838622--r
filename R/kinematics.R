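#' Hits per hand and per release bin
#'
#' Counts paddle-ball hits in an object-hit task log, keyed by hand and by
#' the bin the ball was released from. The number of hits per hand is the
#' primary outcome measure of the assessment task.
#'
#' @param log a [task_log()].
#' @return list with `left` and `right`, each an integer vector of length
#'   `n_bins` (counts per release bin), plus `total` (named vector of the two
#'   hand totals).
#' @export
count_hits <- function(log) {
  stopifnot(inherits(log, "task_log"))
  per_bin <- function(hand) {
    h <- log$hits[log$hits$hand == hand, , drop = FALSE]
    tabulate(h$bin + 1L, nbins = log$n_bins)
  }
  left <- per_bin("left"); right <- per_bin("right")
  list(left = left, right = right,
       total = c(left = sum(left), right = sum(right)))
}

# zero-phase 2nd-order Butterworth low-pass, guarding short inputs
lowpass_traj <- function(v, rate, cutoff) {
  if (is.null(cutoff) || cutoff <= 0 || length(v) < 12L) return(v)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  signal::filtfilt(bf, v)
}

#' Hand speed and absolute acceleration from a planar trajectory
#'
#' Differentiates a sampled (x, y) hand trajectory into speed and absolute
#' acceleration magnitudes. Positions are first low-passed (zero-phase
#' 2nd-order Butterworth, default 10 Hz) to suppress sensor noise, then
#' differentiated by central differences (one-sided at the endpoints).
#'
#' @param traj_x,traj_y [timeseries()] of x and y position in cm, equal
#'   length and rate.
#' @param smooth_hz low-pass cut-off in Hz, or `NULL` to skip smoothing.
#' @return list with `speed` and `abs_accel` ([timeseries()], cm/s and
#'   cm/s^2) plus scalar summaries `mean_speed` and `mean_abs_accel`.
#' @export
hand_speed_accel <- function(traj_x, traj_y, smooth_hz = 10) {
  stopifnot(inherits(traj_x, "timeseries"), inherits(traj_y, "timeseries"))
  if (length(traj_x$values) != length(traj_y$values) ||
      traj_x$rate != traj_y$rate)
    stop("validation error: x/y trajectories must share length and rate")
  n <- length(traj_x$values)
  if (n < 3L) stop("validation error: trajectory too short to differentiate")
  rate <- traj_x$rate
  x <- lowpass_traj(traj_x$values, rate, smooth_hz)
  y <- lowpass_traj(traj_y$values, rate, smooth_hz)
  d1 <- function(v) {
    dv <- numeric(n)
    dv[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) * rate / 2
    dv[1L] <- (v[2L] - v[1L]) * rate
    dv[n] <- (v[n] - v[n - 1L]) * rate
    dv
  }
  vx <- d1(x); vy <- d1(y)
  ax <- d1(vx); ay <- d1(vy)
  speed <- sqrt(vx^2 + vy^2)
  accel <- sqrt(ax^2 + ay^2)
  list(
    speed = timeseries(speed, rate = rate, t0 = traj_x$t0, units = "cm/s",
                       channel = traj_x$channel),
    abs_accel = timeseries(accel, rate = rate, t0 = traj_x$t0,
                           units = "cm/s^2", channel = traj_x$channel),
    mean_speed = mean(speed), mean_abs_accel = mean(accel))
}

# cells crossed by segment (x0,y0)-(x1,y1): exact supercover — enumerate the
# segment's crossings of grid lines and mark the cell containing each
# inter-crossing midpoint; returns 0-based cell ids (cx + cy * nx)
rasterise_segment <- function(x0, y0, x1, y1, cell, ox, oy, nx, ny) {
  dx <- x1 - x0; dy <- y1 - y0
  ts <- c(0, 1)
  crossings <- function(lo, hi, o, d, p0) {
    k0 <- ceiling((lo - o) / cell); k1 <- floor((hi - o) / cell)
    if (k0 > k1) return(numeric(0))
    ((k0:k1) * cell + o - p0) / d
  }
  if (abs(dx) > 0)
    ts <- c(ts, crossings(min(x0, x1), max(x0, x1), ox, dx, x0))
  if (abs(dy) > 0)
    ts <- c(ts, crossings(min(y0, y1), max(y0, y1), oy, dy, y0))
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mid <- (ts[-1L] + ts[-length(ts)]) / 2
  mid <- c(mid, 0, 1)  # include endpoints so a point segment marks its cell
  cx <- pmin(pmax(floor((x0 + mid * dx - ox) / cell), 0), nx - 1L)
  cy <- pmin(pmax(floor((y0 + mid * dy - oy) / cell), 0), ny - 1L)
  unique(cx + cy * nx)
}

#' Space covered by a hand across the task
#'
#' Measures the workspace area a hand covered as the total area of
#' occupancy-grid cells its trajectory visited. Consecutive samples are
#' joined by straight segments and every cell a segment crosses is marked, so
#' fast sweeps are not undercounted. Samples outside the workspace are
#' clipped to its boundary with a warning.
#'
#' @param traj_x,traj_y [timeseries()] of x and y position in cm.
#' @param cell_size occupancy cell edge length in cm (default 1).
#' @param workspace `c(width, height)` of the workspace in cm (default the
#'   76 x 44 cm task field).
#' @param origin `c(x, y)` of the workspace lower-left corner (default 0,0).
#' @return list with `area` (cm^2), `n_cells` visited, and `grid`
#'   (integer visit-count matrix, rows = y cells, cols = x cells) with
#'   attributes `cell_size` and `origin`.
#' @export
space_covered <- function(traj_x, traj_y, cell_size = 1,
                          workspace = c(76, 44), origin = c(0, 0)) {
  stopifnot(inherits(traj_x, "timeseries"), inherits(traj_y, "timeseries"))
  x <- traj_x$values; y <- traj_y$values
  if (length(x) != length(y))
    stop("validation error: x/y trajectories must share length")
  nx <- as.integer(ceiling(workspace[1L] / cell_size))
  ny <- as.integer(ceiling(workspace[2L] / cell_size))
  out_of_bounds <- x < origin[1L] | x > origin[1L] + workspace[1L] |
                   y < origin[2L] | y > origin[2L] + workspace[2L]
  if (any(out_of_bounds)) {
    warning(sum(out_of_bounds), " trajectory samples outside the workspace;",
            " clipped to the boundary")
    x <- pmin(pmax(x, origin[1L]), origin[1L] + workspace[1L])
    y <- pmin(pmax(y, origin[2L]), origin[2L] + workspace[2L])
  }
  counts <- integer(nx * ny)
  if (length(x) == 1L) {
    id <- rasterise_segment(x, y, x, y, cell_size, origin[1L], origin[2L],
                            nx, ny)
    counts[id + 1L] <- counts[id + 1L] + 1L
  } else {
    for (i in seq_len(length(x) - 1L)) {
      id <- rasterise_segment(x[i], y[i], x[i + 1L], y[i + 1L], cell_size,
                              origin[1L], origin[2L], nx, ny)
      counts[id + 1L] <- counts[id + 1L] + 1L
    }
  }
  grid <- matrix(counts, nrow = ny, ncol = nx, byrow = TRUE)
  attr(grid, "cell_size") <- cell_size
  attr(grid, "origin") <- origin
  list(area = sum(grid > 0) * cell_size^2, n_cells = sum(grid > 0),
       grid = grid)
}

#' Kinematic outcome summary for one hand
#'
#' Bundles the assessment-task outcome measures for one hand: total hits,
#' hits per bin, mean speed, mean absolute acceleration and space covered.
#'
#' @param log a [task_log()] with trajectories.
#' @param hand `"left"` or `"right"`.
#' @param cell_size occupancy cell size in cm for [space_covered()].
#' @param smooth_hz trajectory smoothing cut-off for [hand_speed_accel()].
#' @return An object of class `"kinematic_summary"`: list with `hand`,
#'   `hits_total`, `hits_per_bin`, `mean_speed`, `mean_abs_accel`,
#'   `space_covered` and `occupancy` (the grid).
#' @export
kinematic_summary <- function(log, hand = c("left", "right"), cell_size = 1,
                              smooth_hz = 10) {
  stopifnot(inherits(log, "task_log"))
  hand <- match.arg(hand)
  if (is.null(log$trajectories) || is.null(log$trajectories[[hand]]))
    stop("task log has no trajectory for the ", hand, " hand")
  hits <- count_hits(log)
  tr <- log$trajectories[[hand]]
  sa <- hand_speed_accel(tr$x, tr$y, smooth_hz = smooth_hz)
  sc <- space_covered(tr$x, tr$y, cell_size = cell_size)
  structure(list(hand = hand,
                 hits_total = unname(hits$total[hand]),
                 hits_per_bin = hits[[hand]],
                 mean_speed = sa$mean_speed,
                 mean_abs_accel = sa$mean_abs_accel,
                 space_covered = sc$area,
                 occupancy = sc$grid),
            class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf(paste0("<kinematic_summary> %s hand: %d hits, ",
                     "mean speed %.2f cm/s, mean |accel| %.2f cm/s^2, ",
                     "space covered %.0f cm^2\n"),
              x$hand, x$hits_total, x$mean_speed, x$mean_abs_accel,
              x$space_covered))
  invisible(x)
}
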