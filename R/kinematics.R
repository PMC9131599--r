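#' Crank angle from pedal and axis marker trajectories
#'
#' Projects the pedal-minus-axis vector onto the plane of maximal marker
#' variance (the crank plane; for sagittal pedaling, x-z), measures the angle
#' of each frame's vector from the projection of the lab vertical ("straight
#' up" = 0 deg, the upper dead center), and unwraps it so the angle increases
#' continuously in the direction of rotation.
#'
#' @param markers Data frame with columns `time_s`, `pedal_x/y/z`,
#'   `axis_x/y/z` (m), one row per frame.
#' @return Object of class `crank_trace`: `t` (s), `angle_deg` (unwrapped,
#'   0 at upper dead center), `cycle_bounds` (NULL until [segment_cycles()]).
#' @export
compute_crank_angle <- function(markers) {
  need <- c("time_s", "pedal_x", "pedal_y", "pedal_z",
            "axis_x", "axis_y", "axis_z")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0) stop("markers missing column(s): ", paste(miss, collapse = ", "))
  v <- cbind(markers$pedal_x - markers$axis_x,
             markers$pedal_y - markers$axis_y,
             markers$pedal_z - markers$axis_z)
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-9)) {
    stop("pedal and axis markers coincide at frame ", which(r < 1e-9)[1])
  }
  # crank plane = span of the two leading principal axes of the crank vector
  if (sum(apply(v, 2, stats::var)) < 1e-12) {
    stop("markers show no rotation: crank vector is constant across frames")
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  e1 <- pc$rotation[, 1]; e2 <- pc$rotation[, 2]
  up <- c(0, 0, 1)
  u <- c(sum(up * e1), sum(up * e2))
  if (sqrt(sum(u^2)) < 1e-6) {
    stop("crank plane is horizontal; cannot orient the upper dead center")
  }
  a <- v %*% e1
  b <- v %*% e2
  # signed angle from the projected vertical to each frame's crank vector
  raw <- atan2(b, a) - atan2(u[2], u[1])
  ang <- unwrap_deg(raw * 180 / pi)
  if (ang[length(ang)] < ang[1]) ang <- -ang  # positive = direction of rotation
  ang <- ang - round(ang[1] / 360) * 360      # keep start near its wrapped value
  structure(list(t = markers$time_s, angle_deg = as.numeric(ang),
                 cycle_bounds = NULL),
            class = "crank_trace")
}

unwrap_deg <- function(x) {
  d <- diff(x)
  d <- (d + 180) %% 360 - 180
  cumsum(c(x[1], d))
}

#' Segment a crank trace into pedaling cycles
#'
#' One cycle runs from one upper dead center to the next: boundaries are the
#' upward crossings of multiples of 360 deg in the unwrapped angle, located by
#' linear interpolation between the bracketing frames. Leading and trailing
#' partial cycles are discarded.
#'
#' @param trace `crank_trace` from [compute_crank_angle()].
#' @return The trace with `cycle_bounds` set: a data frame of
#'   (`start_s`, `end_s`) per complete cycle.
#' @export
segment_cycles <- function(trace) {
  stopifnot(inherits(trace, "crank_trace"))
  ang <- trace$angle_deg
  tt <- trace$t
  span <- ang[length(ang)] - ang[1]
  if (span < 720 - 1e-6) {
    stop("insufficient data: unwrapped angle spans ", round(span, 1),
         " deg; need at least 720 (two upper-dead-center cycles)")
  }
  # 1 deg tolerance: marker jitter must not drop a boundary lying exactly on
  # the first/last frame (retained cycles still span 360 +/- 1 deg)
  tol <- 1.0
  m_first <- ceiling((ang[1] - tol) / 360)
  m_last <- floor((ang[length(ang)] + tol) / 360)
  if (m_last - m_first < 1) stop("fewer than 2 upper-dead-center crossings")
  cross_t <- vapply(m_first:m_last, function(m) {
    target <- m * 360
    i <- which(ang >= target - 1e-9)[1]
    if (is.na(i)) return(tt[length(tt)])   # boundary within tol past the end
    if (i == 1L) return(tt[1])
    # linear interpolation between the bracketing frames
    tt[i - 1] + (target - ang[i - 1]) / (ang[i] - ang[i - 1]) * (tt[i] - tt[i - 1])
  }, numeric(1))
  trace$cycle_bounds <- data.frame(start_s = cross_t[-length(cross_t)],
                                   end_s = cross_t[-1])
  trace
}

#' Number of complete cycles in a segmented trace
#' @param trace A segmented `crank_trace`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(trace) {
  if (is.null(trace$cycle_bounds)) stop("trace is not segmented; call segment_cycles()")
  nrow(trace$cycle_bounds)
}
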