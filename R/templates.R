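#' Muscle activation templates on the crank-angle base
#'
#' An activation template describes the expected intensity of a muscle as a
#' function of crank angle (0 deg = upper dead center), built as a sum of
#' periodic raised-cosine bursts. Templates drive the synthetic sEMG generator
#' and provide the analytic ground truth against which the offline pipeline is
#' validated.
#'
#' @name activation-templates
NULL

MUSCLES <- c("VL", "ST", "RF", "BF")
CONDITIONS <- c("NFB", "VLFB", "STFB", "VL-STFB")
TEMPLATE_GRID_N <- 360L

#' Build an activation template from raised-cosine bursts
#'
#' Each burst is a raised cosine `amp * 0.5 * (1 + cos(2*pi*(theta - center)/width))`
#' supported on `center +/- width/2`, wrapping periodically across 0/360 deg.
#' The profile is the pointwise sum of all bursts, evaluated on a uniform
#' 360-point grid over `[0, 360)` degrees.
#'
#' @param muscle Channel label, one of `"VL"`, `"ST"`, `"RF"`, `"BF"`.
#' @param burst_params List of numeric triples `c(center_deg, width_deg, amplitude)`.
#'   Centers are taken modulo 360; widths must be strictly positive. An empty
#'   list is only allowed with `null_template = TRUE`.
#' @param null_template Logical; allow an all-zero template (no bursts).
#' @return An object of class `activation_template` with fields `muscle`,
#'   `profile` (length-360 numeric), `grid_deg`, and `burst_params`.
#' @examples
#' vl <- build_template("VL", list(c(350, 90, 1)))
#' plot(vl$grid_deg, vl$profile, type = "l")
#' @export
build_template <- function(muscle, burst_params, null_template = FALSE) {
  muscle <- match.arg(muscle, MUSCLES)
  if (length(burst_params) == 0L && !null_template) {
    stop("empty burst list: template for '", muscle,
         "' would be unusable (pass null_template = TRUE for a silent channel)")
  }
  burst_params <- lapply(burst_params, function(b) {
    b <- as.numeric(b)
    if (length(b) != 3L) stop("each burst must be c(center_deg, width_deg, amplitude)")
    if (b[2] <= 0) stop("burst width must be > 0 (got ", b[2], ")")
    if (b[3] < 0) stop("burst amplitude must be >= 0")
    b[1] <- b[1] %% 360
    b
  })
  grid <- seq(0, 360, length.out = TEMPLATE_GRID_N + 1L)[seq_len(TEMPLATE_GRID_N)]
  profile <- rowSums(vapply(
    burst_params,
    function(b) raised_cosine(grid, b[1], b[2], b[3]),
    numeric(TEMPLATE_GRID_N)
  ))
  if (length(burst_params) == 0L) profile <- numeric(TEMPLATE_GRID_N)
  structure(
    list(muscle = muscle, profile = profile, grid_deg = grid,
         burst_params = burst_params),
    class = "activation_template"
  )
}

# single periodic raised-cosine burst evaluated at angles theta (deg)
raised_cosine <- function(theta, center, width, amp) {
  d <- (theta - center) %% 360
  d <- ifelse(d > 180, d - 360, d)     # wrapped distance in (-180, 180]
  out <- numeric(length(theta))
  inside <- abs(d) <= width / 2
  out[inside] <- amp * 0.5 * (1 + cos(2 * pi * d[inside] / width))
  out
}

#' Evaluate a template at arbitrary crank angles
#'
#' Linear interpolation on the periodic 360-point grid.
#'
#' @param template An `activation_template`.
#' @param angle_deg Numeric vector of crank angles (degrees, any range;
#'   reduced modulo 360).
#' @return Numeric vector of activation values.
#' @export
eval_template <- function(template, angle_deg) {
  stopifnot(inherits(template, "activation_template"))
  a <- angle_deg %% 360
  # append the wrap point so interpolation is periodic
  x <- c(template$grid_deg, 360)
  y <- c(template$profile, template$profile[1])
  stats::approx(x, y, xout = a, method = "linear")$y
}

#' Default activation templates for the four recorded muscles
#'
#' Encodes the crank-phase-locked activation patterns of pedaling: the vastus
#' lateralis (VL) bursts around the top dead center; the semitendinosus (ST)
#' is active over the downstroke (0-180 deg) and again late in the upstroke
#' (270-360 deg); the rectus femoris (RF) is active except over 90-180 deg;
#' the biceps femoris (BF) is active over the downstroke (0-180 deg).
#'
#' @param st_shift_deg Degrees added to both ST burst centers; positive values
#'   move ST activity toward the VL burst and increase the designed VL-ST
#'   overlap. Used to impose a known condition effect in simulations.
#' @return Named list of `activation_template` objects (`VL`, `ST`, `RF`, `BF`).
#' @export
default_templates <- function(st_shift_deg = 0) {
  list(
    VL = build_template("VL", list(c(350, 90, 1))),
    ST = build_template("ST", list(c(90 + st_shift_deg, 180, 1),
                                   c(315 + st_shift_deg, 90, 0.8))),
    RF = build_template("RF", list(c(0, 160, 1), c(230, 100, 0.6))),
    BF = build_template("BF", list(c(90, 180, 1)))
  )
}

#' Analytic co-contraction index of two templates
#'
#' Computes the COI the offline pipeline should recover from a simulated trial:
#' the modelled envelope of each channel is `noise_floor + snr * noise_floor *
#' profile / max(profile)` (amplitude-modulated noise rectifies to an envelope
#' proportional to its modulation), each envelope is normalized to its own
#' peak (mirroring per-muscle peak normalization), and the common-area COI is
#' evaluated on a 200-point cycle base.
#'
#' @param t1,t2 `activation_template` objects.
#' @param noise_floor,snr Baseline amplitude and burst-to-baseline ratio of the
#'   simulated recording. `noise_floor = 0` gives the COI of the bare templates.
#' @param n_points Grid size of the cycle base (default 200).
#' @return COI in percent.
#' @export
designed_coi <- function(t1, t2, noise_floor = 0, snr = 10, n_points = 200L) {
  frac <- seq(0, 1, length.out = n_points + 1L)[seq_len(n_points)]
  ang <- 360 * frac
  m1 <- eval_template(t1, ang)
  m2 <- eval_template(t2, ang)
  if (noise_floor > 0) {
    m1 <- noise_floor + snr * noise_floor * m1 / max(m1)
    m2 <- noise_floor + snr * noise_floor * m2 / max(m2)
  }
  coi(m1 / max(m1), m2 / max(m2))
}
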