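#' Common area between two rectified envelopes
#'
#' The common area operationalizes "simultaneous activation" as the integral
#' of the pointwise minimum of the two envelopes (Winter's convention),
#' evaluated by the trapezoidal rule on the shared uniform grid with unit
#' spacing. Envelopes live on the half-open periodic cycle base (point k at
#' cycle fraction k/n; the wrap point is not duplicated), so the trapezoid
#' over the closed periodic domain reduces to the plain sum of the values.
#' The spacing cancels in the COI ratio, so areas are in point x amplitude
#' units.
#'
#' @param e1,e2 Non-negative numeric envelopes of equal length >= 2.
#' @return Scalar area, `0 <= area <= min(area(e1), area(e2))`.
#' @export
common_area <- function(e1, e2) {
  check_envelope_pair(e1, e2)
  trapz_periodic(pmin(e1, e2))
}

# trapezoid rule, unit spacing, periodic domain: sum_k (y_k + y_{k+1})/2 over
# the n wrap-closed segments collapses to sum(y)
trapz_periodic <- function(y) {
  sum(y)
}

check_envelope_pair <- function(e1, e2) {
  if (length(e1) != length(e2)) stop("envelopes differ in length")
  if (length(e1) < 2) stop("envelopes must have length >= 2")
  if (any(e1 < 0) || any(e2 < 0)) {
    stop("negative envelope values: inputs must be rectified envelopes")
  }
  invisible(TRUE)
}

#' Co-contraction index (COI) of two envelopes
#'
#' \deqn{COI = \frac{2 \times CommonArea}{area_{EMG1} + area_{EMG2}} \times 100}
#'
#' where the areas are trapezoidal integrals over the shared grid and the
#' common area is the integral of the pointwise minimum. 100 means the two
#' envelopes coincide; 0 means their supports are disjoint.
#'
#' @param e1,e2 Non-negative numeric envelopes of equal length >= 2.
#' @return COI in percent, in `[0, 100]`.
#' @export
coi <- function(e1, e2) {
  check_envelope_pair(e1, e2)
  a1 <- trapz_periodic(e1)
  a2 <- trapz_periodic(e2)
  if (a1 + a2 <= 0) {
    stop("both envelopes are identically zero: COI is undefined")
  }
  min(100, max(0, 2 * common_area(e1, e2) / (a1 + a2) * 100))
}

#' COI of a trial from two cycle-envelope sets
#'
#' Two bases are supported: `"ensemble"` (default) computes the COI of the two
#' ensemble-averaged waveforms, matching how cycle-normalized sEMG is usually
#' presented; `"per_cycle_mean"` computes a COI per cycle and averages.
#'
#' @param set1,set2 `cycle_envelope_set` objects for the two muscles of a pair,
#'   same participant/condition and (for `per_cycle_mean`) equal cycle counts.
#' @param basis `"ensemble"` or `"per_cycle_mean"`.
#' @return Data frame (one row): `participant`, `condition`, `pair`,
#'   `coi_percent`, `basis`, `n_cycles`.
#' @export
coi_for_trial <- function(set1, set2, basis = c("ensemble", "per_cycle_mean")) {
  basis <- match.arg(basis)
  stopifnot(inherits(set1, "cycle_envelope_set"),
            inherits(set2, "cycle_envelope_set"))
  if (!identical(set1$participant, set2$participant) ||
      !identical(set1$condition, set2$condition)) {
    stop("mismatched trial metadata: ", set1$participant, "/", set1$condition,
         " vs ", set2$participant, "/", set2$condition)
  }
  if (basis == "per_cycle_mean" && nrow(set1$cycles) != nrow(set2$cycles)) {
    stop("per_cycle_mean basis requires equal cycle counts")
  }
  value <- if (basis == "ensemble") {
    coi(ensemble_average(set1)$mean, ensemble_average(set2)$mean)
  } else {
    mean(vapply(seq_len(nrow(set1$cycles)), function(i) {
      coi(set1$cycles[i, ], set2$cycles[i, ])
    }, numeric(1)))
  }
  data.frame(
    participant = set1$participant, condition = set1$condition,
    pair = paste(set1$muscle, set2$muscle, sep = "-"),
    coi_percent = value, basis = basis,
    n_cycles = nrow(set1$cycles)
  )
}
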