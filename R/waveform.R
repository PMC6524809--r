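# Pulsatile inflow waveforms: square-law scaling to the inlet
# cross-section and conversion to plug-profile velocity.
#
# The protocol prescribes a literature waveform scaled to each group's
# inlet diameter with a square law (flow proportional to D^2), and a plug
# (spatially uniform) inlet velocity justified by a long inlet extrusion.
# The package ships a parametric two-harmonic surrogate plus a CSV reader
# for user-supplied curves; the reference curve itself is external input.

#' Pulsatile inflow waveform
#'
#' @param times sample times (s), strictly increasing, spanning one period.
#' @param q flow rate at `times` (ml/s).
#' @param period cycle length T (s); default `max(times)`.
#' @param d_ref reference inlet diameter (mm) the waveform belongs to.
#' @return object of class `waveform`.
#' @export
waveform <- function(times, q, period = NULL, d_ref = 4) {
  .assert(length(times) >= 2 && all(diff(times) > 0),
          "aneumorph_format_error", "times must be strictly increasing")
  .assert(length(q) == length(times), "aneumorph_format_error",
          "q and times differ in length")
  if (is.null(period)) period <- max(times)
  .assert(period > 0 && d_ref > 0, "aneumorph_domain_error",
          "period and d_ref must be positive")
  qm <- mean(q)
  .assert(qm > 0, "aneumorph_domain_error",
          "waveform mean flow must be positive")
  scale <- max(abs(q))
  .assert(abs(q[1] - q[length(q)]) <= 0.01 * scale + 1e-12,
          "aneumorph_domain_error",
          "waveform is not periodic: |Q(0) - Q(T)| exceeds 1%% of the amplitude")
  structure(list(times = as.numeric(times), q = as.numeric(q),
                 period = period, d_ref = d_ref),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: T = %g s, mean Q = %.3f ml/s (range %.3f - %.3f), D_ref = %g mm\n",
              x$period, mean(x$q), min(x$q), max(x$q), x$d_ref))
  invisible(x)
}

#' Two-harmonic surrogate inflow waveform
#'
#' `Q(t) = Q_mean (1 + a1 sin(2 pi t/T + p1) + a2 sin(4 pi t/T + p2))` —
#' a smooth pulsatile curve with exact cycle mean `Q_mean`, standing in
#' for measured internal-carotid inflow curves when none are supplied.
#' @param q_mean cycle-mean flow rate (ml/s).
#' @param period T (s).
#' @param a1,a2 relative amplitudes of the first two harmonics.
#' @param p1,p2 phases (rad).
#' @param n number of samples over one period (endpoints included).
#' @param d_ref reference diameter (mm).
#' @return a [waveform].
#' @export
two_harmonic_waveform <- function(q_mean = 2, period = 1, a1 = 0.25,
                                  a2 = 0.10, p1 = 0, p2 = pi / 3,
                                  n = 41L, d_ref = 4) {
  t <- seq(0, period, length.out = n)
  q <- q_mean * (1 + a1 * sin(2 * pi * t / period + p1) +
                 a2 * sin(4 * pi * t / period + p2))
  # enforce exact periodicity of the sampled curve
  q[n] <- q[1]
  waveform(t, q, period = period, d_ref = d_ref)
}

#' Read/write waveform CSV (columns `t_s`, `Q_ml_per_s`)
#' @param path CSV path.
#' @param period,d_ref see [waveform()].
#' @return a [waveform].
#' @export
read_waveform_csv <- function(path, period = NULL, d_ref = 4) {
  df <- utils::read.csv(path, comment.char = "#")
  .assert(all(c("t_s", "Q_ml_per_s") %in% names(df)),
          "aneumorph_format_error",
          "waveform CSV needs columns t_s and Q_ml_per_s")
  waveform(df$t_s, df$Q_ml_per_s, period = period, d_ref = d_ref)
}

#' @rdname read_waveform_csv
#' @param wave a [waveform] to write.
#' @export
write_waveform_csv <- function(wave, path) {
  utils::write.csv(data.frame(t_s = wave$times, Q_ml_per_s = wave$q),
                   path, row.names = FALSE)
  invisible(path)
}

#' Square-law scaling of a waveform to an inlet cross-section
#'
#' Flow is scaled by `(D / D_ref)^2` with the effective inlet diameter
#' `D = 2 sqrt(A / pi)`; times and period are unchanged, so the waveform
#' shape is preserved exactly.
#' @param wave a [waveform].
#' @param inlet_area inlet cross-sectional area (mm^2).
#' @return the scaled [waveform] (its `d_ref` becomes the new diameter).
#' @export
scale_waveform <- function(wave, inlet_area) {
  .assert(is.numeric(inlet_area) && inlet_area > 0,
          "aneumorph_domain_error", "inlet area must be positive")
  D <- 2 * sqrt(inlet_area / pi)
  f <- (D / wave$d_ref)^2
  waveform(wave$times, wave$q * f, period = wave$period, d_ref = D)
}

#' Plug-profile inlet velocity from a waveform
#'
#' `U(t) = Q(t) / A` in SI units (ml/s over mm^2 gives m/s directly).
#' Under square-law scaling the plug velocity is independent of the inlet
#' area: scaling Q by `(D/D_ref)^2` and dividing by the matching area
#' cancels exactly.
#' @param wave a [waveform].
#' @param inlet_area inlet cross-sectional area (mm^2).
#' @return list with `times` (s) and `u` (m/s).
#' @export
plug_velocity <- function(wave, inlet_area) {
  .assert(is.numeric(inlet_area) && inlet_area > 0,
          "aneumorph_domain_error", "inlet area must be positive")
  list(times = wave$times, u = wave$q / inlet_area)
}
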