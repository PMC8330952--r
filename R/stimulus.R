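## Spatiotemporal extracellular cAMP fields. Protocols are piecewise-constant
## in time (each segment holds one static field), which keeps the NSM sampler
## exact: propensities that read the field are refreshed only at segment
## changepoints. Fields are evaluated at node coordinates; extracellular
## diffusion of the ligand is not simulated.

#' Create a stimulus protocol
#'
#' @param segments list of segments, each
#'   `list(t_start=, t_end=, field=)` with a field from [uniform_field()],
#'   [gaussian_field()] or [sum_field()]. Segments must be time-ordered and
#'   non-overlapping; gaps mean zero cAMP.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(segments) {
  t0 <- vapply(segments, `[[`, 0, "t_start")
  t1 <- vapply(segments, `[[`, 0, "t_end")
  if (any(t1 <= t0)) stop("segment with t_end <= t_start")
  o <- order(t0)
  t0 <- t0[o]; t1 <- t1[o]; segments <- segments[o]
  if (any(t0[-1] < t1[-length(t1)] - 1e-12))
    stop("overlapping stimulus segments")
  structure(list(segments = segments), class = "stimulus_protocol")
}

#' Spatially uniform cAMP field
#' @param dose concentration, uM (`>= 0`).
#' @export
uniform_field <- function(dose) {
  if (dose < 0) stop("doses must be >= 0")
  structure(list(kind = "uniform", dose = dose), class = "camp_field")
}

#' Stationary 3D Gaussian micropipette field
#'
#' Emulates chemoattractant released from a needle: concentration
#' `amplitude * exp(-sum((x - center)^2 / (2 widths^2)))`, with the centre
#' conventionally an edge point on the basal rim.
#'
#' @param center 3D point (um).
#' @param amplitude peak concentration, uM.
#' @param widths Gaussian sigma per axis (um), recycled to length 3.
#' @export
gaussian_field <- function(center, amplitude, widths) {
  if (amplitude < 0) stop("doses must be >= 0")
  widths <- rep_len(widths, 3)
  structure(list(kind = "gaussian", center = center,
                 amplitude = amplitude, widths = widths),
            class = "camp_field")
}

#' Sum of cAMP fields
#' @param ... `camp_field` objects.
#' @export
sum_field <- function(...) {
  structure(list(kind = "sum", fields = list(...)), class = "camp_field")
}

eval_field <- function(field, coords) {
  switch(field$kind,
    uniform = rep(field$dose, nrow(coords)),
    gaussian = {
      d2 <- sweep(coords, 2, field$center)^2
      field$amplitude *
        exp(-rowSums(sweep(d2, 2, 2 * field$widths^2, "/")))
    },
    sum = Reduce(`+`, lapply(field$fields, eval_field, coords = coords)),
    stop("unknown field kind"))
}

#' Evaluate a protocol at node coordinates and a time
#'
#' Deterministic and side-effect free; returns the cAMP concentration (uM)
#' at each node.
#'
#' @param protocol a [stimulus_protocol()] (or `NULL` for no stimulus).
#' @param coords n x 3 matrix of node coordinates.
#' @param t time, seconds.
#' @export
camp_at <- function(protocol, coords, t) {
  if (is.null(protocol)) return(numeric(nrow(coords)))
  for (seg in protocol$segments)
    if (t >= seg$t_start - 1e-12 && t < seg$t_end - 1e-12)
      return(eval_field(seg$field, coords))
  numeric(nrow(coords))
}

## Flatten a protocol into changepoint starts + per-segment node
## concentration vectors for the engine (zero-filled gaps).
protocol_segments <- function(protocol, coords, t_end) {
  if (is.null(protocol))
    return(list(start = 0, conc = list(numeric(0))))
  start <- 0; conc <- list(numeric(0))  # empty vector = zero field
  for (seg in protocol$segments) {
    if (seg$t_start >= t_end) break
    f <- eval_field(seg$field, coords)
    if (seg$t_start <= utils::tail(start, 1) + 1e-12) {
      conc[[length(conc)]] <- f
    } else {
      start <- c(start, seg$t_start)
      conc <- c(conc, list(f))
    }
    if (seg$t_end < t_end) {
      start <- c(start, seg$t_end)
      conc <- c(conc, list(numeric(0)))
    }
  }
  list(start = start, conc = conc)
}

#' Uniform step protocol
#' @param dose concentration (uM) from `t_on` to `t_off`.
#' @param t_on,t_off step window, seconds.
#' @export
make_step_protocol <- function(dose, t_on = 0, t_off = Inf) {
  stimulus_protocol(list(list(t_start = t_on, t_end = t_off,
                              field = uniform_field(dose))))
}

#' Staircase of uniform doses
#' @param doses concentrations (uM) per stage.
#' @param times stage boundaries: `length(doses) + 1` increasing times.
#' @export
make_staircase_protocol <- function(doses, times) {
  stopifnot(length(times) == length(doses) + 1)
  segs <- lapply(seq_along(doses), function(i)
    list(t_start = times[i], t_end = times[i + 1],
         field = uniform_field(doses[i])))
  stimulus_protocol(segs)
}

#' Train of uniform pulses
#'
#' Delays are offset-to-onset: the gap between the end of one pulse and the
#' start of the next.
#'
#' @param duration_s pulse duration, seconds (> 0).
#' @param dose pulse concentration, uM.
#' @param n_pulses number of pulses.
#' @param delay_s gap between consecutive pulses, seconds (> 0 when
#'   `n_pulses > 1`).
#' @param t_start onset of the first pulse.
#' @export
make_pulse_protocol <- function(duration_s, dose, n_pulses = 1,
                                delay_s = NULL, t_start = 0) {
  if (duration_s <= 0) stop("duration must be > 0")
  if (n_pulses > 1 && (is.null(delay_s) || delay_s <= 0))
    stop("delay must be > 0")
  gap <- if (is.null(delay_s)) 0 else delay_s
  segs <- lapply(seq_len(n_pulses), function(i) {
    on <- t_start + (i - 1) * (duration_s + gap)
    list(t_start = on, t_end = on + duration_s,
         field = uniform_field(dose))
  })
  stimulus_protocol(segs)
}

#' Calibrate a micropipette gradient to front/back receptor occupancy
#'
#' Chooses the amplitude and width of a basal-rim Gaussian field such that
#' the steady-state receptor occupancy at the cell front (node nearest the
#' needle) and back (antipodal basal point) hit the requested percentages.
#' The inversion uses the mean-field dose-response map of the receptor
#' module ([dose_response()]); front/back targets are solved from the
#' two-parameter Gaussian along the basal diameter.
#'
#' @param front_target_RO,back_target_RO percentages, `0 <= back < front <= 100`.
#' @param mesh a `shell_mesh`.
#' @param params GPCR parameters for the dose-response inversion.
#' @param needle optional needle location; default: basal rim point on +x.
#' @return a `camp_field` (Gaussian, or uniform saturating field when
#'   `front == back == 100`).
#' @export
calibrate_gradient <- function(front_target_RO, back_target_RO, mesh,
                               params = gpcr_params(), needle = NULL) {
  if (!(back_target_RO <= front_target_RO && front_target_RO <= 100 &&
        back_target_RO >= 0))
    stop("need 0 <= back <= front <= 100 % R.O.")
  R <- mesh$spec$radius
  if (is.null(needle)) needle <- c(R, 0, 0)
  if (front_target_RO == back_target_RO) {
    return(uniform_field(saturating_dose(params)))
  }
  dr <- dose_response_map(params)
  c_front <- dr$inverse(front_target_RO)
  c_back <- dr$inverse(back_target_RO)
  if (!is.finite(c_front) || !is.finite(c_back))
    stop("infeasible receptor-occupancy targets")
  ## Gaussian along the basal diameter: front at distance ~0 (the rim point
  ## nearest the needle), back at distance 2R.
  d_front <- 0; d_back <- 2 * R
  sigma <- sqrt((d_back^2 - d_front^2) / (2 * log(c_front / c_back)))
  amplitude <- c_front * exp(d_front^2 / (2 * sigma^2))
  gaussian_field(center = needle, amplitude = amplitude,
                 widths = rep(sigma, 3))
}
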