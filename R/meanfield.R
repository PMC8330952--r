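## Deterministic mean-field (large-copy-number) oracle. The reaction-rate
## equations are solved compartmentally: each species is well mixed over the
## volume of its localization class (membrane or whole shell), and each
## reaction fires in its locale's volume, so fluxes between classes carry
## the volume ratio. Used for half-times, dose-response curves, parameter
## calibration, and high-copy validation of the stochastic engine.

#' Compartment volumes of a mesh
#' @param mesh a `shell_mesh` or `voxel_graph`.
#' @return named vector: membrane and total volume (um^3).
#' @export
compartment_volumes <- function(mesh) {
  v <- mesh$nodal_volumes
  c(membrane = sum(v[nodes_of(mesh, "membrane")]), all = sum(v))
}

## Default compartment volumes of the full-scale cell (mesh-free use).
default_volumes <- function() c(membrane = 22.2, all = 44.4)

#' Mean-field ODE simulation
#'
#' @param model an [rd_model()].
#' @param init named vector of initial *total molecule counts* (as for
#'   [simulate_nsm()]); concentrations are derived from the compartment
#'   volumes.
#' @param t_end end time (s).
#' @param volumes named vector `c(membrane=, all=)` in um^3, or a mesh to
#'   take them from.
#' @param stimulus optional [stimulus_protocol()]; uniform fields only
#'   (the well-mixed model has no spatial axis).
#' @param dt output time step (s).
#' @param times explicit output times (overrides `dt`).
#' @param ... passed to [deSolve::ode()].
#' @return matrix of class `meanfield_trajectory`: column `time` plus one
#'   concentration column (uM, over the species' own compartment) per
#'   species; attribute `volumes` holds the compartment volumes.
#' @export
simulate_meanfield <- function(model, init, t_end, volumes = default_volumes(),
                               stimulus = NULL, dt = 0.1, times = NULL, ...) {
  if (inherits(volumes, c("shell_mesh", "voxel_graph")))
    volumes <- compartment_volumes(volumes)
  nm <- model$species_names
  loc <- vapply(model$species, `[[`, "", "localization")
  Vsp <- unname(volumes[ifelse(loc == "membrane", "membrane", "all")])
  y0 <- numeric(length(nm)); names(y0) <- nm
  y0[names(init)] <- init / (MOLEC_PER_UM3_UM * Vsp[match(names(init), nm)])

  rx <- model$reactions
  Vrx <- unname(volumes[ifelse(vapply(rx, `[[`, "", "locale") == "membrane",
                               "membrane", "all")])
  ro <- model$rr_readout
  camp_of <- function(t) {
    if (is.null(stimulus)) return(0)
    f <- camp_at(stimulus, matrix(0, 1, 3), t)
    f[1]
  }

  rhs <- function(t, y, parms) {
    camp <- camp_of(t)
    dy <- numeric(length(y))
    for (j in seq_along(rx)) {
      r <- rx[[j]]
      c1 <- if (length(r$reactants) >= 1) y[[r$reactants[1]]] else NA
      c2 <- if (length(r$reactants) >= 2) y[[r$reactants[2]]] else NA
      flux <- switch(r$type,
        zeroth = r$k,
        first = r$k * c1,
        second = r$k * c1 * c2,
        second_self = r$k * c1^2,
        pool_second = {
          pool_c <- r$pool_total / (MOLEC_PER_UM3_UM * Vrx[j])
          r$k * max(0, pool_c - c1) * c2
        },
        ## saturated (zero-order in the gated species) degradation; the soft
        ## gate keeps the mean-field RHS smooth near depletion
        cat_gated = r$k * c1 * c2 / (c2 + 1e-4),
        sten_r3 = {
          rr <- if (is.null(ro)) y[["RR"]] else {
            g <- y[[ro$g]]; i <- y[[ro$i]]
            if (ro$mode == "difference")
              max(0, ro$par[1] + ro$par[2] * (g - ro$par[3] * i))
            else ro$par[1] * (ro$par[2] + g) / (ro$par[3] + i)
          }
          (r$a30 + r$a3 * rr) / (r$a4^2 * c2^2 + 1) * c1
        })
      if (r$camp) flux <- flux * camp
      if (flux == 0) next
      sp <- match(names(r$stoich), nm)
      dy[sp] <- dy[sp] + r$stoich * flux * Vrx[j] / Vsp[sp]
    }
    list(dy)
  }

  if (is.null(times)) times <- seq(0, t_end, by = dt)
  ## restart integration at stimulus changepoints (discontinuous forcing)
  cps <- if (is.null(stimulus)) numeric(0) else
    sort(unique(unlist(lapply(stimulus$segments, function(s)
      c(s$t_start, s$t_end)))))
  cps <- cps[cps > min(times) & cps < max(times) & is.finite(cps)]
  bounds <- sort(unique(c(min(times), cps, max(times))))
  out <- NULL; y <- y0
  for (b in seq_len(length(bounds) - 1L)) {
    tt <- sort(unique(c(bounds[b],
                        times[times >= bounds[b] & times <= bounds[b + 1]],
                        bounds[b + 1])))
    ## evaluate the field just inside the interval
    seg <- deSolve::ode(y, tt, rhs, parms = NULL, ...)
    y <- seg[nrow(seg), -1]
    keep <- seg[, 1] %in% times
    if (!is.null(out)) keep[1] <- FALSE  # avoid duplicated boundary row
    out <- rbind(out, seg[keep, , drop = FALSE])
  }
  colnames(out) <- c("time", nm)
  if (any(!is.finite(out)))
    stop("stiff-solver failure: non-finite mean-field solution; ",
         "try smaller rtol/atol or a different method")
  structure(out, volumes = volumes, class = c("meanfield_trajectory",
                                              "matrix"))
}

#' Pooled concentration trace from a mean-field trajectory
#' @param mf result of [simulate_meanfield()].
#' @param species species name(s); summed.
#' @export
mf_trace <- function(mf, species) {
  rowSums(mf[, species, drop = FALSE])
}

#' Half-time of a monotone trace
#'
#' Linear interpolation of the time at which a trace crosses the midpoint
#' between its initial and final plateau values. For `direction = "rise"`
#' the trace is expected to increase toward the final plateau, for
#' `"decay"` to decrease; the monotone trend is enforced by using the
#' first crossing of the midpoint.
#'
#' @param time,value the trace.
#' @param direction `"rise"` or `"decay"` (default: inferred from the
#'   endpoint values).
#' @param from,to override the plateau values.
#' @return time from `time[1]` to the midpoint crossing (s).
#' @export
half_time <- function(time, value, direction = NULL, from = NULL, to = NULL) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (is.null(from)) from <- value[1]
  if (is.null(to)) to <- value[length(value)]
  if (is.null(direction)) direction <- if (to >= from) "rise" else "decay"
  mid <- (from + to) / 2
  cross <- if (direction == "rise") which(value >= mid) else which(value <= mid)
  cross <- cross[cross > 1][1]
  if (is.na(cross)) return(NA_real_)
  i <- cross
  t0 <- time[i - 1]; t1 <- time[i]
  v0 <- value[i - 1]; v1 <- value[i]
  if (v1 == v0) return(t1 - time[1])
  t0 + (mid - v0) / (v1 - v0) * (t1 - t0) - time[1]
}
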