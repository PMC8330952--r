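## Gillespie direct-method sampler on the flattened model (diffusion hops
## expanded into ordinary first-order channels). Statistically exact for the
## same master equation as the NSM engine; written independently of it in
## plain R and used only for cross-validation on small fixtures.

#' Direct-method stochastic simulation (oracle)
#'
#' @inheritParams simulate_nsm
#' @param record snapshot times (`list(times = ...)` or `list(dt = ...)`).
#' @return an `rd_trajectory` (without per-node recording; `final` holds the
#'   end state).
#' @export
simulate_direct_ssa <- function(model, mesh, init, t_end, seed = 1L,
                                stimulus = NULL, record = list(dt = 0.5),
                                t0 = 0) {
  prep <- nsm_prepare(model, mesh, stimulus, t_end)
  x <- init_counts(model, mesh, init)
  storage.mode(x) <- "double"
  nm <- prep$species_names
  S <- nrow(x); N <- ncol(x)
  uV <- prep$uV

  ## flatten diffusion into (species, from, to, rate) channels
  dif <- list()
  for (s in seq_len(S)) {
    D <- prep$sp_D[s]
    if (D <= 0) next
    g <- prep$graphs[[prep$sp_graph[s] + 1L]]
    ii <- rep.int(seq_len(N), diff(g$ptr))
    if (length(ii))
      dif[[length(dif) + 1L]] <- data.frame(s = s, from = ii,
                                            to = g$idx + 1L,
                                            rate = D * g$w)
  }
  dif <- if (length(dif)) do.call(rbind, dif) else
    data.frame(s = integer(0), from = integer(0), to = integer(0),
               rate = numeric(0))

  seg_start <- prep$stim$start
  seg_conc <- prep$stim$conc
  camp_of <- function(t) {
    if (is.null(seg_start)) return(numeric(N))
    k <- findInterval(t + 1e-12, seg_start)
    if (k < 1 || length(seg_conc[[k]]) == 0) numeric(N) else seg_conc[[k]]
  }

  rr_conc <- function(v) {
    rr <- prep$rr
    if (is.null(rr)) return(0)
    if (rr$mode == 0L) return(uV[v] * x[rr$sp + 1L, v])
    g <- uV[v] * x[rr$g + 1L, v]; i <- uV[v] * x[rr$i + 1L, v]
    if (rr$mode == 1L) max(0, rr$par[1] + rr$par[2] * (g - rr$par[3] * i))
    else rr$par[1] * (rr$par[2] + g) / (rr$par[3] + i)
  }

  rxn_prop <- function(camp) {
    vapply(seq_along(prep$reactions), function(j) {
      r <- prep$reactions[[j]]
      vapply(seq_len(N), function(v) {
        k <- r$rate[v]
        if (k == 0) return(0)
        if (r$camp == 1L) k <- k * camp[v]
        switch(r$type + 1L,
               k,                                     # zeroth
               k * x[r$s1 + 1L, v],                   # first
               k * x[r$s1 + 1L, v] * x[r$s2 + 1L, v], # second
               k * x[r$s1 + 1L, v] * (x[r$s1 + 1L, v] - 1),
               k * max(0, r$pool[v] - x[r$s1 + 1L, v]) * x[r$s2 + 1L, v],
               {                                      # sten_r3
                 p2 <- x[r$pip2 + 1L, v]
                 (r$a30 + r$a3 * rr_conc(v)) /
                   (r$a4^2 * uV[v]^2 * p2 * (p2 - 1) + 1) * x[r$s1 + 1L, v]
               },
               if (x[r$s2 + 1L, v] >= 1) k * x[r$s1 + 1L, v] else 0)
      }, 0)
    }, numeric(N))
  }

  times <- record$times
  if (is.null(times)) times <- seq(t0, t_end,
                                   by = if (is.null(record$dt)) 0.5
                                        else record$dt)
  wc <- matrix(0, S, length(times), dimnames = list(nm, NULL))
  next_rec <- 1L
  set.seed(as.integer(seed) %% .Machine$integer.max)
  t <- t0
  n_events <- 0
  repeat {
    camp <- camp_of(t)
    ap_r <- rxn_prop(camp)                      # N x R
    ap_d <- if (nrow(dif)) dif$rate * x[cbind(dif$s, dif$from)] else numeric(0)
    a0 <- sum(ap_r) + sum(ap_d)
    ## next stimulus changepoint bounds the validity of the propensities
    t_next_cp <- if (is.null(seg_start)) Inf else {
      nxt <- seg_start[seg_start > t + 1e-12]
      if (length(nxt)) nxt[1] else Inf
    }
    tau <- if (a0 > 0) stats::rexp(1, a0) else Inf
    t_event <- t + tau
    t_cap <- min(t_next_cp, t_end)
    while (next_rec <= length(times) &&
           times[next_rec] <= min(t_event, t_cap) + 1e-12) {
      wc[, next_rec] <- rowSums(x); next_rec <- next_rec + 1L
    }
    if (t_event > t_cap) {
      if (t_cap >= t_end) break
      t <- t_cap
      next
    }
    t <- t_event
    n_events <- n_events + 1
    u <- stats::runif(1) * a0
    if (u <= sum(ap_r)) {
      k <- which(cumsum(as.numeric(ap_r)) >= u - 1e-15)[1]
      v <- (k - 1) %% N + 1
      j <- (k - 1) %/% N + 1
      r <- prep$reactions[[j]]
      sp <- r$st_sp + 1L
      x[sp, v] <- x[sp, v] + r$st_dl
      if (any(x[sp, v] < 0)) stop("internal consistency error: negative count")
    } else {
      u <- u - sum(ap_r)
      k <- which(cumsum(ap_d) >= u - 1e-15)[1]
      x[dif$s[k], dif$from[k]] <- x[dif$s[k], dif$from[k]] - 1
      x[dif$s[k], dif$to[k]] <- x[dif$s[k], dif$to[k]] + 1
      if (x[dif$s[k], dif$from[k]] < 0)
        stop("internal consistency error: negative count")
    }
  }
  storage.mode(x) <- "integer"
  structure(list(times = times, wc = wc, node = NULL, final = x,
                 n_events = n_events, species = nm,
                 volumes = prep$volumes, seed = seed),
            class = "rd_trajectory")
}
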