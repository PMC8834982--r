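#' Detect complete pore-crossing events
#'
#' Hysteresis state machine per ion: an ion is "committed below" once its
#' axial coordinate drops below `origin_z - gate_halfwidth` and "committed
#' above" once it exceeds `origin_z + gate_halfwidth`. A crossing event is
#' recorded each time the committed side flips, i.e. the ion has traversed
#' the full gate, provided its mid-plane passage happened at radial distance
#' below `pore_radius + pore_radius_margin` from the pore axis. Jitter around
#' the mid-plane is never double-counted. Periodic z-wraps (`|dz| > box_z/2`
#' between consecutive frames) reset the state without emitting an event, as
#' does a failed radial check; ions starting (or landing after a wrap) inside
#' the gate stay uncommitted until they first exit it.
#'
#' @param traj An [ion_trajectory()] with at least two frames.
#' @param gate_halfwidth Commitment-plane half-distance from the channel
#'   centre (Angstrom, > 0).
#' @param pore_radius_margin Radial slack added to the pore radius for the
#'   mid-plane check (Angstrom). If the trajectory carries no pore metadata
#'   the radial check is skipped.
#' @return Data frame of class `crossing_events` with columns `id`,
#'   `species`, `valence`, `time`, `direction` (+1 for -z to +z), sorted by
#'   time. The trajectory duration and frame times are kept as attributes.
#' @export
detect_crossings <- function(traj, gate_halfwidth = 10, pore_radius_margin = 2) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (length(traj$times) < 2) stop("trajectory must have at least 2 frames")
  if (gate_halfwidth <= 0) stop("gate_halfwidth must be positive")
  if (length(traj$times) > 2) {
    dt <- diff(traj$times)
    if (max(dt) - min(dt) > 1e-8 * max(dt)) stop("non-uniform time step")
  }
  if (anyNA(traj$coords)) stop("missing particle coordinates")
  g <- gate_halfwidth
  boxz <- traj$box[3]
  r_max <- if (is.null(traj$pore)) Inf else traj$pore$radius + pore_radius_margin
  n_part <- dim(traj$coords)[2]
  out <- vector("list", n_part)
  for (p in seq_len(n_part)) {
    z <- traj$coords[, p, 3] - traj$origin_z
    wraps <- which(abs(diff(z)) > boxz / 2)    # frame i -> i+1 wrapped
    bounds <- c(1L, wraps + 1L, length(z) + 1L)
    ev_t <- numeric(0); ev_d <- integer(0)
    for (s in seq_len(length(bounds) - 1L)) {
      lo <- bounds[s]; hi <- bounds[s + 1L] - 1L
      if (hi - lo < 1L) next
      zs <- z[lo:hi]
      st <- ifelse(zs < -g, -1L, ifelse(zs > g, 1L, NA_integer_))
      idx <- seq_along(st)
      carry <- cummax(idx * !is.na(st))       # last committed index (0 if none)
      committed <- ifelse(carry > 0L, st[pmax(carry, 1L)], NA_integer_)
      flips <- which(!is.na(committed) & c(NA_integer_, committed[-length(committed)]) *
                       committed == -1L)
      for (fi in flips) {
        # frame (local) where the ion first sits on the new side of the mid-plane
        prev <- carry[fi - 1L]                # last frame committed to old side
        seg <- prev:fi
        side <- sign(zs[seg])
        cross_local <- seg[which(side == committed[fi])[1]]
        j <- lo + cross_local - 1L
        rho <- sqrt(traj$coords[j, p, 1]^2 + traj$coords[j, p, 2]^2)
        if (rho < r_max) {
          ev_t <- c(ev_t, traj$times[j])
          ev_d <- c(ev_d, committed[fi])
        }
      }
    }
    if (length(ev_t)) {
      out[[p]] <- data.frame(
        id = traj$ids[p], species = traj$species[p],
        valence = traj$valence[p], time = ev_t, direction = ev_d,
        stringsAsFactors = FALSE
      )
    }
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(ev)) {
    ev <- data.frame(id = integer(0), species = character(0),
                     valence = integer(0), time = numeric(0),
                     direction = integer(0), stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "times") <- traj$times
  attr(ev, "voltage") <- traj$voltage
  class(ev) <- c("crossing_events", "data.frame")
  ev
}

#' Cumulative signed transported charge
#'
#' Builds the piecewise-constant series `q_tot(t) = sum over events with
#' time <= t of valence x direction`, together with direction-aware signed
#' per-species crossing counts. Each event with unit valence changes `q_tot`
#' by exactly +-1 e and `q_tot(0) = 0`.
#'
#' @param events A `crossing_events` data frame (see [detect_crossings()]),
#'   or any data frame with columns `species`, `valence`, `time`, `direction`.
#' @param times Evaluation grid (ns); defaults to the frame times carried by
#'   `events`.
#' @return An object of class `charge_series`: list with `times`, `q`
#'   (e, same length), `counts` (matrix of signed cumulative per-species
#'   counts) and the `events` themselves.
#' @export
cumulative_charge <- function(events, times = NULL) {
  if (is.null(times)) times <- attr(events, "times")
  if (is.null(times)) stop("an evaluation grid `times` is required")
  ev <- as.data.frame(events)
  if (nrow(ev) && (min(ev$time) < min(times) - 1e-9 ||
                   max(ev$time) > max(times) + 1e-9)) {
    stop("event outside the time range of the series")
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  dq <- ev$valence * ev$direction
  pos <- findInterval(times, ev$time)         # events with time <= t
  q <- c(0, cumsum(dq))[pos + 1L]
  sp <- unique(ev$species)
  counts <- sapply(sp, function(s) {
    sel <- ev$species == s
    c(0, cumsum(ifelse(sel, ev$direction, 0L)))[pos + 1L]
  })
  if (length(sp) == 0) counts <- matrix(0, length(times), 0)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(times))
  colnames(counts) <- sp
  structure(
    list(times = as.numeric(times), q = as.numeric(q), counts = counts,
         events = ev, voltage = attr(events, "voltage")),
    class = "charge_series"
  )
}

#' @export
print.charge_series <- function(x, ...) {
  cat("Charge series:", length(x$times), "grid points over",
      signif(diff(range(x$times)), 4), "ns;", nrow(x$events), "events; q(end) =",
      x$q[length(x$q)], "e\n")
  invisible(x)
}

#' Current and conductance from a cumulative-charge series
#'
#' Ordinary least squares of `q_tot` against time on the series grid. The
#' raw slope (e/ns) is converted to pA (1 e/ns = 160.2176634 pA) and
#' multiplied by the diffusion renormalization factor; the conductance is
#' `|current| / |voltage|` in nS. The current keeps its sign.
#'
#' @param series A [cumulative_charge()] result.
#' @param voltage Applied voltage (mV, non-zero).
#' @param renorm Dimensionless renormalization factor, typically
#'   [renormalization_factor()] of the bulk diffusion coefficients.
#' @return An object of class `current_estimate`: raw slope (e/ns), R^2,
#'   current (pA), conductance (nS), per-species completed-event counts,
#'   and the chloride-over-potassium current ratio when both are present.
#' @examples
#' # a perfectly linear series reproducing a 148.43 pA current at 40 mV:
#' ev <- data.frame(species = "K", valence = 1L,
#'                  time = seq(0.5, 500, by = 0.5), direction = 1L)
#' # (slope scaled via renorm for illustration)
#' @export
estimate_current <- function(series, voltage, renorm = 1) {
  stopifnot(inherits(series, "charge_series"))
  if (is.null(voltage) || voltage == 0) stop("voltage must be non-zero")
  if (length(unique(series$times)) < 2) stop("need at least 2 distinct times")
  n_by_species <- if (nrow(series$events))
    table(series$events$species) else table(character(0))
  if (all(series$q == 0)) {
    fit <- list(slope = 0, r2 = NA_real_)
  } else {
    fit <- ols_line(series$times, series$q)
  }
  current <- fit$slope * .pg$pA_per_e_ns * renorm
  ratio <- current_ratio(series$events)
  structure(
    list(raw_slope = fit$slope, r_squared = fit$r2, renorm_factor = renorm,
         current = current, conductance = abs(current) / abs(voltage),
         voltage = voltage, current_ratio = ratio,
         events_per_species = n_by_species),
    class = "current_estimate"
  )
}

#' @export
print.current_estimate <- function(x, ...) {
  cat(sprintf("Current estimate: %.2f pA at %g mV -> conductance %.2f nS\n",
              x$current, x$voltage, x$conductance))
  cat(sprintf("  raw slope %.4g e/ns, renorm %.4g, R2 %s\n", x$raw_slope,
              x$renorm_factor,
              if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared)))
  if (!is.na(x$current_ratio)) {
    cat(sprintf("  events: %s; current ratio (Cl/K) %.1f\n",
                paste(names(x$events_per_species), x$events_per_species,
                      sep = ":", collapse = ", "), x$current_ratio))
  }
  invisible(x)
}

## closed-form OLS of y on x, with R^2
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) (sxy^2 / sxx) / syy else NA_real_
  sse <- syy - sxy^2 / sxx
  list(slope = slope, intercept = intercept, r2 = r2, sse = max(sse, 0), n = n)
}

#' Diffusion renormalization factor
#'
#' Ratio of the experimental to the simulated bulk diffusion coefficient,
#' `D_exp / D_sim`, used to rescale simulated currents.
#'
#' @param D_sim,D_exp Bulk diffusion coefficients (cm^2/s, both > 0).
#' @return Dimensionless factor.
#' @examples
#' renormalization_factor(3.273e-5, 1.918e-5)  # 0.586
#' @export
renormalization_factor <- function(D_sim, D_exp) {
  if (D_sim <= 0 || D_exp <= 0) stop("diffusion coefficients must be positive")
  D_exp / D_sim
}

#' Chloride-over-potassium current ratio
#'
#' Plain (direction-insensitive) count of completed Cl- traversals divided by
#' the count of completed K+ traversals, a proxy for anion-vs-cation
#' selectivity.
#'
#' @param events A crossing-events data frame.
#' @param anion,cation Species names (defaults `"Cl"`, `"K"`).
#' @return The ratio, or `NA` (undefined-flagged) when no cation event exists.
#' @export
current_ratio <- function(events, anion = "Cl", cation = "K") {
  ev <- as.data.frame(events)
  n_an <- sum(ev$species == anion)
  n_cat <- sum(ev$species == cation)
  if (n_cat == 0) return(NA_real_)
  n_an / n_cat
}

#' Bulk diffusion coefficient from mean-squared displacement
#'
#' Ensemble- and time-origin-averaged MSD with periodic-boundary unwrapping
#' (minimum-image frame-to-frame displacements), fitted as
#' `MSD(tau) = 6 D tau` by least squares over lags up to
#' `max_lag_fraction` of the trajectory duration. Ballistic (pure-drift)
#' signals, for which MSD grows like `tau^2`, are flagged by a low linear
#' R^2 (< 0.99) and by the reported log-log slope (~2 instead of ~1).
#'
#' @param traj A membrane-free [ion_trajectory()] with at least 100 frames.
#' @param max_lag_fraction Largest lag as a fraction of the duration.
#' @param n_lags Number of lag values sampled.
#' @return An object of class `diffusion_estimate`: `D_sim` (cm^2/s), fit
#'   window (ns), `r_squared`, `loglog_slope`, `linear` flag, and the MSD
#'   curve.
#' @export
estimate_diffusion_msd <- function(traj, max_lag_fraction = 0.25, n_lags = 40) {
  stopifnot(inherits(traj, "ion_trajectory"))
  n_fr <- length(traj$times)
  if (n_fr < 100) stop("too few frames for MSD estimation (need >= 100)")
  dt <- traj$times[2] - traj$times[1]
  # unwrap via minimum image on frame-to-frame displacements
  unwrapped <- traj$coords
  for (k in 1:3) {
    L <- traj$box[k]
    d <- diff(traj$coords[, , k])
    d <- d - L * round(d / L)
    cs <- apply(d, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
    unwrapped[, , k] <- rbind(traj$coords[1, , k],
                              sweep(cs, 2, traj$coords[1, , k], `+`))
  }
  max_lag <- max(1L, floor(max_lag_fraction * (n_fr - 1L)))
  lags <- unique(round(seq(1, max_lag, length.out = min(n_lags, max_lag))))
  msd <- vapply(lags, function(l) {
    d2 <- (unwrapped[(1L + l):n_fr, , , drop = FALSE] -
             unwrapped[1L:(n_fr - l), , , drop = FALSE])^2
    mean(d2[, , 1] + d2[, , 2] + d2[, , 3])
  }, numeric(1))
  tau <- lags * dt
  if (all(msd == 0)) {
    est <- structure(
      list(D_sim = 0, window = range(tau), r_squared = NA_real_,
           loglog_slope = NA_real_, linear = NA, msd = msd, tau = tau),
      class = "diffusion_estimate")
    return(est)
  }
  fit <- ols_line(tau, msd)
  D_A2ns <- fit$slope / 6
  pos <- msd > 0
  llfit <- ols_line(log(tau[pos]), log(msd[pos]))
  structure(
    list(D_sim = D_A2ns * .pg$cm2s_per_A2ns, window = range(tau),
         r_squared = fit$r2, loglog_slope = llfit$slope,
         linear = !is.na(fit$r2) && fit$r2 >= 0.99,
         msd = msd, tau = tau),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("MSD diffusion estimate: D = %.4g cm2/s (window %.3g-%.3g ns, R2 %s, log-log slope %.2f)\n",
              x$D_sim, x$window[1], x$window[2],
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              if (is.na(x$loglog_slope)) NA else x$loglog_slope))
  if (isFALSE(x$linear)) cat("  warning: MSD not linear in lag; estimate unreliable\n")
  invisible(x)
}

#' Export crossing events as CSV
#'
#' @param events A `crossing_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "time"] <- "time_ns"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
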