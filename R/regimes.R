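#' Fit conducting regimes to a cumulative-charge series
#'
#' The central model of the package: the transported-charge series
#' `q_tot(t)` is modelled either by a single straight line (one conducting
#' regime) or by two independent line segments separated by a bifurcation
#' time (an abrupt switch between a low- and a high-conducting regime). The
#' change point is located by exhaustive grid search minimizing the total
#' residual sum of squares of the two segments (continuity is not enforced),
#' and the two-segment model is retained only if it improves a BIC computed
#' on the per-step increments of the series — the increments of a counting
#' series are exchangeable under both models, whereas level residuals are
#' strongly autocorrelated.
#'
#' @param series A [cumulative_charge()] result.
#' @param voltage Applied voltage (mV); used to express segment slopes as
#'   conductances. Defaults to the voltage recorded on the series.
#' @param renorm Diffusion renormalization factor (see
#'   [renormalization_factor()]).
#' @param min_segment Minimal segment length (ns) on either side of a
#'   candidate bifurcation time.
#' @param criterion Model-selection rule passed to [select_model()].
#' @return An object of class `regime_fit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods. Fields: `model`
#'   (`"single"` or `"two-segment"`), `segments` (one row per segment with
#'   slope, intercept, conductance, R^2, event counts and current ratio),
#'   `bifurcation_time`, `selection_score`, `sse`.
#' @examples
#' ev <- data.frame(species = "Cl", valence = -1L,
#'                  time = sort(runif(200, 0, 100)), direction = 1L)
#' qs <- cumulative_charge(ev, times = seq(0, 100, by = 0.1))
#' fit <- regime_fit(qs, voltage = 40)
#' fit
#' @export
regime_fit <- function(series, voltage = NULL, renorm = 1,
                       min_segment = NULL, criterion = "bic_increments") {
  single <- fit_single(series, voltage = voltage, renorm = renorm)
  duration <- diff(range(series$times))
  if (is.null(min_segment)) min_segment <- duration / 10
  if (duration >= 2 * min_segment &&
      sum(series$times >= min(series$times) + min_segment &
          series$times <= max(series$times) - min_segment) >= 2) {
    two <- fit_changepoint(series, min_segment, voltage = voltage, renorm = renorm)
    select_model(single, two, criterion = criterion)
  } else {
    single
  }
}

#' Synthetic piecewise-linear charge series
#'
#' Generates a cumulative-charge series with one or two slope regimes and
#' Gaussian step noise on the increments (a random walk around the trend,
#' the natural null/alternative model for a counting series). Used as the
#' ground-truth fixture for change-point recovery and model-selection
#' calibration.
#'
#' @param slopes Numeric vector of one or two slopes (e/ns).
#' @param change_at Change-point time (ns); ignored for a single slope.
#' @param duration Total duration (ns).
#' @param dt Grid step (ns).
#' @param noise_sd Noise standard deviation (e) per grid step.
#' @param noise `"level"` adds independent Gaussian jitter to each grid
#'   value of the piecewise-linear trend; `"step"` adds the jitter to the
#'   per-step increments, producing a random walk around the trend.
#' @param seed Integer RNG seed.
#' @param voltage Voltage annotation carried on the series (mV).
#' @return A `charge_series` (with an empty event table).
#' @export
synthetic_charge_series <- function(slopes, change_at = NULL, duration = 500,
                                    dt = 0.1, noise_sd = 0.5,
                                    noise = c("level", "step"), seed = 1L,
                                    voltage = 40) {
  noise <- match.arg(noise)
  times <- seq(0, duration, by = dt)
  n <- length(times)
  slope_t <- if (length(slopes) == 1) rep(slopes, n - 1) else {
    ifelse(times[-1] <= change_at, slopes[1], slopes[2])
  }
  trend <- c(0, cumsum(slope_t * dt))
  q <- with_seed(seed, {
    if (noise == "level") {
      trend + stats::rnorm(n, sd = noise_sd)
    } else {
      c(0, cumsum(slope_t * dt + stats::rnorm(n - 1, sd = noise_sd)))
    }
  })
  structure(
    list(times = times, q = q,
         counts = matrix(0, n, 0),
         events = data.frame(id = integer(0), species = character(0),
                             valence = integer(0), time = numeric(0),
                             direction = integer(0)),
         voltage = voltage),
    class = "charge_series"
  )
}

#' Single-regime linear fit
#'
#' One ordinary-least-squares segment over the full series.
#'
#' @inheritParams regime_fit
#' @return A `regime_fit` with `model = "single"`.
#' @export
fit_single <- function(series, voltage = NULL, renorm = 1) {
  stopifnot(inherits(series, "charge_series"))
  if (length(series$times) < 10) stop("need at least 10 grid points")
  if (is.null(voltage)) voltage <- series$voltage
  fit <- ols_line(series$times, series$q)
  degenerate <- stats::var(series$q) == 0
  seg <- segment_row(series, min(series$times), max(series$times),
                     fit, voltage, renorm)
  new_regime_fit(model = "single", segments = seg, bifurcation_time = NA_real_,
                 sse = fit$sse, series = series, voltage = voltage,
                 renorm = renorm, degenerate = degenerate)
}

#' Two-segment change-point fit
#'
#' Exhaustive grid search of the bifurcation time minimizing the total SSE
#' of two independent fits, followed by two OLS line segments on the level
#' series for reporting. Two search objectives are available, matched to
#' the noise structure of the series: `"levels"` fits two OLS lines to the
#' level series (optimal when grid values carry independent jitter), while
#' `"increments"` fits two constant means to the per-step increments (the
#' mean-shift maximum-likelihood change point, optimal when the series is a
#' random walk around the trend, as a raw counting series is — there the
#' level residuals have long-range correlations and localize poorly).
#' `"auto"` (default) picks by the lag-1 autocorrelation of the detrended
#' increments: near 0 for a random walk, near -1/2 for level jitter.
#' Candidate change points leave at least `min_segment` of data on each
#' side; ties resolve to the earliest candidate.
#'
#' @inheritParams regime_fit
#' @param min_segment Minimal segment length (ns) on each side.
#' @param objective `"auto"`, `"levels"` or `"increments"`.
#' @return A `regime_fit` with `model = "two-segment"` and the estimated
#'   `bifurcation_time`.
#' @export
fit_changepoint <- function(series, min_segment, voltage = NULL, renorm = 1,
                            objective = c("auto", "levels", "increments")) {
  stopifnot(inherits(series, "charge_series"))
  objective <- match.arg(objective)
  if (is.null(voltage)) voltage <- series$voltage
  t <- series$times; q <- series$q
  n <- length(t)
  duration <- t[n] - t[1]
  if (duration < 2 * min_segment) stop("series shorter than 2 * min_segment")
  d <- diff(q)
  m <- n - 1L
  if (objective == "auto") {
    res <- d - mean(d)
    ac1 <- sum(res[-1] * res[-m]) / sum(res^2)
    objective <- if (is.finite(ac1) && ac1 < -0.25) "levels" else "increments"
  }
  if (objective == "increments") {
    # split after increment k: left = d[1..k] (up to time t[k+1]), right = rest
    cd <- cumsum(d); cdd <- cumsum(d * d)
    k_all <- seq_len(m - 1L)
    sse_left <- cdd[k_all] - cd[k_all]^2 / k_all
    sse_right <- (cdd[m] - cdd[k_all]) - (cd[m] - cd[k_all])^2 / (m - k_all)
    tau_all <- t[k_all + 1L]
    admissible <- tau_all >= t[1] + min_segment & tau_all <= t[n] - min_segment
    if (!any(admissible)) stop("no admissible change point under min_segment")
    total <- ifelse(admissible, sse_left + sse_right, Inf)
    k <- which.min(total) + 1L             # level index of the change point
  } else {
    # zero-padded prefix sums for O(1) two-line level SSE (sum i..j = P[j+1]-P[i])
    c1 <- c(0, cumsum(rep(1, n))); ct <- c(0, cumsum(t)); cq <- c(0, cumsum(q))
    ctt <- c(0, cumsum(t * t)); ctq <- c(0, cumsum(t * q)); cqq <- c(0, cumsum(q * q))
    seg_sse <- function(i, j) {
      mm <- c1[j + 1] - c1[i]
      st <- ct[j + 1] - ct[i]; sq <- cq[j + 1] - cq[i]
      stt <- ctt[j + 1] - ctt[i]; stq <- ctq[j + 1] - ctq[i]
      sqq <- cqq[j + 1] - cqq[i]
      sxx <- stt - st * st / mm
      sxy <- stq - st * sq / mm
      syy <- sqq - sq * sq / mm
      pmax(syy - ifelse(sxx > 0, sxy^2 / sxx, 0), 0)
    }
    cand <- which(t >= t[1] + min_segment & t <= t[n] - min_segment)
    cand <- cand[cand >= 3L & cand <= n - 2L]
    if (!length(cand)) stop("no admissible change point under min_segment")
    total <- seg_sse(1L, cand) + seg_sse(cand + 1L, n)
    k <- cand[which.min(total)]
  }
  tau <- t[k]
  fit1 <- ols_line(t[1:k], q[1:k])
  fit2 <- ols_line(t[(k + 1):n], q[(k + 1):n])
  seg <- rbind(segment_row(series, t[1], tau, fit1, voltage, renorm),
               segment_row(series, tau, t[n], fit2, voltage, renorm))
  new_regime_fit(model = "two-segment", segments = seg, bifurcation_time = tau,
                 sse = fit1$sse + fit2$sse, series = series, voltage = voltage,
                 renorm = renorm, degenerate = FALSE)
}

segment_row <- function(series, t0, t1, fit, voltage, renorm) {
  ev <- series$events
  in_seg <- ev$time > t0 - 1e-9 & ev$time <= t1 + 1e-9
  cond <- if (!is.null(voltage) && voltage != 0) {
    abs(fit$slope * .pg$pA_per_e_ns * renorm) / abs(voltage)
  } else NA_real_
  data.frame(
    start = t0, end = t1, slope = fit$slope, intercept = fit$intercept,
    conductance = cond, r_squared = fit$r2,
    n_events = sum(in_seg),
    current_ratio = current_ratio(ev[in_seg, , drop = FALSE])
  )
}

new_regime_fit <- function(model, segments, bifurcation_time, sse, series,
                           voltage, renorm, degenerate = FALSE,
                           selection_score = NA_real_) {
  structure(
    list(model = model, segments = segments,
         bifurcation_time = bifurcation_time, sse = sse,
         selection_score = selection_score, voltage = voltage,
         renorm = renorm, degenerate = degenerate, series = series),
    class = "regime_fit"
  )
}

#' Choose between the single- and two-segment regime fits
#'
#' Returns the two-segment fit iff its information criterion improves on the
#' single-segment one. The default criterion is a BIC evaluated on the
#' per-step increments of the series (fitted increment means derive from the
#' segment slopes), charging the two-segment model 2 extra parameters. The
#' selection score (criterion difference, positive favouring two segments)
#' is recorded on the returned fit.
#'
#' @param single,two `regime_fit` objects for the same series.
#' @param criterion `"bic_increments"` (default) or `"bic_levels"`.
#' @return The selected `regime_fit`, with `selection_score` filled in.
#' @export
select_model <- function(single, two, criterion = "bic_increments") {
  stopifnot(inherits(single, "regime_fit"), inherits(two, "regime_fit"))
  series <- single$series
  t <- series$times; q <- series$q
  n_inc <- length(q) - 1
  if (criterion == "bic_increments") {
    dq <- diff(q); dt <- diff(t)
    rss1 <- sum((dq - single$segments$slope[1] * dt)^2)
    tau <- two$bifurcation_time
    left <- t[-1] <= tau
    mu <- ifelse(left, two$segments$slope[1], two$segments$slope[2]) * dt
    rss2 <- sum((dq - mu)^2)
    bic1 <- n_inc * log(max(rss1, 1e-300) / n_inc) + 2 * log(n_inc)
    bic2 <- n_inc * log(max(rss2, 1e-300) / n_inc) + 4 * log(n_inc)
  } else if (criterion == "bic_levels") {
    n <- length(q)
    bic1 <- n * log(max(single$sse, 1e-300) / n) + 2 * log(n)
    bic2 <- n * log(max(two$sse, 1e-300) / n) + 4 * log(n)
  } else {
    stop("unknown criterion: ", criterion)
  }
  score <- bic1 - bic2
  out <- if (is.finite(score) && score > 0) two else single
  out$selection_score <- score
  out
}

#' @export
print.regime_fit <- function(x, ...) {
  cat("Conducting-regime fit:", x$model)
  if (!is.na(x$bifurcation_time)) {
    cat(sprintf(" (bifurcation at %.4g ns)", x$bifurcation_time))
  }
  cat("\n")
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("  [%.4g, %.4g] ns: slope %.4g e/ns", seg$start[i], seg$end[i],
                seg$slope[i]))
    if (!is.na(seg$conductance[i])) {
      cat(sprintf(", conductance %.2f nS", seg$conductance[i]))
    }
    cat(sprintf(", R2 %s", if (is.na(seg$r_squared[i])) "NA"
                else sprintf("%.4f", seg$r_squared[i])))
    if (!is.na(seg$current_ratio[i])) {
      cat(sprintf(", I_Cl/I_K %.1f", seg$current_ratio[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.regime_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  SSE %.6g; selection score %s; renorm %.4g\n", object$sse,
              if (is.na(object$selection_score)) "NA"
              else sprintf("%.3g", object$selection_score), object$renorm))
  invisible(object)
}

#' @export
coef.regime_fit <- function(object, ...) {
  seg <- object$segments
  out <- as.vector(rbind(seg$intercept, seg$slope))
  names(out) <- as.vector(rbind(paste0("intercept", seq_len(nrow(seg))),
                                paste0("slope", seq_len(nrow(seg)))))
  out
}

#' @export
predict.regime_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$series$times
  seg <- object$segments
  if (object$model == "single") {
    seg$intercept[1] + seg$slope[1] * times
  } else {
    tau <- object$bifurcation_time
    ifelse(times <= tau,
           seg$intercept[1] + seg$slope[1] * times,
           seg$intercept[2] + seg$slope[2] * times)
  }
}

#' @export
fitted.regime_fit <- function(object, ...) predict(object)

#' @export
residuals.regime_fit <- function(object, ...) object$series$q - fitted(object)

#' @export
plot.regime_fit <- function(x, ...) {
  graphics::plot(x$series$times, x$series$q, type = "l", xlab = "time (ns)",
                 ylab = "q_tot (e)", ...)
  graphics::lines(x$series$times, fitted(x), col = 2, lwd = 2)
  if (!is.na(x$bifurcation_time)) {
    graphics::abline(v = x$bifurcation_time, lty = 2, col = 4)
  }
  invisible(x)
}

#' Classify the conducting state of a fitted trajectory
#'
#' Applies the stability and band thresholds to a [regime_fit()]:
#' a single-regime fit is `open-like` when its conductance lies within
#' `open_tol` (default 15%) of the open-state reference, `stable-low` when
#' `sigma <= sigma_max` and `R^2 >= r2_min`; a two-segment fit is `bistable`
#' when one segment falls inside the closed-state band (fractions of the
#' open conductance) and the other within `open_tol` of the reference.
#' Everything else is `unstable`.
#'
#' @param fit A `regime_fit` whose segments carry conductances.
#' @param open_reference_nS Open-state reference conductance (nS, > 0).
#' @param thresholds List with `sigma` (nS), `r2`, `band` (length-2
#'   fractions) and `open_tol`.
#' @return An object of class `state_class`: `label` and a `criteria` record
#'   (per-segment conductance, R^2, fraction of the open-state conductance).
#' @export
classify_state <- function(fit, open_reference_nS,
                           thresholds = list(sigma = 2.3, r2 = 0.99,
                                             band = c(0.40, 0.60),
                                             open_tol = 0.15)) {
  stopifnot(inherits(fit, "regime_fit"))
  if (!is.numeric(open_reference_nS) || open_reference_nS <= 0) {
    stop("open_reference_nS must be positive")
  }
  th <- utils::modifyList(list(sigma = 2.3, r2 = 0.99, band = c(0.40, 0.60),
                               open_tol = 0.15), thresholds)
  seg <- fit$segments
  if (anyNA(seg$conductance)) stop("fit carries no conductances; supply a voltage")
  frac <- seg$conductance / open_reference_nS
  near_open <- abs(seg$conductance - open_reference_nS) / open_reference_nS <= th$open_tol
  in_band <- frac >= th$band[1] & frac <= th$band[2]
  label <- if (fit$model == "single") {
    if (near_open[1]) "open-like"
    else if (seg$conductance[1] <= th$sigma &&
             !is.na(seg$r_squared[1]) && seg$r_squared[1] >= th$r2) "stable-low"
    else "unstable"
  } else {
    if ((in_band[1] && near_open[2]) || (in_band[2] && near_open[1])) "bistable"
    else "unstable"
  }
  structure(
    list(label = label,
         criteria = data.frame(sigma = seg$conductance,
                               r_squared = seg$r_squared,
                               fraction_of_open = frac),
         thresholds = th, open_reference_nS = open_reference_nS),
    class = "state_class"
  )
}

#' @export
print.state_class <- function(x, ...) {
  cat("Conducting state:", x$label, "\n")
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  segment %d: sigma %.2f nS (%.0f%% of open), R2 %s\n", i,
                x$criteria$sigma[i], 100 * x$criteria$fraction_of_open[i],
                if (is.na(x$criteria$r_squared[i])) "NA"
                else sprintf("%.3f", x$criteria$r_squared[i])))
  }
  invisible(x)
}

#' Screen conformers by conductance threshold
#'
#' Selects the conformers whose quick conductance estimate falls strictly
#' below the threshold — the fast pre-filter applied before long verification
#' runs. The summary expresses the threshold as an integer (truncated)
#' percentage of the open-state reference.
#'
#' @param estimates A data frame with a `conductance` column (nS), or a list
#'   of `current_estimate` objects.
#' @param threshold_nS Selection threshold (nS); default 2.5.
#' @param open_reference_nS Open-state reference conductance (nS), used only
#'   for the percentage in the summary.
#' @return List with `selected` (the sub-data-frame), and `summary`
#'   (`n_total`, `n_selected`, `threshold_nS`, `percent_of_open`).
#' @export
screen_conformers <- function(estimates, threshold_nS = 2.5,
                              open_reference_nS = NULL) {
  if (!is.data.frame(estimates)) {
    estimates <- data.frame(
      conformer = seq_along(estimates),
      conductance = vapply(estimates, function(e) e$conductance, numeric(1))
    )
  }
  if (!nrow(estimates)) stop("empty batch")
  sel <- estimates[estimates$conductance < threshold_nS, , drop = FALSE]
  pct <- if (!is.null(open_reference_nS)) {
    trunc(100 * threshold_nS / open_reference_nS)
  } else NA_real_
  list(
    selected = sel,
    summary = list(n_total = nrow(estimates), n_selected = nrow(sel),
                   threshold_nS = threshold_nS, percent_of_open = pct)
  )
}
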