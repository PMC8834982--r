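#' Single-term accelerated-MD boost
#'
#' The boost added to the potential when it falls below the threshold
#' energy: `dV = (E - V)^2 / (alpha + E - V)` for `V < E`, and 0 otherwise.
#' It satisfies `0 <= dV < E - V` and decreases monotonically in `V` below
#' the threshold.
#'
#' @param V Potential energy (kcal/mol); vectorized.
#' @param E Threshold energy (kcal/mol).
#' @param alpha Smoothing parameter (kcal/mol, > 0).
#' @return Boost energy (kcal/mol), same length as `V`.
#' @examples
#' amd_boost(V = 0, E = 10, alpha = 5)  # 100/15
#' @export
amd_boost <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  u <- E - V
  ifelse(u > 0, u^2 / (alpha + u), 0)
}

## d(V + dV)/dV = (alpha / (alpha + E - V))^2 for V < E, 1 otherwise:
## the force-scaling factor of the boosted surface.
amd_force_factor <- function(V, E, alpha) {
  u <- E - V
  ifelse(u > 0, (alpha / (alpha + u))^2, 1)
}

#' Dual-boost accelerated-MD bias
#'
#' Sum of a total-potential-energy term and a dihedral-energy term:
#' `dV(x) = boost(V, E_p, alpha_p) + boost(V_d, E_d, alpha_d)`.
#'
#' @param V_total Total potential energy (kcal/mol).
#' @param V_dihedral Dihedral energy (kcal/mol).
#' @param params An [amd_params()] object.
#' @return Total boost (kcal/mol).
#' @export
total_boost <- function(V_total, V_dihedral, params) {
  stopifnot(inherits(params, "amd_params"))
  amd_boost(V_total, params$E_p, params$alpha_p) +
    amd_boost(V_dihedral, params$E_d, params$alpha_d)
}

#' Dual-boost parameterization from system size
#'
#' Threshold energies scale with system size from the unbiased averages:
#' `E_p = E_p0 + gamma_p * n_atoms` and
#' `E_d = E_d0 + gamma_d * n_residues + gamma_d_prime * n_lipids`.
#' Defaults: `gamma_p = 0.16` kcal/mol/atom, `gamma_d = 3.5`
#' kcal/mol/residue, `gamma_d_prime = 30.0` kcal/mol/lipid. The smoothing
#' parameters default to the standard dual-boost convention
#' `alpha_p = gamma_p * n_atoms` and `alpha_d = gamma_d * n_residues / 5`
#' (with floors to stay positive for tiny toy systems).
#'
#' @param E_p0,E_d0 Unbiased average total and dihedral energies (kcal/mol).
#' @param n_atoms,n_residues,n_lipids Non-negative counts.
#' @param gamma_p,gamma_d,gamma_d_prime Per-unit threshold increments.
#' @param alpha_p,alpha_d Smoothing parameters; `NULL` applies the
#'   convention above.
#' @return An object of class `amd_params`.
#' @examples
#' amd_params(E_p0 = -1000, E_d0 = 100, n_atoms = 500, n_residues = 20)
#' @export
amd_params <- function(E_p0, E_d0, n_atoms = 0, n_residues = 0, n_lipids = 0,
                       gamma_p = 0.16, gamma_d = 3.5, gamma_d_prime = 30.0,
                       alpha_p = NULL, alpha_d = NULL) {
  if (n_atoms < 0 || n_residues < 0 || n_lipids < 0) {
    stop("counts must be non-negative")
  }
  E_p <- E_p0 + gamma_p * n_atoms
  E_d <- E_d0 + gamma_d * n_residues + gamma_d_prime * n_lipids
  if (is.null(alpha_p)) alpha_p <- max(gamma_p * n_atoms, 1)
  if (is.null(alpha_d)) alpha_d <- max(gamma_d * n_residues / 5, 1)
  if (alpha_p <= 0 || alpha_d <= 0) stop("alphas must be positive")
  structure(
    list(E_p = E_p, E_d = E_d, alpha_p = alpha_p, alpha_d = alpha_d,
         E_p0 = E_p0, E_d0 = E_d0, gamma_p = gamma_p, gamma_d = gamma_d,
         gamma_d_prime = gamma_d_prime, n_atoms = n_atoms,
         n_residues = n_residues, n_lipids = n_lipids),
    class = "amd_params"
  )
}

#' @export
print.amd_params <- function(x, ...) {
  cat(sprintf("Dual-boost parameters: E_p = %.4g, E_d = %.4g kcal/mol (alpha_p %.4g, alpha_d %.4g)\n",
              x$E_p, x$E_d, x$alpha_p, x$alpha_d))
  cat(sprintf("  gammas: %.3g /atom (n=%d), %.3g /residue (n=%d), %.3g /lipid (n=%d)\n",
              x$gamma_p, x$n_atoms, x$gamma_d, x$n_residues,
              x$gamma_d_prime, x$n_lipids))
  invisible(x)
}

#' Analytic 1D toy landscapes
#'
#' Differentiable potentials for exercising the boosted Langevin propagator.
#' Each landscape carries the total potential `V`, its gradient, and a
#' designated "dihedral-like" component `Vd` (with gradient) used by the
#' dual-boost split; for the well landscapes the whole potential is the
#' designated term.
#'
#' @param k Spring constant (kcal/mol/A^2).
#' @param barrier Barrier height (kcal/mol).
#' @param half_width Distance of the minima from the origin (A).
#' @param spacing Distance between adjacent wells (A).
#' @param depth Well depth (kcal/mol).
#' @param width Gaussian well width (A).
#' @return An object of class `amd_landscape` with function fields `V`,
#'   `grad`, `Vd`, `gradd` and a `minima` attribute.
#' @name landscapes
NULL

new_landscape <- function(V, grad, Vd = NULL, gradd = NULL, minima = numeric(0)) {
  if (is.null(Vd)) { Vd <- function(x) 0 * x; gradd <- function(x) 0 * x }
  structure(list(V = V, grad = grad, Vd = Vd, gradd = gradd, minima = minima),
            class = "amd_landscape")
}

#' @rdname landscapes
#' @export
harmonic_landscape <- function(k = 1) {
  new_landscape(V = function(x) 0.5 * k * x^2,
                grad = function(x) k * x, minima = 0)
}

#' @rdname landscapes
#' @export
double_well_landscape <- function(barrier = 3.55, half_width = 1) {
  B <- barrier; w <- half_width
  V <- function(x) B * ((x / w)^2 - 1)^2
  g <- function(x) 4 * B * x / w^2 * ((x / w)^2 - 1)
  new_landscape(V = V, grad = g, Vd = V, gradd = g, minima = c(-w, w))
}

#' @rdname landscapes
#' @export
triple_well_landscape <- function(depth = 4, spacing = 3, width = 1, k = 0.05) {
  centres <- c(-spacing, 0, spacing)
  depth <- rep_len(depth, 3)
  V <- function(x) {
    out <- 0.5 * k * x^2
    for (i in 1:3) out <- out - depth[i] * exp(-(x - centres[i])^2 / (2 * width^2))
    out
  }
  g <- function(x) {
    out <- k * x
    for (i in 1:3) {
      out <- out + depth[i] * (x - centres[i]) / width^2 *
        exp(-(x - centres[i])^2 / (2 * width^2))
    }
    out
  }
  new_landscape(V = V, grad = g, Vd = V, gradd = g, minima = centres)
}

#' Overdamped Langevin propagation on a (boosted) toy landscape
#'
#' Euler-Maruyama integration of
#' `dx = -(D/kT) d(V + dV)/dx dt + sqrt(2 D dt) dW` with the dual-boost
#' force scaling `d(V + dV)/dV = (alpha/(alpha + E - V))^2` applied to the
#' total-energy and dihedral-like terms. With `params = NULL` the dynamics
#' are unbiased. Per-step energies and boosts are recorded.
#'
#' @param landscape An `amd_landscape`.
#' @param params An [amd_params()] or `NULL` (no boost).
#' @param steps Number of steps.
#' @param dt Time step (toy units).
#' @param temperature Temperature (K) setting `kT` in kcal/mol.
#' @param seed Integer RNG seed.
#' @param x0 Initial position.
#' @param D Diffusion coefficient (toy units; default 1).
#' @return List of class `toy_trajectory`: `x` (positions, length
#'   `steps + 1`), `V`, `Vd`, `boost` (per recorded position), `dt`.
#' @export
toy_propagate <- function(landscape, params = NULL, steps, dt,
                          temperature = 298, seed = 1L, x0 = NULL, D = 1) {
  stopifnot(inherits(landscape, "amd_landscape"))
  kT <- .kT_kcal(temperature)
  if (is.null(x0)) {
    x0 <- if (length(landscape$minima)) landscape$minima[1] else 0
  }
  with_seed(seed, {
    noise <- stats::rnorm(steps, sd = sqrt(2 * D * dt))
    x <- numeric(steps + 1)
    x[1] <- x0
    xi <- x0
    for (s in seq_len(steps)) {
      Vtot <- landscape$V(xi)
      force <- -landscape$grad(xi)
      if (!is.null(params)) {
        fp <- amd_force_factor(Vtot, params$E_p, params$alpha_p)
        fd <- amd_force_factor(landscape$Vd(xi), params$E_d, params$alpha_d)
        # total-energy term scales the full gradient; the dihedral term adds
        # the extra scaling of its own component
        force <- -(landscape$grad(xi) * fp + landscape$gradd(xi) * (fd - 1))
      }
      if (!is.finite(force) || !is.finite(Vtot)) {
        stop("non-finite energy encountered at step ", s)
      }
      xi <- xi + (D / kT) * force * dt + noise[s]
      x[s + 1] <- xi
    }
    V <- landscape$V(x)
    Vd <- landscape$Vd(x)
    boost <- if (is.null(params)) 0 * x else {
      amd_boost(V, params$E_p, params$alpha_p) +
        amd_boost(Vd, params$E_d, params$alpha_d)
    }
    structure(list(x = x, V = V, Vd = Vd, boost = boost, dt = dt),
              class = "toy_trajectory")
  })
}

#' Count well-to-well barrier crossings of a 1D trajectory
#'
#' Hysteresis counter: a crossing is recorded each time the committed well
#' flips, with commitment thresholds at `+-commit` around the barrier.
#'
#' @param x Numeric positions.
#' @param commit Commitment half-width.
#' @return Integer crossing count.
#' @export
count_well_crossings <- function(x, commit = 0.5) {
  s <- ifelse(x < -commit, -1L, ifelse(x > commit, 1L, NA_integer_))
  s <- s[!is.na(s)]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0L)
}

#' Multi-walker exploration with cluster restarts
#'
#' Runs `n_walkers` trajectory segments in parallel rounds; after each
#' round, all conformers generated so far are pooled and clustered into
#' `n_walkers` clusters, and the representative of cluster k becomes the
#' starting point of walker k for the next round (clusters ordered by size,
#' then by lowest member index). The log records every segment, clustering
#' and restart, and the totals satisfy
#' `simulated_time = n_walkers * segment_length * n_rounds` and
#' `frames_saved = simulated_time / save_interval`.
#'
#' @param n_walkers Number of concurrent walkers.
#' @param segment_length Segment duration (ns).
#' @param n_rounds Number of rounds.
#' @param save_interval Frame-saving interval (ns); `segment_length` must be
#'   a multiple.
#' @param propagate_fn `function(x0, segment_length, save_interval, seed)`
#'   returning `list(frames = matrix n_saved x dim, final = numeric)`.
#'   Default: boosted [toy_propagate()] on a [double_well_landscape()].
#' @param cluster_fn `function(pool, k, seed)` returning exactly `k` row
#'   indices of `pool` (the representatives). Default: seeded k-means with
#'   medoid representatives.
#' @param seed Master seed; all segment and clustering seeds derive from it.
#' @param init Initial walker positions (matrix `n_walkers x dim` or a
#'   single numeric recycled).
#' @param pool_stride Optional stride for subsampling the cumulative pool
#'   before clustering (1 = use every frame, the default).
#' @return An object of class `exploration_log`: `rounds` (per-round list
#'   with per-walker segment records, restart indices), `totals`
#'   (`simulated_time_ns`, `frames_saved`), `pool` (all saved frames),
#'   `final_states`.
#' @examples
#' log <- run_exploration(n_walkers = 2, segment_length = 1, n_rounds = 2,
#'                        save_interval = 0.5, seed = 1)
#' log$totals
#' @export
run_exploration <- function(n_walkers, segment_length, n_rounds, save_interval,
                            propagate_fn = NULL, cluster_fn = NULL,
                            seed = 1L, init = 0, pool_stride = 1L) {
  if (n_walkers < 1 || n_rounds < 1) stop("need at least one walker and one round")
  frames_per_seg <- segment_length / save_interval
  if (abs(frames_per_seg - round(frames_per_seg)) > 1e-9) {
    stop("segment_length must be a multiple of save_interval")
  }
  frames_per_seg <- as.integer(round(frames_per_seg))
  if (is.null(propagate_fn)) propagate_fn <- default_propagator()
  if (is.null(cluster_fn)) cluster_fn <- default_cluster_fn
  state <- if (is.matrix(init)) init else
    matrix(rep_len(init, n_walkers), n_walkers, 1)
  pool <- NULL
  pool_round <- integer(0)
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    segs <- vector("list", n_walkers)
    for (w in seq_len(n_walkers)) {
      res <- tryCatch(
        propagate_fn(state[w, ], segment_length, save_interval,
                     child_seed(seed, r, w)),
        error = function(e) e)
      if (inherits(res, "error")) {
        rounds[[r]] <- list(round = r, error = conditionMessage(res),
                            completed_walkers = w - 1L)
        return(finish_log(rounds[seq_len(r)], pool, state, n_walkers,
                          segment_length, save_interval, partial = TRUE))
      }
      fr <- res$frames
      if (is.null(dim(fr))) fr <- matrix(fr, ncol = 1)
      if (nrow(fr) != frames_per_seg) {
        stop("propagate_fn returned ", nrow(fr), " frames; expected ",
             frames_per_seg)
      }
      segs[[w]] <- list(walker = w, frames = fr, final = res$final)
      pool <- rbind(pool, fr)
      pool_round <- c(pool_round, rep(r, nrow(fr)))
      state[w, ] <- res$final
    }
    cl_pool_idx <- seq(1, nrow(pool), by = pool_stride)
    reps_local <- cluster_fn(pool[cl_pool_idx, , drop = FALSE], n_walkers,
                             child_seed(seed, r, 0L))
    reps <- cl_pool_idx[reps_local]
    if (length(reps) != n_walkers || anyNA(reps)) {
      stop("cluster_fn must return exactly n_walkers representatives")
    }
    rounds[[r]] <- list(round = r, segments = segs, restart_frames = reps)
    state <- pool[reps, , drop = FALSE]
  }
  finish_log(rounds, pool, state, n_walkers, segment_length, save_interval,
             partial = FALSE)
}

finish_log <- function(rounds, pool, state, n_walkers, segment_length,
                       save_interval, partial) {
  n_complete <- sum(vapply(rounds, function(r) is.null(r$error), logical(1)))
  sim_time <- n_walkers * segment_length * n_complete
  structure(
    list(rounds = rounds,
         totals = list(simulated_time_ns = sim_time,
                       frames_saved = if (save_interval > 0)
                         as.integer(round(sim_time / save_interval)) else 0L),
         pool = pool, final_states = state, partial = partial),
    class = "exploration_log"
  )
}

#' @export
print.exploration_log <- function(x, ...) {
  cat("Exploration log:", length(x$rounds), "rounds",
      if (x$partial) "(partial)" else "", "\n")
  cat("  totals:", x$totals$simulated_time_ns, "ns simulated,",
      x$totals$frames_saved, "frames saved\n")
  invisible(x)
}

default_propagator <- function(landscape = double_well_landscape(),
                               params = NULL, dt = 0.002, temperature = 298) {
  function(x0, segment_length, save_interval, seed) {
    steps_per_save <- max(1L, as.integer(round(save_interval / dt)))
    n_saves <- as.integer(round(segment_length / save_interval))
    steps <- steps_per_save * n_saves
    tr <- toy_propagate(landscape, params = params, steps = steps, dt = dt,
                        temperature = temperature, seed = seed, x0 = x0[1])
    idx <- seq_len(n_saves) * steps_per_save + 1L
    list(frames = matrix(tr$x[idx], ncol = 1), final = tr$x[length(tr$x)])
  }
}

## seeded k-means clustering; representatives are cluster medoids,
## clusters ordered by size (desc) then lowest member index
default_cluster_fn <- function(pool, k, seed) {
  n <- nrow(pool)
  n_distinct <- nrow(unique(pool))
  if (n <= k || n_distinct <= k) {
    # degenerate pool: recycle the most recent distinct frames
    idx <- which(!duplicated(pool, fromLast = TRUE))
    return(rep_len(rev(idx), k))
  }
  with_seed(seed, {
    km <- suppressWarnings(stats::kmeans(pool, centers = min(k, n),
                                         nstart = 1, iter.max = 50))
    sizes <- km$size
    first_member <- vapply(seq_along(sizes), function(c0)
      which(km$cluster == c0)[1], integer(1))
    ord <- order(-sizes, first_member)
    vapply(ord, function(c0) {
      members <- which(km$cluster == c0)
      centre <- km$centers[c0, , drop = FALSE]
      d <- rowSums((pool[members, , drop = FALSE] -
                      matrix(centre, length(members), ncol(pool),
                             byrow = TRUE))^2)
      members[which.min(d)]
    }, integer(1))
  })
}

#' Simulated time of a fixed-step Brownian-dynamics run
#'
#' `n_steps * dt`, reported in ns.
#'
#' @param n_steps Number of BD cycles.
#' @param dt_ps Time step in ps.
#' @return Simulated time in ns.
#' @examples
#' gcbd_time_accounting(2e7, 0.01)  # 200 ns
#' @export
gcbd_time_accounting <- function(n_steps, dt_ps) {
  if (n_steps < 0 || dt_ps < 0) stop("inputs must be non-negative")
  n_steps * dt_ps / 1000
}
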