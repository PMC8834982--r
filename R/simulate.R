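#' Brownian-dynamics simulation of ion permeation through a cylindrical pore
#'
#' Overdamped Langevin dynamics of charged point ions in a periodic box
#' containing an impermeable slab pierced by a cylindrical pore. Per
#' coordinate and step, `dx = (D/kT) F dt + sqrt(2 D dt) N(0,1)`. The applied
#' voltage drops entirely across the slab: ions inside the slab feel a
#' constant axial force `q E` with `E = V / pore_length`, the steady-state
#' field profile of an electrolyte bathing a non-conducting membrane. With a
#' positive voltage the force on a cation points toward -z (cations traverse
#' downward, anions upward).
#'
#' Collisions are resolved by specular reflection: off the slab faces for
#' ions arriving from the bulk, radially off the pore wall inside the pore;
#' moves that cannot be reflected consistently are rejected. A blocked
#' angular sector of area fraction `obstruction_fraction` inside
#' `obstruction_zrange` models partial occlusion of the lumen, so the open
#' cross-section scales exactly as `1 - f`.
#'
#' The bulk compartments are laterally stirred reservoirs: every step, ions
#' outside the slab receive fresh uniform (x, y) positions while their axial
#' dynamics stay fully physical. Lateral stirring removes the
#' diffusion-limited convergence of ions toward the pore mouth (the access
#' resistance, which the cylinder conductance formula excludes), while axial
#' resupply runs over the whole box cross-section and is never limiting.
#' This plays the role of the grand-canonical buffers of grid-based channel
#' BD codes: the bath concentration seen by the pore mouths stays at its
#' nominal value.
#'
#' @param spec A [channel_spec()].
#' @param duration Simulated time (ns); must be at least `100 * dt`.
#' @param dt Integration step (ns). Must satisfy
#'   `sqrt(2 * D * dt) < pore_radius / 2` for the fastest species.
#' @param n_ions_per_species Ions per species; `NULL` (default) derives the
#'   count from the species concentrations and the accessible box volume.
#' @param seed Integer RNG seed; identical `(spec, seed)` give identical
#'   trajectories.
#' @param save_interval Time between stored frames (ns); defaults to
#'   `20 * dt`, snapped to a multiple of `dt`.
#' @return An [ion_trajectory()] with pore metadata attached.
#' @seealso [analytic_pore_conductance()] for the closed-form oracle.
#' @export
simulate_pore_bd <- function(spec, duration, dt, n_ions_per_species = NULL,
                             seed = 1L, save_interval = NULL) {
  stopifnot(inherits(spec, "channel_spec"))
  if (dt <= 0 || duration <= 0) stop("duration and dt must be positive")
  if (duration < 100 * dt) stop("duration must be at least 100 * dt")
  D_A <- .D_A2ns(spec$species$diffusion_coeff)
  step_sd <- sqrt(2 * max(D_A) * dt)
  if (step_sd >= spec$pore_radius / 2) {
    stop(sprintf(
      "dt too large: stability bound sqrt(2 D dt) < pore_radius/2 violated (%.3g >= %.3g A)",
      step_sd, spec$pore_radius / 2))
  }
  if (is.null(save_interval)) save_interval <- 20 * dt
  steps_per_save <- max(1L, as.integer(round(save_interval / dt)))
  n_steps <- as.integer(round(duration / dt))
  n_saves <- n_steps %/% steps_per_save

  Lx <- spec$box[1]; Ly <- spec$box[2]; Lz <- spec$box[3]
  hl <- spec$pore_length / 2
  r <- spec$pore_radius; r2 <- r * r
  f <- spec$obstruction_fraction
  obs_lo <- max(spec$obstruction_zrange[1], -hl)
  obs_hi <- min(spec$obstruction_zrange[2], hl)
  blocked_arc <- 2 * pi * f

  # accessible volume: bulk + open part of the pore
  obs_len <- max(0, obs_hi - obs_lo)
  v_acc <- Lx * Ly * (Lz - 2 * hl) + pi * r2 * 2 * hl - pi * r2 * f * obs_len
  if (is.null(n_ions_per_species)) {
    n_ions_per_species <- pmax(1L, as.integer(round(
      spec$species$concentration * v_acc * 1e-27 * .pg$avogadro)))
  } else {
    n_ions_per_species <- rep_len(as.integer(n_ions_per_species),
                                  nrow(spec$species))
  }
  n <- sum(n_ions_per_species)
  species <- rep(spec$species$name, n_ions_per_species)
  valence <- rep(spec$species$valence, n_ions_per_species)
  D_ion <- rep(D_A, n_ions_per_species)
  sig <- sqrt(2 * D_ion * dt)
  # axial drift velocity inside the slab (A/ns); +V pushes cations to -z
  vdrift <- -(D_ion * valence * spec$voltage / .thermal_mV(spec$temperature)) /
    spec$pore_length

  forbidden <- function(px, py, pz) {
    in_slab <- abs(pz) < hl
    rho2 <- px * px + py * py
    bad <- in_slab & rho2 >= r2
    if (f > 0) {
      idx <- which(in_slab & pz >= obs_lo & pz <= obs_hi & rho2 < r2)
      if (length(idx)) {
        ang <- atan2(py[idx], px[idx]) %% (2 * pi)
        bad[idx[ang < blocked_arc]] <- TRUE
      }
    }
    bad
  }

  with_seed(seed, {
    # uniform initial placement over the accessible region
    x <- y <- z <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      x[todo] <- stats::runif(length(todo), -Lx / 2, Lx / 2)
      y[todo] <- stats::runif(length(todo), -Ly / 2, Ly / 2)
      z[todo] <- stats::runif(length(todo), -Lz / 2, Lz / 2)
      todo <- todo[forbidden(x[todo], y[todo], z[todo])]
    }

    coords <- array(NA_real_, c(n_saves + 1L, n, 3))
    coords[1, , 1] <- x; coords[1, , 2] <- y; coords[1, , 3] <- z
    isave <- 1L

    for (step in seq_len(n_steps)) {
      noise <- stats::rnorm(3L * n)
      px <- x + sig * noise[seq_len(n)]
      py <- y + sig * noise[n + seq_len(n)]
      pz <- z + vdrift * dt * (abs(z) < hl) + sig * noise[2L * n + seq_len(n)]
      bad <- forbidden(px, py, pz)
      if (any(bad)) {
        i <- which(bad)
        from_out <- i[abs(z[i]) >= hl]
        if (length(from_out)) {             # bounced off a slab face
          zf <- sign(z[from_out]) * hl
          pz2 <- 2 * zf - pz[from_out]
          ok <- !forbidden(px[from_out], py[from_out], pz2)
          pz[from_out[ok]] <- pz2[ok]
        }
        from_in <- i[abs(z[i]) < hl]
        if (length(from_in)) {
          rho <- sqrt(px[from_in]^2 + py[from_in]^2)
          hit_wall <- rho >= r
          # radial bounce off the curved pore wall
          sub <- from_in[hit_wall]
          if (length(sub)) {
            rs <- rho[hit_wall]
            newrho <- 2 * r - rs
            okr <- newrho > 0
            scl <- ifelse(okr, newrho / rs, 1)
            qx <- px[sub] * scl
            qy <- py[sub] * scl
            ok <- okr & !forbidden(qx, qy, pz[sub])
            px[sub[ok]] <- qx[ok]
            py[sub[ok]] <- qy[ok]
          }
          # angular bounce off the nearest blocked-sector boundary
          sub <- from_in[!hit_wall]
          if (length(sub) && f > 0 && f < 1) {
            rs <- rho[!hit_wall]
            ang <- atan2(py[sub], px[sub]) %% (2 * pi)
            newang <- ifelse(ang < blocked_arc / 2,
                             (2 * pi - ang) %% (2 * pi),
                             2 * blocked_arc - ang)
            qx <- rs * cos(newang)
            qy <- rs * sin(newang)
            ok <- !forbidden(qx, qy, pz[sub])
            px[sub[ok]] <- qx[ok]
            py[sub[ok]] <- qy[ok]
          }
        }
        still <- forbidden(px, py, pz)
        if (any(still)) {                   # unresolvable: reject the move
          px[still] <- x[still]; py[still] <- y[still]; pz[still] <- z[still]
        }
      }
      # laterally stirred reservoirs: fresh (x, y) for bath ions
      bath <- abs(pz) >= hl
      nb <- sum(bath)
      if (nb) {
        px[bath] <- stats::runif(nb, -Lx / 2, Lx / 2)
        py[bath] <- stats::runif(nb, -Ly / 2, Ly / 2)
      }
      px <- ((px + Lx / 2) %% Lx) - Lx / 2
      py <- ((py + Ly / 2) %% Ly) - Ly / 2
      pz <- ((pz + Lz / 2) %% Lz) - Lz / 2
      x <- px; y <- py; z <- pz

      if (step %% steps_per_save == 0L) {
        isave <- isave + 1L
        coords[isave, , 1] <- x; coords[isave, , 2] <- y; coords[isave, , 3] <- z
      }
    }

    ion_trajectory(
      times = seq(0, by = steps_per_save * dt, length.out = n_saves + 1L),
      coords = coords, species = species, valence = valence,
      box = spec$box, voltage = spec$voltage, origin_z = 0,
      pore = list(radius = spec$pore_radius, length = spec$pore_length,
                  obstruction_fraction = f)
    )
  })
}

#' Brownian-dynamics simulation of a bulk electrolyte
#'
#' Free, unbiased Brownian motion of ions in a periodic box with no membrane
#' and no field; the stand-in for the dilute-solution simulation from which
#' the bulk diffusion coefficient is estimated via mean-squared displacement.
#' Displacements over one frame interval are exact Gaussians with variance
#' `2 D dt` per coordinate.
#'
#' @param spec An [electrolyte_spec()].
#' @param duration Simulated time (ns); `0` yields a single-frame trajectory.
#' @param dt Frame interval (ns).
#' @param seed Integer RNG seed.
#' @param n_ions_per_species Ions per species; `NULL` derives counts from the
#'   concentrations and box volume.
#' @return An [ion_trajectory()] (wrapped coordinates).
#' @seealso [estimate_diffusion_msd()]
#' @export
simulate_bulk_bd <- function(spec, duration, dt, seed = 1L,
                             n_ions_per_species = NULL) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  if (dt <= 0) stop("dt must be positive")
  if (duration < 0) stop("duration must be non-negative")
  D_A <- .D_A2ns(spec$species$diffusion_coeff)
  if (is.null(n_ions_per_species)) {
    n_ions_per_species <- pmax(1L, as.integer(round(
      spec$species$concentration * prod(spec$box) * 1e-27 * .pg$avogadro)))
  } else {
    n_ions_per_species <- rep_len(as.integer(n_ions_per_species),
                                  nrow(spec$species))
  }
  n <- sum(n_ions_per_species)
  species <- rep(spec$species$name, n_ions_per_species)
  valence <- rep(spec$species$valence, n_ions_per_species)
  D_ion <- rep(D_A, n_ions_per_species)
  n_frames <- as.integer(round(duration / dt)) + 1L

  with_seed(seed, {
    coords <- array(NA_real_, c(n_frames, n, 3))
    for (k in 1:3) {
      L <- spec$box[k]
      start <- stats::runif(n, -L / 2, L / 2)
      if (n_frames > 1L) {
        steps <- matrix(stats::rnorm((n_frames - 1L) * n), n_frames - 1L, n)
        steps <- sweep(steps, 2, sqrt(2 * D_ion * dt), `*`)
        cs <- apply(steps, 2, cumsum)
        if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
        unwrapped <- rbind(start, sweep(cs, 2, start, `+`))
        coords[, , k] <- ((unwrapped + L / 2) %% L) - L / 2
      } else {
        coords[1, , k] <- start
      }
    }
    ion_trajectory(
      times = seq(0, by = dt, length.out = n_frames),
      coords = coords, species = species, valence = valence,
      box = spec$box, voltage = 0, origin_z = 0, pore = NULL
    )
  })
}
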