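## Shared fixtures and independent reference implementations.

## Build an ion_trajectory from scripted per-ion z paths (x = y = 0 unless
## given), mainly for exercising the crossing-event state machine.
scripted_trajectory <- function(z, times = NULL, box = c(60, 60, 60),
                                species = NULL, valence = NULL,
                                x = NULL, y = NULL, voltage = 40,
                                pore = list(radius = 5, length = 30)) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  n_frames <- nrow(z); n <- ncol(z)
  if (is.null(times)) times <- seq(0, by = 0.1, length.out = n_frames)
  if (is.null(species)) species <- rep("K", n)
  if (is.null(valence)) valence <- ifelse(species == "K", 1L, -1L)
  if (is.null(x)) x <- matrix(0, n_frames, n)
  if (is.null(y)) y <- matrix(0, n_frames, n)
  coords <- array(NA_real_, c(n_frames, n, 3))
  coords[, , 1] <- x; coords[, , 2] <- y; coords[, , 3] <- z
  ion_trajectory(times, coords, species, valence, box = box,
                 voltage = voltage, origin_z = 0, pore = pore)
}

## Independent brute-force crossing counter: plain per-frame state machine,
## one ion at a time, no vectorization tricks. Reference semantics:
## commitment planes at +-g, wrap reset at |dz| > boxz/2, event on committed
## side flip with the first frame past the mid-plane radially inside
## r + margin.
brute_force_crossings <- function(traj, g = 10, margin = 2) {
  boxz <- traj$box[3]
  rmax <- if (is.null(traj$pore)) Inf else traj$pore$radius + margin
  n <- dim(traj$coords)[2]
  out <- data.frame(id = integer(0), time = numeric(0), direction = integer(0))
  for (p in seq_len(n)) {
    z <- traj$coords[, p, 3] - traj$origin_z
    state <- NA_integer_
    last_commit <- NA_integer_
    for (i in seq_along(z)) {
      if (i > 1 && abs(z[i] - z[i - 1]) > boxz / 2) {
        state <- NA_integer_; last_commit <- NA_integer_
      }
      s <- if (z[i] < -g) -1L else if (z[i] > g) 1L else 0L
      if (s != 0L) {
        if (!is.na(state) && s != state) {
          # first frame after last committed frame sitting on the new side
          j <- last_commit
          while (sign(z[j]) != s) j <- j + 1
          rho <- sqrt(traj$coords[j, p, 1]^2 + traj$coords[j, p, 2]^2)
          if (rho < rmax) {
            out <- rbind(out, data.frame(id = traj$ids[p],
                                         time = traj$times[j], direction = s))
          }
        }
        state <- s
        last_commit <- i
      }
    }
  }
  out[order(out$time, out$id), , drop = FALSE]
}

## Events table shorthand
events_df <- function(n_k = 0, n_cl = 0, dir_k = -1L, dir_cl = 1L,
                      t_max = 500) {
  k <- if (n_k) data.frame(id = seq_len(n_k), species = "K", valence = 1L,
                           time = seq_len(n_k) * t_max / (n_k + 1),
                           direction = dir_k) else NULL
  cl <- if (n_cl) data.frame(id = 1000 + seq_len(n_cl), species = "Cl",
                             valence = -1L,
                             time = seq_len(n_cl) * t_max / (n_cl + 1),
                             direction = dir_cl) else NULL
  ev <- rbind(k, cl)
  if (is.null(ev)) {
    ev <- data.frame(id = integer(0), species = character(0),
                     valence = integer(0), time = numeric(0),
                     direction = integer(0))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  attr(ev, "times") <- seq(0, t_max, by = 1)
  attr(ev, "voltage") <- 40
  class(ev) <- c("crossing_events", "data.frame")
  ev
}

## Small labelled toy frame set for clustering / superposition tests
toy_atoms <- function(n = 10) {
  data.frame(resid = seq_len(n), resname = "GLY", role = "CA",
             segment = "barrel", stringsAsFactors = FALSE)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
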