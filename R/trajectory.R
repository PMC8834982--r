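#' Ion trajectory container
#'
#' Time-stamped positions of labelled charged particles in a periodic box
#' under an applied voltage — the substrate of all permeation analysis.
#' Coordinates are box-centred (each axis spans `[-L/2, L/2)`), the pore axis
#' is z and `origin_z` marks the channel centre along it.
#'
#' @param times Strictly increasing, uniformly spaced frame times (ns).
#' @param coords Numeric array `n_frames x n_particles x 3` (Angstrom).
#' @param species Character vector, one entry per particle.
#' @param valence Integer vector (units of e), one entry per particle.
#' @param box Length-3 box edge lengths (Angstrom).
#' @param voltage Applied voltage (mV).
#' @param origin_z Channel centre of mass along the pore axis (Angstrom).
#' @param pore Optional list with `radius`, `length` (Angstrom) describing the
#'   pore geometry, carried as metadata for event detection.
#' @param ids Optional particle identifiers (default `1:n`).
#' @return An object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(times, coords, species, valence, box,
                           voltage = 0, origin_z = 0, pore = NULL, ids = NULL) {
  times <- as.numeric(times)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an n_frames x n_particles x 3 array")
  }
  n_frames <- dim(coords)[1]
  n_part <- dim(coords)[2]
  if (length(times) != n_frames) stop("times length must match the number of frames")
  if (n_frames > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(dt)) stop("times must be uniformly spaced")
  }
  if (!all(is.finite(coords))) stop("positions must be finite")
  if (length(species) != n_part || length(valence) != n_part) {
    stop("species and valence must have one entry per particle")
  }
  if (is.null(ids)) ids <- seq_len(n_part)
  structure(
    list(
      times = times, coords = coords, ids = ids,
      species = as.character(species), valence = as.integer(valence),
      box = as.numeric(box), voltage = voltage, origin_z = origin_z,
      axis = c(0, 0, 1), pore = pore
    ),
    class = "ion_trajectory"
  )
}

#' @export
print.ion_trajectory <- function(x, ...) {
  n_frames <- length(x$times)
  cat("Ion trajectory:", dim(x$coords)[2], "particles,", n_frames, "frames")
  if (n_frames > 1) {
    cat(sprintf(" (%.4g ns, dt = %.4g ns)", x$times[n_frames] - x$times[1],
                x$times[2] - x$times[1]))
  }
  cat("\n  box", paste(signif(x$box, 4), collapse = " x "), "A; voltage",
      x$voltage, "mV\n")
  tab <- table(x$species)
  cat("  species:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an ion trajectory as CSV plus JSON sidecar
#'
#' The columnar table has columns `frame, time_ns, id, species, valence,
#' x, y, z`; box, voltage, axis, origin and pore metadata go to
#' `<basename>.json`.
#'
#' @param traj An [ion_trajectory()].
#' @param basename Path prefix; `.csv` and `.json` are appended.
#' @return `write_trajectory` returns `basename` invisibly;
#'   `read_trajectory` returns the reconstructed `ion_trajectory`.
#' @export
write_trajectory <- function(traj, basename) {
  stopifnot(inherits(traj, "ion_trajectory"))
  n_frames <- length(traj$times)
  n_part <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(n_frames), each = n_part),
    time_ns = rep(traj$times, each = n_part),
    id = rep(traj$ids, n_frames),
    species = rep(traj$species, n_frames),
    valence = rep(traj$valence, n_frames),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3]))
  )
  utils::write.csv(df, paste0(basename, ".csv"), row.names = FALSE)
  meta <- list(box = traj$box, voltage = traj$voltage, axis = traj$axis,
               origin_z = traj$origin_z, pore = traj$pore)
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(basename) {
  df <- utils::read.csv(paste0(basename, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  frames <- sort(unique(df$frame))
  ids <- unique(df$id[df$frame == frames[1]])
  n_frames <- length(frames)
  n_part <- length(ids)
  if (nrow(df) != n_frames * n_part) {
    stop("corrupt trajectory table: every id must be present in every frame")
  }
  df <- df[order(df$frame, match(df$id, ids)), ]
  if (!all(df$id == rep(ids, n_frames))) {
    stop("corrupt trajectory table: particle roster differs between frames")
  }
  coords <- array(NA_real_, c(n_frames, n_part, 3))
  coords[, , 1] <- matrix(df$x, n_frames, n_part, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, n_frames, n_part, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, n_frames, n_part, byrow = TRUE)
  first <- df[df$frame == frames[1], ]
  pore <- meta$pore
  if (!is.null(pore) && length(pore) == 0) pore <- NULL
  ion_trajectory(
    times = unique(df$time_ns), coords = coords,
    species = first$species, valence = first$valence,
    box = meta$box, voltage = meta$voltage, origin_z = meta$origin_z,
    pore = pore, ids = ids
  )
}
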