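#' Conformation ensemble container
#'
#' Ordered conformational frames sharing one atom roster, with segment
#' annotations (e.g. `tail`, `barrel`) and an optional condition label
#' (e.g. `"+40mV"`). Coordinates live in an `n_frames x n_atoms x 3` array.
#'
#' @param atoms Data frame with one row per atom: columns `resid` (integer),
#'   `resname`, `role` (e.g. `"CA"`, `"backbone"`), `segment`.
#' @param coords Numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param condition Optional condition label carried through analyses.
#' @return An object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(atoms, coords, condition = NA_character_) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(1, dim(coords)))
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(atoms)) stop("coords second dimension must match atoms")
  if (!all(is.finite(coords))) stop("positions must be finite")
  for (col in c("resid", "resname", "role", "segment")) {
    if (is.null(atoms[[col]])) stop("atoms must have column ", col)
  }
  structure(list(atoms = atoms, coords = coords, condition = condition),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat("Conformation ensemble:", dim(x$coords)[1], "frames x",
      dim(x$coords)[2], "atoms")
  if (!is.na(x$condition)) cat(" [", x$condition, "]", sep = "")
  cat("\n  segments:", paste(names(table(x$atoms$segment)),
                             table(x$atoms$segment), sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens A [conformation_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

## index atoms by segment / role / residue range
select_atoms <- function(ens, segment = NULL, role = NULL, resid = NULL) {
  keep <- rep(TRUE, nrow(ens$atoms))
  if (!is.null(segment)) keep <- keep & ens$atoms$segment %in% segment
  if (!is.null(role)) keep <- keep & ens$atoms$role %in% role
  if (!is.null(resid)) keep <- keep & ens$atoms$resid %in% resid
  which(keep)
}

#' Toy ensemble specification
#'
#' Parameters of the synthetic barrel + N-tail coordinate generator: an
#' elliptic ring stack (the barrel) plus a short chain of tail pseudo-residues
#' placed vertically along the wall, horizontally across the pore middle, or
#' detached below the barrel, with seeded Gaussian jitter.
#'
#' @param n_frames Number of frames (>= 1).
#' @param n_points Points per barrel ring.
#' @param n_rings Number of rings.
#' @param radius_a,radius_b Barrel semi-axes (Angstrom); `radius_a >= radius_b > 0`.
#' @param height Barrel height (Angstrom).
#' @param n_residues Tail length in pseudo-residues.
#' @param placement One of `"vertical"`, `"horizontal-mid-pore"`,
#'   `"detached-below"`.
#' @param jitter_sd Gaussian jitter SD per coordinate (Angstrom, >= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `toy_ensemble_spec`.
#' @export
toy_ensemble_spec <- function(n_frames = 10, n_points = 24, n_rings = 8,
                              radius_a = 15, radius_b = 15, height = 30,
                              n_residues = 11,
                              placement = c("vertical", "horizontal-mid-pore",
                                            "detached-below"),
                              jitter_sd = 0.5, seed = 1L) {
  placement <- match.arg(placement)
  if (!(radius_a >= radius_b && radius_b > 0)) {
    stop("semi-axes must satisfy radius_a >= radius_b > 0")
  }
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(
    list(n_frames = as.integer(n_frames), n_points = as.integer(n_points),
         n_rings = as.integer(n_rings), radius_a = radius_a, radius_b = radius_b,
         height = height, n_residues = as.integer(n_residues),
         placement = placement, jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "toy_ensemble_spec"
  )
}

#' Generate a toy barrel + tail conformation ensemble
#'
#' Deterministic template geometry plus seeded per-frame jitter. Ring points
#' are tagged segment `"barrel"`, chain points `"tail"` with residue indices
#' `1..n_residues`; all points carry role `"CA"`.
#'
#' @param spec A [toy_ensemble_spec()].
#' @param condition Condition label stored on the ensemble.
#' @return A [conformation_ensemble()]. The noise-free template is attached
#'   as attribute `"template"` (an `n_atoms x 3` matrix).
#' @export
make_toy_ensemble <- function(spec, condition = NA_character_) {
  stopifnot(inherits(spec, "toy_ensemble_spec"))
  theta <- 2 * pi * (seq_len(spec$n_points) - 1) / spec$n_points
  zs <- if (spec$n_rings == 1) 0 else
    seq(-spec$height / 2, spec$height / 2, length.out = spec$n_rings)
  barrel <- do.call(rbind, lapply(zs, function(z0)
    cbind(spec$radius_a * cos(theta), spec$radius_b * sin(theta), z0)))
  nr <- spec$n_residues
  tail_xyz <- switch(
    spec$placement,
    "vertical" = cbind(rep(0.9 * spec$radius_a, nr), rep(0, nr),
                       seq(spec$height / 2, -spec$height / 2, length.out = max(nr, 2))[seq_len(nr)]),
    "horizontal-mid-pore" = cbind(seq(-0.8 * spec$radius_b, 0.8 * spec$radius_b,
                                      length.out = max(nr, 2))[seq_len(nr)],
                                  rep(0, nr), rep(0, nr)),
    "detached-below" = cbind(seq(-2, 2, length.out = max(nr, 2))[seq_len(nr)],
                             rep(0, nr), rep(-spec$height / 2 - 6, nr))
  )
  template <- rbind(barrel, tail_xyz)
  n_atoms <- nrow(template)
  atoms <- data.frame(
    resid = c(seq_len(nrow(barrel)) + 100L, seq_len(nr)),
    resname = c(rep("BAR", nrow(barrel)), rep("TAI", nr)),
    role = "CA",
    segment = c(rep("barrel", nrow(barrel)), rep("tail", nr)),
    stringsAsFactors = FALSE
  )
  coords <- with_seed(spec$seed, {
    out <- array(NA_real_, c(spec$n_frames, n_atoms, 3))
    for (i in seq_len(spec$n_frames)) {
      out[i, , ] <- template +
        if (spec$jitter_sd > 0)
          matrix(stats::rnorm(n_atoms * 3, sd = spec$jitter_sd), n_atoms, 3)
        else 0
    }
    out
  })
  ens <- conformation_ensemble(atoms, coords, condition)
  attr(ens, "template") <- template
  ens
}

#' Write an ensemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; segment tags are carried in the
#' chain identifier (first letter of the segment, upper-cased) and residue
#' names/numbers.
#'
#' @param ens A [conformation_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  a <- ens$atoms
  chain <- toupper(substr(a$segment, 1, 1))
  name <- ifelse(a$role == "CA", "CA", substr(toupper(a$role), 1, 3))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(a)), name, substr(a$resname, 1, 3), chain, a$resid,
      ens$coords[i, , 1], ens$coords[i, , 2], ens$coords[i, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
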