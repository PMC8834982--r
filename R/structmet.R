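## Conformational analytics: superposition/RMSD, barrel ellipticity,
## residue z statistics, PCA landscapes, overlap, clustering, averages,
## sequence apparent charge.

## Kabsch optimal rotation: returns the rotation matrix aligning mobile onto
## reference after both are centred.
kabsch_rotation <- function(mobile, reference) {
  H <- crossprod(mobile, reference)      # minimize ||mobile %*% M - reference||
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose an ensemble on a reference frame
#'
#' Least-squares rigid-body superposition (optimal rotation + translation,
#' Kabsch) of every frame onto the reference, fitted on `fit_sel` atoms;
#' the per-frame RMSD is scored on `score_sel` (defaults to the fit
#' selection). With `reference = NULL` the ensemble mean is used after one
#' iteration of mean-realignment: frames are first aligned to the first
#' frame, the mean is computed, and all frames are re-aligned to that mean.
#'
#' @param ens A [conformation_ensemble()].
#' @param reference Either `NULL` (mean reference), a frame index, or an
#'   `n_atoms x 3` coordinate matrix.
#' @param fit_sel,score_sel Integer atom indices (see segments/roles in
#'   `ens$atoms`); default all atoms.
#' @return The ensemble with aligned coordinates and a numeric `rmsd`
#'   field (one value per frame).
#' @export
superpose <- function(ens, reference = NULL, fit_sel = NULL, score_sel = NULL) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(ens$atoms))
  if (!length(fit_sel)) stop("empty fit selection")
  if (is.null(score_sel)) score_sel <- fit_sel
  nf <- n_frames(ens)
  align_to <- function(coords, ref) {
    ref_sub <- ref[fit_sel, , drop = FALSE]
    ref_cen <- colMeans(ref_sub)
    ref_sub <- sweep(ref_sub, 2, ref_cen)
    for (i in seq_len(dim(coords)[1])) {
      mob <- coords[i, fit_sel, , drop = TRUE]
      mob_cen <- colMeans(mob)
      R <- kabsch_rotation(sweep(mob, 2, mob_cen), ref_sub)
      coords[i, , ] <- sweep(sweep(coords[i, , ], 2, mob_cen) %*% R, 2,
                             ref_cen, `+`)
    }
    coords
  }
  if (is.null(reference)) {
    coords <- align_to(ens$coords, ens$coords[1, , ])
    ref <- apply(coords, c(2, 3), mean)
    coords <- align_to(coords, ref)
  } else {
    ref <- if (is.matrix(reference)) reference else ens$coords[reference, , ]
    if (nrow(ref) != nrow(ens$atoms)) stop("reference/selection mismatch")
    coords <- align_to(ens$coords, ref)
  }
  out <- ens
  out$coords <- coords
  out$rmsd <- vapply(seq_len(nf), function(i)
    rmsd_xyz(coords[i, score_sel, , drop = TRUE],
             ref[score_sel, , drop = FALSE]), numeric(1))
  out
}

#' Per-frame barrel ellipticity
#'
#' Projects the selected atoms of each frame onto the plane normal to the
#' pore axis (z) and returns `sqrt(lambda1 / lambda2)` of the 2D covariance
#' eigenvalues (`lambda1 >= lambda2`) — 1 for a circular cross-section,
#' larger for elliptic deformation. Invariant under rotation about the pore
#' axis, translation, and uniform scaling.
#'
#' @param ens A [conformation_ensemble()].
#' @param sel Atom indices; defaults to segment `"barrel"` atoms of role
#'   `"CA"` (falling back to all `"barrel"` atoms).
#' @return Numeric vector, one ellipticity (>= 1) per frame.
#' @export
ellipticity_series <- function(ens, sel = NULL) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  if (is.null(sel)) {
    sel <- select_atoms(ens, segment = "barrel", role = "CA")
    if (!length(sel)) sel <- select_atoms(ens, segment = "barrel")
  }
  if (length(sel) < 3) stop("need at least 3 barrel atoms per frame")
  vapply(seq_len(n_frames(ens)), function(i) {
    xy <- ens$coords[i, sel, 1:2, drop = TRUE]
    ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) {
      stop("colinear points: ellipticity undefined")
    }
    sqrt(ev[1] / ev[2])
  }, numeric(1))
}

#' Mean and spread of residue axial positions
#'
#' Per-residue mean and population standard deviation (divide by n) of the
#' C-alpha z coordinate relative to the channel origin, across frames —
#' z = 0 corresponds to the pore middle.
#'
#' @param ens A [conformation_ensemble()].
#' @param residues Integer residue indices (must have a `CA` atom).
#' @param origin_z Axial origin to subtract (Angstrom).
#' @return Data frame `resid`, `mean_z`, `sd_z`.
#' @export
residue_z_stats <- function(ens, residues, origin_z = 0) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  out <- lapply(residues, function(r) {
    idx <- select_atoms(ens, role = "CA", resid = r)
    if (!length(idx)) stop("missing residue: ", r)
    z <- ens$coords[, idx[1], 3] - origin_z
    n <- length(z)
    data.frame(resid = r, mean_z = mean(z),
               sd_z = sqrt(sum((z - mean(z))^2) / n))
  })
  do.call(rbind, out)
}

#' PCA conformational landscape
#'
#' Principal component analysis of flattened selection coordinates pooled
#' across one or more (pre-superposed) ensembles; per-frame projections are
#' kept with their condition labels so that ensembles sampled under
#' different conditions can be compared on a common basis.
#'
#' @param ensembles A [conformation_ensemble()] or list of them, superposed
#'   on a common reference (see [superpose()]).
#' @param sel Atom indices for the PCA selection (e.g. tail atoms); default
#'   segment `"tail"`, falling back to all atoms.
#' @return An object of class `landscape_model`: `mean` (coordinate mean),
#'   `basis` (orthonormal PC loadings in columns), `projections` (data frame
#'   `PC1`, `PC2`, ..., `condition`), `explained` (variance fractions,
#'   descending), `degenerate` flag.
#' @export
pca_landscape <- function(ensembles, sel = NULL) {
  if (inherits(ensembles, "conformation_ensemble")) ensembles <- list(ensembles)
  stopifnot(all(vapply(ensembles, inherits, logical(1), "conformation_ensemble")))
  if (is.null(sel)) {
    sel <- select_atoms(ensembles[[1]], segment = "tail")
    if (!length(sel)) sel <- seq_len(nrow(ensembles[[1]]$atoms))
  }
  mats <- lapply(ensembles, function(e) {
    nf <- n_frames(e)
    m <- matrix(NA_real_, nf, length(sel) * 3)
    for (i in seq_len(nf)) m[i, ] <- as.vector(e$coords[i, sel, ])
    m
  })
  X <- do.call(rbind, mats)
  if (nrow(X) < 2) stop("need at least 2 frames for PCA")
  condition <- rep(vapply(ensembles, function(e) e$condition, character(1)),
                   vapply(mats, nrow, integer(1)))
  total_var <- sum(apply(X, 2, stats::var))
  degenerate <- total_var < .Machine$double.eps * ncol(X)
  if (degenerate) {
    pc <- matrix(0, nrow(X), 2, dimnames = list(NULL, c("PC1", "PC2")))
    basis <- NULL
    explained <- rep(0, 2)
  } else {
    p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(ncol(p$x), max(2, sum(p$sdev > 1e-12)))
    pc <- p$x[, seq_len(k), drop = FALSE]
    basis <- p$rotation[, seq_len(k), drop = FALSE]
    explained <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  }
  structure(
    list(mean = colMeans(X), basis = basis,
         projections = data.frame(pc, condition = condition,
                                  stringsAsFactors = FALSE),
         explained = explained, degenerate = degenerate, sel = sel),
    class = "landscape_model"
  )
}

#' @export
print.landscape_model <- function(x, ...) {
  if (x$degenerate) {
    cat("PCA landscape: degenerate (zero total variance)\n")
  } else {
    cat(sprintf("PCA landscape: %d frames; PC1 %.1f%%, PC2 %.1f%% of variance\n",
                nrow(x$projections), 100 * x$explained[1], 100 * x$explained[2]))
  }
  invisible(x)
}

#' Overlap between two condition ensembles on the PC1/PC2 plane
#'
#' Bins the (PC1, PC2) projections of both conditions on a common grid and
#' returns the overlap fraction `sum_bins min(p_A, p_B)` of the normalized
#' densities, together with the mask of bins where both densities exceed a
#' floor — the "region of overlap" between the two conditions.
#'
#' @param model A [pca_landscape()] result, or a data frame with columns
#'   `PC1`, `PC2`, `condition`.
#' @param cond_a,cond_b Condition labels to compare.
#' @param grid_bins Number of bins per axis.
#' @param floor Minimal per-bin probability for the overlap-region mask.
#' @return List `overlap` (in [0, 1]), `mask` (logical `grid_bins x
#'   grid_bins`), `breaks_x`, `breaks_y`.
#' @export
ensemble_overlap <- function(model, cond_a, cond_b, grid_bins = 40,
                             floor = 0) {
  proj <- if (inherits(model, "landscape_model")) model$projections else model
  pa <- proj[proj$condition == cond_a, c("PC1", "PC2")]
  pb <- proj[proj$condition == cond_b, c("PC1", "PC2")]
  if (!nrow(pa) || !nrow(pb)) stop("empty condition: no frames for one label")
  rx <- range(c(pa$PC1, pb$PC1)); ry <- range(c(pa$PC2, pb$PC2))
  rx <- rx + c(-1, 1) * max(diff(rx), 1e-9) * 1e-6
  ry <- ry + c(-1, 1) * max(diff(ry), 1e-9) * 1e-6
  bx <- seq(rx[1], rx[2], length.out = grid_bins + 1)
  by <- seq(ry[1], ry[2], length.out = grid_bins + 1)
  hist2 <- function(p) {
    ix <- findInterval(p$PC1, bx, rightmost.closed = TRUE)
    iy <- findInterval(p$PC2, by, rightmost.closed = TRUE)
    m <- matrix(0, grid_bins, grid_bins)
    for (k in seq_len(nrow(p))) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
    m / nrow(p)
  }
  da <- hist2(pa); db <- hist2(pb)
  list(overlap = sum(pmin(da, db)), mask = da > floor & db > floor,
       breaks_x = bx, breaks_y = by)
}

#' RMSD-based agglomerative clustering of frames
#'
#' Average-linkage hierarchical clustering on the pairwise RMSD matrix of
#' the selected (hydrogen-free) atoms of a superposed ensemble, cut to
#' exactly `n_clusters`. The representative of each cluster is its medoid
#' (minimal summed RMSD to the other members); ties break to the lowest
#' frame index. Fully deterministic.
#'
#' @param ens A superposed [conformation_ensemble()].
#' @param n_clusters Number of clusters (1..n_frames).
#' @param sel Atom indices used for the RMSD; default all atoms.
#' @return An object of class `cluster_result`: `assignment` (integer per
#'   frame), `n_clusters`, `representatives` (medoid frame index per
#'   cluster), `linkage`.
#' @export
cluster_frames <- function(ens, n_clusters, sel = NULL) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  nf <- n_frames(ens)
  if (n_clusters <= 0) stop("n_clusters must be positive")
  if (n_clusters > nf) stop("n_clusters must not exceed the number of frames")
  if (is.null(sel)) sel <- seq_len(nrow(ens$atoms))
  X <- matrix(NA_real_, nf, length(sel) * 3)
  for (i in seq_len(nf)) X[i, ] <- as.vector(ens$coords[i, sel, ])
  d <- stats::dist(X) / sqrt(length(sel))          # euclidean -> RMSD
  assignment <- if (n_clusters == nf) seq_len(nf) else {
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, k = n_clusters)
    # relabel clusters by order of first appearance for determinism
    match(cl, unique(cl))
  }
  dm <- as.matrix(d)
  reps <- vapply(seq_len(n_clusters), function(k) {
    members <- which(assignment == k)
    if (length(members) == 1) return(members)
    tot <- rowSums(dm[members, members, drop = FALSE])
    members[which.min(tot)]                        # which.min: lowest index on ties
  }, integer(1))
  structure(
    list(assignment = assignment, n_clusters = as.integer(n_clusters),
         representatives = reps, linkage = "average", rmsd_matrix = dm),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("RMSD clustering:", x$n_clusters, "clusters over",
      length(x$assignment), "frames (", x$linkage, "linkage )\n")
  sizes <- table(x$assignment)
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  representatives:", paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' Coordinate-wise average structure
#'
#' Per-atom mean coordinates over the (superposed) frames, with a per-atom
#' RMSF sidecar — coordinate means of disordered segments can be
#' unphysical, and the RMSF records how much each atom fluctuates about the
#' average.
#'
#' @param ens A superposed [conformation_ensemble()].
#' @param frames Optional frame subset (e.g. one cluster).
#' @return List of class `conformation_frame`: `atoms`, `xyz` (n_atoms x 3),
#'   `rmsf` (Angstrom per atom).
#' @export
average_structure <- function(ens, frames = NULL) {
  stopifnot(inherits(ens, "conformation_ensemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  if (!length(frames)) stop("empty frame set")
  sub <- ens$coords[frames, , , drop = FALSE]
  xyz <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), xyz)^2
  rmsf <- sqrt(apply(dev2[, , 1, drop = FALSE] + dev2[, , 2, drop = FALSE] +
                       dev2[, , 3, drop = FALSE], 2, mean))
  structure(list(atoms = ens$atoms, xyz = xyz, rmsf = as.vector(rmsf)),
            class = "conformation_frame")
}

#' @export
print.conformation_frame <- function(x, ...) {
  cat("Conformation frame:", nrow(x$xyz), "atoms; mean RMSF",
      signif(mean(x$rmsf), 3), "A\n")
  invisible(x)
}

#' Apparent net charge of a peptide sequence
#'
#' Henderson-Hasselbalch sum over ionizable groups:
#' `sum_basic 1/(1 + 10^(pH - pKa)) - sum_acidic 1/(1 + 10^(pKa - pH))`,
#' optionally including the free termini. The pKa table is an explicit,
#' pluggable input (standard textbook values by default); no ionic-strength
#' or structure-based correction is applied.
#'
#' @param sequence One-letter amino-acid string.
#' @param pH pH value.
#' @param pKa Named vector of pKa values; recognized names are the acidic
#'   groups `D`, `E`, `C`, `Y`, `Cterm` and basic groups `K`, `R`, `H`,
#'   `Nterm`.
#' @param n_terminus,c_terminus Include the respective free terminus.
#' @return Net charge in units of e.
#' @examples
#' sequence_apparent_charge("D", n_terminus = FALSE, c_terminus = FALSE)
#' @export
sequence_apparent_charge <- function(sequence, pH = 7,
                                     pKa = default_pka_table(),
                                     n_terminus = TRUE, c_terminus = TRUE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% valid)) {
    stop("unknown residue: ", paste(setdiff(aa, valid), collapse = ", "))
  }
  basic <- c("K", "R", "H"); acidic <- c("D", "E", "C", "Y")
  q <- 0
  for (r in aa[aa %in% basic]) q <- q + 1 / (1 + 10^(pH - pKa[[r]]))
  for (r in aa[aa %in% acidic]) q <- q - 1 / (1 + 10^(pKa[[r]] - pH))
  if (n_terminus) q <- q + 1 / (1 + 10^(pH - pKa[["Nterm"]]))
  if (c_terminus) q <- q - 1 / (1 + 10^(pKa[["Cterm"]] - pH))
  unname(q)
}

#' @rdname sequence_apparent_charge
#' @export
default_pka_table <- function() {
  c(D = 3.65, E = 4.25, C = 8.30, Y = 10.07, K = 10.53, R = 12.48, H = 6.00,
    Nterm = 9.00, Cterm = 3.60)
}
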