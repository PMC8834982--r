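#' Channel system specification
#'
#' Describes the synthetic permeation system: a cylindrical pore of radius
#' `pore_radius` through an impermeable slab of thickness `pore_length`,
#' centred in a periodic box, bathed in an electrolyte under an applied
#' transmembrane voltage. A fraction of the pore cross-section can be blocked
#' to emulate partial occlusion of the lumen (e.g. by an unfolded N-terminal
#' tail lying across the pore).
#'
#' @param pore_radius Pore radius in Angstrom (> 0).
#' @param pore_length Slab thickness in Angstrom; must be smaller than the
#'   box z-length.
#' @param box Numeric length-3 vector of box edge lengths (Angstrom).
#' @param voltage Applied transmembrane voltage in mV (sign matters: positive
#'   voltage pushes cations toward -z through the pore).
#' @param temperature Temperature in K.
#' @param species Data frame with columns `name`, `valence` (integer, e),
#'   `diffusion_coeff` (cm^2/s), `concentration` (mol/L). Defaults to 1 M KCl
#'   with textbook infinite-dilution diffusion coefficients.
#' @param obstruction_fraction Fraction of the pore cross-section blocked,
#'   in [0, 1].
#' @param obstruction_zrange Length-2 z-interval (Angstrom, pore-centred
#'   coordinates) over which the obstruction acts; defaults to the full slab.
#' @return An object of class `channel_spec`.
#' @examples
#' spec <- channel_spec(pore_radius = 5, pore_length = 30)
#' analytic_pore_conductance(spec)
#' @export
channel_spec <- function(pore_radius = 5,
                         pore_length = 30,
                         box = c(64, 64, 48),
                         voltage = 40,
                         temperature = 298,
                         species = kcl_species(),
                         obstruction_fraction = 0,
                         obstruction_zrange = NULL) {
  if (!is.numeric(pore_radius) || length(pore_radius) != 1 || pore_radius <= 0) {
    stop("pore_radius must be a single positive number")
  }
  if (!is.numeric(pore_length) || length(pore_length) != 1 || pore_length <= 0) {
    stop("pore_length must be a single positive number")
  }
  if (length(box) != 3 || any(box <= 0)) stop("box must be three positive lengths")
  if (pore_length >= box[3]) stop("pore_length must be smaller than the box z-length")
  if (obstruction_fraction < 0 || obstruction_fraction > 1) {
    stop("obstruction_fraction must lie in [0, 1]")
  }
  species <- validate_species(species)
  if (is.null(obstruction_zrange)) {
    obstruction_zrange <- c(-pore_length / 2, pore_length / 2)
  }
  if (length(obstruction_zrange) != 2 || obstruction_zrange[1] > obstruction_zrange[2]) {
    stop("obstruction_zrange must be an ordered length-2 interval")
  }
  structure(
    list(
      pore_radius = pore_radius, pore_length = pore_length, box = as.numeric(box),
      voltage = voltage, temperature = temperature, species = species,
      obstruction_fraction = obstruction_fraction,
      obstruction_zrange = as.numeric(obstruction_zrange)
    ),
    class = "channel_spec"
  )
}

#' Bulk electrolyte specification (no membrane)
#'
#' Periodic box of freely diffusing ions, used to estimate the bulk diffusion
#' coefficient from mean-squared displacement for the current renormalization
#' factor.
#'
#' @param box Numeric length-3 box edge lengths (Angstrom).
#' @param temperature Temperature in K.
#' @param species As in [channel_spec()]; defaults to dilute (10 mM) KCl.
#' @return An object of class `electrolyte_spec`.
#' @export
electrolyte_spec <- function(box = c(80, 80, 80),
                             temperature = 298,
                             species = kcl_species(concentration = 0.01)) {
  if (length(box) != 3 || any(box <= 0)) stop("box must be three positive lengths")
  species <- validate_species(species)
  structure(
    list(box = as.numeric(box), temperature = temperature, species = species),
    class = "electrolyte_spec"
  )
}

#' Default KCl species table
#'
#' @param concentration Molar concentration applied to both species (mol/L).
#' @param D_K,D_Cl Diffusion coefficients in cm^2/s.
#' @return Data frame with columns `name`, `valence`, `diffusion_coeff`,
#'   `concentration`.
#' @export
kcl_species <- function(concentration = 1,
                        D_K = 1.96e-5, D_Cl = 2.03e-5) {
  data.frame(
    name = c("K", "Cl"),
    valence = c(1L, -1L),
    diffusion_coeff = c(D_K, D_Cl),
    concentration = concentration,
    stringsAsFactors = FALSE
  )
}

validate_species <- function(species) {
  req <- c("name", "valence", "diffusion_coeff", "concentration")
  if (!is.data.frame(species) || !all(req %in% names(species)) || nrow(species) < 1) {
    stop("species must be a data frame with columns ", paste(req, collapse = ", "))
  }
  if (any(species$diffusion_coeff <= 0)) stop("diffusion coefficients must be positive")
  if (any(species$concentration <= 0)) stop("concentrations must be positive")
  species
}

#' Closed-form conductance of an obstructed cylindrical pore
#'
#' Nernst-Einstein bulk conductivity, `kappa = (e^2/kT) N_A sum_i c_i z_i^2 D_i`,
#' applied to a cylinder: `G = kappa * pi r^2 (1 - f) / L_p`, with `f` the
#' blocked area fraction. Serves as the independent oracle for the
#' Brownian-dynamics pore simulator.
#'
#' @param spec A [channel_spec()].
#' @return Conductance in nS.
#' @examples
#' analytic_pore_conductance(channel_spec())  # ~3.9 nS for a 5 x 30 A pore in 1 M KCl
#' @export
analytic_pore_conductance <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$pore_length <= 0) stop("pore_length must be positive")
  if (spec$pore_radius == 0) return(0)
  kT <- .pg$kB_JK * spec$temperature
  # SI: concentrations mol/L -> mol/m^3 (x1000), D cm^2/s -> m^2/s (x1e-4)
  kappa <- (.pg$e_C^2 / kT) * .pg$avogadro *
    sum(1000 * spec$species$concentration * spec$species$valence^2 *
          1e-4 * spec$species$diffusion_coeff)
  area <- pi * (spec$pore_radius * 1e-10)^2 * (1 - spec$obstruction_fraction)
  G_S <- kappa * area / (spec$pore_length * 1e-10)
  G_S * 1e9
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("Channel spec: pore r =", x$pore_radius, "A, L =", x$pore_length,
      "A; box", paste(x$box, collapse = " x "), "A\n")
  cat("  voltage", x$voltage, "mV at", x$temperature, "K; blocked fraction",
      x$obstruction_fraction, "\n")
  cat("  species:", paste(sprintf("%s (z=%+d, D=%.3g cm2/s, %g M)",
                                  x$species$name, x$species$valence,
                                  x$species$diffusion_coeff, x$species$concentration),
                          collapse = "; "), "\n")
  invisible(x)
}
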