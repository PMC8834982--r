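## Physical constants and unit conversions used package-wide.
## Package units: lengths in Angstrom, times in ns, voltages in mV,
## charges in elementary charge e, currents in pA, conductances in nS,
## diffusion coefficients in cm^2/s at the interface (A^2/ns internally),
## energies in kcal/mol where the aMD machinery needs them.

.pg <- list(
  e_C        = 1.602176634e-19,  # elementary charge [C]
  kB_JK      = 1.380649e-23,     # Boltzmann constant [J/K]
  avogadro   = 6.02214076e23,    # [1/mol]
  kcalmol_J  = 6.947695e-21,     # 1 kcal/mol per molecule [J]
  # 1 e/ns expressed in pA: 1.602176634e-19 C / 1e-9 s = 0.1602176634 nA
  pA_per_e_ns = 160.2176634,
  # 1 A^2/ns in cm^2/s
  cm2s_per_A2ns = 1e-7
)

## thermal voltage kT/e in mV at temperature T [K]
.thermal_mV <- function(temperature) {
  1000 * .pg$kB_JK * temperature / .pg$e_C
}

## D in cm^2/s -> A^2/ns
.D_A2ns <- function(D_cm2s) D_cm2s / .pg$cm2s_per_A2ns

## kT in kcal/mol at temperature T [K]
.kT_kcal <- function(temperature) {
  .pg$kB_JK * temperature / .pg$kcalmol_J
}

#' Uniform electric field equivalent to a transmembrane voltage
#'
#' Converts an applied voltage and the length over which it drops into a
#' uniform field, `E = V / L`, the constant-field convention used to impose a
#' transmembrane potential in simulation boxes. The sign of the field follows
#' the sign of the voltage.
#'
#' @param voltage_mV Applied voltage in mV.
#' @param box_length_A Length over which the voltage drops, in Angstrom.
#' @return Field strength in V/m (signed).
#' @examples
#' field_from_voltage(40, 90.2)   # ~4.43e6 V/m
#' @export
field_from_voltage <- function(voltage_mV, box_length_A) {
  stopifnot(is.numeric(voltage_mV), is.numeric(box_length_A))
  if (any(box_length_A <= 0)) {
    stop("box_length_A must be positive")
  }
  (voltage_mV / 1000) / (box_length_A * 1e-10)
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## Deterministic child seed below 2^31, derived from a base seed and tags.
child_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed)
  for (t in tags) s <- (s * 69069 + as.double(t) + 1) %% 2147483629
  as.integer(s)
}
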