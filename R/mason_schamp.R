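# Low-field Mason-Schamp relation for drift-tube ion mobility:
# converts measured arrival times to collision cross sections in a buffer
# gas (nitrogen by default) and back. Inputs use instrument-native units
# (ms, V/cm, cm, Torr, K, Da); all unit conversion happens here, against a
# single registry of CODATA physical constants.

#' Physical constants used by the drift-time/CCS conversion
#'
#' CODATA values: elementary charge `e` (C), Boltzmann constant `kb` (J/K),
#' Loschmidt number density `N0` at 273.15 K / 760 Torr (m^-3), and the
#' atomic mass unit `da_kg` (kg per Da). Exposed so users can audit the
#' conversion.
#'
#' @return Named list of constants.
#' @export
ims_constants <- function() {
  list(
    e     = 1.602176634e-19,   # C
    kb    = 1.380649e-23,      # J/K
    N0    = 2.6867811e25,      # m^-3, gas number density at STP (Loschmidt)
    da_kg = 1.66053907e-27,    # kg per Dalton
    T0    = 273.15,            # K, reference temperature
    P0    = 760                # Torr, reference pressure
  )
}

# unit conversion factors into the instrument-native set (ms, V/cm, cm, Torr, K)
.unit_factors <- list(
  mobility = c(t_a = 1, e_field = 1, length = 1, pressure = 1),
  si       = c(t_a = 1e3,            # s     -> ms
               e_field = 1e-2,       # V/m   -> V/cm
               length = 1e2,         # m     -> cm
               pressure = 1 / 133.322368)  # Pa -> Torr
)

#' Drift-tube measurement conditions
#'
#' Bundles the quantities entering the low-field Mason-Schamp relation.
#' Default units are the instrument-native ion-mobility conventions; pass
#' `units = "si"` to supply seconds, V/m, m and Pa instead (temperature is
#' always K, masses always Da).
#'
#' @param t_a arrival (drift) time, ms. May be `NA` when the conditions are
#'   only used to invert a CCS into a drift time.
#' @param e_field applied electric field, V/cm.
#' @param length drift-tube length, cm.
#' @param pressure drift-cell pressure, Torr.
#' @param temperature drift-cell temperature, K.
#' @param ion_mass ion mass, Da.
#' @param gas_mass buffer-gas mass, Da (default molecular nitrogen,
#'   28.0134 Da).
#' @param z charge number, integer >= 1 (the magnitude of the ion charge).
#' @param units `"mobility"` (default) or `"si"`.
#' @return Object of class `drift_conditions`.
#' @examples
#' drift_conditions(t_a = 20, e_field = 15, length = 78, pressure = 4,
#'                  temperature = 300, ion_mass = 300)
#' @export
drift_conditions <- function(t_a = NA_real_, e_field, length, pressure,
                             temperature, ion_mass, gas_mass = 28.0134,
                             z = 1L, units = c("mobility", "si")) {
  units <- match.arg(units)
  f <- .unit_factors[[units]]
  cond <- list(
    t_a = t_a * f[["t_a"]],
    e_field = e_field * f[["e_field"]],
    length = length * f[["length"]],
    pressure = pressure * f[["pressure"]],
    temperature = temperature,
    ion_mass = ion_mass,
    gas_mass = gas_mass,
    z = as.integer(z)
  )
  for (nm in setdiff(names(cond), "t_a")) {
    v <- cond[[nm]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      stop(sprintf("drift condition '%s' must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (!is.na(cond$t_a) && cond$t_a <= 0) {
    stop("arrival time t_a must be strictly positive", call. = FALSE)
  }
  structure(cond, class = "drift_conditions")
}

#' @export
print.drift_conditions <- function(x, ...) {
  cat(sprintf(paste0(
    "<drift conditions: t_A = %s ms, E = %g V/cm, L = %g cm, P = %g Torr,\n",
    "  T = %g K, m_i = %g Da, m_B = %g Da, z = %d>\n"),
    if (is.na(x$t_a)) "?" else format(x$t_a), x$e_field, x$length,
    x$pressure, x$temperature, x$ion_mass, x$gas_mass, x$z))
  invisible(x)
}

#' A collision cross section value
#'
#' @param value CCS in Angstrom^2, strictly positive.
#' @param buffer_gas label of the buffer gas the value refers to.
#' @return Object of class `ccs_value`.
#' @export
ccs_value <- function(value, buffer_gas = "N2") {
  if (!is.numeric(value) || !is.finite(value) || value <= 0) {
    stop("CCS value must be strictly positive and finite", call. = FALSE)
  }
  structure(list(value = value, buffer_gas = buffer_gas),
            class = "ccs_value")
}

#' @export
print.ccs_value <- function(x, ...) {
  cat(sprintf("<CCS %.4g A^2 in %s>\n", x$value, x$buffer_gas))
  invisible(x)
}

#' Reduced-mass factor of the Mason-Schamp relation
#'
#' The square-root term `sqrt(1/m_i + 1/m_B)` coupling ion and buffer-gas
#' masses. Symmetric in its arguments and strictly decreasing in each mass;
#' its limit for a heavy ion is `sqrt(1/m_B)`.
#'
#' @param ion_mass,gas_mass masses in Da, strictly positive.
#' @return `sqrt(1/ion_mass + 1/gas_mass)` in Da^(-1/2).
#' @examples
#' reduced_mass_term(28, 28)   # sqrt(2/28)
#' reduced_mass_term(100, 28)
#' @export
reduced_mass_term <- function(ion_mass, gas_mass) {
  if (any(!is.finite(ion_mass)) || any(!is.finite(gas_mass)) ||
      any(ion_mass <= 0) || any(gas_mass <= 0)) {
    stop("masses must be strictly positive", call. = FALSE)
  }
  sqrt(1 / ion_mass + 1 / gas_mass)
}

#' Collision cross section from drift-tube conditions
#'
#' Evaluates the low-field Mason-Schamp relation
#' \deqn{\Omega = \frac{\sqrt{18\pi}}{16}\,\frac{ze}{\sqrt{k_b T}}
#'   \sqrt{\frac{1}{m_i}+\frac{1}{m_B}}\;\frac{t_A E}{L}\;
#'   \frac{760}{P}\,\frac{T}{273.15}\,\frac{1}{N_0}}
#' with masses in kg and times/lengths in SI internally; the result is
#' expressed in Angstrom^2. The relation is linear in `t_A` and `E` and
#' inversely linear in `L` and `P`.
#'
#' @param cond a [drift_conditions()] object with a finite arrival time.
#' @return A [ccs_value()] in Angstrom^2.
#' @examples
#' cond <- drift_conditions(t_a = 20, e_field = 15, length = 78,
#'                          pressure = 4, temperature = 300, ion_mass = 300)
#' ccs_from_drift(cond)
#' @export
ccs_from_drift <- function(cond) {
  stopifnot(inherits(cond, "drift_conditions"))
  if (is.na(cond$t_a)) {
    stop("drift conditions carry no arrival time t_a", call. = FALSE)
  }
  k <- ims_constants()
  # into SI: s, V/m, m, kg
  t_s <- cond$t_a * 1e-3
  E <- cond$e_field * 1e2
  L <- cond$length * 1e-2
  mi <- cond$ion_mass * k$da_kg
  mb <- cond$gas_mass * k$da_kg
  ccs_m2 <- sqrt(18 * pi) / 16 *
    (abs(cond$z) * k$e) / sqrt(k$kb * cond$temperature) *
    sqrt(1 / mi + 1 / mb) *
    (t_s * E / L) *
    (k$P0 / cond$pressure) * (cond$temperature / k$T0) *
    (1 / k$N0)
  ccs_value(ccs_m2 * 1e20, buffer_gas = if (abs(cond$gas_mass - 28.0134) < 1e-3) "N2" else "custom")
}

#' Drift time implied by a collision cross section
#'
#' Algebraic inversion of [ccs_from_drift()]: the arrival time an ion of the
#' given CCS would show under the stated conditions. Exact inverse, so
#' `ccs_from_drift()` applied to the returned time reproduces the input CCS
#' to machine precision.
#'
#' @param ccs a [ccs_value()] or a plain CCS number in Angstrom^2.
#' @param cond [drift_conditions()]; its `t_a` field is ignored.
#' @return Arrival time in ms.
#' @export
drift_time_from_ccs <- function(ccs, cond) {
  stopifnot(inherits(cond, "drift_conditions"))
  value <- if (inherits(ccs, "ccs_value")) ccs$value else ccs
  if (!is.numeric(value) || !is.finite(value) || value <= 0) {
    stop("CCS must be strictly positive", call. = FALSE)
  }
  ref <- cond
  ref$t_a <- 1          # CCS is linear in t_A: scale from a unit drift time
  per_ms <- ccs_from_drift(ref)$value
  value / per_ms
}
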