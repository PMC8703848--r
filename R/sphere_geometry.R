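# Hard-sphere geometry: a measured/computed CCS is modelled as the
# projected area of two colliding hard spheres, ion and buffer-gas
# molecule, so CCS = pi * (r_i + r_B)^2. Subtracting the buffer-gas kinetic
# radius turns a CCS into a projected ion radius, which can then be held
# against the dimensions of pores in the blood-brain barrier. Because a
# drift experiment really measures a momentum-transfer cross section, which
# can exceed the geometric one by up to 40%, a corrected branch divides the
# CCS by a correction factor (default 1.4) before extracting the radius.

#' Buffer-gas hard-sphere specification
#'
#' @param name gas label.
#' @param kinetic_radius effective hard-sphere (kinetic) radius in Angstrom.
#' @return Object of class `buffer_gas_spec`.
#' @seealso [nitrogen_gas()] for the N2 default.
#' @export
buffer_gas_spec <- function(name, kinetic_radius) {
  if (!is.numeric(kinetic_radius) || !is.finite(kinetic_radius) ||
      kinetic_radius <= 0) {
    stop("kinetic_radius must be strictly positive", call. = FALSE)
  }
  structure(list(name = name, kinetic_radius = kinetic_radius),
            class = "buffer_gas_spec")
}

#' Molecular nitrogen buffer gas
#'
#' N2 with a kinetic radius of 1.82 Angstrom (kinetic diameter 3.64 A), the
#' buffer gas of essentially all drug CCS measurements and the value under
#' which the package's published reference radii/areas are reproduced.
#' @return A [buffer_gas_spec()].
#' @export
nitrogen_gas <- function() buffer_gas_spec("N2", 1.82)

#' Threshold projected ion radius for BBB-permeant compounds
#'
#' The projected ion radius corresponding to the 200 Angstrom^2 CCS
#' threshold in nitrogen, i.e. the maximum radius still compatible with
#' brain penetration under the single-descriptor CCS rule.
#' @return 6.2 (Angstrom).
#' @export
bbb_radius_threshold <- function() 6.2

#' Built-in BBB pore models
#'
#' Two pore geometries relevant to passive brain penetration: transient
#' kinks in the endothelial lipid bilayer (diameter 10 A) and the pore-like
#' assemblies formed by tight-junction claudins (8-10 A).
#'
#' @param name `"membrane_kink"` or `"claudin"`, or use `diameter` directly
#'   for a custom pore.
#' @param diameter single diameter or length-2 range (low, high) in
#'   Angstrom; overrides `name` when given.
#' @return Object of class `pore_model` with fields `name` and `diameter`.
#' @export
pore_model <- function(name = c("membrane_kink", "claudin"), diameter = NULL) {
  if (is.null(diameter)) {
    name <- match.arg(name)
    diameter <- switch(name, membrane_kink = 10, claudin = c(8, 10))
  } else {
    name <- if (length(name) == 1L && !identical(name, c("membrane_kink", "claudin")))
      as.character(name) else "custom"
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("pore diameter must be strictly positive", call. = FALSE)
  }
  if (length(diameter) == 2L && diameter[1] > diameter[2]) {
    diameter <- rev(diameter)
  }
  structure(list(name = name, diameter = diameter), class = "pore_model")
}

.min_ccs <- function(gas) pi * gas$kinetic_radius^2

#' Projected ion radius from a collision cross section
#'
#' Under the hard-sphere model, `ccs = pi * (r_i + r_B)^2`, so
#' `r_i = sqrt(ccs / pi) - r_B` with `r_B` the buffer-gas kinetic radius.
#' Strictly increasing in the CCS. The CCS must be at least `pi * r_B^2`
#' (the cross section of the bare buffer-gas sphere), otherwise the implied
#' ion radius would be negative.
#'
#' @param ccs CCS in Angstrom^2 (vectorised) or a [ccs_value()].
#' @param gas a [buffer_gas_spec()]; default nitrogen.
#' @return Projected ion radius in Angstrom.
#' @examples
#' ion_radius_from_ccs(174)   # ~5.6 A, mean of BBB-permeant drugs
#' ion_radius_from_ccs(200)   # ~6.2 A, the CCS-threshold radius
#' @export
ion_radius_from_ccs <- function(ccs, gas = nitrogen_gas()) {
  stopifnot(inherits(gas, "buffer_gas_spec"))
  value <- if (inherits(ccs, "ccs_value")) ccs$value else ccs
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("ccs must be finite numeric", call. = FALSE)
  }
  if (any(value < .min_ccs(gas))) {
    stop(sprintf(
      "CCS below the minimum representable %.4g A^2 (= pi * r_B^2 for %s)",
      .min_ccs(gas), gas$name), call. = FALSE)
  }
  sqrt(value / pi) - gas$kinetic_radius
}

#' Collision cross section from a projected ion radius
#'
#' Exact inverse of [ion_radius_from_ccs()]: `ccs = pi * (r_i + r_B)^2`.
#'
#' @param r_i projected ion radius in Angstrom, non-negative (vectorised).
#' @param gas a [buffer_gas_spec()].
#' @return CCS in Angstrom^2.
#' @export
ccs_from_ion_radius <- function(r_i, gas = nitrogen_gas()) {
  stopifnot(inherits(gas, "buffer_gas_spec"))
  if (!is.numeric(r_i) || any(!is.finite(r_i)) || any(r_i < 0)) {
    stop("ion radius must be non-negative and finite", call. = FALSE)
  }
  pi * (r_i + gas$kinetic_radius)^2
}

#' Hard-sphere projection of a CCS, with momentum-transfer correction
#'
#' Computes the projected ion radius `r_i` and area `A_i = pi * r_i^2` from
#' a CCS, plus the momentum-transfer-corrected pair (`r_con`, `A_con`)
#' obtained by dividing the CCS by `correction_factor` before the radius
#' extraction (the measured momentum-transfer cross section can exceed the
#' geometric collision cross section by up to 40%, hence the default 1.4).
#'
#' @param ccs CCS in Angstrom^2 or a [ccs_value()].
#' @param gas a [buffer_gas_spec()].
#' @param correction_factor unitless, >= 1.
#' @return Object of class `sphere_projection` with fields `ccs`, `r_i`,
#'   `a_i`, `r_con`, `a_con`, `correction_factor`, `gas`.
#' @examples
#' projection_from_ccs(174)  # r_i ~5.6 A, A_i ~99 A^2, A_con ~63 A^2
#' @export
projection_from_ccs <- function(ccs, gas = nitrogen_gas(),
                                correction_factor = 1.4) {
  value <- if (inherits(ccs, "ccs_value")) ccs$value else ccs
  if (!is.numeric(correction_factor) || !is.finite(correction_factor) ||
      correction_factor < 1) {
    stop("correction_factor must be >= 1", call. = FALSE)
  }
  r_i <- ion_radius_from_ccs(value, gas)
  corrected <- value / correction_factor
  if (any(corrected < .min_ccs(gas))) {
    stop(sprintf(
      "corrected CCS below the minimum representable %.4g A^2 for %s",
      .min_ccs(gas), gas$name), call. = FALSE)
  }
  r_con <- ion_radius_from_ccs(corrected, gas)
  structure(list(
    ccs = value,
    r_i = r_i, a_i = pi * r_i^2,
    r_con = r_con, a_con = pi * r_con^2,
    correction_factor = correction_factor,
    gas = gas
  ), class = "sphere_projection")
}

#' @export
print.sphere_projection <- function(x, ...) {
  cat(sprintf("<hard-sphere projection of CCS %.4g A^2 in %s>\n",
              x$ccs[1], x$gas$name))
  cat(sprintf("  r_i   = %.1f A   A_i   = %.0f A^2\n", x$r_i[1], x$a_i[1]))
  cat(sprintf("  r_con = %.1f A   A_con = %.0f A^2  (factor %.2g)\n",
              x$r_con[1], x$a_con[1], x$correction_factor))
  invisible(x)
}

#' Propagate a CCS spread through the hard-sphere conversion
#'
#' Converts a CCS standard deviation into spreads of the derived radius and
#' areas. The default `"endpoint"` method evaluates each derived quantity at
#' `ccs_mean + ccs_sd` and subtracts its value at `ccs_mean` (one-sided
#' endpoint propagation, the convention the reference radii/area spreads
#' follow); `"delta"` uses first-order error propagation
#' `|f'(mean)| * sd` instead.
#'
#' @param ccs_mean,ccs_sd mean and standard deviation of the CCS (A^2),
#'   `ccs_sd >= 0`.
#' @param gas a [buffer_gas_spec()].
#' @param correction_factor unitless, >= 1.
#' @param method `"endpoint"` (default) or `"delta"`.
#' @return Named list of spreads: `r_i`, `a_i`, `r_con`, `a_con`.
#' @examples
#' propagate_spread(174, 25)  # r_i spread ~0.5 A, A_i spread ~19 A^2
#' @export
propagate_spread <- function(ccs_mean, ccs_sd, gas = nitrogen_gas(),
                             correction_factor = 1.4,
                             method = c("endpoint", "delta")) {
  method <- match.arg(method)
  if (!is.numeric(ccs_sd) || !is.finite(ccs_sd) || ccs_sd < 0) {
    stop("ccs_sd must be non-negative", call. = FALSE)
  }
  at <- function(ccs) projection_from_ccs(ccs, gas, correction_factor)
  if (method == "endpoint") {
    hi <- at(ccs_mean + ccs_sd)
    mid <- at(ccs_mean)
    list(r_i = hi$r_i - mid$r_i, a_i = hi$a_i - mid$a_i,
         r_con = hi$r_con - mid$r_con, a_con = hi$a_con - mid$a_con)
  } else {
    # d r_i / d ccs = 1 / (2 sqrt(pi ccs)); d A_i / d ccs = r_i / (r_i + r_B)
    mid <- at(ccs_mean)
    rb <- gas$kinetic_radius
    dr <- ccs_sd / (2 * sqrt(pi * ccs_mean))
    da <- ccs_sd * mid$r_i / (mid$r_i + rb)
    ccs_c <- ccs_mean / correction_factor
    dr_c <- (ccs_sd / correction_factor) / (2 * sqrt(pi * ccs_c))
    da_c <- (ccs_sd / correction_factor) * mid$r_con / (mid$r_con + rb)
    list(r_i = dr, a_i = da, r_con = dr_c, a_con = da_c)
  }
}

#' Does a spherical molecule of radius r fit through a pore?
#'
#' A molecule fits when its diameter does not exceed the pore diameter
#' (`2 * r <= diameter`; the boundary counts as fitting). For a range pore
#' (such as the 8-10 A claudin assemblies) verdicts at both endpoints are
#' reported.
#'
#' @param r molecular (projected ion) radius in Angstrom, `>= 0`.
#' @param pore a [pore_model()].
#' @return List of class `pore_verdict`: `fits` (logical; for a range pore,
#'   `TRUE` only if it fits the narrow end), `verdict` (character),
#'   `at_low`/`at_high` for range pores.
#' @examples
#' fits_pore(4.4, pore_model("membrane_kink"))$verdict
#' fits_pore(4.6, pore_model("claudin"))$verdict
#' @export
fits_pore <- function(r, pore) {
  stopifnot(inherits(pore, "pore_model"))
  if (!is.numeric(r) || !is.finite(r) || r < 0) {
    stop("radius must be non-negative and finite", call. = FALSE)
  }
  d <- 2 * r
  if (length(pore$diameter) == 1L) {
    fits <- d <= pore$diameter
    out <- list(fits = fits,
                verdict = if (fits) "fits" else "does not fit",
                pore = pore, molecule_diameter = d)
  } else {
    at_low <- d <= pore$diameter[1]
    at_high <- d <= pore$diameter[2]
    verdict <- if (at_low) "fits across entire pore range"
      else if (at_high) "fits at the wide end only"
      else "does not fit"
    out <- list(fits = at_low, verdict = verdict, at_low = at_low,
                at_high = at_high, pore = pore, molecule_diameter = d)
  }
  structure(out, class = "pore_verdict")
}

#' @export
print.pore_verdict <- function(x, ...) {
  dia <- paste(format(x$pore$diameter), collapse = "-")
  cat(sprintf("<molecule diameter %.1f A vs %s pore (%s A): %s>\n",
              x$molecule_diameter, x$pore$name, dia, x$verdict))
  invisible(x)
}
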