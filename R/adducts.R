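# Adduct selection from the predominant charge at physiological pH.
# Screening libraries annotate each drug as positive, negative or neutral at
# pH 7.4; the ion whose CCS is computed is the matching protomer:
# positive/neutral -> (M+H)+, negative -> (M-H)-.

#' Proton mass in Dalton
#'
#' Mass of the proton used for (M+H)+ / (M-H)- adduct mass arithmetic.
#' @export
PROTON_MASS_DA <- 1.007276

#' Construct an adduct specification
#'
#' An adduct spec fixes the ion species whose collision cross section is
#' computed or measured: the protonated molecule `(M+H)+` (charge +1, mass
#' shift `+1.007276` Da) or the deprotonated molecule `(M-H)-` (charge -1,
#' mass shift `-1.007276` Da).
#'
#' @param kind `"protonated"` or `"deprotonated"`.
#' @return An object of class `adduct_spec` with fields `kind`, `label`
#'   (`"(M+H)+"` / `"(M-H)-"`), `z` (signed charge number) and
#'   `mass_shift` (Da).
#' @examples
#' adduct_spec("protonated")
#' @export
adduct_spec <- function(kind = c("protonated", "deprotonated")) {
  kind <- match.arg(kind)
  spec <- if (kind == "protonated") {
    list(kind = kind, label = "(M+H)+", z = 1L, mass_shift = +PROTON_MASS_DA)
  } else {
    list(kind = kind, label = "(M-H)-", z = -1L, mass_shift = -PROTON_MASS_DA)
  }
  structure(spec, class = "adduct_spec")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat(sprintf("<adduct %s: z = %+d, mass shift = %+.6f Da>\n",
              x$label, x$z, x$mass_shift))
  invisible(x)
}

#' Select the ionic adduct from the physiological charge class
#'
#' Mimics the biological scenario: compounds predominantly positive at
#' physiological pH are considered as `(M+H)+` ions, predominantly negative
#' compounds as `(M-H)-`, and neutrals as `(M+H)+`. When the charge class is
#' unknown (as in libraries published without charge annotation) a
#' configurable fallback applies; the default falls back to `(M+H)+`, the
#' convention used when whole libraries lack charge data.
#'
#' @param charge_class character vector with values among
#'   `"positive"`, `"negative"`, `"neutral"`, `"unknown"`.
#' @param unknown_fallback adduct kind used for `"unknown"` entries
#'   (default `"protonated"`).
#' @param quiet suppress the message emitted when the fallback fires.
#' @return For a single charge class, an [adduct_spec()]; for a vector, a
#'   list of `adduct_spec` objects.
#' @examples
#' select_adduct("negative")$label   # "(M-H)-"
#' select_adduct("neutral")$label    # "(M+H)+"
#' @export
select_adduct <- function(charge_class,
                          unknown_fallback = c("protonated", "deprotonated"),
                          quiet = FALSE) {
  unknown_fallback <- match.arg(unknown_fallback)
  one <- function(cc) {
    cc <- match.arg(tolower(cc),
                    c("positive", "negative", "neutral", "unknown"))
    switch(cc,
      positive = adduct_spec("protonated"),
      negative = adduct_spec("deprotonated"),
      neutral  = adduct_spec("protonated"),
      unknown  = {
        if (!quiet) {
          message("charge class unknown: falling back to ",
                  adduct_spec(unknown_fallback)$label, " adduct")
        }
        adduct_spec(unknown_fallback)
      })
  }
  if (length(charge_class) == 1L) one(charge_class) else lapply(charge_class, one)
}

#' Mass of the adduct ion
#'
#' @param neutral_mass neutral monoisotopic (or average) mass in Da; must be
#'   strictly positive.
#' @param spec an [adduct_spec()].
#' @return Ion mass in Da (`neutral_mass + mass_shift`).
#' @examples
#' adduct_mass(100, adduct_spec("protonated"))     # 101.007276
#' adduct_mass(180.0634, adduct_spec("deprotonated"))
#' @export
adduct_mass <- function(neutral_mass, spec) {
  stopifnot(inherits(spec, "adduct_spec"))
  if (!is.numeric(neutral_mass) || any(!is.finite(neutral_mass)) ||
      any(neutral_mass <= 0)) {
    stop("neutral_mass must be strictly positive and finite", call. = FALSE)
  }
  m <- neutral_mass + spec$mass_shift
  if (any(m <= 0)) {
    stop("adduct mass is non-positive; neutral mass below the proton mass",
         call. = FALSE)
  }
  m
}
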