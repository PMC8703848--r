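# End-to-end workflow: ingest (or simulate) -> adduct annotation ->
# classification -> accuracy evaluation (+ optional descriptor importance)
# -> hard-sphere geometry report. All artifacts are plain CSV/JSON/text in
# a run directory; a manifest records config, seeds and versions so a rerun
# with the same config reproduces the outputs byte for byte.

# one global seed fans out to fixed per-stage seeds so stages can be rerun
# in isolation
.stage_seed <- function(seed, stage) {
  offsets <- c(ingest = 0L, importance = 1L, split = 2L, folds = 3L)
  (as.integer(seed) + offsets[[stage]] * 7919L) %% 2147483647L
}

# tiny FNV-1a over a string; enough to fingerprint a config in the manifest
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h a double within 2^32
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Pipeline run configuration
#'
#' @param input path to a compound CSV, or `NULL` when simulating.
#' @param preset synthetic preset name (see [preset_config()]), or `NULL`
#'   when reading a file. Exactly one of `input`/`preset` must be given.
#' @param rule `"ccs200"`, `"ccs-xlogp3"`, a path to a JSON rule file, or a
#'   rule object.
#' @param validation a [validation_config()]; by default one is derived
#'   from the global seed via the stage-seed fan-out.
#' @param correction_factor momentum-transfer correction for the geometry
#'   stage.
#' @param gas buffer gas for the geometry stage.
#' @param run_importance fit the descriptor-importance forest (can be slow
#'   on large libraries; `TRUE` by default).
#' @param importance_descriptors descriptor columns for the importance
#'   stage (default: all recognised descriptors present in the data).
#' @param out_dir output directory, created if needed.
#' @param seed global integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = NULL, rule = "ccs200",
                       validation = NULL, correction_factor = 1.4,
                       gas = nitrogen_gas(), run_importance = TRUE,
                       importance_descriptors = NULL,
                       out_dir = tempfile("bbbccs_run_"), seed = 1L) {
  if (is.null(input) == is.null(preset)) {
    stop("exactly one of 'input' or 'preset' must be supplied", call. = FALSE)
  }
  if (is.null(validation)) {
    validation <- validation_config(split_seed = .stage_seed(seed, "split"),
                                    rf_seed = .stage_seed(seed, "importance"))
  }
  structure(list(input = input, preset = preset, rule = rule,
                 validation = validation,
                 correction_factor = correction_factor, gas = gas,
                 run_importance = isTRUE(run_importance),
                 importance_descriptors = importance_descriptors,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.resolve_rule <- function(rule) {
  if (inherits(rule, "threshold_rule") || inherits(rule, "combined_rule")) {
    return(rule)
  }
  if (identical(rule, "ccs200")) return(ccs200_rule())
  if (identical(rule, "ccs-xlogp3")) return(ccs_xlogp3_rule())
  if (is.character(rule) && file.exists(rule)) return(read_rule_file(rule))
  stop("unknown rule: ", rule, call. = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full BBB-CCS workflow
#'
#' Executes ingest/simulate, adduct annotation, rule classification,
#' accuracy evaluation, optional random-forest descriptor importance, and
#' the hard-sphere geometry report, writing all artifacts into the run
#' directory: `predictions.csv`, `report.json`, `importance.csv`,
#' `geometry.csv`, `summary.txt` and `manifest.json`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `predictions`, `report`, `importance`, `geometry`, `out_dir`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message("[bbbccs] ", msg)
    log_line <<- c(log_line, msg)
  }

  ds <- .stage("ingest", {
    if (!is.null(cfg$preset)) {
      simulate_dataset(preset_config(cfg$preset,
                                     seed = .stage_seed(cfg$seed, "ingest")))
    } else {
      read_compound_table(cfg$input)
    }
  })
  s <- dataset_summary(ds)
  say("ingest: %d records (%d BBB+, %d BBB-, %d unlabelled)",
      s$n_total, s$n_plus, s$n_minus, s$n_unknown)

  adducts <- .stage("adducts", {
    specs <- select_adduct(ds$charge_class, quiet = TRUE)
    if (inherits(specs, "adduct_spec")) specs <- list(specs)
    lab <- vapply(specs, `[[`, character(1), "label")
    ion_mass <- if ("mw" %in% names(ds)) {
      shift <- vapply(specs, `[[`, numeric(1), "mass_shift")
      ifelse(is.na(ds$mw) | ds$mw <= 0, NA_real_, ds$mw + shift)
    } else rep(NA_real_, nrow(ds))
    data.frame(id = ds$id, adduct = lab, ion_mass = ion_mass,
               stringsAsFactors = FALSE)
  })
  say("adducts: %d (M+H)+ / %d (M-H)-",
      sum(adducts$adduct == "(M+H)+"), sum(adducts$adduct == "(M-H)-"))

  rule <- .resolve_rule(cfg$rule)
  predictions <- .stage("classify", classify_dataset(ds, rule))
  say("classify: %d BBB+ predicted, %d unclassifiable",
      sum(predictions$predicted == "BBB_plus", na.rm = TRUE),
      length(attr(predictions, "unclassifiable")))

  report <- .stage("evaluate", {
    if (s$n_plus + s$n_minus > 0) {
      confusion_and_accuracy(predictions$predicted, ds$bbb_label)
    } else NULL
  })
  if (!is.null(report)) {
    say("evaluate: accuracy %.1f%% (class errors BBB+ %.1f%%, BBB- %.1f%%)",
        100 * report$accuracy, 100 * report$class_error_plus,
        100 * report$class_error_minus)
  }

  importance <- NULL
  if (cfg$run_importance && !is.null(report)) {
    importance <- .stage("importance", {
      descs <- cfg$importance_descriptors %||%
        intersect(descriptor_names(), names(ds))
      rf_importance(ds, descs, cfg$validation)
    })
    say("importance: top descriptor '%s' (OOB error %.1f%%)",
        importance$ranking[1], 100 * importance$fit$oob_error)
  }

  geometry <- .stage("geometry", {
    has_ccs <- "ccs" %in% names(ds)
    if (!has_ccs) NULL else {
      ok <- !is.na(ds$ccs) & ds$ccs >= pi * cfg$gas$kinetic_radius^2 *
        cfg$correction_factor
      proj <- projection_from_ccs(ds$ccs[ok], cfg$gas, cfg$correction_factor)
      kink <- pore_model("membrane_kink")
      claudin <- pore_model("claudin")
      data.frame(
        id = ds$id[ok], ccs = ds$ccs[ok],
        r_i = proj$r_i, a_i = proj$a_i,
        r_con = proj$r_con, a_con = proj$a_con,
        fits_membrane_kink = 2 * proj$r_con <= kink$diameter,
        fits_claudin_narrow = 2 * proj$r_con <= claudin$diameter[1],
        stringsAsFactors = FALSE)
    }
  })
  if (!is.null(geometry)) {
    say("geometry: %d compounds converted; %d fit the 10 A membrane pore",
        nrow(geometry), sum(geometry$fits_membrane_kink))
  }

  # artifacts
  write_predictions(ds, predictions, file.path(cfg$out_dir, "predictions.csv"))
  if (!is.null(report)) {
    jsonlite::write_json(list(
      accuracy = report$accuracy,
      class_error_plus = report$class_error_plus,
      class_error_minus = report$class_error_minus,
      n_classified = report$n_classified,
      n_unclassifiable = report$n_unclassifiable,
      confusion = as.data.frame(report$confusion)
    ), file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(importance)) {
    write.csv(data.frame(descriptor = names(importance$scores),
                         mean_decrease_accuracy = unname(importance$scores)),
              file.path(cfg$out_dir, "importance.csv"), row.names = FALSE)
  }
  if (!is.null(geometry)) {
    write.csv(geometry, file.path(cfg$out_dir, "geometry.csv"),
              row.names = FALSE)
  }
  writeLines(log_line, file.path(cfg$out_dir, "summary.txt"))
  cfg_json <- jsonlite::toJSON(list(
    input = cfg$input, preset = cfg$preset,
    rule = if (is.character(cfg$rule)) cfg$rule else "custom-object",
    seed = cfg$seed, correction_factor = cfg$correction_factor,
    gas = cfg$gas$name, validation = unclass(cfg$validation)
  ), auto_unbox = TRUE, null = "null")
  jsonlite::write_json(list(
    package = "bbbccs",
    version = as.character(utils::packageVersion("bbbccs")),
    config = jsonlite::fromJSON(cfg_json),
    config_hash = .fnv1a(as.character(cfg_json)),
    stage_seeds = list(ingest = .stage_seed(cfg$seed, "ingest"),
                       importance = .stage_seed(cfg$seed, "importance"),
                       split = .stage_seed(cfg$seed, "split")),
    n_records = s$n_total, n_plus = s$n_plus, n_minus = s$n_minus
  ), file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, adducts = adducts, predictions = predictions,
                 report = report, importance = importance,
                 geometry = geometry, out_dir = cfg$out_dir))
}
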