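# BBB permeation decision rules. The single-descriptor rule labels a
# compound BBB-permeant when its CCS lies below 200 A^2; the combined rule
# adds lipophilicity (XlogP3 > -1) with inclusive-OR semantics. Rules are
# data, so custom thresholds/descriptors compose the same way.

#' A single-descriptor threshold rule
#'
#' @param descriptor descriptor name the rule reads (see
#'   [descriptor_names()]).
#' @param threshold finite numeric cut-off.
#' @param direction `"below_is_positive"` (values under the threshold vote
#'   BBB-permeant) or `"above_is_positive"`.
#' @param strictness `"strict"` (boundary value does NOT fire the rule;
#'   default, matching the "below 200 A^2" convention) or `"inclusive"`.
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(descriptor, threshold,
                           direction = c("below_is_positive",
                                         "above_is_positive"),
                           strictness = c("strict", "inclusive")) {
  direction <- match.arg(direction)
  strictness <- match.arg(strictness)
  if (!is.numeric(threshold) || !is.finite(threshold)) {
    stop("threshold must be finite", call. = FALSE)
  }
  structure(list(descriptor = descriptor, threshold = threshold,
                 direction = direction, strictness = strictness),
            class = "threshold_rule")
}

#' The 200 A^2 CCS threshold rule
#'
#' BBB-permeant iff CCS < 200 A^2 (strict: exactly 200 classifies as
#' non-permeant).
#' @param strictness see [threshold_rule()].
#' @return A [threshold_rule()].
#' @export
ccs200_rule <- function(strictness = "strict") {
  threshold_rule("ccs", 200, "below_is_positive", strictness)
}

#' Combine several threshold rules
#'
#' @param clauses list of [threshold_rule()]s (at least one).
#' @param combiner `"any"` (inclusive OR, default) or `"all"` (AND).
#' @return Object of class `combined_rule`.
#' @export
combined_rule <- function(clauses, combiner = c("any", "all")) {
  combiner <- match.arg(combiner)
  if (length(clauses) < 1L ||
      !all(vapply(clauses, inherits, logical(1), "threshold_rule"))) {
    stop("clauses must be a non-empty list of threshold rules", call. = FALSE)
  }
  structure(list(clauses = clauses, combiner = combiner),
            class = "combined_rule")
}

#' The combined CCS / lipophilicity rule
#'
#' BBB-permeant if XlogP3 > -1 and/or CCS < 200 A^2 (inclusive OR).
#' @return A [combined_rule()].
#' @export
ccs_xlogp3_rule <- function() {
  combined_rule(list(
    threshold_rule("xlogp3", -1, "above_is_positive", "strict"),
    ccs200_rule()
  ), combiner = "any")
}

#' Read a rule from a JSON file
#'
#' Schema: `{"combiner": "any", "clauses": [{"descriptor": "ccs",
#' "op": "<", "threshold": 200}, ...]}`. Ops `<` and `>` are strict, `<=`
#' and `>=` inclusive. A file with one clause yields a [threshold_rule()].
#'
#' @param path JSON rule file.
#' @return A [threshold_rule()] or [combined_rule()].
#' @export
read_rule_file <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cl <- spec$clauses
  if (is.null(cl)) stop("rule file needs a 'clauses' array", call. = FALSE)
  cl <- as.data.frame(cl, stringsAsFactors = FALSE)
  rules <- lapply(seq_len(nrow(cl)), function(i) {
    op <- cl$op[i]
    threshold_rule(
      cl$descriptor[i], as.numeric(cl$threshold[i]),
      direction = if (op %in% c("<", "<=")) "below_is_positive" else "above_is_positive",
      strictness = if (op %in% c("<", ">")) "strict" else "inclusive")
  })
  if (length(rules) == 1L) rules[[1]] else
    combined_rule(rules, combiner = spec$combiner %||% "any")
}

# does a clause fire on a single descriptor value? NA in, NA out
.clause_fires <- function(rule, value) {
  if (is.na(value)) return(NA)
  if (rule$direction == "below_is_positive") {
    if (rule$strictness == "strict") value < rule$threshold else value <= rule$threshold
  } else {
    if (rule$strictness == "strict") value > rule$threshold else value >= rule$threshold
  }
}

#' Classify by CCS threshold
#'
#' @param ccs numeric vector of CCS values (A^2); `NA` entries are
#'   unclassifiable and come back as `NA`.
#' @param rule a [threshold_rule()] on the `ccs` descriptor (default the
#'   200 A^2 rule).
#' @return Character vector of `"BBB_plus"` / `"BBB_minus"` / `NA`.
#' @examples
#' classify_by_ccs(c(174, 200, 250))   # plus, minus, minus
#' @export
classify_by_ccs <- function(ccs, rule = ccs200_rule()) {
  stopifnot(inherits(rule, "threshold_rule"))
  vapply(ccs, function(v) {
    f <- .clause_fires(rule, v)
    if (is.na(f)) NA_character_ else if (f) "BBB_plus" else "BBB_minus"
  }, character(1))
}

#' Classify one compound by a combined rule
#'
#' OR semantics: BBB-permeant as soon as any clause fires; clauses whose
#' descriptor is missing are skipped. With `combiner = "all"`, every
#' evaluable clause must fire. If no clause is evaluable the compound is
#' unclassifiable (`NA`).
#'
#' @param descriptors named list or named numeric vector of descriptor
#'   values for one compound.
#' @param rule a [combined_rule()] (default CCS/XlogP3) or a
#'   [threshold_rule()].
#' @return `"BBB_plus"`, `"BBB_minus"` or `NA` with attribute
#'   `"fired"` naming the clause(s) that fired.
#' @examples
#' classify_combined(list(ccs = 250, xlogp3 = 0))    # BBB_plus
#' classify_combined(list(ccs = 250, xlogp3 = -2))   # BBB_minus
#' @export
classify_combined <- function(descriptors, rule = ccs_xlogp3_rule()) {
  if (inherits(rule, "threshold_rule")) rule <- combined_rule(list(rule))
  stopifnot(inherits(rule, "combined_rule"))
  vals <- vapply(rule$clauses, function(cl) {
    v <- descriptors[[cl$descriptor]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  fired <- mapply(.clause_fires, rule$clauses, vals)
  evaluable <- !is.na(fired)
  if (!any(evaluable)) {
    return(structure(NA_character_, fired = character(0)))
  }
  hit <- if (rule$combiner == "any") any(fired[evaluable]) else all(fired[evaluable])
  which_fired <- vapply(rule$clauses[evaluable & fired %in% TRUE],
                        function(cl) cl$descriptor, character(1))
  structure(if (hit) "BBB_plus" else "BBB_minus",
            fired = which_fired)
}

#' Classify every compound in a dataset
#'
#' Applies a threshold or combined rule record by record. Deterministic and
#' order-preserving; records that no clause can evaluate are flagged
#' unclassifiable instead of being dropped.
#'
#' @param ds a [compound_dataset()].
#' @param rule a [threshold_rule()] or [combined_rule()].
#' @return data.frame with columns `id`, `predicted`
#'   (`"BBB_plus"`/`"BBB_minus"`/`NA`) and `rule_fired` (comma-separated
#'   descriptors of the clauses that fired, `"none"` if none, `NA` if
#'   unclassifiable); attribute `"unclassifiable"` holds the affected ids.
#' @export
classify_dataset <- function(ds, rule = ccs200_rule()) {
  stopifnot(inherits(ds, "compound_dataset"))
  if (inherits(rule, "threshold_rule")) rule <- combined_rule(list(rule))
  preds <- character(nrow(ds))
  fired <- character(nrow(ds))
  for (i in seq_len(nrow(ds))) {
    row <- as.list(ds[i, intersect(descriptor_names(), names(ds)),
                      drop = FALSE])
    res <- classify_combined(row, rule)
    preds[i] <- as.character(res)
    fired[i] <- if (is.na(res)) NA_character_ else {
      f <- attr(res, "fired")
      if (length(f) == 0L) "none" else paste(f, collapse = ",")
    }
  }
  out <- data.frame(id = ds$id, predicted = preds, rule_fired = fired,
                    stringsAsFactors = FALSE)
  attr(out, "unclassifiable") <- ds$id[is.na(preds)]
  out
}
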