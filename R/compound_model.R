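# Compound-library container and CSV I/O. A compound dataset is a
# data.frame (one row per compound) with identity columns (id, smiles,
# charge_class, bbb_label) and sparse numeric descriptor columns; absent
# descriptors are NA, never zero.

#' Descriptor columns recognised in compound tables
#'
#' The descriptor families relevant to CNS drugs: collision cross section
#' (`ccs`, A^2), molecular weight (`mw`, Da), polar surface area (`psa`,
#' A^2), lipophilicity at physiological pH (`logd74`) and computed
#' octanol-water partition (`xlogp3`), hydrogen-bond acceptor/donor counts,
#' rotatable-bond count, and `pka`.
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function() {
  c("ccs", "mw", "psa", "logd74", "xlogp3",
    "h_acceptors", "h_donors", "rotatable_bonds", "pka")
}

.charge_levels <- c("positive", "negative", "neutral", "unknown")
.label_levels <- c("BBB_plus", "BBB_minus", "unknown")

# BBB+/CNS+/1/p etc., case-insensitive
.normalize_bbb_label <- function(x) {
  key <- tolower(trimws(as.character(x)))
  plus <- c("bbb+", "cns+", "bbb_plus", "bbbplus", "1", "p", "plus", "+",
            "positive", "yes", "true")
  minus <- c("bbb-", "cns-", "bbb_minus", "bbbminus", "0", "n", "minus", "-",
             "negative", "no", "false")
  out <- rep("unknown", length(key))
  out[key %in% plus] <- "BBB_plus"
  out[key %in% minus] <- "BBB_minus"
  out
}

.normalize_charge <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(key))
  out[key %in% c("positive", "pos", "+", "cation", "cationic", "basic")] <- "positive"
  out[key %in% c("negative", "neg", "-", "anion", "anionic", "acidic")] <- "negative"
  out[key %in% c("neutral", "n", "0", "uncharged")] <- "neutral"
  out
}

# light syntactic SMILES screen: allowed characters, balanced brackets and
# parentheses, paired ring-closure digits. No chemistry; just catches the
# "erroneous SMILES" class of rows.
.smiles_ok <- function(s) {
  vapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) return(FALSE)
    if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$/\\\\%.*:]", x)) return(FALSE)
    chars <- strsplit(x, "")[[1]]
    if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
    if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
    digits <- gsub("%[0-9]{2}", "", gsub("\\[[^]]*\\]", "", x))
    digits <- gsub("[^0-9]", "", digits)
    if (nzchar(digits)) {
      tab <- table(strsplit(digits, "")[[1]])
      if (any(tab %% 2 != 0)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Construct a compound dataset
#'
#' @param records data.frame with at least an `id` column; recognised
#'   columns are `id`, `smiles`, `charge_class`, `bbb_label` and the
#'   numeric descriptors of [descriptor_names()]. Missing identity columns
#'   are filled with `"unknown"` / `NA`; missing descriptor columns stay
#'   absent.
#' @param name dataset label (e.g. `"adenot"`, `"synthetic"`).
#' @return Object of classes `compound_dataset` and `data.frame`.
#' @export
compound_dataset <- function(records, name = "dataset") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    stop("empty dataset: no compound records", call. = FALSE)
  }
  if (is.null(records$id)) {
    records$id <- sprintf("cmpd_%d", seq_len(nrow(records)))
  }
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    stop("compound ids must be unique within a dataset", call. = FALSE)
  }
  if (is.null(records$smiles)) records$smiles <- NA_character_
  records$charge_class <- if (is.null(records$charge_class)) "unknown" else
    .normalize_charge(records$charge_class)
  records$bbb_label <- if (is.null(records$bbb_label)) "unknown" else
    .normalize_bbb_label(records$bbb_label)
  for (d in intersect(descriptor_names(), names(records))) {
    if (!is.numeric(records[[d]])) {
      suppressWarnings(records[[d]] <- as.numeric(records[[d]]))
    }
  }
  for (d in c("ccs", "mw", "psa")) {
    if (d %in% names(records) && any(records[[d]] < 0, na.rm = TRUE)) {
      stop(sprintf("descriptor '%s' must be non-negative", d), call. = FALSE)
    }
  }
  structure(records, name = name,
            class = c("compound_dataset", "data.frame"))
}

#' @export
print.compound_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf(
    "<compound dataset '%s': %d records (%d BBB+, %d BBB-, %d unknown)>\n",
    attr(x, "name"), s$n_total, s$n_plus, s$n_minus, s$n_unknown))
  NextMethod()
}

#' Read a compound table from CSV
#'
#' Two dialects are supported. `"standard"` expects a header with some of
#' the columns `id`, `smiles`, `charge` (or `charge_class`), `bbb` (or
#' `bbb_label`) plus descriptor columns; `column_map` renames
#' non-standard headers. `"ccsbase_batch"` is the single-`smiles`-column
#' upload format of batch CCS prediction services. Label and charge strings
#' are mapped case-insensitively (`BBB+`, `CNS+`, `1`, `p`, ... all mean
#' BBB-permeant). Unparseable numeric cells (e.g. `"n/a"`) become absent
#' descriptors with a warning; rows are never dropped for that reason.
#'
#' @param path CSV file path (header row required).
#' @param dialect `"standard"` or `"ccsbase_batch"`.
#' @param column_map optional named character vector mapping file headers
#'   to canonical names, e.g. `c(compound = "id", logP = "xlogp3")`.
#' @param validate_smiles if `TRUE`, rows whose SMILES fail a light
#'   syntactic screen are dropped and counted in a warning (mirrors the
#'   "erroneous SMILES" exclusion applied to curated drug sets).
#' @param name dataset label; defaults to the file name.
#' @return A [compound_dataset()].
#' @export
read_compound_table <- function(path,
                                dialect = c("standard", "ccsbase_batch"),
                                column_map = NULL,
                                validate_smiles = FALSE,
                                name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (nrow(raw) == 0L) {
    stop("empty dataset: '", path, "' has a header but no data rows",
         call. = FALSE)
  }
  names(raw) <- tolower(trimws(names(raw)))
  if (!is.null(column_map)) {
    hits <- match(tolower(names(column_map)), names(raw))
    names(raw)[hits[!is.na(hits)]] <- unname(column_map)[!is.na(hits)]
  }
  # header aliases seen in the wild
  alias <- c(charge = "charge_class", bbb = "bbb_label", label = "bbb_label",
             compound = "id", identifier = "id", "ccs_a2" = "ccs")
  for (a in names(alias)) {
    if (a %in% names(raw) && !(alias[[a]] %in% names(raw))) {
      names(raw)[names(raw) == a] <- alias[[a]]
    }
  }
  if (dialect == "ccsbase_batch" && !("smiles" %in% names(raw))) {
    stop("format error: ccsbase_batch dialect requires a 'smiles' column",
         call. = FALSE)
  }
  for (d in intersect(descriptor_names(), names(raw))) {
    cell <- trimws(raw[[d]])
    cell[cell == ""] <- NA
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is.na(cell) & is.na(num)
    if (any(bad)) {
      warning(sprintf(
        "%d unparseable '%s' cell(s) treated as absent (e.g. \"%s\")",
        sum(bad), d, cell[bad][1]), call. = FALSE)
    }
    raw[[d]] <- num
  }
  if (isTRUE(validate_smiles) && "smiles" %in% names(raw)) {
    ok <- .smiles_ok(raw$smiles)
    if (any(!ok)) {
      warning(sprintf("dropped %d row(s) with erroneous SMILES", sum(!ok)),
              call. = FALSE)
      raw <- raw[ok, , drop = FALSE]
      if (nrow(raw) == 0L) {
        stop("empty dataset: all rows had erroneous SMILES", call. = FALSE)
      }
    }
  }
  compound_dataset(raw, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a compound dataset
#'
#' Counts of BBB-permeant (`BBB_plus`), non-permeant (`BBB_minus`) and
#' unlabelled compounds, plus the class ratio `n_plus / n_minus` rounded to
#' one decimal (the precision drug-library ratios are conventionally
#' printed at). The ratio is `NA` when there are no negatives.
#'
#' @param ds a [compound_dataset()].
#' @return List with `n_total`, `n_plus`, `n_minus`, `n_unknown`, `ratio`.
#' @examples
#' ds <- compound_dataset(data.frame(id = 1:4,
#'   bbb_label = c("BBB+", "BBB+", "BBB-", "?")))
#' dataset_summary(ds)$ratio   # 2.0
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "compound_dataset"))
  n_plus <- sum(ds$bbb_label == "BBB_plus")
  n_minus <- sum(ds$bbb_label == "BBB_minus")
  n_unknown <- sum(ds$bbb_label == "unknown")
  list(
    n_total = nrow(ds),
    n_plus = n_plus,
    n_minus = n_minus,
    n_unknown = n_unknown,
    ratio = if (n_minus > 0) round(n_plus / n_minus, 1) else NA_real_
  )
}

#' Write per-compound predictions alongside the original table
#'
#' Writes a CSV with the dataset's columns plus `predicted` (the predicted
#' BBB label) and `rule_fired` (which rule clause produced it). The output
#' round-trips through [read_compound_table()].
#'
#' @param ds a [compound_dataset()].
#' @param predictions data.frame with columns `id`, `predicted` and
#'   optionally `rule_fired`, as produced by [classify_dataset()]; must
#'   cover exactly the dataset's ids.
#' @param path output CSV path.
#' @return The output path, invisibly.
#' @export
write_predictions <- function(ds, predictions, path) {
  stopifnot(inherits(ds, "compound_dataset"))
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  if (!all(c("id", "predicted") %in% names(predictions))) {
    stop("predictions need 'id' and 'predicted' columns", call. = FALSE)
  }
  idx <- match(ds$id, as.character(predictions$id))
  if (anyNA(idx) || nrow(predictions) != nrow(ds)) {
    missing_ids <- setdiff(ds$id, predictions$id)
    extra <- setdiff(predictions$id, ds$id)
    stop("alignment error: predictions do not match dataset ids (",
         "missing: ", length(missing_ids), ", extraneous: ", length(extra), ")",
         call. = FALSE)
  }
  out <- as.data.frame(ds)
  out$predicted <- predictions$predicted[idx]
  out$rule_fired <- if ("rule_fired" %in% names(predictions))
    predictions$rule_fired[idx] else NA_character_
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
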