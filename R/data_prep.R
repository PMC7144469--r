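## Curation of raw bioactivity records into per-compound regression datasets.
##
## Raw tables carry one measurement per row: an activity parameter (Ki,
## log(Ki), pKi, IC50, log(IC50), pIC50), a relation symbol, a value and a
## concentration unit. Curation filters to the binding-parameter whitelist,
## the chosen relation set and the allowed units, converts everything to a
## common log10(Ki in nM) scale (IC50-family values are halved first, the
## Cheng-Prusoff-style Ki = IC50/2 convention for competitive binding), and
## aggregates repeated measurements per compound.

.PARAM_WHITELIST <- c("Ki", "logKi", "pKi", "IC50", "logIC50", "pIC50")
.RELATIONS_EXTENDED <- c("=", "<", ">", "<=", ">=", "~")
.UNIT_TO_NM <- c(M = 1e9, mM = 1e6, uM = 1e3, nM = 1, pM = 1e-3, fM = 1e-6)

## Canonicalize parameter / relation / unit spellings found in exports.
normalizeParameter <- function(x) {
  x <- trimws(as.character(x))
  map <- c("Ki" = "Ki", "KI" = "Ki", "ki" = "Ki",
           "log(Ki)" = "logKi", "logKi" = "logKi", "Log Ki" = "logKi",
           "pKi" = "pKi", "pKI" = "pKi",
           "IC50" = "IC50", "ic50" = "IC50",
           "log(IC50)" = "logIC50", "logIC50" = "logIC50",
           "Log IC50" = "logIC50",
           "pIC50" = "pIC50")
  out <- unname(map[x])
  out[is.na(out)] <- NA_character_
  out
}

normalizeRelation <- function(x) {
  x <- trimws(as.character(x))
  x[x == "≤" | x == "=<"] <- "<="
  x[x == "≥" | x == "=>"] <- ">="
  x[!x %in% .RELATIONS_EXTENDED] <- NA_character_
  x
}

normalizeUnit <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("µM", "μM", "uM")] <- "uM"
  x[x == ""] <- NA_character_
  x[!is.na(x) & !x %in% names(.UNIT_TO_NM)] <-
    paste0("unknown:", x[!is.na(x) & !x %in% names(.UNIT_TO_NM)])
  x
}

#' Read an activity-record table
#'
#' Reads a CSV/TSV export of bioactivity measurements and maps its columns to
#' the internal record schema. Defaults follow ChEMBL-export-like headers.
#'
#' @param path path to a CSV or TSV file (separator sniffed from the
#'   extension: `.tsv`/`.txt` read as tab-separated).
#' @param columns named list mapping internal fields (`compound_id`, `smiles`,
#'   `parameter`, `relation`, `value`, `unit`, `organism`) to column names in
#'   the file. Fields whose column is absent are filled with `NA` (and the
#'   organism filter becomes a no-op).
#' @return data.frame of typed activity records with columns `record_id`,
#'   `compound_id`, `smiles`, `parameter`, `relation`, `value`, `unit`,
#'   `organism`.
#' @export
readActivityRecords <- function(path,
                                columns = list(
                                  compound_id = "molecule_chembl_id",
                                  smiles = "canonical_smiles",
                                  parameter = "standard_type",
                                  relation = "standard_relation",
                                  value = "standard_value",
                                  unit = "standard_units",
                                  organism = "organism")) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", encoding = "UTF-8",
                           check.names = FALSE)
  pick <- function(field) {
    col <- columns[[field]]
    if (!is.null(col) && col %in% names(raw)) return(raw[[col]])
    ## fall back to the package's own record schema (e.g. tables written
    ## by the synthetic generator)
    if (field %in% names(raw)) return(raw[[field]])
    rep(NA, nrow(raw))
  }
  activityRecords(
    compound_id = as.character(pick("compound_id")),
    smiles = as.character(pick("smiles")),
    parameter = pick("parameter"),
    relation = pick("relation"),
    value = suppressWarnings(as.numeric(pick("value"))),
    unit = pick("unit"),
    organism = as.character(pick("organism")),
    record_id = if ("record_id" %in% names(raw)) raw$record_id else NULL)
}

#' Build a typed activity-record table from vectors
#'
#' @param compound_id,smiles,parameter,relation,value,unit,organism aligned
#'   vectors, one element per measurement. `parameter`, `relation` and `unit`
#'   are canonicalized (unknown spellings are kept, marked, and dropped later
#'   by [filterRecords()] rather than raising an error).
#' @param record_id optional record identifiers; generated when missing.
#' @return data.frame of typed records.
#' @export
activityRecords <- function(compound_id, parameter, relation, value,
                            unit = NA, smiles = NA, organism = NA,
                            record_id = NULL) {
  n <- length(compound_id)
  if (is.null(record_id)) record_id <- sprintf("rec_%05d", seq_len(n))
  df <- data.frame(
    record_id = as.character(record_id),
    compound_id = as.character(compound_id),
    smiles = as.character(rep_len(smiles, n)),
    parameter = normalizeParameter(rep_len(parameter, n)),
    parameter_raw = as.character(rep_len(parameter, n)),
    relation = normalizeRelation(rep_len(relation, n)),
    value = as.numeric(rep_len(value, n)),
    unit = normalizeUnit(rep_len(unit, n)),
    organism = as.character(rep_len(organism, n)),
    stringsAsFactors = FALSE)
  df
}

#' Filter activity records through the curation protocol
#'
#' Applies, in order: (1) an optional organism filter (a no-op when the
#' organism column is all-`NA`), (2) the binding-parameter whitelist
#' (Ki, log(Ki), pKi, IC50, log(IC50), pIC50), (3) the relation filter —
#' `"strict"` keeps only `=`; `"extended"` keeps `=`, `<`, `>`, `<=`, `>=`,
#' `~` — and (4) the unit filter: concentration parameters (Ki, IC50) must
#' carry a unit in \{M, mM, uM, nM, pM, fM\}; log/p-form parameters carry
#' none (any stray unit on them is ignored). Records with unknown parameter
#' or unit strings are dropped and counted, never an error.
#'
#' @param records data.frame from [activityRecords()] / [readActivityRecords()].
#' @param relation_mode `"strict"` or `"extended"`.
#' @param organism_keep regular expression; records whose organism is non-`NA`
#'   and does not match are dropped. Default keeps human-related rows.
#' @return list with `records` (the surviving rows) and `report`, a
#'   data.frame of `(stage, records_in, records_out)` in protocol order.
#' @examples
#' recs <- activityRecords(c("a", "b"), "Ki", c("=", "<"), c(10, 20), "nM")
#' filterRecords(recs, "strict")$report
#' @export
filterRecords <- function(records, relation_mode = c("strict", "extended"),
                          organism_keep = "Homo sapiens|^human$") {
  relation_mode <- match.arg(relation_mode)
  report <- data.frame(stage = character(0), records_in = integer(0),
                       records_out = integer(0), stringsAsFactors = FALSE)
  stage <- function(name, keep) {
    n_in <- nrow(records)
    records <<- records[keep, , drop = FALSE]
    report <<- rbind(report, data.frame(stage = name, records_in = n_in,
                                        records_out = nrow(records),
                                        stringsAsFactors = FALSE))
  }

  org <- records$organism
  keep_org <- is.na(org) | grepl(organism_keep, org, ignore.case = TRUE)
  stage("organism_filter", keep_org)

  stage("parameter_filter",
        !is.na(records$parameter) & records$parameter %in% .PARAM_WHITELIST)

  allowed_rel <- if (relation_mode == "strict") "=" else .RELATIONS_EXTENDED
  stage("relation_filter",
        !is.na(records$relation) & records$relation %in% allowed_rel)

  conc <- records$parameter %in% c("Ki", "IC50")
  unit_ok <- ifelse(conc,
                    !is.na(records$unit) & records$unit %in% names(.UNIT_TO_NM),
                    TRUE)
  stage("unit_filter", unit_ok)

  if (nrow(records) == 0L)
    warning("no records survive the curation filters (empty dataset)")
  list(records = records, report = report)
}

#' Convert one measurement to the standard log-activity scale
#'
#' Standardizes a filtered record to log10 of Ki expressed in nM (so 1 nM
#' maps to 0). IC50-family values are first converted to Ki via Ki = IC50/2;
#' p-forms are interpreted as -log10 of the molar value; concentration values
#' are unit-converted to nM before taking logs. Plain `logKi` / `logIC50`
#' inputs are rejected unless `log_form` spells out their base and unit,
#' because exports do not define them — silent misinterpretation is worse
#' than rejection.
#'
#' @param parameter one of `Ki`, `logKi`, `pKi`, `IC50`, `logIC50`, `pIC50`.
#' @param relation relation symbol (kept for interface symmetry; the value is
#'   standardized regardless of relation — filtering happens earlier).
#' @param value numeric measurement in the parameter's native scale.
#' @param unit concentration unit for Ki/IC50; ignored for log/p forms.
#' @param log_convention `"lognM"` (default; log10 Ki in nM) or `"pKi"`
#'   (-log10 Ki in M).
#' @param log_form `NULL` (reject plain log forms) or a list
#'   `list(base = 10, unit = "nM")` declaring how `logKi` / `logIC50` values
#'   are encoded.
#' @return single numeric log-activity; errors on non-positive
#'   concentrations (log undefined) and undeclared plain log forms.
#' @examples
#' standardizeValue("IC50", "=", 100, "nM")  # log10(50)
#' standardizeValue("Ki", "=", 1, "uM")      # 3
#' @export
standardizeValue <- function(parameter, relation, value, unit = NA,
                             log_convention = c("lognM", "pKi"),
                             log_form = NULL) {
  log_convention <- match.arg(log_convention)
  parameter <- normalizeParameter(parameter)
  if (is.na(parameter) || !parameter %in% .PARAM_WHITELIST)
    stop("unknown activity parameter")
  if (!is.finite(value)) stop("non-finite activity value")

  lognm <- if (parameter %in% c("Ki", "IC50")) {
    u <- normalizeUnit(unit)
    if (is.na(u) || !u %in% names(.UNIT_TO_NM))
      stop("missing or unknown concentration unit '", unit, "'")
    v_nm <- value * .UNIT_TO_NM[[u]]
    if (parameter == "IC50") v_nm <- v_nm / 2
    if (v_nm <= 0)
      stop("non-positive concentration (", value, " ", u,
           "): logarithm undefined, record rejected")
    log10(v_nm)
  } else if (parameter %in% c("pKi", "pIC50")) {
    ## pX = -log10(molar); in nM: log10(nM) = 9 - pX. IC50 halving subtracts
    ## log10(2) on the log scale.
    l <- 9 - value
    if (parameter == "pIC50") l <- l - log10(2)
    l
  } else { # logKi / logIC50
    if (is.null(log_form))
      stop("plain log-form parameter '", parameter,
           "' has no defined base/unit; configure 'log_form' or drop it")
    base <- log_form$base %||% 10
    u <- normalizeUnit(log_form$unit %||% "nM")
    if (!u %in% names(.UNIT_TO_NM)) stop("unknown log_form unit")
    l <- value * log(base, 10) + log10(.UNIT_TO_NM[[u]])
    if (parameter == "logIC50") l <- l - log10(2)
    l
  }
  if (log_convention == "pKi") 9 - lognm else lognm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a table of filtered records
#'
#' Vectorized wrapper around [standardizeValue()]: records that cannot be
#' standardized (non-positive concentration, undeclared plain log form) are
#' dropped with a per-reason count rather than raising.
#'
#' @inheritParams standardizeValue
#' @param records filtered record data.frame.
#' @return list with `records` (surviving rows plus a `log_activity` column)
#'   and `rejected`, a data.frame of `record_id`, `reason`.
#' @export
standardizeRecords <- function(records, log_convention = "lognM",
                               log_form = NULL) {
  n <- nrow(records)
  la <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      standardizeValue(records$parameter[i], records$relation[i],
                       records$value[i], records$unit[i],
                       log_convention = log_convention, log_form = log_form),
      error = function(e) e)
    if (inherits(res, "error")) reason[i] <- conditionMessage(res)
    else la[i] <- res
  }
  ok <- is.na(reason)
  out <- records[ok, , drop = FALSE]
  out$log_activity <- la[ok]
  list(records = out,
       rejected = data.frame(record_id = records$record_id[!ok],
                             reason = reason[!ok], stringsAsFactors = FALSE))
}

#' Aggregate standardized records per compound
#'
#' Groups standardized measurements by compound and computes the count, the
#' log-scale mean (the default regression label), the population standard
#' deviation (divide-by-n, so a single measurement has spread exactly 0) and
#' the nM-scale mean Ki for reporting. Compounds are emitted sorted by id.
#'
#' @param records data.frame with `compound_id`, `smiles`, `log_activity`
#'   (output of [standardizeRecords()]).
#' @param label_scale `"log"` (label = mean of log-activities, default) or
#'   `"nM"` (label = log10 of the nM-scale mean Ki).
#' @return data.frame with one row per compound: `compound_id`, `smiles`,
#'   `n_values`, `mean_log_activity`, `std_log_activity`, `mean_ki_nm`,
#'   `label`.
#' @examples
#' recs <- activityRecords("CHEMBL139089", "Ki", "=", c(37, 68.2), "nM")
#' std <- standardizeRecords(recs)$records
#' aggregateCompounds(std)
#' @export
aggregateCompounds <- function(records, label_scale = c("log", "nM")) {
  label_scale <- match.arg(label_scale)
  stopIfNot(nrow(records) > 0, "no standardized records to aggregate")
  ids <- sort(unique(records$compound_id))
  rows <- lapply(ids, function(id) {
    g <- records[records$compound_id == id, , drop = FALSE]
    smi <- unique(g$smiles[!is.na(g$smiles)])
    if (length(smi) > 1L)
      stop("conflicting SMILES for compound '", id, "'")
    la <- g$log_activity
    mean_log <- mean(la)
    mean_nm <- mean(10^la)
    data.frame(compound_id = id,
               smiles = if (length(smi)) smi else NA_character_,
               n_values = length(la),
               mean_log_activity = mean_log,
               std_log_activity = popSd(la),
               mean_ki_nm = mean_nm,
               label = if (label_scale == "log") mean_log else log10(mean_nm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full curation pipeline on a record table
#'
#' Convenience wrapper: [filterRecords()], [standardizeRecords()] (counted as
#' an extra `standardization` report stage), [aggregateCompounds()].
#'
#' @inheritParams filterRecords
#' @inheritParams standardizeRecords
#' @inheritParams aggregateCompounds
#' @return list with `compounds` (curated table), `records` (standardized
#'   surviving records), `report` (per-stage counts incl. standardization),
#'   `rejected` (standardization rejections with reasons).
#' @export
prepareActivityData <- function(records, relation_mode = "strict",
                                organism_keep = "Homo sapiens|^human$",
                                log_convention = "lognM", log_form = NULL,
                                label_scale = "log") {
  filt <- filterRecords(records, relation_mode, organism_keep)
  std <- standardizeRecords(filt$records, log_convention, log_form)
  report <- rbind(filt$report,
                  data.frame(stage = "standardization",
                             records_in = nrow(filt$records),
                             records_out = nrow(std$records),
                             stringsAsFactors = FALSE))
  if (nrow(std$records) == 0L)
    stop("empty dataset: no records survive standardization")
  list(compounds = aggregateCompounds(std$records, label_scale),
       records = std$records, report = report, rejected = std$rejected)
}

#' Unit conversion helpers
#'
#' `unitToNm()` converts a concentration to nM; `nmToUnit()` inverts it.
#' Round-tripping is exact to floating point for all six supported units.
#'
#' @param value numeric concentration.
#' @param unit one of `M`, `mM`, `uM` (µM accepted), `nM`, `pM`, `fM`.
#' @return numeric.
#' @export
unitToNm <- function(value, unit) {
  u <- normalizeUnit(unit)
  stopIfNot(all(u %in% names(.UNIT_TO_NM)), "unknown unit")
  value * unname(.UNIT_TO_NM[u])
}

#' @rdname unitToNm
#' @export
nmToUnit <- function(value, unit) {
  u <- normalizeUnit(unit)
  stopIfNot(all(u %in% names(.UNIT_TO_NM)), "unknown unit")
  value / unname(.UNIT_TO_NM[u])
}
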