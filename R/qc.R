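# Collagen quality control: exclude diagenetically altered specimens and
# age-ineligible animals before any statistics.

#' Quality-control thresholds for bone collagen
#'
#' Closed acceptance intervals for the standard collagen-purity indicators.
#' Defaults follow the conventional screens for isotope work on
#' archaeological bone: atomic C:N in \[2.9, 3.6\], atomic C:S in
#' \[300, 900\], atomic N:S in \[100, 300\] and weight %S in \[0.15, 0.35\].
#' Animals with a known age at or below `min_age_exclusive_years` are
#' excluded because nursing enriches nitrogen.
#'
#' @param cn_range,cs_range,ns_range,pctS_range Length-2 numeric intervals.
#' @param min_age_exclusive_years Known ages `<=` this are excluded (years).
#' @param require_sulfur_qc If `TRUE`, specimens lacking the sulfur fields
#'   fail the sulfur criteria instead of being recorded as not evaluable.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cn_range = c(2.9, 3.6),
                          cs_range = c(300, 900),
                          ns_range = c(100, 300),
                          pctS_range = c(0.15, 0.35),
                          min_age_exclusive_years = 2,
                          require_sulfur_qc = FALSE) {
  chk <- function(r, nm) {
    if (length(r) != 2 || anyNA(r) || r[1] > r[2])
      stop(nm, " must be a length-2 interval with lo <= hi")
    as.numeric(r)
  }
  structure(list(
    cn_range = chk(cn_range, "cn_range"),
    cs_range = chk(cs_range, "cs_range"),
    ns_range = chk(ns_range, "ns_range"),
    pctS_range = chk(pctS_range, "pctS_range"),
    min_age_exclusive_years = min_age_exclusive_years,
    require_sulfur_qc = isTRUE(require_sulfur_qc)),
    class = "qc_thresholds")
}

#' Assess one specimen against the collagen-purity criteria
#'
#' Every criterion whose inputs exist is checked; intervals are closed, so a
#' boundary value passes. Criteria whose inputs are missing are listed as
#' not evaluable and, by default policy, do not fail the record (set
#' `require_sulfur_qc` in [qc_thresholds()] to tighten this for the sulfur
#' screens).
#'
#' @param record A one-row data.frame (or list) with fields `CN`, `CS`, `NS`,
#'   `pct_S` as available (see [read_specimens()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_result`: `specimen_id`, `passed`,
#'   `failures` (data.frame criterion/observed/lo/hi), `not_evaluable`.
#' @export
assess_collagen <- function(record, thresholds = qc_thresholds()) {
  crit <- list(CN = thresholds$cn_range, CS = thresholds$cs_range,
               NS = thresholds$ns_range, pct_S = thresholds$pctS_range)
  sulfur <- c("CS", "NS", "pct_S")
  fail <- data.frame(criterion = character(), observed = numeric(),
                     lo = numeric(), hi = numeric())
  not_eval <- character()
  for (nm in names(crit)) {
    x <- record[[nm]]
    x <- if (is.null(x)) NA_real_ else as.numeric(x)[1]
    if (is.na(x)) {
      if (thresholds$require_sulfur_qc && nm %in% sulfur) {
        fail <- rbind(fail, data.frame(criterion = nm, observed = NA_real_,
                                       lo = crit[[nm]][1], hi = crit[[nm]][2]))
      } else not_eval <- c(not_eval, nm)
      next
    }
    if (x < crit[[nm]][1] || x > crit[[nm]][2])
      fail <- rbind(fail, data.frame(criterion = nm, observed = x,
                                     lo = crit[[nm]][1], hi = crit[[nm]][2]))
  }
  structure(list(
    specimen_id = as.character(record[["specimen_id"]] %||% NA_character_),
    passed = nrow(fail) == 0L,
    failures = fail,
    not_evaluable = not_eval), class = "qc_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter specimens by age eligibility
#'
#' Removes animals with a known age at or below the threshold (default 2
#' years, when the mother's milk still shapes the nitrogen signature), the
#' `cub` age class, and records of entirely unknown age unless they were
#' judged adult from bone size (`unknown_adult_by_bone_size`, retained with
#' a provenance note). Order-preserving and deterministic.
#'
#' @param records Specimen data.frame with `age_class` and optional
#'   `age_years` columns.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `retained` (with a `provenance` column) and
#'   `excluded` (with a `reason` column).
#' @export
filter_age <- function(records, thresholds = qc_thresholds()) {
  n <- nrow(records)
  age <- if (!is.null(records$age_years)) as.numeric(records$age_years)
         else rep(NA_real_, n)
  cls <- if (!is.null(records$age_class)) as.character(records$age_class)
         else rep("unknown", n)
  cutoff <- thresholds$min_age_exclusive_years
  reason <- rep(NA_character_, n)
  reason[!is.na(age) & age <= cutoff] <-
    sprintf("known age <= %s years", cutoff)
  reason[is.na(reason) & cls == "cub"] <- "cub age class"
  reason[is.na(reason) & cls == "unknown"] <- "age unknown, not adult by bone size"
  keep <- is.na(reason)
  retained <- records[keep, , drop = FALSE]
  retained$provenance <- ifelse(cls[keep] == "unknown_adult_by_bone_size",
                                "adult judged from bone size", "age record")
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = retained, excluded = excluded)
}

#' Run the full quality-control stage
#'
#' Applies [filter_age()] then [assess_collagen()] to every record. The
#' exclusion log holds one row per failed criterion (or per age exclusion),
#' ready to be written as CSV.
#'
#' @param records Specimen data.frame (see [read_specimens()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `clean` (retained records) and `log` (data.frame
#'   `specimen_id`, `stage`, `criterion`, `observed`, `lo`, `hi`).
#' @export
run_qc <- function(records, thresholds = qc_thresholds()) {
  logs <- list()
  aged <- filter_age(records, thresholds)
  if (nrow(aged$excluded))
    logs[[1]] <- data.frame(specimen_id = aged$excluded$specimen_id,
                            stage = "age", criterion = aged$excluded$reason,
                            observed = NA_real_, lo = NA_real_, hi = NA_real_)
  keep <- logical(nrow(aged$retained))
  for (i in seq_len(nrow(aged$retained))) {
    res <- assess_collagen(aged$retained[i, ], thresholds)
    keep[i] <- res$passed
    if (!res$passed)
      logs[[length(logs) + 1L]] <- cbind(
        data.frame(specimen_id = res$specimen_id, stage = "collagen"),
        res$failures)
  }
  clean <- aged$retained[keep, , drop = FALSE]
  if (!nrow(clean)) warning("no specimens passed quality control")
  log <- if (length(logs)) do.call(rbind, logs)
         else data.frame(specimen_id = character(), stage = character(),
                         criterion = character(), observed = numeric(),
                         lo = numeric(), hi = numeric())
  rownames(log) <- NULL
  list(clean = clean, log = log)
}
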