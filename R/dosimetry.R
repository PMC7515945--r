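# Staff radiation-exposure bookkeeping and the procedures-to-limit
# extrapolation.

#' Dose records for surgical staff
#'
#' One row per staff role with the measured personal dose per procedure
#' (electronic personal dosimeter reading, mSv) and the applicable annual
#' dose limit. The default limit of 1 mSv is the public annual limit;
#' classified radiation workers may use 6 or 20 mSv.
#'
#' @param role character vector of roles (e.g. "scrub_nurse", "surgeon",
#'   "anaesthetist", "periphery_nurse", "researcher")
#' @param dose dose per procedure (mSv), >= 0
#' @param limit annual dose limit (mSv), > 0
#' @return data.frame with columns role, dose_mSv, annual_limit_mSv
#' @examples
#' doseRecords(c("scrub_nurse", "surgeon"), c(0.016, 0.005))
#' @export
doseRecords <- function(role, dose, limit = 1) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(limit <= 0)) stop("annual limit must be > 0")
  data.frame(role = role, dose_mSv = dose, annual_limit_mSv = limit,
             stringsAsFactors = FALSE)
}

#' Maximum procedures before reaching the annual dose limit
#'
#' `floor(limit / dose)` procedures per year; a zero dose returns `Inf`
#' (unlimited).
#'
#' @param dose dose per procedure (mSv), >= 0 (vectorized)
#' @param limit annual dose limit (mSv), > 0
#' @return integer-valued numeric; `Inf` for zero dose
#' @examples
#' maxProcedures(0.016)  # 62 procedures at the 1 mSv public limit
#' maxProcedures(0.005)  # 200
#' @export
maxProcedures <- function(dose, limit = 1) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(limit <= 0)) stop("annual limit must be > 0")
  ifelse(dose == 0, Inf, floor(limit / dose))
}

#' Cohort dose report
#'
#' One row per record with the procedures-to-limit extrapolation, sorted by
#' descending dose; roles whose single-procedure dose already exceeds the
#' annual limit are flagged.
#'
#' @param records data.frame from [doseRecords()] (or a CSV read with the
#'   same columns)
#' @return data.frame (role, dose_mSv, annual_limit_mSv, max_procedures,
#'   over_limit) sorted by descending dose
#' @examples
#' cohortDoseReport(doseRecords(
#'   c("scrub_nurse", "anaesthetist", "surgeon", "periphery_nurse",
#'     "researcher"),
#'   c(0.016, 0.001, 0.005, 0.002, 0.001)))
#' @export
cohortDoseReport <- function(records) {
  if (nrow(records) == 0) stop("no dose records")
  records$max_procedures <- maxProcedures(records$dose_mSv,
                                          records$annual_limit_mSv)
  records$over_limit <- records$dose_mSv > records$annual_limit_mSv
  records[order(-records$dose_mSv), , drop = FALSE]
}

#' Read dose records from CSV
#'
#' Expects columns `role` and `dose_mSv`; an optional `annual_limit_mSv`
#' column overrides the default limit.
#'
#' @param path CSV path
#' @param limit default annual limit (mSv) when the file has none
#' @return data.frame as from [doseRecords()]
#' @export
readDoseCsv <- function(path, limit = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("role", "dose_mSv") %in% names(df)))
    stop("dose CSV needs columns role, dose_mSv")
  if (is.null(df$annual_limit_mSv)) df$annual_limit_mSv <- limit
  doseRecords(df$role, df$dose_mSv, df$annual_limit_mSv)
}
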