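.dataset_cols <- c("ID", "TIME", "EVID", "AMT", "ROUTE", "DVID", "DV",
                   "BLQ", "GROUP")

#' Write a study dataset to CSV
#'
#' NONMEM-like long layout, one row per dose event or observation, with the
#' exact header `ID,TIME,EVID,AMT,ROUTE,DVID,DV,BLQ,GROUP`. Missing fields
#' (e.g. `DV` on dose rows) are written as empty cells. Numeric values are
#' written with 17 significant digits so a write/read round trip reproduces
#' the dataset exactly.
#'
#' @param dataset A `study_dataset` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(all(.dataset_cols %in% names(dataset)))
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  fmt_int <- function(x) ifelse(is.na(x), "", as.character(as.integer(x)))
  out <- data.frame(
    ID = fmt_int(dataset$ID), TIME = fmt_num(dataset$TIME),
    EVID = fmt_int(dataset$EVID), AMT = fmt_num(dataset$AMT),
    ROUTE = ifelse(is.na(dataset$ROUTE), "", dataset$ROUTE),
    DVID = fmt_int(dataset$DVID), DV = fmt_num(dataset$DV),
    BLQ = fmt_int(dataset$BLQ), GROUP = fmt_int(dataset$GROUP),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a study dataset
#'
#' Parses the CSV layout written by [write_dataset()] and validates it,
#' collecting every violation before failing: exact header, numeric fields,
#' dose rows carrying `AMT`/`ROUTE` but no `DV`, observation rows carrying
#' `DVID`/`DV`/`BLQ` but no dose fields, non-negative `DV`, no duplicate
#' `(ID, TIME, DVID)` observations, and at least one dose event per subject
#' at or before its first observation. Errors report 1-based file line
#' numbers (the header is line 1).
#'
#' @param path CSV file path.
#' @return A `study_dataset` tibble.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!identical(names(raw), .dataset_cols)) {
    stop("bad header: expected ", paste(.dataset_cols, collapse = ","),
         " got ", paste(names(raw), collapse = ","), call. = FALSE)
  }
  errs <- character(0)
  note <- function(line, msg) {
    errs <<- c(errs, sprintf("line %d: %s", line + 1L, msg))
  }
  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  ID <- num(raw$ID); TIME <- num(raw$TIME); EVID <- num(raw$EVID)
  AMT <- num(raw$AMT); DVID <- num(raw$DVID); DV <- num(raw$DV)
  BLQ <- num(raw$BLQ); GROUP <- num(raw$GROUP)
  for (i in seq_len(n)) {
    if (is.na(ID[i]) || ID[i] != round(ID[i])) note(i, "ID must be an integer")
    if (is.na(TIME[i]) && nzchar(raw$TIME[i])) note(i, "malformed TIME")
    if (is.na(TIME[i]) && !nzchar(raw$TIME[i])) note(i, "missing TIME")
    if (!EVID[i] %in% c(0, 1)) note(i, "EVID must be 0 or 1")
    if (!GROUP[i] %in% c(0, 1)) note(i, "GROUP must be 0 or 1")
    if (isTRUE(EVID[i] == 1)) {
      if (is.na(AMT[i]) || AMT[i] < 0) note(i, "dose row needs AMT >= 0")
      if (!raw$ROUTE[i] %in% c("ORAL_TEG", "IV_5FU")) {
        note(i, "dose row needs ROUTE ORAL_TEG or IV_5FU")
      }
      if (nzchar(raw$DV[i])) note(i, "DV must be empty on dose rows")
      if (nzchar(raw$DVID[i])) note(i, "DVID must be empty on dose rows")
    } else if (isTRUE(EVID[i] == 0)) {
      if (!DVID[i] %in% c(1, 2, 3)) note(i, "observation needs DVID 1, 2 or 3")
      if (is.na(DV[i])) note(i, "observation needs a numeric DV")
      else if (DV[i] < 0) note(i, "DV must be non-negative")
      if (!BLQ[i] %in% c(0, 1)) note(i, "observation needs BLQ 0 or 1")
      if (nzchar(raw$AMT[i])) note(i, "AMT must be empty on observations")
      if (nzchar(raw$ROUTE[i])) note(i, "ROUTE must be empty on observations")
    }
  }
  obs_key <- paste(raw$ID, raw$TIME, raw$DVID)[EVID == 0]
  dup <- duplicated(obs_key)
  if (any(dup)) {
    lines <- which(EVID == 0)[dup]
    for (i in lines) note(i, "duplicate (ID, TIME, DVID) observation")
  }
  for (id in unique(ID[!is.na(ID)])) {
    has_dose <- any(EVID == 1 & ID == id, na.rm = TRUE)
    if (!has_dose) {
      note(which(ID == id)[1], sprintf("subject %d has no dose event", id))
    } else {
      t_dose <- min(TIME[EVID == 1 & ID == id], na.rm = TRUE)
      t_obs <- TIME[EVID == 0 & ID == id & TIME > 0]
      if (length(t_obs) > 0 && min(t_obs) < t_dose) {
        note(which(ID == id)[1],
             sprintf("subject %d observed before first dose", id))
      }
    }
  }
  if (length(errs) > 0) {
    stop("invalid dataset:\n", paste(errs, collapse = "\n"), call. = FALSE)
  }
  .as_study_dataset(tibble::tibble(
    ID = as.integer(ID), TIME = TIME, EVID = as.integer(EVID), AMT = AMT,
    ROUTE = ifelse(nzchar(raw$ROUTE), raw$ROUTE, NA_character_),
    DVID = as.integer(DVID), DV = DV, BLQ = as.integer(BLQ),
    GROUP = as.integer(GROUP)
  ))
}

#' Published noncompartmental summary of the rat study
#'
#' The published group summaries (mean, SD, n = 5 per group) of the
#' noncompartmental parameters of tegafur, 5-FU and gimeracil after oral S-1
#' in rats pretreated with vehicle (control) or with single/repeated doses
#' of Sipjeondaebo-tang (SDT). Shipped as a plain-text table; these are the
#' observed-data summaries against which the model-based pipeline is
#' checked.
#'
#' @return A tibble with columns `analyte`, `parameter`, `phase`
#'   (`single`/`multiple` pretreatment dosing), `group`, `mean`, `sd`, `n`.
#' @export
reference_nca_summary <- function() {
  path <- system.file("extdata", "reference_nca_summary.csv",
                      package = "s1pk", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pretreatment effect ratios
#'
#' The headline herb-drug interaction quantities, recomputed from the
#' published summaries and population estimates: the fold-change in 5-FU
#' clearance, the SDT-to-control percentage ratios of tegafur Cmax, of the
#' 5-FU/tegafur AUC ratio, and of gimeracil Cmax and AUC-infinity, and the
#' fold-change in 5-FU AUC-infinity (all repeated-dose pretreatment vs
#' control).
#'
#' @param summary A summary table in the layout of
#'   [reference_nca_summary()].
#' @return A tibble with columns `quantity` and `value`.
#' @export
pretreatment_effect_summary <- function(summary = reference_nca_summary()) {
  cell <- function(analyte, parameter, group) {
    v <- summary$mean[summary$analyte == analyte &
                        summary$parameter == parameter &
                        summary$phase == "multiple" &
                        summary$group == group]
    stopifnot(length(v) == 1)
    v
  }
  ratio <- function(analyte, parameter) {
    cell(analyte, parameter, "sdt") / cell(analyte, parameter, "control")
  }
  tibble::tibble(
    quantity = c("cl_5fu_fold", "teg_cmax_pct", "fu_teg_auc_ratio_pct",
                 "fu_auc_inf_fold", "gim_cmax_pct", "gim_auc_inf_pct"),
    value = c(
      reference_params("sdt")$cl_5fu / reference_params("control")$cl_5fu,
      100 * ratio("tegafur", "cmax"),
      100 * ratio("fu", "auc_ratio_pct"),
      ratio("fu", "auc_inf"),
      100 * ratio("gimeracil", "cmax"),
      100 * ratio("gimeracil", "auc_inf")
    )
  )
}
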