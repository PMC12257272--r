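#' Validate a long-format pharmacokinetic dataset
#'
#' The canonical dataset is one row per event with NONMEM-style `evid`
#' semantics: columns `id` (subject), `trial`, `route`, `bw` (kg), `time`
#' (h since the subject's first dose), `evid` (1 = dose, 0 = observation),
#' `amt` (mg/kg base, dose rows), `conc` (ug/mL, observation rows) and
#' `lloq` (ug/mL).  Validation errors name the offending rows.
#'
#' @param data a data frame in the canonical layout.
#' @return The validated data frame (row order normalised by id then time).
#' @export
validate_pk_dataset <- function(data) {
  required <- c("id", "trial", "route", "bw", "time", "evid", "amt", "conc", "lloq")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!data$route %in% pk_routes())
  if (length(bad))
    stop("unknown route label(s) in rows: ", paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(data$time) | data$time < 0)
  if (length(bad))
    stop("negative or missing time in rows: ", paste(head(bad, 5), collapse = ", "))
  bad <- which(!data$evid %in% c(0, 1))
  if (length(bad))
    stop("evid must be 0 or 1; offending rows: ", paste(head(bad, 5), collapse = ", "))
  bad <- which(data$evid == 1 & (!is.finite(data$amt) | data$amt <= 0))
  if (length(bad))
    stop("dose rows need positive amt; offending rows: ", paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(data$bw) | data$bw <= 0)
  if (length(bad))
    stop("bw must be positive; offending rows: ", paste(head(bad, 5), collapse = ", "))
  # every subject needs a dose at or before its first observation
  for (s in unique(data$id)) {
    sub <- data[data$id == s, ]
    if (!any(sub$evid == 1))
      stop("subject ", s, " has observations but no dose event")
    if (min(sub$time[sub$evid == 1]) > min(sub$time[sub$evid == 0], Inf))
      stop("subject ", s, " has an observation before its first dose")
  }
  data[order(data$id, data$time, -data$evid), , drop = FALSE]
}

#' Read a long-format PK dataset from CSV
#'
#' @param path CSV file (comma-separated, header row; times in hours,
#'   concentrations in ug/mL, doses in mg/kg doxycycline base).
#' @return Validated dataset data frame.
#' @seealso [validate_pk_dataset()] for the column contract,
#'   [write_pk_dataset()] for the inverse.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pk_dataset(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a long-format PK dataset to CSV
#'
#' @param data a validated dataset.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  data <- validate_pk_dataset(data)
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}
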