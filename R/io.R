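# CSV round trip for the dataset tables. Dates are ISO-8601; missing values
# are empty fields. Writing the same dataset twice produces byte-identical
# files.

DATASET_TABLES <- c("children", "mothers", "clinical_events", "use_events",
                    "codelist", "tariffs", "cpi", "population")

DATE_COLS <- list(
  children = c("birth_date", "death_date", "registration_start",
               "registration_end", "practice_uts_date",
               "practice_collection_end"),
  mothers = c("registration_start", "registration_end", "death_date",
              "practice_uts_date", "practice_collection_end"),
  clinical_events = "date",
  use_events = "date"
)

#' Write a dataset to a directory of CSV files
#'
#' Emits `children.csv`, `mothers.csv`, `clinical_events.csv`,
#' `use_events.csv`, `codelists.csv`, `tariffs.csv`, `cpi.csv` and
#' `population.csv`. The `truth` component is not written (it is simulation
#' metadata, not data a real extract would carry).
#'
#' @param dataset an `mmi_dataset` from [simulate_cohort()], or any list with
#'   the table components.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create directory: ", directory, call. = FALSE)
    }
  }
  files <- c(codelist = "codelists.csv")
  for (tab in DATASET_TABLES) {
    if (is.null(dataset[[tab]])) next
    fname <- if (tab %in% names(files)) files[[tab]] else paste0(tab, ".csv")
    fwrite(as.data.table(dataset[[tab]]), file.path(directory, fname),
           dateTimeAs = "ISO")
  }
  invisible(directory)
}

#' Read a dataset back from a directory of CSV files
#'
#' @param directory directory written by [write_dataset()].
#' @return list with the dataset tables (no `truth`).
#' @export
read_dataset <- function(directory) {
  out <- list()
  files <- c(codelist = "codelists.csv")
  for (tab in DATASET_TABLES) {
    fname <- if (tab %in% names(files)) files[[tab]] else paste0(tab, ".csv")
    path <- file.path(directory, fname)
    if (!file.exists(path)) next
    dt <- fread(path, na.strings = c("", "NA"))
    for (cc in intersect(DATE_COLS[[tab]], names(dt))) {
      set(dt, j = cc, value = as_date(dt[[cc]]))
    }
    out[[tab]] <- setDF(dt)
  }
  out
}
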