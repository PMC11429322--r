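# NONMEM-dialect rectangular CSV I/O: missing fields are ".", dosing rows
# carry AMT/RATE with MDV 1, observation rows carry DV with EVID 0.

#' Write a NONMEM-style dataset to CSV
#'
#' Numeric fields are written with 17 significant digits so a write/read
#' round trip is lossless; missing values become `"."`.
#'
#' @param data Dataset (e.g. from [generate_study()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nonmem_csv <- function(data, path) {
  fmt <- lapply(data, function(col) {
    if (is.numeric(col)) {
      out <- vapply(col, function(x) {
        if (is.na(x)) "." else formatC(x, digits = 17, format = "g")
      }, character(1))
    } else {
      out <- as.character(col)
      out[is.na(out)] <- "."
    }
    out
  })
  fmt <- as.data.frame(fmt, stringsAsFactors = FALSE, optional = TRUE)
  names(fmt) <- names(data)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NONMEM-style CSV dataset
#'
#' @param path File path.
#' @return `data.frame` with `"."` parsed as `NA` and numeric columns restored.
#' @export
read_nonmem_csv <- function(path) {
  out <- utils::read.csv(path, na.strings = ".", stringsAsFactors = FALSE)
  for (nm in names(out)) {
    if (is.character(out[[nm]])) {
      suppressWarnings(num <- as.numeric(out[[nm]]))
      if (!any(is.na(num) & !is.na(out[[nm]]))) out[[nm]] <- num
    }
  }
  out
}

#' Per-subject profiles from a NONMEM-style dataset
#'
#' @param data Dataset with `ID`, `TIME`, `DV`, `EVID`, `AMT`, `RATE` columns.
#' @return Named list of [subject_profile()]s (names are subject IDs).
#' @export
profiles_from_dataset <- function(data) {
  stopifnot(all(c("ID", "TIME", "DV", "EVID", "AMT", "RATE") %in% names(data)))
  lapply(split(data, data$ID), function(d) {
    dose_row <- d[d$EVID == 1, ][1, ]
    obs <- d[d$EVID == 0, ]
    subject_profile(obs$TIME, obs$DV, dose = dose_row$AMT,
                    tinf = dose_row$AMT / dose_row$RATE, id = dose_row$ID)
  })
}
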