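#' Validate a cohort mortality table
#'
#' Checks that a data frame is a valid mortality table: columns `cohort`,
#' `sex`, `age`, `deaths`, `exposure`; ages strictly increasing contiguous
#' integers within each (cohort, sex) series; non-negative deaths and
#' exposures; and no deaths recorded at ages with zero exposure. Errors name
#' the offending row.
#'
#' @param data A data frame with columns `cohort`, `sex`, `age`, `deaths`,
#'   `exposure`.
#' @return The validated table, as a tibble, invisibly usable in pipes.
#' @export
validate_mortality_table <- function(data) {
  required <- c("cohort", "sex", "age", "deaths", "exposure")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("mortality table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("mortality table has no rows", call. = FALSE)
  bad <- which(!is.finite(data$age) | data$age < 0 | data$age != floor(data$age))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": age must be a non-negative integer", call. = FALSE)
  }
  bad <- which(!is.finite(data$deaths) | data$deaths < 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": deaths must be >= 0", call. = FALSE)
  }
  bad <- which(!is.finite(data$exposure) | data$exposure < 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": exposure must be >= 0", call. = FALSE)
  }
  bad <- which(data$exposure == 0 & data$deaths > 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], ": deaths > 0 with zero exposure", call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(data)),
                     paste(data$cohort, data$sex, sep = "\r"))
  for (idx in split_idx) {
    ages <- data$age[idx]
    step <- diff(ages)
    if (any(step != 1)) {
      stop("row ", idx[which(step != 1)[1] + 1L],
           ": ages must be contiguous increasing integers", call. = FALSE)
    }
  }
  data
}

#' Write a mortality table to a tab-separated file
#'
#' Canonical on-disk format: optional `#`-prefixed header comments recording
#' provenance (generator parameters and seed, when the table carries them as
#' attributes), then a TSV with columns `cohort`, `sex`, `age`, `deaths`,
#' `exposure`.
#'
#' @param data A mortality table (see [validate_mortality_table()]).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_mortality_table <- function(data, path) {
  data <- validate_mortality_table(data)
  comments <- character(0)
  gen <- attr(data, "generator")
  if (!is.null(gen)) {
    comments <- paste0("# ", names(gen), " = ",
                       vapply(gen, function(v) format(v, digits = 15), ""))
  }
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(comments, con)
  utils::write.table(
    data[, c("cohort", "sex", "age", "deaths", "exposure")],
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a mortality table from the canonical TSV format
#'
#' @param path Path to a file written by [write_mortality_table()] (or any
#'   TSV with the same columns; `#` lines are comments).
#' @return A validated mortality tibble.
#' @export
read_mortality_table <- function(path) {
  data <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      cohort = readr::col_character(),
      sex = readr::col_character(),
      age = readr::col_double(),
      deaths = readr::col_double(),
      exposure = readr::col_double()
    )
  )
  if (nrow(data) == 0) {
    stop("no data rows in ", path, call. = FALSE)
  }
  validate_mortality_table(data)
}

#' Read Human Mortality Database 1x1 deaths and exposures files
#'
#' Parses the HMD "1x1" text layout: a one-line preamble, a blank line, then
#' a whitespace-separated table with columns `Year`, `Age`, `Female`, `Male`,
#' `Total`. A deaths file and an exposures file are read and joined on
#' (year, age). The open age interval `110+` is dropped; missing values
#' (`.`) cause their rows to be dropped with a warning.
#'
#' @param deaths_path,exposures_path Paths to the paired HMD 1x1 files.
#' @param sex One of `"female"`, `"male"`, `"total"`: which column to keep.
#' @return A validated mortality tibble with `cohort` set to the HMD year.
#' @export
read_hmd_1x1 <- function(deaths_path, exposures_path,
                         sex = c("female", "male", "total")) {
  sex <- match.arg(sex)
  column <- c(female = "Female", male = "Male", total = "Total")[[sex]]
  deaths <- parse_hmd_file(deaths_path, column, "deaths")
  exposures <- parse_hmd_file(exposures_path, column, "exposure")
  data <- dplyr::inner_join(deaths, exposures, by = c("cohort", "age"))
  if (nrow(data) == 0) {
    stop("no overlapping (year, age) rows between deaths and exposures",
         call. = FALSE)
  }
  n_na <- sum(!stats::complete.cases(data))
  if (n_na > 0) {
    warning(n_na, " row(s) with missing values dropped", call. = FALSE)
    data <- data[stats::complete.cases(data), ]
  }
  data$sex <- sex
  validate_mortality_table(
    data[, c("cohort", "sex", "age", "deaths", "exposure")]
  )
}

parse_hmd_file <- function(path, column, value_name) {
  lines <- readLines(path)
  header_at <- grep("^\\s*Year\\s+Age\\s+Female\\s+Male\\s+Total", lines)
  if (length(header_at) == 0) {
    stop("no 'Year Age Female Male Total' header found in ", path,
         call. = FALSE)
  }
  tab <- utils::read.table(
    text = lines[-seq_len(header_at[1])],
    col.names = c("Year", "Age", "Female", "Male", "Total"),
    colClasses = "character"
  )
  tab <- tab[tab$Age != "110+", , drop = FALSE] # open interval dropped
  out <- tibble::tibble(
    cohort = tab$Year,
    age = as.numeric(tab$Age),
    value = suppressWarnings(as.numeric(ifelse(tab[[column]] == ".", NA,
                                               tab[[column]])))
  )
  if (anyNA(out$age)) {
    stop("unparseable Age value in ", path, call. = FALSE)
  }
  names(out)[names(out) == "value"] <- value_name
  out
}
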