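dataset_columns <- c(
  "subject_id", "event", "time_h", "amount_mg", "infusion_h",
  "conc_mg_L", "lloq_flag", "age_y", "sex", "weight_kg", "scr_mg_dL",
  "crcl_mL_min"
)

validate_dataset <- function(data) {
  missing_cols <- setdiff(dataset_columns, names(data))
  if (length(missing_cols)) {
    abort(paste0("dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  bad_event <- !data$event %in% c("dose", "obs")
  if (any(bad_event)) {
    abort(paste0("row ", which(bad_event)[1],
                 ": `event` must be \"dose\" or \"obs\"."))
  }
  if (any(data$time_h < 0, na.rm = TRUE)) {
    abort(paste0("row ", which(data$time_h < 0)[1], ": `time_h` must be >= 0."))
  }
  is_dose <- data$event == "dose"
  bad_dose <- is_dose & (is.na(data$amount_mg) | is.na(data$infusion_h))
  if (any(bad_dose)) {
    abort(paste0("row ", which(bad_dose)[1],
                 ": dose rows need `amount_mg` and `infusion_h`."))
  }
  bad_obs <- !is_dose & !is.na(data$amount_mg)
  if (any(bad_obs)) {
    abort(paste0("row ", which(bad_obs)[1],
                 ": obs rows must leave `amount_mg` empty."))
  }
  bad_conc <- !is_dose & (is.na(data$conc_mg_L) | data$conc_mg_L < 0)
  if (any(bad_conc)) {
    abort(paste0("row ", which(bad_conc)[1],
                 ": obs rows need non-negative `conc_mg_L`."))
  }
  if (any(data$crcl_mL_min <= 0, na.rm = TRUE)) {
    abort("`crcl_mL_min` must be > 0 for every subject.")
  }
  data
}

#' Read / write the long-format dosing and observation dataset
#'
#' The dataset CSV carries one row per dosing event or observation, with the
#' subject's covariates repeated on each row. Columns: `subject_id`, `event`
#' (`"dose"` or `"obs"`), `time_h`, `amount_mg` and `infusion_h` (dose rows
#' only), `conc_mg_L` and `lloq_flag` (observation rows only), `age_y`,
#' `sex`, `weight_kg`, `scr_mg_dL`, `crcl_mL_min`. Missing values are empty
#' fields.
#'
#' @param path File path.
#' @return `read_dataset()` returns a validated tibble; `write_dataset()`
#'   invisibly returns `path`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      event = readr::col_character(),
      time_h = readr::col_double(),
      amount_mg = readr::col_double(),
      infusion_h = readr::col_double(),
      conc_mg_L = readr::col_double(),
      lloq_flag = readr::col_logical(),
      age_y = readr::col_double(),
      sex = readr::col_character(),
      weight_kg = readr::col_double(),
      scr_mg_dL = readr::col_double(),
      crcl_mL_min = readr::col_double()
    ),
    comment = "#"
  )
  data <- validate_dataset(data)
  message(sprintf("read %d rows, %d subjects, %d observations",
                  nrow(data), length(unique(data$subject_id)),
                  sum(data$event == "obs")))
  data
}

#' @rdname read_dataset
#' @param data A dataset tibble (schema above).
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Write a probability-of-target-attainment table
#'
#' Serialises a PTA table (see [simulate_pta()]) as a long-format CSV with a
#' comment header recording the simulation seed and cohort size; percentages
#' are rounded to one decimal.
#'
#' @param table A `pta_table` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pta_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  hdr <- sprintf(
    "# pta table | seed: %s | n per cohort: %s",
    attr(table, "seed") %||% "NA", attr(table, "n") %||% "NA"
  )
  out <- dplyr::mutate(
    table,
    dplyr::across(dplyr::ends_with("_pct"), ~ round(.x, 1))
  )
  readr::write_lines(hdr, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write a nonparametric population model
#'
#' The population model file is a plain-text CSV of support points
#' (`intercept`, `slope`, `vc`, `weight`) preceded by comment lines carrying
#' the full-model covariance matrix row by row (`# cov: a b c`).
#'
#' @param dist An [np_distribution()].
#' @param path File path.
#' @return `read_population_model()` returns an [np_distribution()];
#'   `write_population_model()` invisibly returns `path`.
#' @export
write_population_model <- function(dist, path) {
  stopifnot(inherits(dist, "np_distribution"))
  cov_lines <- apply(dist$covariance, 1, function(r) {
    paste0("# cov: ", paste(format(r, digits = 17), collapse = " "))
  })
  readr::write_lines(cov_lines, path)
  readr::write_csv(dist$points, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_population_model
#' @export
read_population_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  cov_lines <- grep("^# cov:", lines, value = TRUE)
  if (length(cov_lines) != 3) {
    abort("population model file must carry three `# cov:` lines.")
  }
  covariance <- do.call(rbind, lapply(cov_lines, function(l) {
    as.numeric(strsplit(trimws(sub("^# cov:", "", l)), "\\s+")[[1]])
  }))
  points <- readr::read_csv(
    path, comment = "#",
    col_types = readr::cols(.default = readr::col_double())
  )
  np_distribution(points, covariance)
}
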