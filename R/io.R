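#' Read a species parameter table
#'
#' Reads a CSV of per-species neurogenic parameters. Required columns:
#' `species`, `gestation_days`, `neurogenic_days`, `observed_neurons`,
#' `founder_pool`, `cell_cycle_hours`. Optional columns (kept when present):
#' `gi`, `gi_group`, `brain_weight_g`, and any others. `"NA"` entries become
#' missing values; scientific notation such as `1.63E+10` is accepted.
#' Row-level validation problems (non-positive parameters, neurogenic period
#' exceeding gestation) are collected and reported together.
#'
#' @param path path to a CSV file (both LF and CRLF line endings accepted).
#' @return A `data.frame` with one validated row per species.
#' @examples
#' tab <- read_species_csv(cortigen_example("species_params.csv"))
#' nrow(tab)  # 17
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE,
                         na.strings = c("NA", ""), strip.white = TRUE)
  required <- c("species", "gestation_days", "neurogenic_days",
                "observed_neurons", "founder_pool", "cell_cycle_hours")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("species table has no rows", call. = FALSE)
  num_cols <- setdiff(required, "species")
  for (cc in num_cols) tab[[cc]] <- as.numeric(tab[[cc]])
  problems <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    for (cc in num_cols) {
      v <- row[[cc]]
      if (!is.na(v) && v <= 0) {
        problems <- c(problems, sprintf("row %d (%s): %s must be > 0",
                                        i, row$species, cc))
      }
    }
    if (!is.na(row$gestation_days) && !is.na(row$neurogenic_days) &&
        row$neurogenic_days > row$gestation_days) {
      problems <- c(problems,
                    sprintf("row %d (%s): neurogenic period exceeds gestation",
                            i, row$species))
    }
  }
  if (length(problems)) {
    stop("invalid species table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tab
}

#' Write a species parameter table
#'
#' RFC-4180 CSV writer companion to [read_species_csv()]; round-trips
#' losslessly.
#'
#' @param tab a species `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Reference species parameter table
#'
#' The packaged 17-species parameter set (gestation and neurogenic periods
#' in days, observed adult cortical neuron counts, neuroepithelial founder
#' pools, averaged cell-cycle lengths in hours, and a high/low gyrencephaly
#' grouping at GI 1.5). The opossum gestation entry is missing by design.
#'
#' @return A validated `data.frame`, see [read_species_csv()].
#' @export
species_table <- function() {
  read_species_csv(cortigen_example("species_params.csv"))
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
cortigen_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cortigen")))
  }
  system.file("extdata", file, package = "cortigen", mustWork = TRUE)
}
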