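# Plant-level observation tables: readers, writers, validation.
#
# Canonical columns (snake_case); a rename map in `read_observations()` adapts
# other headers. Gas-exchange triplicates are stored wide (Asat_r1..r3 etc.).

id_cols <- c("farm_id", "variety_id", "subplot_id", "plant_id")

rep_cols <- c(paste0("Asat_r", 1:3), paste0("gs_r", 1:3), paste0("TR_r", 1:3))

measure_cols <- c(
  "LA", "leaf_dry_mass", "PD", "RL", "RD", "taproot_dry_mass",
  rep_cols, "SN", "SC", "SP", "temp", "precip"
)

#' Read a plant-level observation table
#'
#' Reads a comma- or tab-separated text file (header required, `.` decimal
#' point) into a typed, validated observation tibble: one row per plant with
#' nested identifiers (farm, variety = plot within farm, subplot, plant), raw
#' morphology, gas-exchange triplicates, subplot-level soil variables and
#' farm-level climate covariates.
#'
#' Rows whose gas-exchange triplicates are entirely missing are flagged in
#' `flag_missing_phys`, never dropped here; exclusion is an explicit
#' preprocessing step (see [preprocess_observations()]).
#'
#' @param path File path.
#' @param config A [run_config()]; the reference variety is placed first in
#'   the variety factor when present.
#' @param rename Optional named character vector `c(canonical = "file header")`
#'   mapping canonical column names to the file's headers.
#' @return A validated observation tibble.
#' @seealso [validate_observations()], [write_table()]
#' @export
read_observations <- function(path, config = run_config(), rename = NULL) {
  delim <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(rename)) {
    missing_src <- setdiff(unname(rename), names(raw))
    if (length(missing_src)) {
      abort(paste0("rename map refers to absent column(s): ",
                   paste(missing_src, collapse = ", ")))
    }
    names(raw)[match(unname(rename), names(raw))] <- names(rename)
  }
  required <- c(id_cols, measure_cols)
  absent <- setdiff(required, names(raw))
  if (length(absent)) {
    abort(paste0("missing required column(s): ", paste(absent, collapse = ", ")),
          class = "te_schema_error")
  }
  out <- tibble::as_tibble(raw)[required]
  for (v in id_cols) {
    lev <- unique(as.character(out[[v]]))
    if (v == "variety_id" && config$reference_variety %in% lev) {
      lev <- c(config$reference_variety, setdiff(lev, config$reference_variety))
    }
    out[[v]] <- factor(as.character(out[[v]]), levels = lev)
  }
  for (v in measure_cols) out[[v]] <- as.numeric(out[[v]])
  out$flag_missing_phys <- flag_missing_phys(out)
  validate_observations(out)
  out
}

flag_missing_phys <- function(data) {
  apply(is.na(as.matrix(data[paste0("Asat_r", 1:3)])), 1L, all) |
    apply(is.na(as.matrix(data[paste0("TR_r", 1:3)])), 1L, all)
}

#' Validate the nested structure of an observation table
#'
#' Checks that the nested key (farm, variety, subplot, plant) is unique, that
#' subplot-level soil values are constant within each subplot, that farm-level
#' climate values are constant within each farm, and that measurements are
#' strictly positive where present.
#'
#' @param data An observation tibble.
#' @return `data`, invisibly; errors of class `te_integrity_error` otherwise.
#' @export
validate_observations <- function(data) {
  if (nrow(data) == 0L) return(invisible(data))
  key <- do.call(paste, c(data[id_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    abort("duplicated nested key (farm, variety, subplot, plant)",
          class = "te_integrity_error")
  }
  sub_key <- do.call(paste, c(data[c("farm_id", "variety_id", "subplot_id")],
                              sep = "\r"))
  for (v in c("SN", "SC", "SP")) {
    n_distinct <- tapply(data[[v]], sub_key, function(x) length(unique(x[!is.na(x)])))
    if (any(n_distinct > 1L, na.rm = TRUE)) {
      abort(paste0("soil variable ", v, " varies within a subplot"),
            class = "te_integrity_error")
    }
  }
  for (v in c("temp", "precip")) {
    n_distinct <- tapply(data[[v]], data$farm_id, function(x) length(unique(x[!is.na(x)])))
    if (any(n_distinct > 1L, na.rm = TRUE)) {
      abort(paste0("climate variable ", v, " varies within a farm"),
            class = "te_integrity_error")
    }
  }
  pos <- setdiff(measure_cols, c("temp", "precip"))
  for (v in pos) {
    if (any(data[[v]] <= 0, na.rm = TRUE)) {
      abort(paste0("non-positive value in measurement column ", v),
            class = "te_integrity_error")
    }
  }
  invisible(data)
}

#' Write a result table as tab-separated text
#'
#' Values round-trip at full double precision, so `read` after `write`
#' reproduces the table exactly up to floating representation. An empty
#' table writes a header-only file.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x), ncol(x) > 0L)
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}
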