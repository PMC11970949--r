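# Lossless serialization of run records to TSV and JSON.

#' Tabulate run records
#'
#' One row per record: `seed`, `run_index`, `solution_key`,
#' `objective_value_original`, `objective_value_perturbed`,
#' `verified_optimal`, `status`, `backend`, `mode`.
#'
#' @param records A `batch_result` or a list of `run_record` objects.
#' @param instance The shared instance (taken from the batch if omitted).
#' @return A `data.frame`.
#' @export
solution_records_frame <- function(records, instance = NULL) {
  if (inherits(records, "batch_result")) {
    instance <- instance %||% records$instance
    records <- records$records
  }
  if (is.null(instance)) stop("`instance` is required with a plain record list")
  if (!length(records)) {
    return(data.frame(seed = integer(0), run_index = integer(0),
                      solution_key = character(0),
                      objective_value_original = numeric(0),
                      objective_value_perturbed = numeric(0),
                      verified_optimal = logical(0), status = character(0),
                      backend = character(0), mode = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(
      seed = r$seed,
      run_index = i,
      solution_key = if (r$solution$status == "optimal") {
        solution_key(instance, r$solution)
      } else NA_character_,
      objective_value_original = r$original_objective_value,
      objective_value_perturbed = r$perturbed_objective_value,
      verified_optimal = r$verified_optimal,
      status = r$solution$status,
      backend = r$backend,
      mode = r$mode,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write run records to disk
#'
#' @param records A `batch_result` or list of `run_record` objects sharing
#'   one instance.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @param instance The shared instance (taken from the batch if omitted).
#' @return `path`, invisibly. Numeric columns are written at full precision
#'   so that [read_solutions()] round-trips losslessly.
#' @export
write_solutions <- function(records, path, format = NULL, instance = NULL) {
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  format <- match.arg(format, c("tsv", "json"))
  df <- solution_records_frame(records, instance)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  } else {
    out <- df
    for (cn in c("objective_value_original", "objective_value_perturbed")) {
      out[[cn]] <- ifelse(is.na(df[[cn]]), "NA", sprintf("%.17g", df[[cn]]))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  invisible(path)
}

#' Read run records written by [write_solutions()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`; guessed from the extension.
#' @return A `data.frame` with the columns of [solution_records_frame()].
#' @export
read_solutions <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  format <- match.arg(format, c("tsv", "json"))
  if (format == "json") {
    df <- jsonlite::fromJSON(path)
    if (!is.data.frame(df)) df <- as.data.frame(df)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(solution_key = "character"),
                            stringsAsFactors = FALSE)
  }
  num <- c("objective_value_original", "objective_value_perturbed")
  for (cn in intersect(num, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  if ("solution_key" %in% names(df)) df$solution_key <- as.character(df$solution_key)
  if ("verified_optimal" %in% names(df)) df$verified_optimal <- as.logical(df$verified_optimal)
  df
}
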