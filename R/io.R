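#' @keywords internal
check_columns <- function(df, required, context) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(context, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read a SMILES (.smi) file
#'
#' One record per line, whitespace-separated `SMILES ID`; lines starting
#' with `#` and blank lines are skipped. When the identifier column is
#' absent, ids `S1...Sn` are assigned.
#'
#' @param path file path.
#' @return data.frame with columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- trimws(lines[keep])
  if (length(lines) == 0) {
    return(data.frame(id = character(), smiles = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (lengths(parts)[i] >= 2) parts[[i]][2] else paste0("S", i)
  }, character(1))
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write a SMILES (.smi) file
#'
#' @param df data.frame with columns `smiles` (or `smiles_std`) and `id`.
#' @param path file path.
#' @export
write_smiles <- function(df, path) {
  smi <- if ("smiles" %in% names(df)) df$smiles else df$smiles_std
  if (is.null(smi)) stop("no 'smiles' or 'smiles_std' column to write")
  writeLines(paste(smi, df$id, sep = "\t"), path)
  invisible(path)
}

#' Read a CSV table, checking required columns
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, required, basename(path))
  df
}

#' Write a CSV table with deterministic column order
#'
#' List-columns are flattened to semicolon-joined strings.
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_checked <- function(df, path) {
  flat <- df
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ";")
    }
  }
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Split semicolon-joined list columns read back from CSV
#'
#' @param x character vector of `;`-joined values.
#' @return list of character vectors (empty strings become `character(0)`).
#' @export
split_list_column <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character() else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

#' Load a YAML or JSON run configuration
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return named list.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext)
  }
}

#' Write a JSON run manifest
#'
#' Records the configuration, the seed, and the MD5 hash of every input
#' file, so a run can be reproduced and its inputs audited.
#'
#' @param path output path for the manifest JSON.
#' @param config named list of run parameters.
#' @param seed integer seed used for the run (or `NULL`).
#' @param files named character vector of input file paths to hash.
#' @return the manifest list, invisibly.
#' @export
run_manifest <- function(path, config, seed = NULL, files = character()) {
  manifest <- list(
    package = "screenlib",
    version = as.character(utils::packageVersion("screenlib")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_hashes = if (length(files)) {
      hashes <- tools::md5sum(unlist(files))
      if (!is.null(names(files))) names(hashes) <- names(files)
      as.list(hashes)
    } else NULL
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}

#' Write target predictions to CSV
#'
#' @param predictions data.frame from [predict_targets()].
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  write_table_checked(
    predictions[, c("compound_id", "max_similarity", "n_targets", "targets")],
    path)
}

#' Read target predictions written by [write_predictions()]
#'
#' @param path file path.
#' @return predictions data.frame with list-column `targets`.
#' @export
read_predictions <- function(path) {
  df <- read_table_checked(path, c("compound_id", "max_similarity", "targets"))
  df$targets <- split_list_column(as.character(df$targets))
  df$n_targets <- lengths(df$targets)
  df
}
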