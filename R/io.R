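#' Read structure records from a file
#'
#' Supported formats:
#' * `.smi` — one structure per line, `SMILES[ whitespace identifier]`; a
#'   missing identifier becomes a sequential id.
#' * SDF (V2000) — records split on `$$$$`; the title line becomes the id.
#' * CSV — structure and id columns configurable via `smiles_col`/`id_col`.
#'
#' Unparseable entries are kept as records with `status = "parse_error"` so a
#' batch run never aborts; [pfas_classify()] reports them as skipped.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"smi"`, `"sdf"`, or `"csv"`.
#' @param smiles_col,id_col CSV column names (default `"smiles"`, `"id"`).
#' @return A named list of `molecule_record` objects.
#' @export
read_records <- function(path, format = c("auto", "smi", "sdf", "csv"),
                         smiles_col = "smiles", id_col = "id") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", mol = "sdf", csv = "csv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass `format`", call. = FALSE))
  }
  switch(format,
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[ \t]+")
      smiles <- vapply(parts, `[[`, character(1), 1L)
      ids <- vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) >= 2L) parts[[i]][2L] else sprintf("mol_%d", i)
      }, character(1))
      parse_structures(smiles, ids, format = "smiles")
    },
    sdf = {
      text <- paste(readLines(path, warn = FALSE), collapse = "\n")
      blocks <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
      blocks <- blocks[nzchar(trimws(blocks))]
      blocks <- sub("^\n+", "", blocks)
      ids <- vapply(seq_along(blocks), function(i) {
        title <- trimws(strsplit(blocks[[i]], "\n")[[1]][1])
        if (nzchar(title)) title else sprintf("mol_%d", i)
      }, character(1))
      parse_structures(blocks, ids, format = "molblock")
    },
    csv = {
      df <- readr::read_csv(path, show_col_types = FALSE)
      if (!smiles_col %in% names(df)) {
        stop("CSV is missing the declared structure column '", smiles_col,
             "'", call. = FALSE)
      }
      ids <- if (id_col %in% names(df)) as.character(df[[id_col]])
             else sprintf("mol_%d", seq_len(nrow(df)))
      parse_structures(df[[smiles_col]], ids, format = "smiles")
    }
  )
}

# fixed, documented report column order
.REPORT_COLUMNS <- c("record_id", "definition_id", "is_pfas", "evidence",
                     "pct_f_excl_h", "pct_f_incl_h", "pct_f_mass", "f_count",
                     "f_c_ratio", "formula")

report_table <- function(classified) {
  stopifnot(is.data.frame(classified))
  classified |>
    dplyr::mutate(
      pct_f_excl_h = round(100 * .data$atom_fraction_excl_h, 1),
      pct_f_incl_h = round(100 * .data$atom_fraction_incl_h, 1),
      pct_f_mass = round(100 * .data$mass_fraction, 1),
      f_c_ratio = .data$f_to_c_ratio,
      evidence = vapply(.data$evidence, function(ev) {
        as.character(jsonlite::toJSON(ev, digits = NA))
      }, character(1))
    ) |>
    dplyr::select(dplyr::all_of(.REPORT_COLUMNS))
}

#' Write a classification report
#'
#' Serialises a [pfas_classify()] result (or the long form of a
#' `pfas_matrix`) to CSV or JSON with a fixed, documented column order:
#' record_id, definition_id, is_pfas, evidence (JSON), percent fluorine
#' excluding/including hydrogen and by mass (one decimal place), fluorine
#' count, F:C ratio, formula. JSON keeps full-precision fractions alongside.
#'
#' @param classified A tibble from [pfas_classify()], or a `pfas_matrix`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(classified, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (inherits(classified, "pfas_matrix")) classified <- classified$classified
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     json = "json",
                     stop("cannot infer report format; pass `format`",
                          call. = FALSE))
  }
  tab <- report_table(classified)
  if (format == "csv") {
    readr::write_csv(tab, path)
  } else {
    full <- classified |>
      dplyr::mutate(evidence = purrr::map(.data$evidence, identity))
    jsonlite::write_json(full, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a CSV classification report back into a tibble
#'
#' Round-trip companion of [write_report()]: re-parses the JSON evidence
#' column into tibbles and restores the logical verdict column.
#'
#' @param path CSV report path.
#' @return A tibble with the report columns; `evidence` is a list-column.
#' @export
read_report <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$evidence <- lapply(df$evidence, function(j) {
    tibble::as_tibble(jsonlite::fromJSON(j))
  })
  df
}

#' Export structures to a .smi file
#'
#' @param data Data frame with SMILES and id columns (e.g. [paper_corpus()]
#'   with `id_col = "name"`).
#' @param path Output path.
#' @param smiles_col,id_col Column names.
#' @return `path`, invisibly.
#' @export
write_smi <- function(data, path, smiles_col = "smiles", id_col = "id") {
  stopifnot(smiles_col %in% names(data))
  ids <- if (id_col %in% names(data)) gsub("[ \t]+", "_", data[[id_col]])
         else sprintf("mol_%d", seq_len(nrow(data)))
  writeLines(paste(data[[smiles_col]], ids), path)
  invisible(path)
}
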