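#' Read and write the package's table formats
#'
#' Thin readr wrappers for the formats used across the pipeline: wide
#' depth matrices (TSV, samples in rows, sample id in the first
#' column), feature-selection tables (TSV), allele-count tables (TSV),
#' diagnostic-site tables (TSV), qPCR crossing-point tables (CSV with
#' columns `sample_id`, `marker`, `rep1`..`rep3`) and ground-truth
#' tables (JSON).
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name radwolb-io
NULL

#' @rdname radwolb-io
#' @export
write_depth_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname radwolb-io
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname radwolb-io
#' @export
write_table_tsv <- function(x, path) {
  drop <- vapply(x, is.list, logical(1))
  if (any(drop)) {
    for (col in names(x)[drop]) {
      x[[col]] <- vapply(x[[col]], function(v) {
        paste(stats::na.omit(v), collapse = ",")
      }, character(1))
    }
  }
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname radwolb-io
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname radwolb-io
#' @export
write_qpcr_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname radwolb-io
#' @export
read_qpcr_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    marker = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @rdname radwolb-io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname radwolb-io
#' @export
read_truth_json <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
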