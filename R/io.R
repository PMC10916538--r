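#' Read a per-cell MFI table
#'
#' Reads a wide CSV/TSV with one row per cell: 32 cytokine MFI columns
#' (names matched against `panel` after normalization, so "TNFa",
#' "TNF-α" and "tnf a" all map to the canonical column) plus metadata
#' columns `sample_id`, `patient_id`, `tissue`, `timepoint`, `subset` and,
#' optionally, `cell_id` and sample-level covariates (`response`, `age`,
#' `prior_HSCT`, `secondary_AML`). Sample covariates may instead be given
#' as a separate table via `samples`.
#'
#' @param path Path to a delimited text file.
#' @param panel A `cytokine_panel` (default [default_panel()]).
#' @param samples Optional per-sample metadata table or path to one.
#' @param delim Field delimiter; `NULL` (default) picks "\\t" for `.tsv`
#'   and "," otherwise.
#' @return A `secretome`. Row order of the input is preserved.
#' @export
read_mfi_table <- function(path, panel = default_panel(), samples = NULL,
                           delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  cells <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  if (is.character(samples) && length(samples) == 1) {
    samples <- readr::read_delim(samples, delim = delim,
                                 show_col_types = FALSE, progress = FALSE)
  }
  secretome(cells, samples = samples, panel = panel)
}

#' Write a per-cell MFI table
#'
#' Writes the cohort as one wide CSV/TSV (RFC-4180 quoting): cell metadata,
#' sample-level covariates joined in, then the cytokine columns in panel
#' order under their canonical ASCII names. The file round-trips through
#' [read_mfi_table()]: values and metadata are reproduced exactly up to
#' decimal serialization (>= 15 significant digits).
#'
#' @param x A `secretome`.
#' @param path Output path; `.tsv` selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_mfi_table <- function(x, path) {
  stopifnot(inherits(x, "secretome"))
  join_cols <- setdiff(names(x$samples),
                       c("patient_id", "tissue", "timepoint"))
  tab <- dplyr::left_join(x$cells,
                          x$samples[, join_cols, drop = FALSE],
                          by = "sample_id")
  tab <- tab[, c(setdiff(names(tab), x$panel$cytokines),
                 x$panel$cytokines)]
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}

#' Read and concatenate per-sample MFI files
#'
#' Loader shim for cohorts shipped as one file per sample: each file is
#' read as in [read_mfi_table()] and the cohorts are concatenated in the
#' order given.
#'
#' @param paths Character vector of file paths.
#' @inheritParams read_mfi_table
#' @return A single `secretome`.
#' @export
read_mfi_tables <- function(paths, panel = default_panel(), samples = NULL,
                            delim = NULL) {
  parts <- lapply(paths, function(p) {
    d <- if (is.null(delim)) (if (grepl("\\.tsv$", p)) "\t" else ",") else delim
    readr::read_delim(p, delim = d, show_col_types = FALSE, progress = FALSE)
  })
  secretome(dplyr::bind_rows(parts), samples = samples, panel = panel)
}
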