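#' Single-cell secretome cohorts
#'
#' A `secretome` bundles a per-cell MFI table with per-sample metadata and
#' the cytokine panel the columns were validated against. `cells` is a
#' tibble with one row per cell: identifier columns (`cell_id`, `sample_id`,
#' `patient_id`, `tissue`, `timepoint`, `subset`) followed by one numeric
#' MFI column per panel cytokine (canonical names). `samples` is a tibble
#' with one row per sample: `sample_id`, `patient_id`, `tissue`,
#' `timepoint`, and any sample-level covariates present (`response`, `age`,
#' `prior_HSCT`, `secondary_AML`, ...).
#'
#' Invariants enforced at construction: all MFI values are finite and
#' non-negative; every cell's `sample_id` appears in `samples`; `tissue`,
#' `timepoint` and `subset` are constant within a sample for a given subset
#' row block; cytokine columns match the panel after name normalization
#' (columns are renamed to the canonical spelling).
#'
#' @param cells Per-cell tibble/data frame (metadata + MFI columns).
#' @param samples Optional per-sample tibble; derived from `cells` when
#'   sample-level columns are present there.
#' @param panel A `cytokine_panel`; defaults to [default_panel()].
#' @return An object of class `secretome`: a list with elements `cells`,
#'   `samples`, `panel`.
#' @export
secretome <- function(cells, samples = NULL, panel = default_panel()) {
  cells <- tibble::as_tibble(cells)

  required <- c("sample_id", "patient_id", "tissue", "timepoint", "subset")
  miss <- setdiff(required, names(cells))
  if (length(miss)) {
    stop("missing mandatory metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"cell_id" %in% names(cells)) {
    cells$cell_id <- paste0(cells$sample_id, ":", seq_len(nrow(cells)))
  }

  rep <- validate_panel(panel, names(cells))
  if (length(rep$missing)) {
    stop("cytokine column(s) missing from input: ",
         paste(rep$missing, collapse = ", "), call. = FALSE)
  }
  # rename matched columns to canonical spelling
  ren <- rep$matched$cytokine
  names(ren) <- rep$matched$column
  names(cells)[match(rep$matched$column, names(cells))] <- unname(ren)

  cyt <- panel$cytokines
  for (cn in cyt) {
    v <- cells[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric MFI in column '", cn, "' at row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop("negative or non-finite MFI in column '", cn, "' at row ",
           bad[1], call. = FALSE)
    }
  }

  sample_level <- c("response", "age", "prior_HSCT", "secondary_AML")
  if (is.null(samples)) {
    samples <- cells |>
      dplyr::select(dplyr::all_of(c("sample_id", "patient_id", "tissue",
                                    "timepoint")),
                    dplyr::any_of(sample_level)) |>
      dplyr::distinct()
  } else {
    samples <- tibble::as_tibble(samples)
  }
  if (anyDuplicated(samples$sample_id) > 0) {
    stop("tissue/timepoint (and sample covariates) must be constant ",
         "within a sample_id", call. = FALSE)
  }
  orphan <- setdiff(cells$sample_id, samples$sample_id)
  if (length(orphan)) {
    stop("cells reference unknown sample_id(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  # sample-level fields must agree between cells and samples
  chk <- cells |>
    dplyr::distinct(.data$sample_id, .data$tissue, .data$timepoint)
  if (anyDuplicated(chk$sample_id) > 0) {
    stop("tissue/timepoint must be constant within a sample_id",
         call. = FALSE)
  }

  meta_cols <- intersect(
    c("cell_id", "sample_id", "patient_id", "tissue", "timepoint", "subset"),
    names(cells))
  extra <- setdiff(names(cells), c(meta_cols, cyt, sample_level))
  cells <- cells[, c(meta_cols, extra, cyt)]

  structure(list(cells = cells, samples = samples, panel = panel),
            class = "secretome")
}

#' @export
print.secretome <- function(x, ...) {
  cat("<secretome> ", nrow(x$cells), " cells x ",
      length(x$panel$cytokines), " cytokines, ",
      nrow(x$samples), " samples, ",
      dplyr::n_distinct(x$samples$patient_id), " patients\n", sep = "")
  tab <- table(x$cells$subset)
  cat("  subsets: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract the cells-by-cytokines MFI matrix
#'
#' @param x A `secretome`.
#' @return Numeric matrix, rownames `cell_id`, columns in panel order.
#' @export
mfi_matrix <- function(x) {
  stopifnot(inherits(x, "secretome"))
  m <- as.matrix(x$cells[, x$panel$cytokines])
  rownames(m) <- x$cells$cell_id
  m
}

#' Subset a cohort by cell-level conditions
#'
#' Filters `cells` with dplyr semantics and drops samples that lose all
#' their cells. Truth labels (simulated cohorts) are subset in step.
#'
#' @param x A `secretome`.
#' @param ... Conditions on the `cells` columns, e.g. `subset == "CD4"`.
#' @return A `secretome` containing the matching cells.
#' @export
filter_cells <- function(x, ...) {
  stopifnot(inherits(x, "secretome"))
  cells <- dplyr::filter(x$cells, ...)
  out <- x
  out$cells <- cells
  out$samples <- dplyr::semi_join(x$samples, cells, by = "sample_id")
  if (!is.null(attr(x, "truth"))) {
    attr(out, "truth") <- dplyr::semi_join(attr(x, "truth"), cells,
                                           by = "cell_id")
  }
  out
}

#' Truth labels of a simulated cohort
#'
#' @param x A `secretome` produced by [simulate_cohort()].
#' @return Tibble with `cell_id`, `population`, `outlier`, or `NULL` for
#'   cohorts without truth labels.
#' @export
truth_labels <- function(x) attr(x, "truth")
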