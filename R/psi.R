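#' Call per-cell cytokine secretion
#'
#' A cytokine is called secreted in a cell iff its MFI strictly exceeds
#' the cytokine's threshold. The default threshold of 0 counts any
#' nonzero signal as secretion, which matches instruments that report
#' background-subtracted MFI; per-cytokine gates can be supplied for
#' data that retain background.
#'
#' @param x A `secretome`.
#' @param thresholds Scalar or per-cytokine numeric vector (panel order,
#'   or named), all >= 0.
#' @return An object of class `secretion_calls`: list with `calls`
#'   (cells x cytokines logical matrix) and `thresholds` (named vector).
#' @export
call_secretion <- function(x, thresholds = 0) {
  stopifnot(inherits(x, "secretome"))
  m <- mfi_matrix(x)
  cyt <- colnames(m)
  if (length(thresholds) == 1) {
    thresholds <- stats::setNames(rep(thresholds, length(cyt)), cyt)
  } else if (!is.null(names(thresholds))) {
    miss <- setdiff(cyt, names(thresholds))
    if (length(miss)) {
      stop("thresholds missing for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    thresholds <- thresholds[cyt]
  } else if (length(thresholds) != length(cyt)) {
    stop("thresholds must have length 1 or ", length(cyt), call. = FALSE)
  } else {
    thresholds <- stats::setNames(thresholds, cyt)
  }
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  calls <- sweep(m, 2, thresholds, ">")
  structure(list(calls = calls, thresholds = thresholds),
            class = "secretion_calls")
}

#' Polyfunctional cells
#'
#' A cell is polyfunctional iff it is called positive for two or more
#' cytokines across the full panel.
#'
#' @param calls A `secretion_calls`.
#' @return Logical vector, one element per cell.
#' @export
polyfunctional_mask <- function(calls) {
  stopifnot(inherits(calls, "secretion_calls"))
  rowSums(calls$calls) >= 2
}

#' Polyfunctional strength index (PSI) per sample, subset and group
#'
#' For each (sample, subset) block and each functional group (plus
#' `"overall"`, and optionally each single cytokine), computes the
#' percentage of polyfunctional cells (0-100 scale), the sum over
#' polyfunctional cells of the MFI of their called-positive cytokines
#' restricted to the group, and their product, the PSI.
#'
#' Polyfunctionality is decided on the full panel; only the MFI sum is
#' group-restricted (set `group_polyfunctionality = TRUE` to require the
#' two positive calls within the group instead). Groups therefore
#' satisfy additivity: the five group `mfi_sum`s add up to the overall
#' `mfi_sum`.
#'
#' @param x A `secretome`.
#' @param calls A `secretion_calls` from [call_secretion()]; computed
#'   with `thresholds` when omitted.
#' @param thresholds Passed to [call_secretion()] when `calls` is NULL.
#' @param level `"group"` (five groups + overall), `"cytokine"`, or
#'   `"both"`.
#' @param group_polyfunctionality If TRUE, the polyfunctional fraction is
#'   recomputed within each group (two or more positive calls in the
#'   group).
#' @param mfi_stat `"sum"` (the index as defined) or `"mean"` (average
#'   over polyfunctional cells, for sensitivity analysis).
#' @return A tibble of class `psi_table`: columns `sample_id`, `subset`,
#'   `group`, `n_cells`, `n_polyfunctional`, `polyfunctional_pct`,
#'   `mfi_sum`, `psi`. Blocks with zero cells yield `NA` psi.
#' @export
compute_psi <- function(x, calls = NULL, thresholds = 0,
                        level = c("group", "cytokine", "both"),
                        group_polyfunctionality = FALSE,
                        mfi_stat = c("sum", "mean")) {
  stopifnot(inherits(x, "secretome"))
  level <- match.arg(level)
  mfi_stat <- match.arg(mfi_stat)
  if (is.null(calls)) calls <- call_secretion(x, thresholds)
  m <- mfi_matrix(x)
  cm <- calls$calls
  stopifnot(identical(dim(m), dim(cm)))
  grp <- panel_groups(x$panel)

  units <- switch(level,
    group = c(as.list(split(names(grp), grp)[unique(grp)]),
              list(overall = colnames(m))),
    cytokine = stats::setNames(as.list(colnames(m)), colnames(m)),
    both = c(as.list(split(names(grp), grp)[unique(grp)]),
             list(overall = colnames(m)),
             stats::setNames(as.list(colnames(m)), colnames(m))))

  blocks <- dplyr::distinct(x$cells, .data$sample_id, .data$subset)
  key <- paste(x$cells$sample_id, x$cells$subset, sep = "\r")
  bkey <- paste(blocks$sample_id, blocks$subset, sep = "\r")
  poly_all <- rowSums(cm) >= 2
  gated <- m * cm   # called-positive MFI only

  out <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    rows <- which(key == bkey[i])
    n <- length(rows)
    purrr::map_dfr(names(units), function(u) {
      cols <- units[[u]]
      poly <- if (group_polyfunctionality) {
        rowSums(cm[rows, cols, drop = FALSE]) >= 2
      } else {
        poly_all[rows]
      }
      npoly <- sum(poly)
      pct <- if (n > 0) 100 * npoly / n else NA_real_
      msum <- sum(gated[rows[poly], cols, drop = FALSE])
      if (mfi_stat == "mean" && npoly > 0) msum <- msum / npoly
      tibble::tibble(
        sample_id = blocks$sample_id[i], subset = blocks$subset[i],
        group = u, n_cells = n, n_polyfunctional = npoly,
        polyfunctional_pct = pct, mfi_sum = msum,
        psi = if (n > 0) pct * msum else NA_real_)
    })
  })
  class(out) <- c("psi_table", class(out))
  attr(out, "level") <- level
  out
}

#' Pseudobulk contrasts of PSI between conditions
#'
#' Sample-level tests of PSI (or any `psi_table` column) between tissues,
#' timepoints, or response arms, per subset and group. Paired contrasts
#' (PB vs BM within patient x timepoint; baseline vs post-IO within
#' patient x tissue) use a paired two-sided t test by default; the
#' responder contrast (CR vs NR, independent arms) uses a two-sided
#' Wilcoxon rank-sum test. p values are BH-adjusted within the contrast
#' family.
#'
#' @param psi_table A `psi_table` from [compute_psi()].
#' @param samples Per-sample metadata tibble (the `samples` element of a
#'   `secretome`).
#' @param contrast One of `"PB_vs_BM"`, `"pre_vs_post"`, `"CR_vs_NR"`.
#' @param value Column of `psi_table` to test (default `"psi"`).
#' @param test `"t"` or `"wilcoxon"`; the default follows the contrast
#'   (t for paired contrasts, rank-sum for CR vs NR).
#' @param timepoint For `"PB_vs_BM"` and `"CR_vs_NR"`: which timepoint's
#'   samples to compare (default `"baseline"`).
#' @param tissue For `"CR_vs_NR"`: restrict to one tissue (`NULL` keeps
#'   tissues as separate strata).
#' @param min_pairs Minimum complete pairs (paired contrasts) or samples
#'   per arm (unpaired) for a testable row.
#' @return A tibble of class `secretome_contrast`: per subset, group and
#'   (where stratified) tissue — the mean difference, test statistic, `p_value`,
#'   BH `q_value`, sample counts, and a `note` flagging degenerate or
#'   untestable rows.
#' @export
pseudobulk_contrast <- function(psi_table, samples,
                                contrast = c("PB_vs_BM", "pre_vs_post",
                                             "CR_vs_NR"),
                                value = "psi", test = NULL,
                                timepoint = "baseline", tissue = NULL,
                                min_pairs = 3) {
  contrast <- match.arg(contrast)
  stopifnot(value %in% names(psi_table))
  paired <- contrast %in% c("PB_vs_BM", "pre_vs_post")
  if (is.null(test)) test <- if (paired) "t" else "wilcoxon"
  test <- match.arg(test, c("t", "wilcoxon"))

  dat <- dplyr::inner_join(psi_table, samples, by = "sample_id")
  strata_cols <- c("subset", "group")
  if (contrast == "PB_vs_BM") {
    dat <- dat |> dplyr::filter(.data$timepoint == !!timepoint)
    arm_col <- "tissue"; a <- "PB"; b <- "BM"; pair_col <- "patient_id"
  } else if (contrast == "pre_vs_post") {
    arm_col <- "timepoint"; a <- "post_IO"; b <- "baseline"
    pair_col <- "patient_id"
    strata_cols <- c(strata_cols, "tissue")
  } else {
    dat <- dat |> dplyr::filter(.data$timepoint == !!timepoint)
    if (!is.null(tissue)) {
      dat <- dat |> dplyr::filter(.data$tissue == !!tissue)
    } else {
      strata_cols <- c(strata_cols, "tissue")
    }
    arm_col <- "response"; a <- "CR"; b <- "NR"; pair_col <- NULL
  }

  run_one <- function(d) {
    va <- d[[value]][d[[arm_col]] == a]
    vb <- d[[value]][d[[arm_col]] == b]
    if (paired) {
      wide <- d |>
        dplyr::filter(.data[[arm_col]] %in% c(a, b)) |>
        dplyr::select(dplyr::all_of(c(pair_col, arm_col, value))) |>
        tidyr::pivot_wider(names_from = dplyr::all_of(arm_col),
                           values_from = dplyr::all_of(value))
      if (!all(c(a, b) %in% names(wide))) {
        return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                              p_value = NA_real_, n = 0L,
                              note = "untestable: arm absent"))
      }
      wide <- wide[stats::complete.cases(wide[, c(a, b)]), ]
      n_pairs <- nrow(wide)
      if (n_pairs < min_pairs) {
        return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                              p_value = NA_real_, n = n_pairs,
                              note = "untestable: insufficient pairs"))
      }
      diffs <- wide[[a]] - wide[[b]]
      if (all(diffs == 0)) {
        return(tibble::tibble(estimate = 0, statistic = NA_real_,
                              p_value = 1, n = n_pairs,
                              note = "degenerate: zero differences"))
      }
      ht <- if (test == "t") {
        stats::t.test(wide[[a]], wide[[b]], paired = TRUE)
      } else {
        stats::wilcox.test(wide[[a]], wide[[b]], paired = TRUE,
                           exact = FALSE)
      }
      tibble::tibble(estimate = mean(diffs),
                     statistic = unname(ht$statistic),
                     p_value = ht$p.value, n = n_pairs, note = NA_character_)
    } else {
      if (length(va) < max(2, min_pairs - 1) ||
          length(vb) < max(2, min_pairs - 1)) {
        return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                              p_value = NA_real_,
                              n = min(length(va), length(vb)),
                              note = "untestable: insufficient samples"))
      }
      if (stats::sd(c(va, vb)) == 0) {
        return(tibble::tibble(estimate = 0, statistic = NA_real_,
                              p_value = 1, n = min(length(va), length(vb)),
                              note = "degenerate: constant values"))
      }
      ht <- if (test == "t") {
        stats::t.test(va, vb)
      } else {
        stats::wilcox.test(va, vb, exact = FALSE)
      }
      tibble::tibble(estimate = stats::median(va) - stats::median(vb),
                     statistic = unname(ht$statistic),
                     p_value = ht$p.value, n = min(length(va), length(vb)),
                     note = NA_character_)
    }
  }

  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols))) |>
    dplyr::group_modify(~ run_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, "BH"),
                  significant_raw = !is.na(.data$p_value) &
                    .data$p_value < 0.05,
                  significant_adj = !is.na(.data$q_value) &
                    .data$q_value < 0.05,
                  contrast = paste(a, "vs", b))
  class(out) <- c("secretome_contrast", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "test") <- test
  attr(out, "value") <- value
  out
}

#' Rank correlation of PSI with a sample covariate
#'
#' Spearman correlation of a `psi_table` column with a sample-level
#' covariate (age by default), per group within tissue x subset strata,
#' BH-adjusted within the family.
#'
#' @param psi_table A `psi_table`.
#' @param samples Per-sample metadata with the covariate column.
#' @param covariate Covariate column name (default `"age"`).
#' @param value Column of `psi_table` to correlate (default `"psi"`).
#' @param timepoint Restrict to one timepoint (default `"baseline"`).
#' @param min_samples Minimum samples with non-missing covariate per
#'   stratum.
#' @return Tibble: `tissue`, `subset`, `group`, `n`, `rho`, `p_value`,
#'   `q_value`, `note`.
#' @export
correlate_covariate <- function(psi_table, samples, covariate = "age",
                                value = "psi", timepoint = "baseline",
                                min_samples = 5) {
  stopifnot(covariate %in% names(samples))
  dat <- dplyr::inner_join(psi_table, samples, by = "sample_id") |>
    dplyr::filter(.data$timepoint == !!timepoint,
                  !is.na(.data[[covariate]]))
  out <- dat |>
    dplyr::group_by(.data$tissue, .data$subset, .data$group) |>
    dplyr::group_modify(function(d, g) {
      n <- nrow(d)
      if (n < min_samples) {
        return(tibble::tibble(n = n, rho = NA_real_, p_value = NA_real_,
                              note = "untestable: too few samples"))
      }
      if (stats::sd(d[[covariate]]) == 0 || stats::sd(d[[value]]) == 0) {
        return(tibble::tibble(n = n, rho = NA_real_, p_value = NA_real_,
                              note = "untestable: constant input"))
      }
      ct <- suppressWarnings(stats::cor.test(d[[covariate]], d[[value]],
                                             method = "spearman"))
      tibble::tibble(n = n, rho = unname(ct$estimate),
                     p_value = ct$p.value, note = NA_character_)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, "BH"))
  out
}
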