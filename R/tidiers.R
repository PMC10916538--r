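#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contrast result
#'
#' @param x A `secretome_contrast`.
#' @param ... Unused.
#' @return A plain tibble of the per-stratum test rows.
#' @export
tidy.secretome_contrast <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a contrast result
#'
#' @param x A `secretome_contrast`.
#' @param ... Unused.
#' @return Tibble: contrast, test, numbers of rows tested and
#'   significant at raw p < 0.05 and BH q < 0.05.
#' @export
glance.secretome_contrast <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast"),
    test = attr(x, "test"),
    n_tested = sum(!is.na(x$p_value)),
    n_sig_raw = sum(x$p_value < 0.05, na.rm = TRUE),
    n_sig_adj = sum(x$q_value < 0.05, na.rm = TRUE))
}

#' Tidy a neighborhood DA analysis
#'
#' @param x A `da_analysis` from [run_da()].
#' @param ... Unused.
#' @return The per-neighborhood result tibble.
#' @export
tidy.da_analysis <- function(x, ...) {
  tibble::as_tibble(x$result)
}

#' One-row summary of a neighborhood DA analysis
#'
#' @param x A `da_analysis`.
#' @param ... Unused.
#' @return Tibble: neighborhood total, exclusivity class counts and
#'   percentages, number significant at the spatial-FDR threshold.
#' @export
glance.da_analysis <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_nhoods = attr(s, "total"),
    baseline_only = s$n[s$class == "baseline_only"],
    baseline_only_pct = s$pct[s$class == "baseline_only"],
    post_only = s$n[s$class == "post_only"],
    post_only_pct = s$pct[s$class == "post_only"],
    mixed = s$n[s$class == "mixed"],
    n_sig = sum(x$result$spatial_fdr < x$fdr_threshold, na.rm = TRUE))
}

#' Tidy a group assignment
#'
#' @param x A `group_assignment`.
#' @param ... Unused.
#' @return Tibble: `cluster`, `group`, `signature` (comma-separated
#'   signature cytokines of the group).
#' @export
tidy.group_assignment <- function(x, ...) {
  sig <- vapply(x$signatures, paste, "", collapse = ", ")
  dplyr::mutate(x$groups, signature = unname(sig[.data$group]))
}
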