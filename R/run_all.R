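#' Configuration for an end-to-end run
#'
#' Bundles every stage's settings with full defaulting; all defaults are
#' echoed into the run manifest so no silent parameter exists.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate one.
#' @param output_dir Directory for artifacts (created if needed).
#' @param pipeline A [pipeline_config()].
#' @param da_proportion,da_fdr_threshold Neighborhood DA settings.
#' @param psi_thresholds Secretion-call threshold(s).
#' @param k_groups Named list/vector of derived-group counts per subset
#'   (default `c(CD4 = 5, CD8 = 6)`).
#' @param design,model Simulation inputs used when `input` is `NULL`
#'   (defaults: [cohort_design()], [default_model()]).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = "secretomics_out",
                       pipeline = pipeline_config(),
                       da_proportion = 0.1, da_fdr_threshold = 0.1,
                       psi_thresholds = 0,
                       k_groups = c(CD4 = 5, CD8 = 6),
                       design = NULL, model = NULL, seed = 1) {
  stopifnot(da_fdr_threshold > 0, da_fdr_threshold < 1)
  pipeline$seed <- as.integer(seed)
  structure(list(input = input, output_dir = output_dir,
                 pipeline = pipeline, da_proportion = da_proportion,
                 da_fdr_threshold = da_fdr_threshold,
                 psi_thresholds = psi_thresholds, k_groups = k_groups,
                 design = design, model = model,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the whole analysis
#'
#' Simulates (or loads) a cohort, computes PSI tables and pseudobulk
#' contrasts, embeds and clusters each T-cell subset, runs neighborhood
#' differential abundance between timepoints, derives de novo
#' polyfunctional groups and tests them against response. Every
#' intermediate artifact is written as CSV under `output_dir`, plus a
#' `manifest.json` capturing the configuration, seed and artifact
#' checksums; rerunning with the same configuration reproduces
#' identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`secretome`,
#'   `psi`, `contrasts`, per-subset `embedding`, `da`, `groups`,
#'   `response`), and `manifest`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$output_dir, name)
  written <- character()
  emit <- function(tab, name) {
    readr::write_csv(tibble::as_tibble(tab), art(name))
    written <<- c(written, name)
  }

  if (is.null(config$input)) {
    design <- config$design %||% cohort_design()
    model <- config$model %||% default_model()
    x <- simulate_cohort(design, model, seed = config$seed)
    write_mfi_table(x, art("cohort.csv"))
    written <- c(written, "cohort.csv")
    if (!is.null(truth_labels(x))) emit(truth_labels(x), "truth.csv")
  } else {
    if (!file.exists(config$input)) {
      stop("input path does not exist: ", config$input, call. = FALSE)
    }
    x <- read_mfi_table(config$input)
  }

  xf <- filter_outlier_cells(x, config$pipeline)
  emit(attr(xf, "removal_report"), "filter_report.csv")

  psi <- compute_psi(xf, thresholds = config$psi_thresholds)
  emit(psi, "psi_table.csv")
  contrasts <- list(
    PB_vs_BM = pseudobulk_contrast(psi, xf$samples, "PB_vs_BM"),
    pre_vs_post = pseudobulk_contrast(psi, xf$samples, "pre_vs_post"),
    CR_vs_NR = pseudobulk_contrast(psi, xf$samples, "CR_vs_NR"))
  for (nm in names(contrasts)) {
    emit(tidy(contrasts[[nm]]), paste0("contrast_", nm, ".csv"))
  }
  if ("age" %in% names(xf$samples)) {
    emit(correlate_covariate(psi, xf$samples), "age_correlation.csv")
  }

  subsets <- sort(unique(xf$cells$subset))
  per_subset <- list()
  for (ss in subsets) {
    xs <- filter_cells(xf, .data$subset == ss)
    emb <- run_pipeline(xs, config$pipeline)
    da <- run_da(emb, proportion = config$da_proportion,
                 fdr_threshold = config$da_fdr_threshold)
    emit(tidy(da), paste0("da_", ss, ".csv"))
    emit(glance(da), paste0("da_summary_", ss, ".csv"))
    sig <- cluster_centroids(emb)
    kg <- config$k_groups[[ss]] %||% min(5, length(sig$clusters))
    kg <- min(kg, length(sig$clusters))
    grp <- derive_groups(sig, kg)
    emit(tidy(grp), paste0("groups_", ss, ".csv"))
    props <- group_proportions(grp, emb$cells)
    emit(props, paste0("group_proportions_", ss, ".csv"))
    resp <- compare_response(props, xf$samples)
    emit(tidy(resp), paste0("response_", ss, ".csv"))
    cellcsv <- dplyr::bind_cols(
      emb$cells,
      tibble::as_tibble(emb$corrected_pcs),
      if (!is.null(emb$umap)) tibble::as_tibble(emb$umap))
    emit(cellcsv, paste0("cells_", ss, ".csv"))
    emit(tibble::as_tibble(sig$z, rownames = "cluster"),
         paste0("signature_", ss, ".csv"))
    per_subset[[ss]] <- list(embedding = emb, da = da, signature = sig,
                             groups = grp, proportions = props,
                             response = resp)
  }

  manifest <- list(
    config = list(seed = config$seed,
                  da_proportion = config$da_proportion,
                  da_fdr_threshold = config$da_fdr_threshold,
                  psi_thresholds = config$psi_thresholds,
                  k_groups = as.list(config$k_groups),
                  pipeline = unclass(config$pipeline),
                  input = config$input %||% "simulated"),
    artifacts = as.list(tools::md5sum(
      file.path(config$output_dir, written))))
  names(manifest$artifacts) <- written
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(secretome = xf, psi = psi, contrasts = contrasts,
                 subsets = per_subset, manifest = manifest))
}
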