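#' Describe a secreting subpopulation
#'
#' Helper for [secretion_model()]: a subpopulation is characterized by a
#' set of signature cytokines it cosecretes frequently and at high
#' intensity; all other cytokines are secreted at a low background
#' probability. Secretion is zero-inflated log-normal: a cytokine is
#' secreted with probability `prob_hi` (signature) or `prob_lo` (rest),
#' and a secreted MFI is drawn LogNormal(`log_mu`, `log_sigma`).
#'
#' Default intensities (median MFI ~300 a.u. for signature channels, ~60
#' for incidental secretion, log-SD 0.4) keep simulated values well inside
#' the instrument's working range, so cells exceeding the outlier filter
#' threshold occur essentially only where planted.
#'
#' @param name Population label (appears in truth labels).
#' @param signature Character vector of signature cytokine names.
#' @param prob_hi,prob_lo Secretion probabilities for signature and
#'   non-signature cytokines.
#' @param log_mu_hi,log_mu_lo Log-scale mean MFI for signature and
#'   non-signature cytokines.
#' @param log_sigma Log-scale SD (scalar, > 0).
#' @param weight Baseline mixing weight (relative; normalized per
#'   condition at simulation).
#' @return A list describing the population.
#' @export
secretion_population <- function(name, signature = character(),
                                 prob_hi = 0.9, prob_lo = 0.05,
                                 log_mu_hi = log(300), log_mu_lo = log(60),
                                 log_sigma = 0.4, weight = 1) {
  stopifnot(log_sigma > 0, prob_hi >= 0, prob_hi <= 1,
            prob_lo >= 0, prob_lo <= 1, weight >= 0)
  list(name = name, signature = signature,
       prob_hi = prob_hi, prob_lo = prob_lo,
       log_mu_hi = log_mu_hi, log_mu_lo = log_mu_lo,
       log_sigma = log_sigma, weight = weight)
}

.condition_grid <- function() {
  tidyr::expand_grid(tissue = c("PB", "BM"),
                     timepoint = c("baseline", "post_IO"),
                     response = c("CR", "NR"))
}

#' Generative model for synthetic secretome cohorts
#'
#' Assembles per-population secretion parameters (zero-inflated log-normal
#' per cytokine), a condition-dependent mixing-weight grid over
#' tissue x timepoint x response, patient-level batch effects (additive
#' offsets on the log-MFI scale shared across a patient's samples),
#' optional Gaussian background noise for non-secreting channels, a
#' planted high-MFI outlier fraction, and an optional age covariate acting
#' on one cytokine's log-mean.
#'
#' @param populations List of populations from [secretion_population()].
#' @param panel A `cytokine_panel`.
#' @param batch_effect_sd SD of patient log-scale offsets (0 disables).
#' @param background_sd SD of half-normal background MFI for
#'   non-secreting channels; 0 (default) gives exact zeros.
#' @param outlier_rate Fraction of cells given one cytokine MFI above
#'   3,000 (drawn uniformly in `outlier_range`) to exercise the outlier
#'   filter.
#' @param outlier_range Range of planted outlier MFI values.
#' @param age_effect Optional `list(cytokine =, slope =, center = 65)`:
#'   the cytokine's log-mean is shifted by `slope * (age - center)`.
#' @return An object of class `secretion_model`.
#' @export
secretion_model <- function(populations, panel = default_panel(),
                            batch_effect_sd = 0.3, background_sd = 0,
                            outlier_rate = 0, outlier_range = c(3001, 6000),
                            age_effect = NULL) {
  stopifnot(length(populations) >= 1, batch_effect_sd >= 0,
            background_sd >= 0, outlier_rate >= 0, outlier_rate < 1)
  names(populations) <- vapply(populations, `[[`, "", "name")
  cyt <- panel$cytokines
  pops <- lapply(populations, function(p) {
    sig_rep <- validate_panel(panel, p$signature)
    if (length(sig_rep$extra)) {
      stop("unknown signature cytokine(s) in population '", p$name, "': ",
           paste(sig_rep$extra, collapse = ", "), call. = FALSE)
    }
    sig <- sig_rep$matched$cytokine
    in_sig <- cyt %in% sig
    list(name = p$name, signature = sig,
         secretion_prob = stats::setNames(
           ifelse(in_sig, p$prob_hi, p$prob_lo), cyt),
         log_mu = stats::setNames(
           ifelse(in_sig, p$log_mu_hi, p$log_mu_lo), cyt),
         log_sigma = stats::setNames(rep(p$log_sigma, length(cyt)), cyt))
  })
  w0 <- vapply(populations, `[[`, 0, "weight")
  weights <- tidyr::expand_grid(population = names(pops),
                                .condition_grid()) |>
    dplyr::mutate(weight = unname(w0[.data$population])) |>
    dplyr::group_by(.data$tissue, .data$timepoint, .data$response) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
  structure(list(panel = panel, populations = pops, weights = weights,
                 batch_effect_sd = batch_effect_sd,
                 background_sd = background_sd,
                 outlier_rate = outlier_rate,
                 outlier_range = outlier_range,
                 age_effect = age_effect),
            class = "secretion_model")
}

#' @export
print.secretion_model <- function(x, ...) {
  cat("<secretion_model> ", length(x$populations), " populations, ",
      length(x$panel$cytokines), " cytokines\n", sep = "")
  for (p in x$populations) {
    cat("  ", p$name, ": signature {",
        paste(p$signature, collapse = ", "), "}\n", sep = "")
  }
  cat("  batch_effect_sd=", x$batch_effect_sd,
      " background_sd=", x$background_sd,
      " outlier_rate=", x$outlier_rate, "\n", sep = "")
  invisible(x)
}

.renormalize_weights <- function(weights) {
  weights |>
    dplyr::group_by(.data$tissue, .data$timepoint, .data$response) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
}

#' Plant a timepoint abundance shift
#'
#' Multiplies one population's mixing weight by `fold_change` in every
#' condition at the given timepoint, then renormalizes weights within each
#' condition. The planted (pre-normalization) log fold-change is recorded
#' in the model's `planted` attribute; note the realized abundance ratio
#' after renormalization is smaller than `fold_change` unless the
#' population is rare.
#'
#' @param model A `secretion_model`.
#' @param population Population name.
#' @param fold_change Multiplier (>= 0; 0 removes the population from the
#'   timepoint).
#' @param timepoint Condition margin shifted (default `"post_IO"`).
#' @return The modified `secretion_model`.
#' @export
plant_da_shift <- function(model, population, fold_change,
                           timepoint = "post_IO") {
  stopifnot(inherits(model, "secretion_model"))
  if (!population %in% names(model$populations)) {
    stop("unknown population: ", population, call. = FALSE)
  }
  if (fold_change < 0) stop("fold_change must be >= 0", call. = FALSE)
  w <- model$weights
  hit <- w$population == population & w$timepoint == timepoint
  w$weight[hit] <- w$weight[hit] * fold_change
  model$weights <- .renormalize_weights(w)
  model$planted <- dplyr::bind_rows(
    model$planted,
    tibble::tibble(population = population, margin = "timepoint",
                   level = timepoint, log_fold_change = log(fold_change)))
  model
}

#' Plant a response-dependent abundance effect
#'
#' Adds `delta_weight` to one population's mixing weight in the
#' `arm` x `tissue` margin (all timepoints), then renormalizes within each
#' condition.
#'
#' @param model A `secretion_model`.
#' @param population Population name.
#' @param delta_weight Additive weight change (resulting weight clamped at
#'   0).
#' @param arm `"CR"` or `"NR"`.
#' @param tissue `"PB"` or `"BM"`.
#' @return The modified `secretion_model`.
#' @export
plant_response_effect <- function(model, population, delta_weight,
                                  arm = "CR", tissue = "BM") {
  stopifnot(inherits(model, "secretion_model"))
  if (!population %in% names(model$populations)) {
    stop("unknown population: ", population, call. = FALSE)
  }
  w <- model$weights
  hit <- w$population == population & w$response == arm &
    w$tissue == tissue
  w$weight[hit] <- pmax(0, w$weight[hit] + delta_weight)
  model$weights <- .renormalize_weights(w)
  model$planted <- dplyr::bind_rows(
    model$planted,
    tibble::tibble(population = population, margin = "response_tissue",
                   level = paste(arm, tissue, sep = ":"),
                   log_fold_change = NA_real_))
  model
}

#' Cohort layout for the simulator
#'
#' Describes patients, sample availability and cell yields. The default
#' mirrors a relapsed/refractory AML checkpoint-blockade cohort: 20
#' patients with baseline peripheral-blood (PB) samples, of whom the first
#' 16 also have baseline bone-marrow (BM) samples, the first 10 have
#' post-immunotherapy (post-IO) PB samples and the first 6 post-IO BM
#' samples; each sample yields on the order of 1,000 profiled cells per
#' T-cell subset.
#'
#' @param n_patients Number of patients.
#' @param cells_per_sample Cells per sample per subset.
#' @param subsets T-cell subsets profiled per sample.
#' @param availability Named vector of patient counts per tissue:timepoint
#'   margin (`PB:baseline`, `BM:baseline`, `PB:post_IO`, `BM:post_IO`);
#'   counts are capped at `n_patients` and assigned to the first patients.
#' @param cr_fraction Fraction of patients labelled complete responders
#'   (assigned deterministically, alternating, to balance arms).
#' @param age_mean,age_sd Normal age distribution parameters (years).
#' @return An object of class `cohort_design` with a `samples` tibble.
#' @export
cohort_design <- function(n_patients = 20, cells_per_sample = 1000,
                          subsets = c("CD4", "CD8"),
                          availability = c("PB:baseline" = 20,
                                           "BM:baseline" = 16,
                                           "PB:post_IO" = 10,
                                           "BM:post_IO" = 6),
                          cr_fraction = 0.5,
                          age_mean = 65, age_sd = 8) {
  stopifnot(n_patients >= 1, cells_per_sample >= 1)
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n_patients)),
    response = "NR")
  # alternate CR through the list so both arms appear in every
  # availability margin, honouring cr_fraction
  n_cr <- round(cr_fraction * n_patients)
  if (n_cr > 0) {
    odd <- seq(1, n_patients, by = 2)
    picks <- c(odd, setdiff(seq_len(n_patients), odd))[seq_len(n_cr)]
    patients$response[picks] <- "CR"
  }
  samples <- purrr::map_dfr(names(availability), function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    n_avail <- min(availability[[key]], n_patients)
    if (n_avail < 1) return(NULL)
    tibble::tibble(patient_id = patients$patient_id[seq_len(n_avail)],
                   tissue = parts[1], timepoint = parts[2])
  }) |>
    dplyr::mutate(sample_id = paste(.data$patient_id, .data$tissue,
                                    .data$timepoint, sep = "_")) |>
    dplyr::left_join(patients, by = "patient_id") |>
    dplyr::select(dplyr::all_of(c("sample_id", "patient_id", "tissue",
                                  "timepoint", "response")))
  structure(list(patients = patients, samples = samples,
                 subsets = subsets, cells_per_sample = cells_per_sample,
                 age_mean = age_mean, age_sd = age_sd),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", nrow(x$patients), " patients, ",
      nrow(x$samples), " samples, ",
      x$cells_per_sample, " cells/sample/subset, subsets: ",
      paste(x$subsets, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Demonstration secretion model
#'
#' Three T-cell subpopulations with distinct cosecretion signatures: a
#' weakly secreting "quiescent" population; an "effector_poly" population
#' cosecreting IFNg, TNFa, MIP-1b and IL8 whose abundance is enriched in
#' complete responders' bone marrow; and a "regulatory" population
#' cosecreting IL4, IL10, IL13 and TGFb1. Includes a patient batch effect
#' (log-scale SD 0.3), a 1% planted high-MFI outlier fraction, and a
#' negative age effect on IL2 secretion intensity.
#'
#' @param panel A `cytokine_panel`.
#' @return A `secretion_model`.
#' @export
default_model <- function(panel = default_panel()) {
  m <- secretion_model(
    list(
      secretion_population("quiescent", character(), prob_lo = 0.05,
                           prob_hi = 0.05, weight = 0.5),
      secretion_population("effector_poly",
                           c("IFNg", "TNFa", "MIP-1b", "IL8"),
                           weight = 0.2),
      secretion_population("regulatory",
                           c("IL4", "IL10", "IL13", "TGFb1"),
                           weight = 0.3)
    ),
    panel = panel,
    batch_effect_sd = 0.3,
    outlier_rate = 0.01,
    age_effect = list(cytokine = "IL2", slope = -0.03, center = 65)
  )
  m <- plant_response_effect(m, "effector_poly", 0.15, arm = "CR",
                             tissue = "BM")
  plant_da_shift(m, "effector_poly", 1.5, timepoint = "post_IO")
}

#' Simulate a single-cell secretome cohort
#'
#' Draws each cell's subpopulation from the model's condition-specific
#' mixing weights, then per cytokine secretes with the population's
#' probability and draws MFI ~ LogNormal(log_mu + patient offset
#' (+ age term), log_sigma); non-secreted channels are exact zeros (or
#' half-normal background when `background_sd > 0`). A planted fraction
#' of cells receives one channel above 3,000 MFI. Deterministic given
#' `seed`.
#'
#' @param design A `cohort_design`.
#' @param model A `secretion_model`.
#' @param seed Integer seed.
#' @return A `secretome` whose `truth` attribute (see [truth_labels()])
#'   records each cell's population and planted-outlier flag.
#' @export
simulate_cohort <- function(design, model, seed = 1) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(model, "secretion_model"))
  set.seed(seed)
  cyt <- model$panel$cytokines
  n_cyt <- length(cyt)
  pops <- model$populations
  pop_names <- names(pops)

  patients <- design$patients
  patients$age <- pmin(90, pmax(18, round(stats::rnorm(
    nrow(patients), design$age_mean, design$age_sd))))
  patients$prior_HSCT <- stats::rbinom(nrow(patients), 1, 0.25) == 1
  patients$secondary_AML <- stats::rbinom(nrow(patients), 1, 0.3) == 1
  offsets <- stats::setNames(
    stats::rnorm(nrow(patients), 0, model$batch_effect_sd),
    patients$patient_id)

  samples <- dplyr::left_join(
    design$samples,
    patients[, c("patient_id", "age", "prior_HSCT", "secondary_AML")],
    by = "patient_id")

  blocks <- tidyr::expand_grid(sample_idx = seq_len(nrow(samples)),
                               subset = design$subsets)
  cell_parts <- vector("list", nrow(blocks))
  mfi_parts <- vector("list", nrow(blocks))
  truth_parts <- vector("list", nrow(blocks))

  for (b in seq_len(nrow(blocks))) {
    s <- samples[blocks$sample_idx[b], ]
    n <- design$cells_per_sample
    w <- model$weights |>
      dplyr::filter(.data$tissue == s$tissue,
                    .data$timepoint == s$timepoint,
                    .data$response == s$response)
    w <- stats::setNames(w$weight, w$population)[pop_names]
    if (sum(w) <= 0) {
      stop("all population weights zero for condition ",
           paste(s$tissue, s$timepoint, s$response), call. = FALSE)
    }
    pop_draw <- sample(pop_names, n, replace = TRUE, prob = w)

    mfi <- matrix(0, n, n_cyt, dimnames = list(NULL, cyt))
    if (model$background_sd > 0) {
      mfi[] <- abs(stats::rnorm(n * n_cyt, 0, model$background_sd))
    }
    for (pn in pop_names) {
      idx <- which(pop_draw == pn)
      if (!length(idx)) next
      p <- pops[[pn]]
      mu <- matrix(p$log_mu, length(idx), n_cyt, byrow = TRUE)
      mu <- mu + offsets[[s$patient_id]]
      ae <- model$age_effect
      if (!is.null(ae)) {
        j <- match(ae$cytokine, cyt)
        ctr <- if (is.null(ae$center)) 65 else ae$center
        mu[, j] <- mu[, j] + ae$slope * (s$age - ctr)
      }
      sec <- matrix(stats::runif(length(idx) * n_cyt), length(idx)) <
        matrix(p$secretion_prob, length(idx), n_cyt, byrow = TRUE)
      val <- exp(mu + matrix(stats::rnorm(length(idx) * n_cyt), length(idx)) *
                   matrix(p$log_sigma, length(idx), n_cyt, byrow = TRUE))
      mfi[idx, ][sec] <- val[sec]
    }

    outlier <- rep(FALSE, n)
    if (model$outlier_rate > 0) {
      n_out <- stats::rbinom(1, n, model$outlier_rate)
      if (n_out > 0) {
        which_out <- sample.int(n, n_out)
        chan <- sample.int(n_cyt, n_out, replace = TRUE)
        mfi[cbind(which_out, chan)] <- stats::runif(
          n_out, model$outlier_range[1], model$outlier_range[2])
        outlier[which_out] <- TRUE
      }
    }

    cell_id <- paste0(s$sample_id, "_", blocks$subset[b], ":", seq_len(n))
    cell_parts[[b]] <- tibble::tibble(
      cell_id = cell_id, sample_id = s$sample_id,
      patient_id = s$patient_id, tissue = s$tissue,
      timepoint = s$timepoint, subset = blocks$subset[b])
    mfi_parts[[b]] <- mfi
    truth_parts[[b]] <- tibble::tibble(cell_id = cell_id,
                                       population = pop_draw,
                                       outlier = outlier)
  }

  cells <- dplyr::bind_cols(
    dplyr::bind_rows(cell_parts),
    tibble::as_tibble(do.call(rbind, mfi_parts)))
  out <- secretome(cells, samples = samples, panel = model$panel)
  attr(out, "truth") <- dplyr::bind_rows(truth_parts)
  out
}
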