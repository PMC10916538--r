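# Shared fixtures: small planted models and cohorts built in code.

# three subpopulations with disjoint cosecretion signatures; the first is
# the response/timepoint-associated effector population
three_pop_model <- function(planted_weight = 0.10, prob_hi = 0.9,
                            prob_lo = 0.05, batch_sd = 0.2,
                            outlier_rate = 0) {
  pops <- list(
    secretion_population("planted", c("IFNg", "TNFa", "MIP-1b", "IL8"),
                         prob_hi = prob_hi, prob_lo = prob_lo,
                         weight = planted_weight),
    secretion_population("bystander", c("IL4", "IL10", "IL13", "TGFb1"),
                         prob_hi = prob_hi, prob_lo = prob_lo,
                         weight = (1 - planted_weight) / 2),
    secretion_population("quiescent", character(), prob_hi = prob_lo,
                         prob_lo = prob_lo,
                         weight = (1 - planted_weight) / 2))
  secretion_model(pops, batch_effect_sd = batch_sd,
                  outlier_rate = outlier_rate)
}

# fully separated populations: deterministic disjoint signatures
separated_model <- function(n_pops = 3) {
  sigs <- list(c("IFNg", "TNFa", "MIP-1b", "IL8"),
               c("IL4", "IL10", "IL13", "TGFb1"),
               c("Granzyme B", "Perforin", "IL2", "IL15"))[seq_len(n_pops)]
  pops <- lapply(seq_len(n_pops), function(i) {
    secretion_population(paste0("pop", i), sigs[[i]], prob_hi = 1,
                         prob_lo = 0, weight = 1 / n_pops)
  })
  secretion_model(pops, batch_effect_sd = 0, outlier_rate = 0)
}

small_design <- function(n_patients = 4, cells = 100,
                         subsets = "CD4",
                         availability = c("PB:baseline" = 4,
                                          "PB:post_IO" = 4)) {
  cohort_design(n_patients = n_patients, cells_per_sample = cells,
                subsets = subsets, availability = availability)
}

# hand-built secretome with explicit MFI values (single sample)
manual_secretome <- function(mfi, subset = "CD4") {
  panel <- default_panel()
  n <- nrow(mfi)
  colnames(mfi) <- panel$cytokines[seq_len(ncol(mfi))]
  full <- matrix(0, n, 32, dimnames = list(NULL, panel$cytokines))
  full[, colnames(mfi)] <- mfi
  cells <- dplyr::bind_cols(
    tibble::tibble(cell_id = paste0("c", seq_len(n)), sample_id = "S1",
                   patient_id = "P1", tissue = "PB",
                   timepoint = "baseline", subset = subset),
    tibble::as_tibble(full))
  secretome(cells)
}

# independent nested-loop PSI oracle over an arbitrary panel
psi_oracle <- function(mfi, thresholds, groups) {
  n <- nrow(mfi)
  calls <- matrix(FALSE, n, ncol(mfi), dimnames = dimnames(mfi))
  for (i in seq_len(n)) for (j in seq_len(ncol(mfi))) {
    calls[i, j] <- mfi[i, j] > thresholds[j]
  }
  poly <- rep(FALSE, n)
  for (i in seq_len(n)) poly[i] <- sum(calls[i, ]) >= 2
  out <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    s <- 0
    for (i in seq_len(n)) {
      if (!poly[i]) next
      for (j in cols) if (calls[i, j]) s <- s + unname(mfi[i, j])
    }
    pct <- 100 * sum(poly) / n
    out[[g]] <- c(pct = pct, mfi_sum = s, psi = pct * s)
  }
  out
}

# plain Benjamini-Hochberg reference used against spatial_fdr
bh_oracle <- function(p) stats::p.adjust(p, method = "BH")
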