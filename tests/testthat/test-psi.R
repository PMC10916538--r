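test_that("secretion calls use a strict threshold comparison", {
  mfi <- matrix(c(0, 50, 100, 150), 2, 2)
  x <- manual_secretome(mfi)
  calls <- call_secretion(x, thresholds = 100)
  m <- mfi_matrix(x)
  expect_identical(unname(calls$calls), unname(m > 100))
  # value exactly at threshold is not called
  expect_false(calls$calls[1, 2])
})

test_that("calls equal the elementwise oracle on random matrices", {
  set.seed(12)
  for (rep in 1:5) {
    mfi <- matrix(round(rexp(50 * 32) * 200), 50, 32)
    x <- manual_secretome(mfi)
    thr <- runif(32, 0, 150)
    calls <- call_secretion(x, stats::setNames(thr, x$panel$cytokines))
    expect_identical(unname(calls$calls), unname(mfi_matrix(x) >
      matrix(thr, 50, 32, byrow = TRUE)))
    expect_equal(polyfunctional_mask(calls),
                 rowSums(calls$calls) >= 2)
  }
})

test_that("a cell needs two positive calls to be polyfunctional", {
  mfi <- rbind(c(100, 0, 0), c(100, 50, 0), c(5, 5, 5))
  x <- manual_secretome(mfi)
  mask <- polyfunctional_mask(call_secretion(x, 0))
  expect_equal(unname(mask), c(FALSE, TRUE, TRUE))
})

test_that("the PSI worked example reproduces by hand", {
  # 10 cells; 2 polyfunctional, each positive for two cytokines of one
  # group at MFI 100 -> pct 20, group mfi_sum 400, PSI 8000
  mfi <- matrix(0, 10, 32)
  mfi[1:2, 5:6] <- 100   # Granzyme B & IFNg: both effector
  x <- manual_secretome(mfi)
  psi <- compute_psi(x)
  eff <- dplyr::filter(psi, group == "effector")
  expect_equal(eff$polyfunctional_pct, 20)
  expect_equal(eff$mfi_sum, 400)
  expect_equal(eff$psi, 8000)
  # the other groups carry the polyfunctional fraction but no MFI
  chem <- dplyr::filter(psi, group == "chemoattractive")
  expect_equal(chem$psi, 0)
  ovr <- dplyr::filter(psi, group == "overall")
  expect_equal(ovr$psi, 8000)
})

test_that("PSI is linear in the MFI of polyfunctional cells", {
  set.seed(3)
  mfi <- matrix(rpois(20 * 32, 30) * rbinom(20 * 32, 1, 0.3), 20, 32)
  x1 <- manual_secretome(mfi)
  x2 <- manual_secretome(mfi * 2.5)
  p1 <- compute_psi(x1, thresholds = 0)
  p2 <- compute_psi(x2, thresholds = 0)
  expect_equal(p2$psi, p1$psi * 2.5)
})

test_that("compute_psi matches the nested-loop oracle exactly", {
  panel5 <- cytokine_panel(LETTERS[1:5],
                           list(g1 = c("A", "B"), g2 = c("C", "D", "E")))
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(1:20, 1)
    mfi <- matrix(round(rexp(n * 5) * 100), n, 5,
                  dimnames = list(NULL, LETTERS[1:5]))
    thr <- runif(5, 0, 80)
    cells <- dplyr::bind_cols(
      tibble::tibble(cell_id = paste0("c", 1:n), sample_id = "S1",
                     patient_id = "P1", tissue = "PB",
                     timepoint = "baseline", subset = "CD4"),
      tibble::as_tibble(mfi))
    x <- secretome(cells, panel = panel5)
    psi <- compute_psi(x, thresholds = stats::setNames(thr, LETTERS[1:5]))
    oracle <- psi_oracle(mfi, thr,
                         list(g1 = c("A", "B"), g2 = c("C", "D", "E"),
                              overall = LETTERS[1:5]))
    for (g in c("g1", "g2", "overall")) {
      row <- dplyr::filter(psi, group == g)
      expect_equal(row$polyfunctional_pct, unname(oracle[[g]]["pct"]))
      expect_equal(row$mfi_sum, unname(oracle[[g]]["mfi_sum"]))
      expect_equal(row$psi, unname(oracle[[g]]["psi"]))
    }
  }
})

test_that("group MFI sums add up to the overall sum", {
  x <- simulate_cohort(small_design(cells = 200), three_pop_model(),
                       seed = 9)
  psi <- compute_psi(x)
  chk <- psi |>
    dplyr::group_by(sample_id, subset) |>
    dplyr::summarise(
      grp = sum(mfi_sum[group != "overall"]),
      ovr = mfi_sum[group == "overall"], .groups = "drop")
  expect_equal(chk$grp, chk$ovr)
})

test_that("identical paired vectors are reported degenerate with p = 1", {
  psi <- tidyr::expand_grid(sample_id = sprintf("S%d", 1:8),
                            subset = "CD4", group = "effector") |>
    dplyr::mutate(psi = 5)
  samples <- tibble::tibble(
    sample_id = sprintf("S%d", 1:8),
    patient_id = rep(sprintf("P%d", 1:4), 2),
    tissue = rep(c("PB", "BM"), each = 4),
    timepoint = "baseline", response = "NR", age = 60)
  ct <- pseudobulk_contrast(psi, samples, "PB_vs_BM")
  expect_equal(ct$p_value, 1)
  expect_match(ct$note, "degenerate")
})

test_that("paired contrasts recover a planted tissue shift", {
  set.seed(31)
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    n_pat <- 10
    base <- rnorm(n_pat, 100, 10)
    psi <- tibble::tibble(
      sample_id = c(sprintf("S%d_PB", 1:n_pat), sprintf("S%d_BM", 1:n_pat)),
      subset = "CD8", group = "effector",
      psi = c(base + 15 + rnorm(n_pat, 0, 10), base + rnorm(n_pat, 0, 10)))
    samples <- tibble::tibble(
      sample_id = psi$sample_id,
      patient_id = rep(sprintf("P%d", 1:n_pat), 2),
      tissue = rep(c("PB", "BM"), each = n_pat),
      timepoint = "baseline", response = "NR", age = 60)
    ct <- pseudobulk_contrast(psi, samples, "PB_vs_BM")
    if (!is.na(ct$p_value) && ct$p_value < 0.05 && ct$estimate > 0) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("unpaired contrast type-I error is near nominal under permutation", {
  set.seed(77)
  vals <- rnorm(16, 50, 8)
  n_perm <- 500
  p <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    arm <- sample(rep(c("CR", "NR"), each = 8))
    psi <- tibble::tibble(sample_id = sprintf("S%d", 1:16),
                          subset = "CD4", group = "overall", psi = vals)
    samples <- tibble::tibble(sample_id = psi$sample_id,
                              patient_id = psi$sample_id,
                              tissue = "BM", timepoint = "baseline",
                              response = arm, age = 60)
    p[i] <- pseudobulk_contrast(psi, samples, "CR_vs_NR",
                                tissue = "BM")$p_value
  }
  expect_gte(mean(p < 0.05), 0.02)
  expect_lte(mean(p < 0.05), 0.08)
})

test_that("insufficient pairs are flagged untestable, not dropped", {
  psi <- tibble::tibble(sample_id = c("S1", "S2"), subset = "CD4",
                        group = "overall", psi = c(1, 2))
  samples <- tibble::tibble(sample_id = c("S1", "S2"),
                            patient_id = "P1",
                            tissue = c("PB", "BM"),
                            timepoint = "baseline", response = "NR",
                            age = 60)
  ct <- pseudobulk_contrast(psi, samples, "PB_vs_BM")
  expect_equal(nrow(ct), 1)
  expect_match(ct$note, "untestable")
  expect_true(is.na(ct$p_value))
})

test_that("covariate correlation finds identity and planted trends", {
  set.seed(5)
  n <- 12
  age <- seq(40, 80, length.out = n)
  psi <- tibble::tibble(sample_id = sprintf("S%d", 1:n), subset = "CD4",
                        group = "IL2", psi = 300 - 3 * age + rnorm(n, 0, 5))
  samples <- tibble::tibble(sample_id = psi$sample_id,
                            patient_id = psi$sample_id, tissue = "PB",
                            timepoint = "baseline", response = "NR",
                            age = age)
  ct <- correlate_covariate(psi, samples)
  expect_lt(ct$rho, -0.8)
  expect_lt(ct$p_value, 0.05)

  # perfect monotone association
  psi2 <- dplyr::mutate(psi, psi = age)
  ct2 <- correlate_covariate(psi2, samples)
  expect_equal(ct2$rho, 1)

  # constant covariate flagged
  ct3 <- correlate_covariate(psi, dplyr::mutate(samples, age = 60))
  expect_match(ct3$note, "untestable")
})

test_that("covariate correlation is calibrated under the null", {
  set.seed(19)
  n_rep <- 400
  sig <- logical(n_rep)
  n <- 10
  samples <- tibble::tibble(sample_id = sprintf("S%d", 1:n),
                            patient_id = sprintf("S%d", 1:n),
                            tissue = "PB", timepoint = "baseline",
                            response = "NR", age = 0)
  crit <- 0.05
  for (i in seq_len(n_rep)) {
    psi <- tibble::tibble(sample_id = samples$sample_id, subset = "CD4",
                          group = "overall", psi = rnorm(n))
    samples$age <- rnorm(n)
    sig[i] <- correlate_covariate(psi, samples)$p_value < crit
  }
  expect_gt(mean(sig), 0.02)
  expect_lt(mean(sig), 0.09)
})
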