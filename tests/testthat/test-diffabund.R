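make_embedding <- function(x, k = 15, seed = 2) {
  run_pipeline(x, pipeline_config(knn_k = k, seed = seed), umap = FALSE)
}

test_that("neighborhood sampling is deterministic and covers at proportion 1", {
  x <- simulate_cohort(small_design(cells = 80), three_pop_model(),
                       seed = 3)
  emb <- make_embedding(x)
  nh1 <- sample_neighborhoods(emb, 0.2, seed = 7)
  nh2 <- sample_neighborhoods(emb, 0.2, seed = 7)
  expect_identical(nh1$index_cells, nh2$index_cells)
  expect_identical(nh1$members, nh2$members)
  # every member list contains its index cell; sizes = k + 1
  expect_true(all(mapply(function(i, mem) i %in% mem,
                         nh1$index_cells, nh1$members)))
  expect_true(all(lengths(nh1$members) == 16))

  # at proportion 1 every cell is a seed; index cells are deduplicated
  # medoids, unique and within range
  nh_full <- sample_neighborhoods(emb, 1, seed = 1)
  expect_equal(anyDuplicated(nh_full$index_cells), 0)
  expect_true(all(nh_full$index_cells %in% seq_len(nrow(emb$cells))))
  nh_full2 <- sample_neighborhoods(emb, 1, seed = 2)
  expect_identical(nh_full$index_cells, nh_full2$index_cells)
})

test_that("neighborhoods never span disconnected populations", {
  x <- simulate_cohort(small_design(cells = 200), separated_model(2),
                       seed = 13)
  emb <- make_embedding(x, k = 10)
  nh <- sample_neighborhoods(emb, 0.3, seed = 5)
  tr <- truth_labels(emb$secretome)$population
  purity <- vapply(nh$members, function(mem) {
    length(unique(tr[mem]))
  }, 0L)
  expect_true(all(purity == 1))
})

test_that("cell counting equals a brute-force tally", {
  x <- simulate_cohort(small_design(cells = 60), three_pop_model(),
                       seed = 8)
  emb <- make_embedding(x, k = 8)
  nh <- sample_neighborhoods(emb, 0.2, seed = 3)
  counts <- count_cells(nh, emb$cells)
  expect_true(all(rowSums(counts) == lengths(nh$members)))
  for (i in sample(seq_along(nh$members), 5)) {
    tally <- table(emb$cells$sample_id[nh$members[[i]]])
    for (s in names(tally)) {
      expect_equal(unname(counts[i, s]), unname(tally[s]))
    }
  }
})

test_that("balanced counts give near-zero LFC and large p", {
  counts <- matrix(rep(c(5L, 5L, 5L, 10L, 10L, 10L), 4), 4, byrow = TRUE)
  colnames(counts) <- sprintf("S%d", 1:6)
  design <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                           timepoint = rep(c("baseline", "post_IO"),
                                           each = 3),
                           total = c(100, 100, 100, 200, 200, 200))
  res <- test_da(counts, design)
  expect_true(all(abs(res$log_fold_change) < 1e-6))
  expect_true(all(res$p_value > 0.9))
})

test_that("all-zero neighborhoods are flagged untestable", {
  counts <- rbind(c(0L, 0L, 0L, 0L), c(3L, 4L, 5L, 6L))
  colnames(counts) <- sprintf("S%d", 1:4)
  design <- tibble::tibble(sample_id = sprintf("S%d", 1:4),
                           timepoint = rep(c("baseline", "post_IO"), 2),
                           total = rep(100, 4))
  res <- test_da(counts, design)
  expect_match(res$note[1], "all-zero")
  expect_true(is.na(res$p_value[1]))
  expect_false(is.na(res$p_value[2]))
})

test_that("spatial FDR reduces to BH with equal distances", {
  set.seed(55)
  for (rep in 1:50) {
    p <- runif(sample(5:200, 1))
    expect_equal(spatial_fdr(p, rep(1, length(p))), bh_oracle(p))
  }
  # trivial cases
  expect_equal(spatial_fdr(rep(1, 5), runif(5)), rep(1, 5))
  p1 <- 0.037
  expect_equal(spatial_fdr(p1, 2), p1)
  # zero distances are capped, not infinite-weighted
  p <- c(0.01, 0.5, 0.9)
  expect_true(all(is.finite(spatial_fdr(p, c(0, 1, 2)))))
  # NA p-values pass through
  p_na <- c(0.01, NA, 0.5)
  out <- spatial_fdr(p_na, c(1, 1, 1))
  expect_true(is.na(out[2]))
  expect_equal(out[!is.na(out)], bh_oracle(p_na[!is.na(p_na)]))
})

test_that("exclusivity classification depends only on membership", {
  nh <- structure(list(index_cells = c(1L, 3L, 5L),
                       members = list(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                       kth_distance = c(1, 1, 1),
                       cell_ids = paste0("c", 1:6)),
                  class = "neighborhood_set")
  meta <- tibble::tibble(timepoint = c("baseline", "baseline", "post_IO",
                                       "post_IO", "baseline", "post_IO"))
  labels <- classify_exclusivity(nh, meta)
  expect_equal(labels, c("baseline_only", "post_only", "mixed"))
})

test_that("the exclusivity summary reproduces printed cohort arithmetic", {
  # CD4: 2,158 neighborhoods, 982 baseline-only, 29 post-only
  cd4 <- c(rep("baseline_only", 982), rep("post_only", 29),
           rep("mixed", 2158 - 982 - 29))
  s4 <- summarize_exclusivity(cd4)
  expect_equal(s4$pct[s4$class == "baseline_only"], 45.5)
  expect_equal(s4$pct[s4$class == "post_only"], 1.3)

  # CD8: 2,706 neighborhoods, 1,097 baseline-only, 23 post-only
  cd8 <- c(rep("baseline_only", 1097), rep("post_only", 23),
           rep("mixed", 2706 - 1097 - 23))
  s8 <- summarize_exclusivity(cd8)
  expect_equal(s8$pct[s8$class == "baseline_only"], 40.5)
  expect_equal(s8$pct[s8$class == "post_only"], 0.85)
})

test_that("exclusive neighborhoods vanish as size grows under mixing", {
  # random balanced timepoints: P(exclusive) = 2^-(size-1) * 2
  set.seed(10)
  n_cells <- 5000
  meta <- tibble::tibble(timepoint = sample(c("baseline", "post_IO"),
                                            n_cells, replace = TRUE))
  frac <- vapply(c(3, 8, 15), function(size) {
    members <- lapply(1:400, function(i) sample.int(n_cells, size))
    nh <- structure(list(index_cells = vapply(members, `[`, 0L, 1),
                         members = members,
                         kth_distance = rep(1, 400),
                         cell_ids = paste0("c", 1:n_cells)),
                    class = "neighborhood_set")
    mean(classify_exclusivity(nh, meta) != "mixed")
  }, 0)
  expect_true(all(diff(frac) <= 0))
  expect_lt(frac[3], 0.005)
})

test_that("beeswarm export joins cluster, DA and exclusivity by row", {
  x <- simulate_cohort(small_design(cells = 60), three_pop_model(),
                       seed = 2)
  emb <- make_embedding(x, k = 8)
  da <- run_da(emb, proportion = 0.2)
  bs <- da$result
  expect_true(all(c("nhood", "cluster", "log_fold_change", "p_value",
                    "spatial_fdr", "exclusivity") %in% names(bs)))
  i <- 1
  expect_equal(bs$cluster[i],
               emb$clusters[da$nhoods$index_cells[bs$nhood[i]]])
  # round trip through CSV preserves the table
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bs, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$log_fold_change, bs$log_fold_change)
  expect_equal(back$exclusivity, bs$exclusivity)
})

test_that("no planted shift keeps significant fraction at the FDR level", {
  m <- three_pop_model()
  x <- simulate_cohort(small_design(n_patients = 8, cells = 300,
                                    availability = c("PB:baseline" = 8,
                                                     "PB:post_IO" = 8)),
                       m, seed = 71)
  emb <- make_embedding(x, k = 40, seed = 3)
  da <- run_da(emb, proportion = 0.1)
  sig <- mean(da$result$spatial_fdr < 0.1, na.rm = TRUE)
  expect_lt(sig, 0.1 + 3 * sqrt(0.1 * 0.9 / sum(!is.na(da$result$spatial_fdr))))
})
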