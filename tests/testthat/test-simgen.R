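test_that("image generator handles the zero-spot case", {
  cfg <- image_sim_config(n_spots_range = c(0, 0), height = 64, width = 64)
  sim <- simulate_ev_image(cfg, seed = 11)
  expect_equal(sim$gt$true_count, 0)
  expect_equal(sum(sim$gt$true_mask), 0)
  expect_equal(nrow(sim$gt$centers), 0)
})

test_that("image generation is a pure function of (config, seed)", {
  cfg <- image_sim_config(height = 64, width = 64, n_spots_range = c(3, 8))
  a <- simulate_ev_image(cfg, seed = 7)
  b <- simulate_ev_image(cfg, seed = 7)
  expect_identical(a, b)
  d1 <- simulate_image_dataset(cfg, 3, seed = 1)
  d2 <- simulate_image_dataset(cfg, 3, seed = 1)
  expect_identical(d1, d2)
})

test_that("ground truth is internally consistent", {
  cfg <- image_sim_config(height = 96, width = 96, n_spots_range = c(1, 15))
  for (s in 1:10) {
    sim <- simulate_ev_image(cfg, seed = s)
    gt <- sim$gt
    expect_equal(gt$true_count, nrow(gt$centers))
    expect_true(all(gt$centers[, 1] >= 1 & gt$centers[, 1] <= 96))
    expect_true(all(gt$centers[, 2] >= 1 & gt$centers[, 2] <= 96))
    expect_lte(gt$mask_components, gt$true_count)
    expect_true(all(dim(gt$true_mask) == c(96, 96)))
    expect_true(all(sim$image >= 0 & sim$image <= 1))
  }
})

test_that("dataset generation scales to a training-corpus size", {
  cfg <- image_sim_config(height = 32, width = 32, n_spots_range = c(1, 3),
                          min_separation_px = 6)
  ds <- simulate_image_dataset(cfg, 115, seed = 1)
  expect_length(ds, 115)
  counts <- vapply(ds, function(p) p$gt$true_count, integer(1))
  expect_true(all(counts >= 1 & counts <= 3))
  expect_error(simulate_image_dataset(cfg, 0, seed = 1), "n_images")
})

test_that("generator rejects invalid configurations by field name", {
  expect_error(image_sim_config(n_spots_range = c(-1, 3)), "n_spots_range")
  expect_error(image_sim_config(spot_amplitude_range = c(0.01, 0.02)),
               "spot_amplitude_range")
  expect_error(image_sim_config(gaussian_sd = -1), "gaussian_sd")
  expect_error(image_sim_config(n_channels = 3, green_index = 5),
               "green_index")
})

test_that("planted fold change is recovered exactly without Cq noise", {
  for (fc in c(1, 0.25)) {
    cfg <- cohort_sim_config(n_patients = 8, n_controls = 8,
                             planted_fold_change = fc, reference_cq_sd = 0)
    tab <- simulate_cq_table(cfg, seed = 2)
    dcq <- delta_cq(tab)
    grp <- unique(tab[, c("sample_id", "group")])
    out <- fold_change(dcq, dcq[grp$sample_id[grp$group == "control"]])
    expect_equal(unname(out[grp$sample_id[grp$group == "case"]]),
                 rep(fc, 8), tolerance = 1e-12)
  }
})

test_that("undetected reactions carry the run-length sentinel", {
  cfg <- cohort_sim_config(n_patients = 30, n_controls = 10,
                           detection_dropout = 0.3)
  tab <- simulate_cq_table(cfg, seed = 4)
  expect_true(any(tab$cq == 45))
  expect_true(all(tab$cq <= 45))
  expect_equal(attr(tab, "max_cycles"), 45)
})

test_that("survival simulation honours the censoring configuration", {
  cfg <- cohort_sim_config(n_patients = 40, censoring_rate = 0)
  st <- simulate_survival_table(cfg, seed = 3)
  expect_true(all(st$event == 1))
  expect_true(all(st$time_months > 0))
  cfg2 <- cohort_sim_config(n_patients = 400, censoring_rate = 0.5)
  st2 <- simulate_survival_table(cfg2, seed = 3)
  expect_gt(mean(st2$event == 0), 0.4)
  expect_lt(mean(st2$event == 0), 0.6)
  expect_error(cohort_sim_config(hazard_ratio_low_vs_high = -2),
               "hazard_ratio")
})

test_that("log-rank power is high under a strong planted hazard ratio", {
  cfg <- cohort_sim_config(n_patients = 200, hazard_ratio_low_vs_high = 4,
                           censoring_rate = 0)
  hits <- vapply(1:30, function(s) {
    st <- simulate_survival_table(cfg, seed = s)
    logrank_test(st$time_months, st$event, st$expression_group)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("omics fixture is deterministic and validates its config", {
  cfg <- omics_sim_config()
  a <- simulate_omics_fixture(cfg, seed = 5)
  b <- simulate_omics_fixture(cfg, seed = 5)
  expect_identical(a, b)
  expect_error(omics_sim_config(planted_pathway = "not_a_pathway"),
               "absent from pathway_db")
})

test_that("omics fixture invariants hold", {
  fx <- simulate_omics_fixture(omics_sim_config(), seed = 9)
  expect_true(all(fx$mirna_edges$gene %in% fx$deg_table$gene_id))
  expect_true(all(vapply(fx$pathway_db, function(p)
    length(unlist(p)) > 0, logical(1))))
  expect_true(all(fx$features$mz > 0))
  expect_true(all(fx$metabolite_matrix >= 0))
  expect_true(all(fx$annotation_library$annotation_level %in%
                    c("1", "2a", "2b", "3")))
})
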