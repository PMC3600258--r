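test_that("the copies-to-Ct law has the documented closed form", {
  p <- sim_params()
  expect_equal(ct_from_copies(1, TRUE, p), 38.0)
  expect_equal(ct_from_copies(1024, TRUE, p), 28.0)   # 38 - log2(1024)
  expect_equal(ct_from_copies(1024, FALSE, p), 40.0)  # + mismatch penalty
  expect_gt(ct_from_copies(8, FALSE, p), p$max_cycle) # 47 -> never crosses
  # delta-Ct of 2 <=> 4-fold template difference at perfect doubling
  for (cp in c(10, 1e3, 1e6)) {
    expect_equal(ct_from_copies(cp, TRUE, p) - ct_from_copies(4 * cp, TRUE, p),
                 2.0)
  }
  # general log-E spacing
  pe <- sim_params(efficiency = 1.9)
  expect_equal(ct_from_copies(100, TRUE, pe) - ct_from_copies(700, TRUE, pe),
               log(7) / log(1.9))
  expect_error(ct_from_copies(0, TRUE, p), class = "tpmt_input_error")
})

test_that("simulated wells behave like the assay", {
  p <- sim_params()
  set.seed(1)
  # matched high-copy template amplifies near the closed-form Ct
  w <- simulate_well("hom_wt", "wt", 1e5, p)
  expect_equal(w$target_ct, ct_from_copies(1e5, TRUE, p), tolerance = 1)
  expect_false(is.na(w$ipc_ct))

  # mismatched primer is late by about the mismatch penalty
  wm <- simulate_well("hom_wt", "var", 1e5, p)
  expect_gt(wm$target_ct, w$target_ct + p$mismatch_penalty - 3 * p$ct_noise_sd)

  # no template: target silent, IPC still amplifies
  w0 <- simulate_well("hom_wt", "wt", 0, p)
  expect_true(is.na(w0$target_ct))
  expect_false(is.na(w0$ipc_ct))
})

test_that("with no noise and full detection the model is deterministic", {
  p <- sim_params(ct_noise_sd = 0, ipc_ct_sd = 0, fluor_noise_sd = 0,
                  per_copy_detection_eff = 1,
                  snp_detection_eff = c("c.719A>G" = 1))
  a <- simulate_well("het", "wt", 5e4, p, "c.460G>A")
  b <- simulate_well("het", "wt", 5e4, p, "c.460G>A")
  expect_identical(a, b)
  expect_equal(a$target_ct, ct_from_copies(2.5e4, TRUE, p))
})

test_that("the noise-free pipeline recovers every diplotype", {
  panel <- load_panel()
  p <- sim_params(ct_noise_sd = 0, ipc_ct_sd = 0, fluor_noise_sd = 0,
                  per_copy_detection_eff = 1,
                  snp_detection_eff = c("c.719A>G" = 1))
  pairs <- all_allele_pairs(panel)
  labels <- vapply(pairs, paste, "", collapse = "/")
  run <- run_small_panel(labels, params = p)
  samples <- run$calls$samples
  for (i in seq_along(pairs)) {
    sid <- run$truth$sample_id[(i - 1) * 3 + 1]
    row <- samples[samples$sample_id == sid, ]
    if (row$ambiguous) {
      alts <- c(row$diplotype, strsplit(row$alternatives, ";")[[1]])
      expect_true(labels[i] %in% alts)
    } else {
      expect_identical(row$diplotype, labels[i])
    }
  }
})

test_that("panel simulation writes a consistent, seed-deterministic plate", {
  d1 <- tempfile("simA")
  d2 <- tempfile("simB")
  d3 <- tempfile("simC")
  strata <- data.frame(diplotype = c("*1/*1", "*1/*3C"), n = c(2L, 1L),
                       conc_ng_per_ul = 10)
  s1 <- simulate_panel(strata, sim_params(seed = 101), d1, mode = "ct")
  s2 <- simulate_panel(strata, sim_params(seed = 101), d2, mode = "ct")
  s3 <- simulate_panel(strata, sim_params(seed = 102), d3, mode = "ct")
  for (f in c("layout.csv", "ct.csv", "meta.csv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "ct.csv")),
                         readLines(file.path(d3, "ct.csv"))))
  # 3 samples x 3 SNPs x 2 primers = 18 wells, 36 Ct rows
  expect_equal(nrow(s1$layout), 18)
  expect_equal(nrow(s1$truth), 9)

  bad <- strata
  bad$n[1] <- 0L
  expect_error(simulate_panel(bad, sim_params(), tempfile(), mode = "ct"),
               class = "tpmt_input_error")
})

test_that("the validation-panel preset has the published composition", {
  strata <- paper_panel_strata()
  expect_equal(sum(strata$n), 246)
  expect_equal(sum(strata$n[strata$group == "patient"]), 244)
  expect_equal(sum(strata$n[strata$diplotype == "*1/*3C" &
                              strata$group == "patient"]), 10)
  g <- golden_run()
  expect_equal(nrow(g$sim$layout), 246 * 6)
  expect_equal(nrow(g$truth), 246 * 3)
})

test_that("the dilution series reproduces the calibrated detection limits", {
  lod_default <- estimate_lod(sim_params(), snp_id = "c.238G>C",
                              replicates = 20, seed = 17)
  expect_equal(lod_default$lod, 100)
  lod_719 <- estimate_lod(sim_params(), snp_id = "c.719A>G",
                          replicates = 20, seed = 17)
  expect_equal(lod_719$lod, 1000)
  # an ideal assay detects 100 copies essentially always
  ideal <- estimate_lod(sim_params(per_copy_detection_eff = 1,
                                   snp_detection_eff = c("c.719A>G" = 1)),
                        snp_id = "c.719A>G", replicates = 20, seed = 17)
  expect_lte(ideal$lod, 100)

  expect_error(estimate_lod(replicates = 3), class = "tpmt_input_error")
  expect_error(estimate_lod(grid = c(100, 1000)), class = "tpmt_input_error")
})

test_that("noise-free delta-Ct equals the log-efficiency copy ratio", {
  p <- sim_params(ct_noise_sd = 0, per_copy_detection_eff = 1)
  for (r in c(2, 4, 10, 64)) {
    expect_equal(ct_from_copies(1e3, TRUE, p) - ct_from_copies(1e3 * r, TRUE, p),
                 log(r) / log(p$efficiency))
  }
})
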