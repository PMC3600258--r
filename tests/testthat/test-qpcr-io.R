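panel <- load_panel()

# write a tiny 1-sample curve-mode plate and return the dir
tiny_plate_dir <- function(diplotype = "*1/*3C", seed = 31L) {
  dir <- tempfile("tiny")
  strata <- data.frame(diplotype = diplotype, n = 1L, conc_ng_per_ul = 10,
                       id_prefix = "SAMPLE1", stringsAsFactors = FALSE)
  simulate_panel(strata, sim_params(seed = seed), dir, mode = "curves",
                 panel = panel)
  dir
}

test_that("layout + curves load into a validated plate", {
  dir <- tiny_plate_dir()
  plate <- read_curves(file.path(dir, "layout.csv"),
                       file.path(dir, "curves.csv"),
                       file.path(dir, "meta.csv"), panel)
  expect_s3_class(plate, "qpcr_plate")
  expect_equal(nrow(plate$layout), 6)       # 3 SNPs x 2 primers
  expect_equal(nrow(plate$curves), 6 * 2 * 45)
  expect_equal(plate$meta$dna_conc_ng_per_ul, 10)
})

test_that("malformed curve inputs fail with informative errors", {
  dir <- tiny_plate_dir()
  layout_path <- file.path(dir, "layout.csv")
  curves <- utils::read.csv(file.path(dir, "curves.csv"))
  well <- curves$well_id[1]

  # missing IPC channel for one well, error names the well
  broken <- curves[!(curves$well_id == well & curves$channel == "IPC"), ]
  f <- tempfile(fileext = ".csv")
  utils::write.csv(broken, f, row.names = FALSE)
  expect_error(read_curves(layout_path, f, panel = panel), well)

  # duplicated (well, channel, cycle)
  dup <- rbind(curves, curves[1, ])
  utils::write.csv(dup, f, row.names = FALSE)
  expect_error(read_curves(layout_path, f, panel = panel),
               class = "tpmt_input_error")

  # non-contiguous cycles
  gap <- curves[!(curves$well_id == well & curves$channel == "TARGET" &
                    curves$cycle == 20), ]
  utils::write.csv(gap, f, row.names = FALSE)
  expect_error(read_curves(layout_path, f, panel = panel), "contiguous")

  # duplicated (sample, snp, primer) triple in the layout
  layout <- utils::read.csv(layout_path)
  dup_layout <- rbind(layout, transform(layout[1, ], well_id = "Z9"))
  lf <- tempfile(fileext = ".csv")
  utils::write.csv(dup_layout, lf, row.names = FALSE)
  expect_error(read_curves(lf, file.path(dir, "curves.csv"), panel = panel),
               class = "tpmt_input_error")

  # snp_id unknown to the panel
  alien <- transform(layout, snp_id = sub("c.238G>C", "c.999G>T", snp_id,
                                          fixed = TRUE))
  utils::write.csv(alien, lf, row.names = FALSE)
  expect_error(read_curves(lf, file.path(dir, "curves.csv"), panel = panel),
               "c.999G>T")
})

test_that("Ct tables parse numbers, UNDETERMINED, and reject bad values", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("well_id,channel,ct",
               "A1,TARGET,24.31",
               "A1,IPC,UNDETERMINED"), f)
  tab <- read_ct_table(f)
  expect_equal(tab$ct[1], 24.31)
  expect_true(is.na(tab$ct[2]))

  writeLines(c("well_id,channel,ct", "A1,TARGET,-3"), f)
  expect_error(read_ct_table(f), class = "tpmt_input_error")
  writeLines(c("well_id,channel,ct", "A1,TARGET,46.2"), f)
  expect_error(read_ct_table(f), class = "tpmt_input_error")
  writeLines(c("well_id,channel,ct", "A1,TARGET,oops"), f)
  expect_error(read_ct_table(f), class = "tpmt_input_error")
})

test_that("Ct and genotype tables round-trip losslessly", {
  cts <- data.frame(well_id = c("A1", "A1", "B1"),
                    channel = c("TARGET", "IPC", "TARGET"),
                    ct = c(24.312345, NA, 41.25))
  f <- tempfile(fileext = ".csv")
  write_ct_table(cts, f)
  back <- read_ct_table(f, max_cycle = 45)
  expect_equal(back$ct, cts$ct)
  expect_identical(back$well_id, cts$well_id)

  g <- data.frame(sample_id = c("S1", "S1", "S2"),
                  snp_id = rep(c("c.719A>G", "c.460G>A"), length.out = 3),
                  genotype = c("het", "hom_wt", "no_call"),
                  stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_genotypes(g, tf)
  expect_equal(read_genotypes(tf), g)
})

test_that("reports carry genotypes, diplotypes and QC through to disk", {
  run <- run_small_panel(c("*1/*1", "*1/*3C"), params = sim_params(seed = 5))
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  report <- write_report(run$calls, tsv, js, seed = 5)

  expect_equal(nrow(report), 2)   # one row per sample
  wt <- report[report$diplotype == "*1/*1", ]
  expect_identical(unname(unlist(
    wt[paste0(panel$snps$snp_id, "_genotype")])), rep("hom_wt", 3))
  expect_identical(wt$phenotype, "normal")
  het <- report[report$diplotype == "*1/*3C", ]
  expect_identical(het[["c.719A>G_genotype"]], "het")
  expect_identical(het$phenotype, "intermediate")

  disk <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(disk), 2)
  expect_true(all(c("diplotype", "ambiguous", "phenotype", "qc_flags") %in%
                    names(disk)))
  j <- jsonlite::read_json(js)
  expect_identical(j$software$package, "tpmtqpcr")
  expect_equal(j$seed, 5)
  expect_equal(j$config$delta_ct_threshold, 2)
  expect_length(j$samples, 2)
})

test_that("an IPC failure propagates to a flagged no_call report row", {
  run <- run_small_panel("*1/*1", params = sim_params(seed = 9))
  # force an IPC failure in one well of c.460G>A
  plate <- run$plate
  i <- which(plate$layout$snp_id == "c.460G>A" &
               plate$layout$primer_allele == "var")
  well <- plate$layout$well_id[i]
  j <- which(plate$cts$well_id == well & plate$cts$channel == "IPC")
  plate$cts$ct[j] <- 32
  calls <- call_plate(plate, panel)
  sc <- calls$snp_calls
  expect_identical(sc$genotype[sc$snp_id == "c.460G>A"], "no_call")
  expect_match(sc$qc_flags[sc$snp_id == "c.460G>A"], "IPC_FAIL_VAR_WELL")
  expect_identical(calls$samples$phenotype, "indeterminate")
  expect_true(is.na(calls$samples$diplotype))
  report <- write_report(calls)
  expect_match(report$qc_flags, "IPC_FAIL_VAR_WELL")
})
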