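# Shared fixtures, all generated in code at test time.

# One cached full-size validation-panel run (curves mode, seed 17),
# shared by the simulator, popstats and acceptance tests.
.golden <- new.env(parent = emptyenv())

golden_run <- function() {
  if (!is.null(.golden$res)) return(.golden$res)
  dir <- file.path(tempdir(), "tpmtqpcr-golden")
  panel <- load_panel()
  params <- sim_params(seed = 17L)
  sim <- simulate_panel(paper_panel_strata(), params, dir, mode = "curves",
                        panel = panel)
  plate <- read_curves(file.path(dir, "layout.csv"),
                       file.path(dir, "curves.csv"),
                       file.path(dir, "meta.csv"), panel)
  calls <- call_plate(plate, panel)
  truth <- read_genotypes(file.path(dir, "truth.tsv"))
  .golden$res <- list(dir = dir, panel = panel, params = params, sim = sim,
                      calls = calls, truth = truth)
  .golden$res
}

# Simulate a small plate (Ct-table mode) for the given diplotypes and call
# it; returns list(calls, truth, sim, plate).
run_small_panel <- function(diplotypes, params = sim_params(),
                            conc = 10, config = run_config()) {
  dir <- tempfile("plate")
  panel <- load_panel()
  strata <- data.frame(diplotype = diplotypes, n = 1L,
                       conc_ng_per_ul = conc,
                       id_prefix = sprintf("D%02d", seq_along(diplotypes)),
                       stringsAsFactors = FALSE)
  sim <- simulate_panel(strata, params, dir, mode = "ct", panel = panel)
  plate <- read_ct_table(file.path(dir, "ct.csv"),
                         file.path(dir, "layout.csv"),
                         file.path(dir, "meta.csv"),
                         max_cycle = params$max_cycle)
  calls <- call_plate(plate, panel, config)
  list(calls = calls, truth = sim$truth, sim = sim, plate = plate, dir = dir)
}

# All unordered pairs of panel alleles.
all_allele_pairs <- function(panel) {
  a <- names(panel$alleles)
  idx <- which(upper.tri(diag(length(a)), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) sort(c(a[idx[i, 1]], a[idx[i, 2]])))
}

# Independent oracle: genotype vector implied by an allele pair, computed
# directly from the panel's variant sets (no package internals).
oracle_pair_genotypes <- function(pair, panel) {
  vapply(panel$snps$snp_id, function(sid) {
    carriers <- sum(sid %in% panel$alleles[[pair[1]]]$variant_snps,
                    sid %in% panel$alleles[[pair[2]]]$variant_snps)
    c("hom_wt", "het", "hom_var")[carriers + 1]
  }, "")
}

# Write a panel YAML built from a raw list; returns the path.
write_raw_panel <- function(raw) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  path
}

raw_default_panel <- function() {
  yaml::read_yaml(default_panel_path())
}
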