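#' Simulation parameters for the duplex allele-specific assay
#'
#' Constants of the generative model that emulates the assay: a log-linear
#' copies-to-Ct law, a fixed Ct penalty for primer/template mismatch,
#' binomial per-copy detection (whose zero class produces detection
#' failures at low template input), Gaussian Ct and fluorescence noise,
#' and a logistic amplification-curve shape.
#'
#' @param efficiency Per-cycle amplification factor E in (1, 2]; 2 is
#'   perfect doubling, under which a Ct difference of 2 corresponds
#'   exactly to a 4-fold template difference.
#' @param ct_intercept Ct of a single matched template copy (cycles).
#' @param mismatch_penalty Extra cycles for a 3'-mismatched primer on the
#'   wrong allele; drives the large delta-Ct of homozygotes.
#' @param ct_noise_sd SD of Gaussian noise added to each well's Ct.
#' @param ipc_ct_mean,ipc_ct_sd Internal-positive-control Ct distribution.
#' @param copies_per_ng Template copies per ng of genomic DNA per uL
#'   (assay calibration constant: 1 ng/uL corresponds to 1e3 copies/uL).
#' @param template_volume_ul Template volume per reaction (uL); converts
#'   copies/uL to copies/reaction.
#' @param per_copy_detection_eff Probability that an individual template
#'   copy seeds a detectable amplification; the binomial zero class sets
#'   the limit of detection. Calibrated so the default assay's LOD is 100
#'   copies/reaction.
#' @param snp_detection_eff Named per-SNP overrides of
#'   `per_copy_detection_eff`; the default lowers c.719A>G to 0.01 so its
#'   LOD is 1000 copies/reaction, reproducing that target's lower
#'   sensitivity.
#' @param max_cycle Number of PCR cycles; model Cts beyond this never
#'   cross threshold (UNDETERMINED).
#' @param fmax,k,baseline,drift,fluor_noise_sd Curve rendering: plateau
#'   fluorescence, logistic steepness (per cycle), constant background,
#'   linear drift per cycle, and per-reading Gaussian noise SD.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(efficiency = 2.0,
                       ct_intercept = 38.0,
                       mismatch_penalty = 12.0,
                       ct_noise_sd = 0.15,
                       ipc_ct_mean = 24.0,
                       ipc_ct_sd = 0.3,
                       copies_per_ng = 1000,
                       template_volume_ul = 5,
                       per_copy_detection_eff = 0.05,
                       snp_detection_eff = c("c.719A>G" = 0.01),
                       max_cycle = 45L,
                       fmax = 3.0,
                       k = 1.8,
                       baseline = 0.5,
                       drift = 0.002,
                       fluor_noise_sd = 0.01,
                       seed = 17L) {
  p <- list(efficiency = efficiency, ct_intercept = ct_intercept,
            mismatch_penalty = mismatch_penalty, ct_noise_sd = ct_noise_sd,
            ipc_ct_mean = ipc_ct_mean, ipc_ct_sd = ipc_ct_sd,
            copies_per_ng = copies_per_ng,
            template_volume_ul = template_volume_ul,
            per_copy_detection_eff = per_copy_detection_eff,
            snp_detection_eff = snp_detection_eff,
            max_cycle = as.integer(max_cycle), fmax = fmax, k = k,
            baseline = baseline, drift = drift,
            fluor_noise_sd = fluor_noise_sd, seed = as.integer(seed))
  stopifnot(efficiency > 1, efficiency <= 2,
            ct_intercept > 0, mismatch_penalty > 0,
            ct_noise_sd >= 0, ipc_ct_sd >= 0,
            copies_per_ng > 0, template_volume_ul > 0,
            per_copy_detection_eff > 0, per_copy_detection_eff <= 1,
            all(snp_detection_eff > 0), all(snp_detection_eff <= 1),
            max_cycle > 0, fmax > 0, k > 0, fluor_noise_sd >= 0)
  structure(p, class = "sim_params")
}

detection_eff <- function(params, snp_id) {
  if (!is.null(snp_id) && snp_id %in% names(params$snp_detection_eff)) {
    unname(params$snp_detection_eff[[snp_id]])
  } else {
    params$per_copy_detection_eff
  }
}

#' Copies per reaction from a DNA concentration
#'
#' `conc * copies_per_ng * template_volume_ul`: with the defaults,
#' 1 ng/uL corresponds to 1e3 copies/uL and a reaction receives 5 uL of
#' template, so 10 ng/uL puts 5e4 copies in the well.
#'
#' @param conc_ng_per_ul DNA concentration (ng/uL).
#' @param params [sim_params()].
#' @return Template copies per reaction.
#' @export
copies_per_reaction <- function(conc_ng_per_ul, params = sim_params()) {
  conc_ng_per_ul * params$copies_per_ng * params$template_volume_ul
}

#' Deterministic Ct from template copies
#'
#' The log-linear core of the simulator:
#' `Ct = A - log(copies)/log(E) + penalty[!matched]`, where A is the Ct of
#' a single matched copy and E the per-cycle efficiency. With E = 2 this
#' is the classic identity that each Ct cycle is one template doubling, so
#' a delta-Ct of 2 corresponds to a 4-fold template difference. Values
#' above `max_cycle` mean the reaction never crosses threshold.
#'
#' @param copies Positive template copy number(s).
#' @param matched Logical: does the allele-specific primer match the
#'   template allele?
#' @param params [sim_params()].
#' @return Ct in cycles (may exceed `max_cycle`; vectorized).
#' @examples
#' ct_from_copies(1024, TRUE)            # 38 - 10 = 28
#' ct_from_copies(4, TRUE) - ct_from_copies(16, TRUE)  # 2 cycles per 4-fold
#' @export
ct_from_copies <- function(copies, matched = TRUE, params = sim_params()) {
  if (any(copies <= 0)) stop_input("copies must be > 0")
  params$ct_intercept - log(copies) / log(params$efficiency) +
    ifelse(matched, 0, params$mismatch_penalty)
}

# Stochastic thinning: number of template copies that seed detectable
# amplification. Binomial(n, p); degenerate (deterministic) at p = 1.
rdetect <- function(copies, p) {
  n <- round(copies)
  if (n <= 0) return(0L)
  if (p >= 1) return(n)
  stats::rbinom(1L, n, p)
}

#' Simulate one allele-specific well
#'
#' Draws the target-channel and IPC-channel Cts for a single duplex
#' reaction. Template copies matching the primer (all, half, or none of
#' the input depending on genotype) amplify on-time; the mismatched
#' allele's copies amplify with the mismatch penalty; each route is
#' subject to binomial per-copy detection and the earlier defined route
#' wins. A route whose Ct exceeds `max_cycle`, or that detects zero
#' copies, is UNDETERMINED (`NA`).
#'
#' @param genotype `"hom_wt"`, `"het"`, or `"hom_var"` at this SNP.
#' @param primer_allele `"wt"` or `"var"`: which allele the well's primer
#'   targets.
#' @param total_copies Total template copies in the reaction (>= 0).
#' @param params [sim_params()].
#' @param snp_id Optional SNP id, used for per-SNP detection efficiency.
#' @return List with `target_ct`, `ipc_ct` (numeric, `NA` = UNDETERMINED).
#' @export
simulate_well <- function(genotype, primer_allele, total_copies,
                          params = sim_params(), snp_id = NULL) {
  stopifnot(genotype %in% c("hom_wt", "het", "hom_var"),
            primer_allele %in% PRIMER_ALLELES, total_copies >= 0)
  matched_frac <- switch(genotype,
    hom_wt = if (primer_allele == "wt") 1 else 0,
    het = 0.5,
    hom_var = if (primer_allele == "var") 1 else 0)
  p <- detection_eff(params, snp_id)
  route_ct <- function(copies, matched) {
    det <- rdetect(copies, p)
    if (det == 0) return(NA_real_)
    ct <- ct_from_copies(det / p, matched, params)
    if (params$ct_noise_sd > 0) ct <- ct + stats::rnorm(1, 0, params$ct_noise_sd)
    ct
  }
  cts <- c(route_ct(total_copies * matched_frac, TRUE),
           route_ct(total_copies * (1 - matched_frac), FALSE))
  cts <- cts[!is.na(cts) & cts <= params$max_cycle]
  target_ct <- if (length(cts) == 0) NA_real_ else min(cts)
  ipc_ct <- params$ipc_ct_mean +
    if (params$ipc_ct_sd > 0) stats::rnorm(1, 0, params$ipc_ct_sd) else 0
  list(target_ct = target_ct, ipc_ct = ipc_ct)
}

#' Render an amplification curve for a given Ct
#'
#' Produces the raw per-cycle fluorescence the instrument would record for
#' a reaction whose threshold crossing is at `ct`: constant background +
#' linear drift + a logistic sigmoid positioned so that, after baseline
#' correction, the noise-free signal crosses the nominal threshold
#' (10x the fluorescence noise SD, or 1e-6 of the plateau for a noise-free
#' render) exactly at `ct`, plus Gaussian read noise. `ct = NA` renders a
#' non-amplifying (baseline-only) well.
#'
#' @param ct Target threshold cycle, or `NA`.
#' @param params [sim_params()].
#' @param channel Unused label, kept for clarity of call sites.
#' @return data.frame with columns `cycle`, `fluorescence`.
#' @export
render_curve <- function(ct, params = sim_params(), channel = "TARGET") {
  cyc <- seq_len(params$max_cycle)
  f <- params$baseline + params$drift * cyc
  if (!is.na(ct)) {
    x0 <- ct + log(params$fmax / render_threshold(params) - 1) / params$k
    f <- f + params$fmax / (1 + exp(-params$k * (cyc - x0)))
  }
  if (params$fluor_noise_sd > 0) {
    f <- f + stats::rnorm(length(cyc), 0, params$fluor_noise_sd)
  }
  data.frame(cycle = cyc, fluorescence = f)
}

render_threshold <- function(params) {
  max(10 * params$fluor_noise_sd, 1e-6 * params$fmax)
}

#' Analytic threshold-crossing cycle of a rendered curve
#'
#' Closed-form crossing point of the noise-free sigmoid rendered by
#' [render_curve()] for nominal Ct `ct`, evaluated at an arbitrary
#' fluorescence `threshold`. Serves as the exact oracle for the Ct
#' estimator.
#'
#' @inheritParams render_curve
#' @param threshold Fluorescence threshold (0 < threshold < `fmax`).
#' @return Crossing cycle (real; may fall outside 1..max_cycle).
#' @export
crossing_cycle <- function(ct, threshold, params = sim_params()) {
  stopifnot(threshold > 0, threshold < params$fmax)
  x0 <- ct + log(params$fmax / render_threshold(params) - 1) / params$k
  x0 - log(params$fmax / threshold - 1) / params$k
}

#' Stratum table for the shipped validation-panel preset
#'
#' 244 patient samples (234 wild-type, 10 heterozygous *1/*3C) plus two
#' reference cell-line DNAs (one *1/*3B, one *1/*3C), all at 10 ng/uL.
#'
#' @return data.frame with columns `diplotype`, `n`, `conc_ng_per_ul`,
#'   `group`, `id_prefix`.
#' @export
paper_panel_strata <- function() {
  data.frame(
    diplotype = c("*1/*1", "*1/*3C", "*1/*3B", "*1/*3C"),
    n = c(234L, 10L, 1L, 1L),
    conc_ng_per_ul = 10,
    group = c("patient", "patient", "control", "control"),
    id_prefix = c("S", "S", "NA09301", "NA03579"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a whole validation panel to disk
#'
#' Expands a stratum table (diplotype, sample count, DNA concentration)
#' into per-sample, per-SNP, per-primer duplex wells, simulates every
#' well, and writes the plate files in the package's I/O dialects:
#' `layout.csv`, `meta.csv`, `truth.tsv` (reference genotype table) and
#' either `ct.csv` or full `curves.csv`. Output is bit-identical for a
#' given seed.
#'
#' @param strata data.frame like [paper_panel_strata()]; `id_prefix` with
#'   `n = 1` is used verbatim as the sample id.
#' @param params [sim_params()]; `params$seed` seeds all randomness.
#' @param dir Output directory (created if needed).
#' @param mode `"curves"` writes raw amplification curves; `"ct"` writes a
#'   pre-computed Ct table.
#' @param panel [load_panel()] object.
#' @return Invisibly, a list with the file `paths`, the `truth` genotype
#'   table, and the per-sample `samples` table.
#' @export
simulate_panel <- function(strata = paper_panel_strata(),
                           params = sim_params(),
                           dir,
                           mode = c("curves", "ct"),
                           panel = load_panel()) {
  mode <- match.arg(mode)
  if (any(strata$n < 1)) stop_input("every stratum must have n >= 1")
  if (!all(c("diplotype", "n", "conc_ng_per_ul") %in% names(strata))) {
    stop_input("strata needs columns diplotype, n, conc_ng_per_ul")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)

  samples <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    prefix <- if ("id_prefix" %in% names(strata)) s$id_prefix else "S"
    ids <- if (s$n == 1 && !prefix %in% c("S", "")) prefix
           else sprintf("%s%03d", prefix, seq_len(s$n))
    data.frame(sample_id = ids, diplotype = s$diplotype,
               conc_ng_per_ul = s$conc_ng_per_ul,
               group = if ("group" %in% names(strata)) s$group else "sample",
               stringsAsFactors = FALSE)
  }))
  # re-number patient-style ids consecutively across strata with same prefix
  dup_prefix <- grepl("^S[0-9]+$", samples$sample_id)
  samples$sample_id[dup_prefix] <- sprintf("S%03d", seq_len(sum(dup_prefix)))
  if (anyDuplicated(samples$sample_id)) stop_input("duplicate sample ids")

  snp_ids <- panel$snps$snp_id
  grid <- expand.grid(sample_idx = seq_len(nrow(samples)),
                      snp_id = snp_ids, primer_allele = PRIMER_ALLELES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_idx, match(grid$snp_id, snp_ids),
                     match(grid$primer_allele, PRIMER_ALLELES)), ]
  grid$well_id <- well_ids(nrow(grid))
  grid$sample_id <- samples$sample_id[grid$sample_idx]

  truth <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    pair <- parse_diplotype(samples$diplotype[i], panel)
    g <- genotypes_from_pair(pair, panel)
    data.frame(sample_id = samples$sample_id[i], snp_id = names(g),
               genotype = unname(g), stringsAsFactors = FALSE)
  }))
  truth_key <- paste(truth$sample_id, truth$snp_id)

  sims <- lapply(seq_len(nrow(grid)), function(j) {
    g <- grid[j, ]
    geno <- truth$genotype[match(paste(g$sample_id, g$snp_id), truth_key)]
    copies <- copies_per_reaction(samples$conc_ng_per_ul[g$sample_idx], params)
    simulate_well(geno, g$primer_allele, copies, params, snp_id = g$snp_id)
  })
  grid$target_ct <- vapply(sims, `[[`, 0, "target_ct")
  grid$ipc_ct <- vapply(sims, `[[`, 0, "ipc_ct")

  layout <- grid[c("well_id", "sample_id", "snp_id", "primer_allele")]
  meta <- data.frame(sample_id = samples$sample_id,
                     dna_conc_ng_per_ul = samples$conc_ng_per_ul,
                     group = samples$group, stringsAsFactors = FALSE)

  paths <- list(layout = file.path(dir, "layout.csv"),
                meta = file.path(dir, "meta.csv"),
                truth = file.path(dir, "truth.tsv"))
  write_atomic(function(f) utils::write.csv(layout, f, row.names = FALSE,
                                            quote = FALSE), paths$layout)
  write_atomic(function(f) utils::write.csv(meta, f, row.names = FALSE,
                                            quote = FALSE), paths$meta)
  write_genotypes(truth, paths$truth)

  if (mode == "ct") {
    ct_tab <- rbind(
      data.frame(well_id = grid$well_id, channel = "TARGET",
                 ct = ct_token(grid$target_ct, params$max_cycle)),
      data.frame(well_id = grid$well_id, channel = "IPC",
                 ct = ct_token(grid$ipc_ct, params$max_cycle)))
    ct_tab <- ct_tab[order(match(ct_tab$well_id, grid$well_id),
                           ct_tab$channel), ]
    paths$ct <- file.path(dir, "ct.csv")
    write_atomic(function(f) utils::write.csv(ct_tab, f, row.names = FALSE,
                                              quote = FALSE), paths$ct)
  } else {
    curves <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
      tc <- render_curve(grid$target_ct[j], params)
      ic <- render_curve(grid$ipc_ct[j], params)
      data.frame(well_id = grid$well_id[j],
                 channel = rep(CHANNELS, each = params$max_cycle),
                 cycle = c(tc$cycle, ic$cycle),
                 fluorescence = sprintf("%.6f", c(tc$fluorescence,
                                                  ic$fluorescence)),
                 stringsAsFactors = FALSE)
    }))
    paths$curves <- file.path(dir, "curves.csv")
    write_atomic(function(f) utils::write.csv(curves, f, row.names = FALSE,
                                              quote = FALSE), paths$curves)
  }
  invisible(list(paths = paths, truth = truth, samples = samples,
                 layout = layout))
}

ct_token <- function(ct, max_cycle) {
  ifelse(is.na(ct) | ct > max_cycle, "UNDETERMINED", sprintf("%.4f", ct))
}

well_ids <- function(n) {
  # 96-well plates A1..H12, prefixed by plate number once n > 96
  per <- 96L
  plate <- (seq_len(n) - 1L) %/% per + 1L
  pos <- (seq_len(n) - 1L) %% per
  coord <- paste0(LETTERS[pos %/% 12L + 1L], pos %% 12L + 1L)
  if (n <= per) coord else sprintf("P%02d-%s", plate, coord)
}

parse_diplotype <- function(s, panel) {
  pair <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(pair) != 2 || !all(pair %in% names(panel$alleles))) {
    stop_input("invalid diplotype '", s, "' for this panel")
  }
  pair
}

#' Estimate the analytical limit of detection
#'
#' Runs a serial-dilution experiment in silico: for each template level
#' (copies/reaction, decreasing powers of 10), simulates `replicates`
#' duplex well pairs on a homozygous-variant template and calls the
#' genotype with [call_snp()]. The LOD is the smallest template level at
#' which at least `min_correct` of replicates (and every level above it)
#' are called `hom_var`.
#'
#' @param params [sim_params()].
#' @param snp_id SNP to assay (sets the per-SNP detection efficiency).
#' @param grid Template levels in copies/reaction, decreasing.
#' @param replicates Wells per level (>= 4).
#' @param min_correct Required fraction of correct calls (default 0.95).
#' @param delta_threshold,max_cycle Calling parameters, as [call_snp()].
#' @param seed Seed (defaults to `params$seed`).
#' @return List: `lod` (copies/reaction, `NA` if never reliable),
#'   `detail` data.frame of per-level correct-call rates.
#' @export
estimate_lod <- function(params = sim_params(), snp_id = NULL,
                         grid = 10^(7:2), replicates = 20L,
                         min_correct = 0.95, delta_threshold = 2.0,
                         max_cycle = params$max_cycle,
                         seed = params$seed) {
  if (replicates < 4) stop_input("replicates must be >= 4 (use quadruplicate or more)")
  if (is.unsorted(rev(grid), strictly = TRUE)) {
    stop_input("grid must be strictly decreasing")
  }
  set.seed(seed)
  rate <- vapply(grid, function(copies) {
    ok <- vapply(seq_len(replicates), function(r) {
      wt <- simulate_well("hom_var", "wt", copies, params, snp_id)
      var <- simulate_well("hom_var", "var", copies, params, snp_id)
      call_snp(wt$target_ct, var$target_ct,
               delta_threshold, max_cycle)$genotype == "hom_var"
    }, TRUE)
    mean(ok)
  }, 0)
  passing <- rate >= min_correct
  run_len <- if (all(passing)) length(grid) else which(!passing)[1] - 1L
  lod <- if (run_len >= 1) grid[run_len] else NA_real_
  list(lod = lod,
       detail = data.frame(copies_per_reaction = grid, correct_rate = rate,
                           pass = passing))
}
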