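#' Internal-positive-control QC gate
#'
#' A duplex reaction is considered successful only if its co-amplified
#' internal positive control (GAPDH channel) produced a Ct strictly below
#' `ipc_max_ct`. An undetermined IPC fails: it indicates reaction failure
#' or inhibition, so the target channel cannot be interpreted.
#'
#' @param ipc_ct IPC Ct (numeric; `NA` = UNDETERMINED).
#' @param ipc_max_ct QC bound in cycles (default 30; strict inequality).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @examples
#' qc_ipc(24)   # TRUE
#' qc_ipc(30)   # FALSE: boundary fails the strict Ct < 30 rule
#' qc_ipc(NA)   # FALSE
#' @export
qc_ipc <- function(ipc_ct, ipc_max_ct = 30.0) {
  !is.na(ipc_ct) & ipc_ct < ipc_max_ct
}

#' Call one SNP genotype from a duplex well pair
#'
#' The delta-Ct interpretation rule: with both allele-specific reactions
#' amplifying, `delta = |ct_wt - ct_var|`; `delta < delta_threshold` is a
#' heterozygote, `delta >= delta_threshold` a homozygote for the allele
#' with the *smaller* (earlier) Ct. The boundary counts as homozygous
#' because under perfect doubling a 2-cycle difference already implies at
#' least a 4-fold allele imbalance, impossible for a germline
#' heterozygote. If only one reaction amplified within `max_cycle`, the
#' sample is homozygous for that allele (the limiting case of a very
#' large delta): delta is recorded as `max_cycle` minus the defined Ct,
#' floored at `delta_threshold`. If neither amplified the SNP is a
#' `no_call` flagged `NO_AMPLIFICATION`.
#'
#' @param ct_wt,ct_var Target-channel Cts of the wild-type-specific and
#'   variant-specific wells (`NA` = UNDETERMINED).
#' @param delta_threshold Calling threshold in cycles (default 2.0).
#' @param max_cycle Cycle count of the protocol (default 45).
#' @return List with `genotype`, `delta_ct` (`NA` when not applicable)
#'   and `qc_flags`.
#' @examples
#' call_snp(24.0, 24.6)$genotype   # "het"
#' call_snp(24.0, 36.5)$genotype   # "hom_wt"
#' call_snp(NA, 25.1)$genotype     # "hom_var"
#' @export
call_snp <- function(ct_wt, ct_var, delta_threshold = 2.0, max_cycle = 45) {
  wt_def <- !is.na(ct_wt)
  var_def <- !is.na(ct_var)
  if (wt_def && var_def) {
    delta <- abs(ct_wt - ct_var)
    genotype <- if (delta < delta_threshold) "het"
                else if (ct_wt < ct_var) "hom_wt" else "hom_var"
    list(genotype = genotype, delta_ct = delta, qc_flags = character())
  } else if (wt_def || var_def) {
    defined <- if (wt_def) ct_wt else ct_var
    list(genotype = if (wt_def) "hom_wt" else "hom_var",
         delta_ct = max(max_cycle - defined, delta_threshold),
         qc_flags = character())
  } else {
    list(genotype = "no_call", delta_ct = NA_real_,
         qc_flags = "NO_AMPLIFICATION")
  }
}

#' Call all panel SNPs for one sample
#'
#' Applies the per-well IPC gate, then the delta-Ct rule per SNP. An IPC
#' failure in either of a SNP's two wells voids that SNP only (flags
#' `IPC_FAIL_WT_WELL` / `IPC_FAIL_VAR_WELL`), not the whole sample,
#' because the control verifies each individual reaction. A DNA input
#' below `min_input_ng_per_ul` adds the advisory flag `LOW_INPUT` (calls
#' are still attempted — the minimum input is a reproducibility
#' requirement, not an interpretation rule); unknown input adds
#' `LOW_INPUT_UNKNOWN`.
#'
#' @param sample_wells data.frame with one row per well: columns `snp_id`,
#'   `primer_allele`, `target_ct`, `ipc_ct`.
#' @param panel [load_panel()] object.
#' @param dna_conc_ng_per_ul Sample DNA concentration, or `NA` if unknown.
#' @param config [run_config()].
#' @return data.frame of per-SNP calls: `snp_id`, `genotype`, `ct_wt`,
#'   `ct_var`, `delta_ct`, `qc_flags` (comma-joined).
#' @export
call_sample <- function(sample_wells, panel, dna_conc_ng_per_ul = NA,
                        config = run_config()) {
  input_flags <- character()
  if (is.na(dna_conc_ng_per_ul)) {
    input_flags <- "LOW_INPUT_UNKNOWN"
  } else if (dna_conc_ng_per_ul < config$min_input_ng_per_ul) {
    input_flags <- "LOW_INPUT"
  }
  do.call(rbind, lapply(panel$snps$snp_id, function(sid) {
    rows <- sample_wells[sample_wells$snp_id == sid, ]
    wt <- rows[rows$primer_allele == "wt", ]
    var <- rows[rows$primer_allele == "var", ]
    if (nrow(wt) != 1 || nrow(var) != 1) {
      stop_input("sample is missing a wt/var well pair for SNP ", sid)
    }
    flags <- input_flags
    ct_wt <- wt$target_ct
    ct_var <- var$target_ct
    if (!qc_ipc(wt$ipc_ct, config$ipc_max_ct)) {
      flags <- c(flags, "IPC_FAIL_WT_WELL")
    }
    if (!qc_ipc(var$ipc_ct, config$ipc_max_ct)) {
      flags <- c(flags, "IPC_FAIL_VAR_WELL")
    }
    if (any(grepl("^IPC_FAIL", flags))) {
      call <- list(genotype = "no_call", delta_ct = NA_real_)
    } else {
      call <- call_snp(ct_wt, ct_var, config$delta_ct_threshold,
                       config$max_cycle)
      flags <- c(flags, call$qc_flags)
    }
    data.frame(snp_id = sid, genotype = call$genotype,
               ct_wt = ct_wt, ct_var = ct_var, delta_ct = call$delta_ct,
               qc_flags = join_flags(flags), stringsAsFactors = FALSE)
  }))
}

#' Pipeline configuration
#'
#' Bundles the interpretation constants: the delta-Ct calling threshold
#' (2 cycles), the IPC QC bound (Ct < 30), the protocol cycle count (45),
#' the minimum reproducible DNA input (5 ng/uL) and the phase-ambiguity
#' policy.
#'
#' @param delta_ct_threshold Calling threshold, cycles.
#' @param ipc_max_ct IPC pass bound, cycles (strict).
#' @param max_cycle PCR cycles per run.
#' @param min_input_ng_per_ul Advisory minimum DNA input.
#' @param ambiguity_policy `"prior"` (rank ambiguous diplotypes by
#'   population priors) or `"worst_case"` (report the one with the worse
#'   phenotype).
#' @param baseline_window Baseline cycles for Ct estimation.
#' @return List of class `run_config`.
#' @export
run_config <- function(delta_ct_threshold = 2.0, ipc_max_ct = 30.0,
                       max_cycle = 45L, min_input_ng_per_ul = 5.0,
                       ambiguity_policy = c("prior", "worst_case"),
                       baseline_window = c(3L, 15L)) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(delta_ct_threshold > 0, ipc_max_ct > 0, max_cycle > 0,
            min_input_ng_per_ul >= 0)
  structure(list(delta_ct_threshold = delta_ct_threshold,
                 ipc_max_ct = ipc_max_ct, max_cycle = as.integer(max_cycle),
                 min_input_ng_per_ul = min_input_ng_per_ul,
                 ambiguity_policy = ambiguity_policy,
                 baseline_window = baseline_window),
            class = "run_config")
}

#' Run the full interpretation pipeline on a plate
#'
#' From a plate (curves or pre-computed Cts) to per-SNP genotype calls,
#' star-allele diplotypes and metabolizer phenotypes for every sample.
#' Curves, when present, are Ct-estimated first with [compute_ct()]'s
#' auto-threshold procedure (one shared plate-wide threshold floor).
#'
#' @param plate A `qpcr_plate` from [read_curves()] or [read_ct_table()]
#'   + layout.
#' @param panel [load_panel()] object.
#' @param config [run_config()].
#' @return Object of class `tpmt_calls`: list with `snp_calls` (per
#'   sample x SNP), `samples` (per-sample diplotype/phenotype table),
#'   `config`, `panel_gene` and `version`.
#' @export
call_plate <- function(plate, panel = load_panel(), config = run_config()) {
  stopifnot(inherits(plate, "qpcr_plate"))
  unknown <- setdiff(plate$layout$snp_id, panel$snps$snp_id)
  if (length(unknown) > 0) {
    stop_input("layout references SNP(s) not in panel: ",
               paste(unique(unknown), collapse = ", "))
  }
  if (is.null(plate$cts)) {
    if (is.null(plate$curves)) stop_input("plate has neither curves nor Cts")
    plate$cts <- estimate_cts_df(plate$curves, config$baseline_window)
  }
  wells <- plate$layout
  key <- paste(plate$cts$well_id, plate$cts$channel)
  wells$target_ct <- plate$cts$ct[match(paste(wells$well_id, "TARGET"), key)]
  wells$ipc_ct <- plate$cts$ct[match(paste(wells$well_id, "IPC"), key)]

  meta <- plate$meta
  sample_ids <- unique(wells$sample_id)
  snp_calls <- do.call(rbind, lapply(sample_ids, function(sid) {
    conc <- if (!is.null(meta) && sid %in% meta$sample_id) {
      meta$dna_conc_ng_per_ul[match(sid, meta$sample_id)]
    } else NA_real_
    calls <- call_sample(wells[wells$sample_id == sid, ], panel, conc, config)
    cbind(sample_id = sid, calls, stringsAsFactors = FALSE)
  }))

  samples <- do.call(rbind, lapply(sample_ids, function(sid) {
    sc <- snp_calls[snp_calls$sample_id == sid, ]
    diplotype_row(sid, sc, panel, config)
  }))

  structure(list(snp_calls = snp_calls, samples = samples, config = config,
                 panel_gene = panel$gene,
                 version = as.character(utils::packageVersion("tpmtqpcr"))),
            class = "tpmt_calls")
}

#' @export
print.tpmt_calls <- function(x, ...) {
  cat("<tpmt_calls>", nrow(x$samples), "samples,",
      nrow(x$snp_calls), "SNP calls\n")
  print(utils::head(x$samples, 10))
  if (nrow(x$samples) > 10) cat("...\n")
  invisible(x)
}

#' @export
summary.tpmt_calls <- function(object, ...) {
  cat("Samples:", nrow(object$samples), "\n")
  cat("Diplotypes:\n")
  print(table(object$samples$diplotype, useNA = "ifany"))
  cat("Phenotypes:\n")
  print(table(object$samples$phenotype))
  flagged <- object$snp_calls$qc_flags != ""
  cat("SNP calls with QC flags:", sum(flagged), "of",
      nrow(object$snp_calls), "\n")
  invisible(object)
}
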