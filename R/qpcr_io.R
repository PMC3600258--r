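#' Read a plate layout plus raw amplification curves
#'
#' Joins a layout CSV (columns `well_id,sample_id,snp_id,primer_allele`)
#' with a long-format curve CSV (`well_id,channel,cycle,fluorescence`;
#' channels `TARGET` and `IPC`, 1-based contiguous cycles) and an
#' optional sample-metadata CSV (`sample_id,dna_conc_ng_per_ul`).
#' Validates that every layout well has both channels, cycles are
#' contiguous without duplicates, and each (sample, SNP, primer) triple
#' appears once. The curve dialect is a deliberately minimal superset of
#' common instrument exports; RDML import is out of scope.
#'
#' @param layout_path,curves_path,meta_path File paths (`meta_path`
#'   optional).
#' @param panel Optional [load_panel()] object; when given, layout
#'   `snp_id`s are validated against it.
#' @return Object of class `qpcr_plate`: list with `layout`, `curves`,
#'   `meta` (or `NULL`), `cts` (`NULL` until estimated).
#' @export
read_curves <- function(layout_path, curves_path, meta_path = NULL,
                        panel = NULL) {
  layout <- read_layout(layout_path, panel)
  curves <- read_table_checked(curves_path,
                               c("well_id", "channel", "cycle", "fluorescence"),
                               what = "curve CSV")
  curves$cycle <- as.integer(curves$cycle)
  curves$fluorescence <- as.numeric(curves$fluorescence)
  if (any(!curves$channel %in% CHANNELS)) {
    stop_input("curve CSV has channel(s) other than ",
               paste(CHANNELS, collapse = "/"))
  }
  if (any(curves$fluorescence < 0, na.rm = TRUE) ||
      anyNA(curves$fluorescence)) {
    stop_input("curve CSV has missing or negative fluorescence values")
  }
  key <- paste(curves$well_id, curves$channel, curves$cycle)
  if (anyDuplicated(key)) {
    stop_input("duplicate (well, channel, cycle) row(s) in curve CSV, e.g. ",
               key[duplicated(key)][1])
  }
  grp <- paste(curves$well_id, curves$channel)
  need <- as.vector(outer(layout$well_id, CHANNELS, paste))
  absent <- setdiff(need, unique(grp))
  if (length(absent) > 0) {
    stop_input("missing channel curve for well(s): ",
               paste(utils::head(absent, 3), collapse = "; "))
  }
  contiguous <- vapply(split(curves$cycle, grp), function(cyc) {
    all(diff(sort(cyc)) == 1)
  }, TRUE)
  if (!all(contiguous)) {
    stop_input("non-contiguous cycles in well/channel: ",
               names(contiguous)[!contiguous][1])
  }
  extra <- setdiff(unique(curves$well_id), layout$well_id)
  if (length(extra) > 0) {
    stop_input("curve CSV has well(s) absent from layout: ",
               paste(extra, collapse = ", "))
  }
  structure(list(layout = layout, curves = curves,
                 meta = read_meta(meta_path), cts = NULL),
            class = "qpcr_plate")
}

read_layout <- function(path, panel = NULL) {
  layout <- read_table_checked(path,
                               c("well_id", "sample_id", "snp_id",
                                 "primer_allele"), what = "layout CSV")
  if (any(!layout$primer_allele %in% PRIMER_ALLELES)) {
    stop_input("layout primer_allele must be one of: ",
               paste(PRIMER_ALLELES, collapse = "/"))
  }
  if (anyDuplicated(layout$well_id)) {
    stop_input("duplicate well_id in layout")
  }
  trip <- paste(layout$sample_id, layout$snp_id, layout$primer_allele)
  if (anyDuplicated(trip)) {
    stop_input("duplicate (sample, SNP, primer) in layout: ",
               trip[duplicated(trip)][1])
  }
  if (!is.null(panel)) {
    unknown <- setdiff(layout$snp_id, panel$snps$snp_id)
    if (length(unknown) > 0) {
      stop_input("layout references SNP(s) not in panel: ",
                 paste(unknown, collapse = ", "))
    }
  }
  layout
}

read_meta <- function(path) {
  if (is.null(path)) return(NULL)
  meta <- read_table_checked(path, c("sample_id", "dna_conc_ng_per_ul"),
                             what = "sample metadata CSV")
  meta$dna_conc_ng_per_ul <- as.numeric(meta$dna_conc_ng_per_ul)
  if (any(meta$dna_conc_ng_per_ul < 0, na.rm = TRUE)) {
    stop_input("dna_conc_ng_per_ul must be non-negative")
  }
  meta
}

#' Read a pre-computed Ct table
#'
#' For instruments that export Cts rather than raw curves: CSV with
#' columns `well_id,channel,ct`, where `ct` is a number in
#' (0, `max_cycle`] or the literal token `UNDETERMINED`.
#'
#' @param path Ct CSV path.
#' @param layout_path Optional layout CSV to attach, making the result a
#'   callable plate.
#' @param meta_path Optional sample metadata CSV.
#' @param max_cycle Upper bound for valid Cts.
#' @return With a layout, a `qpcr_plate`; otherwise the bare Ct
#'   data.frame (`ct` is `NA` for UNDETERMINED).
#' @export
read_ct_table <- function(path, layout_path = NULL, meta_path = NULL,
                          max_cycle = 45) {
  tab <- read_table_checked(path, c("well_id", "channel", "ct"),
                            what = "Ct CSV")
  if (any(!tab$channel %in% CHANNELS)) {
    stop_input("Ct CSV has channel(s) other than ",
               paste(CHANNELS, collapse = "/"))
  }
  raw <- trimws(as.character(tab$ct))
  undet <- raw == "UNDETERMINED"
  ct <- suppressWarnings(as.numeric(raw))
  if (any(is.na(ct) & !undet)) {
    stop_input("Ct CSV has non-numeric ct that is not UNDETERMINED: ",
               raw[is.na(ct) & !undet][1])
  }
  if (any(ct[!undet] <= 0) || any(ct[!undet] > max_cycle)) {
    stop_input("Ct values must lie in (0, ", max_cycle, "]")
  }
  ct[undet] <- NA_real_
  tab$ct <- ct
  key <- paste(tab$well_id, tab$channel)
  if (anyDuplicated(key)) {
    stop_input("duplicate (well, channel) in Ct CSV: ",
               key[duplicated(key)][1])
  }
  if (is.null(layout_path)) return(tab)
  layout <- read_layout(layout_path)
  missing <- setdiff(as.vector(outer(layout$well_id, CHANNELS, paste)), key)
  if (length(missing) > 0) {
    stop_input("Ct CSV is missing (well, channel): ",
               paste(utils::head(missing, 3), collapse = "; "))
  }
  structure(list(layout = layout, curves = NULL,
                 meta = read_meta(meta_path), cts = tab),
            class = "qpcr_plate")
}

#' Write a Ct table
#'
#' Inverse of [read_ct_table()]; `NA` Cts are written as `UNDETERMINED`.
#'
#' @param cts data.frame with `well_id`, `channel`, `ct`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(cts, path) {
  out <- cts[c("well_id", "channel", "ct")]
  out$ct <- ifelse(is.na(out$ct), "UNDETERMINED", format(out$ct, digits = 15))
  write_atomic(function(f) utils::write.csv(out, f, row.names = FALSE,
                                            quote = FALSE), path)
}

#' Read / write a genotype table
#'
#' TSV with columns `sample_id`, `snp_id`, `genotype` (one of `hom_wt`,
#' `het`, `hom_var`, `no_call`), one row per (sample, SNP): the format of
#' reference-method genotypes and of simulator truth tables.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_genotypes <- function(path) {
  tab <- read_table_checked(path, c("sample_id", "snp_id", "genotype"),
                            sep = "\t", what = "genotype TSV")
  bad <- setdiff(unique(tab$genotype), GENOTYPES)
  if (length(bad) > 0) {
    stop_input("genotype TSV has invalid genotype value(s): ",
               paste(bad, collapse = ", "))
  }
  if (anyDuplicated(paste(tab$sample_id, tab$snp_id))) {
    stop_input("genotype TSV has duplicate (sample, SNP) rows")
  }
  tab
}

#' @rdname read_genotypes
#' @param genotypes data.frame with `sample_id`, `snp_id`, `genotype`.
#' @export
write_genotypes <- function(genotypes, path) {
  write_atomic(function(f) {
    utils::write.table(genotypes[c("sample_id", "snp_id", "genotype")], f,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }, path)
}

#' Write per-sample interpretation reports
#'
#' Emits the flat TSV report (one row per sample: per-SNP genotype and
#' delta-Ct columns, diplotype, ambiguity flag, phenotype, QC flags;
#' Cts and delta-Cts rounded to 2 decimals) and a JSON report carrying
#' full provenance: every Ct and threshold, the resolved configuration,
#' package version and, when supplied, the simulation seed.
#'
#' @param calls `tpmt_calls` object from [call_plate()].
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @param seed Optional integer recorded in the JSON provenance block.
#' @return Invisibly, the report data.frame.
#' @export
write_report <- function(calls, tsv_path = NULL, json_path = NULL,
                         seed = NULL) {
  stopifnot(inherits(calls, "tpmt_calls"))
  snp_ids <- unique(calls$snp_calls$snp_id)
  wide <- calls$samples["sample_id"]
  for (sid in snp_ids) {
    sc <- calls$snp_calls[calls$snp_calls$snp_id == sid, ]
    m <- match(wide$sample_id, sc$sample_id)
    wide[[paste0(sid, "_genotype")]] <- sc$genotype[m]
    wide[[paste0(sid, "_delta_ct")]] <- round(sc$delta_ct[m], 2)
  }
  report <- cbind(wide,
                  calls$samples[c("diplotype", "ambiguous", "alternatives",
                                  "phenotype", "alt_phenotype", "qc_flags")])
  if (!is.null(tsv_path)) {
    write_atomic(function(f) {
      utils::write.table(report, f, sep = "\t", row.names = FALSE,
                         quote = FALSE, na = "")
    }, tsv_path)
  }
  if (!is.null(json_path)) {
    payload <- list(
      software = list(package = "tpmtqpcr", version = calls$version),
      config = unclass(calls$config),
      seed = seed,
      samples = calls$samples,
      snp_calls = within(calls$snp_calls, {
        ct_wt <- round(ct_wt, 4); ct_var <- round(ct_var, 4)
        delta_ct <- round(delta_ct, 4)
      }))
    write_atomic(function(f) {
      jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
    }, json_path)
  }
  invisible(report)
}
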