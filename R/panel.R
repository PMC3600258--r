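#' Load a genotyping panel definition
#'
#' A panel declares the biallelic SNPs assayed, the star alleles they
#' compose, population priors used only to rank phase-ambiguous diplotype
#' explanations, and the map from the number of nonfunctional alleles in a
#' diplotype to a metabolizer phenotype. Everything downstream (calling,
#' diplotyping, reporting) is driven by this object, so supporting a new
#' panel is a data change, not a code change.
#'
#' The file format is schema-versioned YAML with keys `snps[]` (`snp_id`,
#' `rsid`, `wt_base`, `var_base`, `protein_change`), `alleles[]` (`name`,
#' `variant_snps`, `prior_freq`, `functional`) and `phenotype_map`. The
#' shipped default is the three-SNP TPMT panel (c.238G>C, c.460G>A,
#' c.719A>G) defining alleles *1, *2, *3A, *3B and *3C.
#'
#' @param path Path to a panel YAML file, or `NULL` for the shipped default
#'   TPMT panel.
#' @return An object of class `pcr_panel`: a list with elements `snps`
#'   (data.frame), `alleles` (named list), `phenotype_map` (named character
#'   vector keyed by nonfunctional-allele count) and `schema_version`.
#' @examples
#' panel <- load_panel()
#' panel$snps$snp_id
#' @export
load_panel <- function(path = NULL) {
  path <- path %||% default_panel_path()
  if (!file.exists(path)) stop_panel("panel file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_panel("panel YAML parse error: ",
                                                 conditionMessage(e)))
  as_pcr_panel(raw)
}

#' @rdname load_panel
#' @export
default_panel_path <- function() {
  system.file("extdata", "tpmt_panel.yaml", package = "tpmtqpcr",
              mustWork = TRUE)
}

as_pcr_panel <- function(raw) {
  for (k in c("snps", "alleles", "phenotype_map")) {
    if (is.null(raw[[k]])) stop_panel("panel is missing key '", k, "'")
  }
  snps <- do.call(rbind, lapply(raw$snps, function(s) {
    for (k in c("snp_id", "wt_base", "var_base")) {
      if (is.null(s[[k]])) stop_panel("SNP entry missing field '", k, "'")
    }
    if (identical(s$wt_base, s$var_base)) {
      stop_panel("SNP ", s$snp_id, ": wt_base equals var_base")
    }
    data.frame(snp_id = s$snp_id, rsid = s$rsid %||% NA_character_,
               wt_base = s$wt_base, var_base = s$var_base,
               protein_change = s$protein_change %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  snps <- snps %||% data.frame(snp_id = character(), rsid = character(),
                               wt_base = character(), var_base = character(),
                               protein_change = character())
  if (anyDuplicated(snps$snp_id)) {
    stop_panel("duplicate snp_id in panel: ",
               join_flags(snps$snp_id[duplicated(snps$snp_id)]))
  }

  alleles <- lapply(raw$alleles, function(a) {
    for (k in c("name", "prior_freq", "functional")) {
      if (is.null(a[[k]])) stop_panel("allele entry missing field '", k, "'")
    }
    if (!a$functional %in% c("normal", "nonfunctional")) {
      stop_panel("allele ", a$name, ": functional must be normal/nonfunctional")
    }
    vs <- as.character(unlist(a$variant_snps %||% character()))
    unknown <- setdiff(vs, snps$snp_id)
    if (length(unknown) > 0) {
      stop_panel("allele ", a$name, " references unknown SNP(s): ",
                 paste(unknown, collapse = ", "))
    }
    list(name = a$name, variant_snps = vs,
         prior_freq = as.numeric(a$prior_freq), functional = a$functional)
  })
  names(alleles) <- vapply(alleles, `[[`, "", "name")
  if (anyDuplicated(names(alleles))) {
    stop_panel("duplicate allele name in panel")
  }
  if (!"*1" %in% names(alleles)) stop_panel("panel must declare allele *1")
  if (length(alleles[["*1"]]$variant_snps) != 0 ||
      alleles[["*1"]]$functional != "normal") {
    stop_panel("*1 must carry no variant SNPs and be functional")
  }
  prior_sum <- sum(vapply(alleles, `[[`, 0, "prior_freq"))
  if (abs(prior_sum - 1) > 1e-9) {
    stop_panel("allele priors must sum to 1 (got ", format(prior_sum), ")")
  }

  pm <- raw$phenotype_map
  pm <- stats::setNames(as.character(unlist(pm)), names(pm))
  for (k in c("0", "1", "2")) {
    if (!k %in% names(pm)) stop_panel("phenotype_map missing count '", k, "'")
  }
  if (!all(pm %in% PHENOTYPES)) {
    stop_panel("phenotype_map values must be one of: ",
               paste(PHENOTYPES, collapse = ", "))
  }

  structure(list(schema_version = raw$schema_version %||% 1L,
                 gene = raw$gene %||% NA_character_,
                 snps = snps, alleles = alleles, phenotype_map = pm),
            class = "pcr_panel")
}

#' Serialize a panel back to YAML
#'
#' Round-trips with [load_panel()]: `load_panel(write_panel(panel, f))`
#' reproduces the panel.
#'
#' @param panel A `pcr_panel` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "pcr_panel"))
  raw <- list(
    schema_version = panel$schema_version,
    gene = panel$gene,
    snps = lapply(seq_len(nrow(panel$snps)), function(i) {
      as.list(panel$snps[i, , drop = FALSE])
    }),
    alleles = lapply(unname(panel$alleles), function(a) {
      list(name = a$name, variant_snps = as.list(a$variant_snps),
           prior_freq = a$prior_freq, functional = a$functional)
    }),
    phenotype_map = as.list(panel$phenotype_map)
  )
  write_atomic(function(tmp) yaml::write_yaml(raw, tmp), path)
}

#' @export
print.pcr_panel <- function(x, ...) {
  cat("<pcr_panel> gene:", x$gene, "| schema", x$schema_version, "\n")
  cat(" SNPs:", paste(x$snps$snp_id, collapse = ", "), "\n")
  cat(" Alleles:\n")
  for (a in x$alleles) {
    cat(sprintf("  %-4s %-13s prior %.4g  [%s]\n", a$name,
                if (length(a$variant_snps)) paste(a$variant_snps, collapse = "+")
                else "(reference)",
                a$prior_freq, a$functional))
  }
  invisible(x)
}

# Genotype vector (named by snp_id) implied by an allele pair.
genotypes_from_pair <- function(pair, panel) {
  carriers <- table(factor(
    c(panel$alleles[[pair[1]]]$variant_snps,
      panel$alleles[[pair[2]]]$variant_snps),
    levels = panel$snps$snp_id))
  stats::setNames(c("hom_wt", "het", "hom_var")[as.integer(carriers) + 1L],
                  panel$snps$snp_id)
}
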