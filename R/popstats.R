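#' Per-SNP variant allele frequencies with exact confidence intervals
#'
#' For each panel SNP, counts variant alleles among the called samples
#' (2 per `hom_var`, 1 per `het`) over a denominator of two alleles per
#' called sample; samples with a `no_call` at a SNP are excluded from
#' that SNP's denominator. Percentages are rounded half-even to two
#' decimals (so 10 of 488 alleles prints 2.05); the 95% CI is exact
#' Clopper-Pearson.
#'
#' @param genotypes Genotype table (data.frame `sample_id`, `snp_id`,
#'   `genotype`), e.g. [read_genotypes()] output or
#'   `tpmt_calls$snp_calls`.
#' @param panel [load_panel()] object.
#' @param samples Optional character vector restricting the cohort (e.g.
#'   patients only, excluding reference cell lines).
#' @return data.frame: `snp_id`, `n_samples`, `variant_count`,
#'   `total_alleles`, `freq_pct`, `ci_lo_pct`, `ci_hi_pct`.
#' @export
allele_frequencies <- function(genotypes, panel, samples = NULL) {
  if (!is.null(samples)) {
    genotypes <- genotypes[genotypes$sample_id %in% samples, ]
  }
  if (nrow(genotypes) == 0) stop_input("empty genotype table")
  do.call(rbind, lapply(panel$snps$snp_id, function(sid) {
    g <- genotypes$genotype[genotypes$snp_id == sid]
    g <- g[g != "no_call"]
    n <- length(g)
    count <- 2L * sum(g == "hom_var") + sum(g == "het")
    total <- 2L * n
    ci <- if (total > 0) {
      stats::binom.test(count, total)$conf.int
    } else c(NA_real_, NA_real_)
    data.frame(snp_id = sid, n_samples = n, variant_count = count,
               total_alleles = total,
               freq_pct = round(100 * count / total, 2),
               ci_lo_pct = round(100 * ci[1], 2),
               ci_hi_pct = round(100 * ci[2], 2),
               stringsAsFactors = FALSE)
  }))
}

#' Star-allele counts and frequencies from resolved diplotypes
#'
#' Tallies each panel allele over the two haplotypes of every resolved
#' sample (samples with no diplotype are skipped).
#'
#' @param sample_calls `samples` table of a `tpmt_calls` object (needs
#'   `sample_id`, `diplotype`).
#' @param panel [load_panel()] object.
#' @param samples Optional cohort restriction, as [allele_frequencies()].
#' @return data.frame: `allele`, `count`, `total_alleles`, `freq_pct`.
#' @export
star_allele_frequencies <- function(sample_calls, panel, samples = NULL) {
  if (!is.null(samples)) {
    sample_calls <- sample_calls[sample_calls$sample_id %in% samples, ]
  }
  resolved <- sample_calls$diplotype[!is.na(sample_calls$diplotype)]
  if (length(resolved) == 0) stop_input("no resolved diplotypes")
  alleles <- unlist(strsplit(resolved, "/", fixed = TRUE))
  counts <- table(factor(alleles, levels = names(panel$alleles)))
  data.frame(allele = names(counts), count = as.integer(counts),
             total_alleles = length(alleles),
             freq_pct = round(100 * as.integer(counts) / length(alleles), 2),
             stringsAsFactors = FALSE)
}

#' Genotype concordance against a reference method
#'
#' Compares two genotype tables (same samples, same SNPs) pairwise. A
#' sample is comparable when both methods produced a defined genotype at
#' every SNP, and concordant when all its genotypes match exactly.
#' Pairs with a `no_call` in either table are excluded from the
#' comparable set and listed separately.
#'
#' @param calls,reference Genotype tables (data.frames with `sample_id`,
#'   `snp_id`, `genotype`).
#' @return Object of class `concordance_report`: `n_samples`,
#'   `n_comparable`, `n_concordant`, `per_snp` breakdown, `discordant`
#'   and `incomparable` sample id vectors.
#' @export
concordance <- function(calls, reference) {
  ck <- paste(calls$sample_id, calls$snp_id)
  rk <- paste(reference$sample_id, reference$snp_id)
  only_c <- setdiff(unique(calls$sample_id), unique(reference$sample_id))
  only_r <- setdiff(unique(reference$sample_id), unique(calls$sample_id))
  if (length(only_c) || length(only_r)) {
    stop_input("sample sets differ between tables; only in calls: [",
               paste(only_c, collapse = ", "), "], only in reference: [",
               paste(only_r, collapse = ", "), "]")
  }
  if (!setequal(ck, rk)) {
    stop_input("(sample, SNP) keys differ between calls and reference")
  }
  m <- match(ck, rk)
  df <- data.frame(sample_id = calls$sample_id, snp_id = calls$snp_id,
                   call = calls$genotype, ref = reference$genotype[m],
                   stringsAsFactors = FALSE)
  df$comparable <- df$call != "no_call" & df$ref != "no_call"
  df$match <- df$comparable & df$call == df$ref

  per_sample <- split(df, df$sample_id)
  sample_comparable <- vapply(per_sample, function(d) all(d$comparable), TRUE)
  sample_match <- vapply(per_sample, function(d) all(d$match), TRUE)

  per_snp <- do.call(rbind, lapply(split(df, df$snp_id), function(d) {
    data.frame(snp_id = d$snp_id[1], n_comparable = sum(d$comparable),
               n_concordant = sum(d$match), stringsAsFactors = FALSE)
  }))
  structure(list(
    n_samples = length(per_sample),
    n_comparable = sum(sample_comparable),
    n_concordant = sum(sample_comparable & sample_match),
    per_snp = per_snp[order(per_snp$snp_id), ],
    discordant = names(per_sample)[sample_comparable & !sample_match],
    incomparable = names(per_sample)[!sample_comparable],
    pairs = df), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d samples concordant (%d compared)\n",
              x$n_concordant, x$n_samples, x$n_comparable))
  print(x$per_snp, row.names = FALSE)
  if (length(x$discordant)) {
    cat("Discordant:", paste(x$discordant, collapse = ", "), "\n")
  }
  if (length(x$incomparable)) {
    cat("Excluded (no_call):", paste(x$incomparable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic SNP: conditions on the observed
#' allele counts, enumerates every heterozygote count of matching parity,
#' and sums the probabilities of all configurations no more probable than
#' the observed one. Preferred over the chi-squared test here because
#' expected homozygote-variant counts are tiny at these allele
#' frequencies.
#'
#' @param n_hom_wt,n_het,n_hom_var Genotype counts (non-negative, not all
#'   zero).
#' @return The exact p-value.
#' @examples
#' hwe_exact_test(234, 10, 0)
#' @export
hwe_exact_test <- function(n_hom_wt, n_het, n_hom_var) {
  stopifnot(n_hom_wt >= 0, n_het >= 0, n_hom_var >= 0)
  n <- n_hom_wt + n_het + n_hom_var
  if (n == 0) stop_input("all genotype counts are zero")
  n_var <- 2L * n_hom_var + n_het       # minor-ish allele count (either ok)
  hets <- seq(n_var %% 2L, min(n_var, 2L * n - n_var), by = 2L)
  logp <- vapply(hets, hwe_log_prob, 0, n = n, n_var = n_var)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# log P(n_het | n diploids, n_var variant alleles) under HWE, up to a
# constant: multinomial count of genotype configurations x 2^het.
hwe_log_prob <- function(n_het, n, n_var) {
  n_hom_var <- (n_var - n_het) / 2
  n_hom_wt <- n - n_het - n_hom_var
  n_het * log(2) - lfactorial(n_hom_wt) - lfactorial(n_het) -
    lfactorial(n_hom_var)
}
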