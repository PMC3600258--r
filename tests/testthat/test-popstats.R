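panel <- load_panel()

# genotype table of n samples, het/hom_var at chosen SNP for some samples
cohort_table <- function(n, snp = "c.719A>G", n_het = 0, n_hom_var = 0) {
  ids <- sprintf("S%03d", seq_len(n))
  tab <- expand.grid(sample_id = ids, snp_id = panel$snps$snp_id,
                     stringsAsFactors = FALSE)
  tab$genotype <- "hom_wt"
  carriers <- ids[seq_len(n_het + n_hom_var)]
  tab$genotype[tab$snp_id == snp & tab$sample_id %in%
                 utils::head(carriers, n_het)] <- "het"
  tab$genotype[tab$snp_id == snp & tab$sample_id %in%
                 utils::tail(carriers, n_hom_var)] <- "hom_var"
  tab
}

test_that("allele frequencies count 2 per hom_var and 1 per het", {
  tab <- cohort_table(244, n_het = 10)
  freq <- allele_frequencies(tab, panel)
  row <- freq[freq$snp_id == "c.719A>G", ]
  expect_equal(row$variant_count, 10)
  expect_equal(row$total_alleles, 488)
  expect_equal(row$freq_pct, 2.05)

  # all wild-type: 0% with CI lower bound 0
  wt <- allele_frequencies(cohort_table(50), panel)
  expect_true(all(wt$freq_pct == 0))
  expect_true(all(wt$ci_lo_pct == 0))

  # 2 variant alleles of 800: 0.25%
  f <- allele_frequencies(cohort_table(400, n_het = 2), panel)
  expect_equal(f$freq_pct[f$snp_id == "c.719A>G"], 0.25)

  # mixed zygosity: 3 het + 2 hom_var in 100 samples -> 7/200
  f <- allele_frequencies(cohort_table(100, n_het = 3, n_hom_var = 2), panel)
  expect_equal(f$variant_count[f$snp_id == "c.719A>G"], 7)
  expect_equal(f$freq_pct[f$snp_id == "c.719A>G"], 3.5)

  expect_error(allele_frequencies(tab[0, ], panel),
               class = "tpmt_input_error")
})

test_that("no_call samples are excluded from a SNP's denominator", {
  tab <- cohort_table(10, n_het = 1)
  tab$genotype[tab$snp_id == "c.719A>G" & tab$sample_id == "S010"] <- "no_call"
  f <- allele_frequencies(tab, panel)
  expect_equal(f$total_alleles[f$snp_id == "c.719A>G"], 18)
  expect_equal(f$total_alleles[f$snp_id == "c.238G>C"], 20)
})

test_that("frequencies over wt and var alleles sum to 100%", {
  set.seed(5)
  for (i in 1:20) {
    tab <- cohort_table(50, n_het = sample(0:10, 1),
                        n_hom_var = sample(0:5, 1))
    f <- allele_frequencies(tab, panel)
    wt_pct <- 100 * (f$total_alleles - f$variant_count) / f$total_alleles
    expect_equal(100 * f$variant_count / f$total_alleles + wt_pct,
                 rep(100, 3))
  }
})

test_that("concordance counts exact per-sample matches", {
  tab <- cohort_table(246, n_het = 10)
  rep0 <- concordance(tab, tab)
  expect_equal(rep0$n_samples, 246)
  expect_equal(rep0$n_comparable, 246)
  expect_equal(rep0$n_concordant, 246)

  flipped <- tab
  i <- which(flipped$sample_id == "S001" & flipped$snp_id == "c.719A>G")
  flipped$genotype[i] <- "hom_wt"
  rep1 <- concordance(flipped, tab)
  expect_equal(rep1$n_concordant, 245)
  expect_identical(rep1$discordant, "S001")

  # no_call excludes the sample from the comparable set
  nc <- tab
  nc$genotype[nc$sample_id == "S002" & nc$snp_id == "c.238G>C"] <- "no_call"
  rep2 <- concordance(nc, tab)
  expect_equal(rep2$n_comparable, 245)
  expect_identical(rep2$incomparable, "S002")
  expect_equal(rep2$n_concordant, 245)

  expect_error(concordance(tab[tab$sample_id != "S001", ], tab),
               class = "tpmt_input_error")
})

test_that("self-concordance is total for arbitrary tables", {
  set.seed(6)
  for (i in 1:10) {
    tab <- cohort_table(30, n_het = sample(0:8, 1),
                        n_hom_var = sample(0:4, 1))
    tab$genotype[sample(nrow(tab), 3)] <- "no_call"
    r <- concordance(tab, tab)
    expect_equal(r$n_concordant, r$n_comparable)
    expect_length(r$discordant, 0)
  }
})

# Independent HWE oracle: ratio recurrence over heterozygote counts
# conditional on allele counts (no shared code with the implementation).
hwe_oracle <- function(n_hom_wt, n_het, n_hom_var) {
  n <- n_hom_wt + n_het + n_hom_var
  n_var <- 2 * n_hom_var + n_het
  h_min <- n_var %% 2
  hets <- seq(h_min, min(n_var, 2 * n - n_var), by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (j in seq_along(hets)[-1]) {
    h <- hets[j - 1]
    aa <- (n_var - h) / 2          # hom-var count at h
    bb <- n - h - aa               # hom-wt count at h
    probs[j] <- probs[j - 1] * 4 * aa * bb / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

test_that("the HWE exact test matches the recurrence oracle", {
  expect_equal(hwe_exact_test(234, 10, 0), 1.0, tolerance = 1e-9)
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)   # monomorphic
  p <- hwe_exact_test(25, 50, 25)
  expect_gte(p, 0)
  expect_lte(p, 1)
  expect_equal(p, hwe_oracle(25, 50, 25), tolerance = 1e-9)

  set.seed(7)
  for (i in 1:50) {
    n <- sample(10:100, 1)
    n_var <- sample(0:min(50, n), 1)       # <= 50 variant alleles
    n_hom_var <- if (n_var < 2) 0 else sample(0:(n_var %/% 2), 1)
    n_het <- n_var - 2 * n_hom_var
    n_hom_wt <- n - n_het - n_hom_var
    expect_equal(hwe_exact_test(n_hom_wt, n_het, n_hom_var),
                 hwe_oracle(n_hom_wt, n_het, n_hom_var),
                 tolerance = 1e-9)
  }
  expect_error(hwe_exact_test(0, 0, 0), class = "tpmt_input_error")
})
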