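#' Enumerate star-allele pairs consistent with observed genotypes
#'
#' Exhaustively checks every unordered pair of panel alleles against the
#' per-SNP genotype vector: a pair is consistent iff, for every SNP, the
#' number of pair members carrying its variant equals 0 for `hom_wt`, 1
#' for `het` and 2 for `hom_var`. Ambiguity arises when the same
#' genotypes admit several explanations — classically, a double
#' heterozygote at c.460G>A and c.719A>G is either *1/*3A (variants in
#' cis) or *3B/*3C (in trans), indistinguishable without phasing.
#'
#' @param genotypes Named character vector (names = panel snp_ids, values
#'   in `hom_wt`/`het`/`hom_var`), or a per-sample `snp_calls` data.frame
#'   slice with columns `snp_id`, `genotype`. `no_call` genotypes are an
#'   error here; handle them upstream.
#' @param panel [load_panel()] object.
#' @return List of consistent pairs, each a sorted length-2 character
#'   vector of allele names.
#' @examples
#' panel <- load_panel()
#' g <- c("c.238G>C" = "hom_wt", "c.460G>A" = "het", "c.719A>G" = "het")
#' enumerate_diplotypes(g, panel)   # *1/*3A and *3B/*3C
#' @export
enumerate_diplotypes <- function(genotypes, panel) {
  g <- as_genotype_vector(genotypes, panel)
  if (any(g == "no_call")) stop_input("cannot diplotype a no_call genotype")
  want <- stats::setNames(match(g, c("hom_wt", "het", "hom_var")) - 1L,
                          names(g))
  alleles <- names(panel$alleles)
  idx <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
  pairs <- lapply(seq_len(nrow(idx)), function(i) {
    sort(c(alleles[idx[i, 1]], alleles[idx[i, 2]]))
  })
  ok <- vapply(pairs, function(pair) {
    carried <- genotypes_from_pair(pair, panel)
    all(match(carried, c("hom_wt", "het", "hom_var")) - 1L == want[names(carried)])
  }, TRUE)
  out <- pairs[ok]
  if (length(out) == 0) {
    stop_input("no star-allele pair explains genotype: ",
               paste(names(g), g, sep = "=", collapse = ", "))
  }
  out
}

as_genotype_vector <- function(genotypes, panel) {
  if (is.data.frame(genotypes)) {
    genotypes <- stats::setNames(genotypes$genotype, genotypes$snp_id)
  }
  missing <- setdiff(panel$snps$snp_id, names(genotypes))
  if (length(missing) > 0) {
    stop_input("genotypes missing for SNP(s): ",
               paste(missing, collapse = ", "))
  }
  genotypes[panel$snps$snp_id]
}

#' Resolve a candidate set to a single diplotype call
#'
#' A single candidate is reported as-is. Multiple candidates are ranked
#' by population prior probability under random mating: the product of
#' the two allele priors, times 2 for heterozygous pairs
#' (Hardy-Weinberg pairing factor). Under the `worst_case` policy the
#' candidate with the most nonfunctional alleles is reported instead
#' (clinically conservative: prefers the poorer-metabolizer
#' explanation). Either way the call is flagged ambiguous and all
#' alternatives are retained with normalized scores.
#'
#' @param candidates List of allele pairs from [enumerate_diplotypes()].
#' @param panel [load_panel()] object.
#' @param policy `"prior"` or `"worst_case"`.
#' @return List: `pair`, `ambiguous`, `alternatives` (data.frame of
#'   pair / prior_score / phenotype), `phenotype`, `alt_phenotype`.
#' @export
resolve_diplotype <- function(candidates, panel,
                              policy = c("prior", "worst_case")) {
  policy <- match.arg(policy)
  if (length(candidates) == 0) stop_input("empty candidate set")
  score <- vapply(candidates, function(pair) {
    p1 <- panel$alleles[[pair[1]]]$prior_freq
    p2 <- panel$alleles[[pair[2]]]$prior_freq
    (if (pair[1] == pair[2]) 1 else 2) * p1 * p2
  }, 0)
  nonfunc <- vapply(candidates, function(pair) {
    sum(vapply(pair, function(a) panel$alleles[[a]]$functional, "") ==
          "nonfunctional")
  }, 0L)
  ord <- if (policy == "prior") {
    order(-score, vapply(candidates, paste, "", collapse = "/"))
  } else {
    order(-nonfunc, -score)
  }
  chosen <- candidates[[ord[1]]]
  phen <- vapply(candidates, predict_phenotype, "", panel = panel)
  alternatives <- data.frame(
    pair = vapply(candidates[ord], paste, "", collapse = "/"),
    prior_score = score[ord] / sum(score),
    phenotype = phen[ord], stringsAsFactors = FALSE)
  list(pair = chosen,
       ambiguous = length(candidates) > 1,
       alternatives = alternatives,
       phenotype = predict_phenotype(chosen, panel),
       alt_phenotype = if (length(candidates) > 1) {
         join_flags(setdiff(phen, predict_phenotype(chosen, panel)))
       } else "")
}

#' Metabolizer phenotype of an allele pair
#'
#' Counts nonfunctional alleles in the pair and applies the panel's
#' phenotype map: 0 nonfunctional alleles predict normal enzyme
#' activity, 1 intermediate, 2 poor (low or undetectable).
#'
#' @param pair Length-2 character vector of allele names.
#' @param panel [load_panel()] object.
#' @return `"normal"`, `"intermediate"` or `"poor"`.
#' @examples
#' panel <- load_panel()
#' predict_phenotype(c("*1", "*3C"), panel)   # intermediate
#' predict_phenotype(c("*3A", "*3C"), panel)  # poor
#' @export
predict_phenotype <- function(pair, panel) {
  stopifnot(length(pair) == 2, all(pair %in% names(panel$alleles)))
  n_nonfunc <- sum(vapply(pair, function(a) panel$alleles[[a]]$functional,
                          "") == "nonfunctional")
  unname(panel$phenotype_map[as.character(n_nonfunc)])
}

# Per-sample diplotype row for the results table; no_call anywhere makes
# the phenotype indeterminate and leaves the diplotype blank.
diplotype_row <- function(sample_id, snp_calls, panel, config) {
  flags <- join_flags(unlist(strsplit(snp_calls$qc_flags, ",")))
  if (any(snp_calls$genotype == "no_call")) {
    return(data.frame(sample_id = sample_id, diplotype = NA_character_,
                      ambiguous = FALSE, alternatives = "",
                      phenotype = "indeterminate", alt_phenotype = "",
                      qc_flags = flags, stringsAsFactors = FALSE))
  }
  cand <- enumerate_diplotypes(snp_calls, panel)
  res <- resolve_diplotype(cand, panel, config$ambiguity_policy)
  data.frame(sample_id = sample_id,
             diplotype = paste(res$pair, collapse = "/"),
             ambiguous = res$ambiguous,
             alternatives = if (res$ambiguous) {
               paste(res$alternatives$pair[-1], collapse = ";")
             } else "",
             phenotype = res$phenotype, alt_phenotype = res$alt_phenotype,
             qc_flags = flags, stringsAsFactors = FALSE)
}
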