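#' Allele frequency in a diploid cohort
#'
#' Convenience for relating isoform-specific peptide abundance to genotype
#' when an assay monitors allele-specific peptides (for example an
#' apolipoprotein E epsilon-4 specific tryptic peptide): the frequency of
#' an allele among genotyped individuals, in percent.
#'
#' @param n_alleles number of copies of the allele observed in the group.
#' @param n_individuals number of genotyped individuals.
#' @param ploidy chromosome copies per individual (2 for autosomal human
#'   loci).
#' @return allele frequency in percent: `100 * n_alleles /
#'   (ploidy * n_individuals)`. Four allele copies among 19 diploid
#'   individuals is 10.5 percent.
#' @examples
#' allele_frequency(4, 19)   # ~10.5
#' allele_frequency(8, 9)    # ~44.4
#' @export
allele_frequency <- function(n_alleles, n_individuals, ploidy = 2L) {
  stopifnot(n_alleles >= 0, n_individuals >= 1, ploidy >= 1,
            n_alleles <= ploidy * n_individuals)
  100 * n_alleles / (ploidy * n_individuals)
}
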