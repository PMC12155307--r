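#' Published annotation-class counts for the Canadian oat and wheat cohorts
#'
#' Per-consequence-class SNP counts reported for the 141-cultivar oat and
#' 142-cultivar wheat Canadian breeding-pool screens (most-severe
#' consequence per site, canonical-transcript SIFT filtering). These printed
#' counts are inputs for recomputing the published aggregate rows --
#' loss-of-function totals and proportions -- with
#' \code{\link{aggregate_lof}}.
#'
#' @return data.frame with columns \code{class}, \code{oat}, \code{wheat}.
#' @export
reported_class_counts <- function() {
  data.frame(
    class = c(
      "missense_variant", "synonymous_variant",
      "splice_acceptor_variant", "splice_donor_variant",
      "stop_gained", "stop_lost", "start_lost",
      "splice_region_variant", "stop_retained_variant",
      "coding_sequence_variant",
      "5_prime_UTR_variant", "3_prime_UTR_variant",
      "non_coding_transcript_exon_variant",
      "intron_variant", "upstream_gene_variant",
      "downstream_gene_variant", "intergenic_variant"
    ),
    oat = c(74655, 125064, 155, 137, 582, 147, 57, 659, 184, 0,
            14382, 52173, 0, 5598, 83198, 131064, 2937),
    wheat = c(94003, 144071, 279, 341, 520, 84, 51, 1214, 127, 3,
              29115, 57649, 190, 8104, 71843, 114488, 20233),
    stringsAsFactors = FALSE
  )
}

#' Published screening totals for the Canadian oat and wheat cohorts
#'
#' Headline counts from the same screens: total filtered SNPs, dSNP catalog
#' size from the combined SIFT + RS rule, fixed dSNPs, severity-band
#' counts, and the low-MAF dSNP counts behind the L-shape spectrum
#' summaries. Chromosome number is 21 for both crops.
#'
#' @return nested list with elements \code{oat} and \code{wheat}.
#' @export
reported_cohort_stats <- function() {
  list(
    oat = list(
      n_cultivars = 141, n_chromosomes = 21,
      total_snps = 253264,
      sift_deleterious = 12182,
      dsnp_count = 5726, fixed_dsnps = 3,
      severity = c(weak = 2348, mild = 2295, high = 1083),
      dsnp_maf_le_0.05 = 3490, dsnp_maf_le_0.01 = 1300
    ),
    wheat = list(
      n_cultivars = 142, n_chromosomes = 21,
      total_snps = 270622,
      sift_deleterious = 12855,
      dsnp_count = 3022, fixed_dsnps = 16,
      severity = c(weak = 2834, mild = 161, high = 27),
      dsnp_maf_le_0.05 = 1663, dsnp_maf_le_0.01 = 745
    )
  )
}
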