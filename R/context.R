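#' Published context values for the Heloniopsis case study
#'
#' The printed summary numbers of the two-species *Heloniopsis* repeat
#' study that motivates this package: genome sizes, read counts, satellite
#' genome proportions, solo-LTR ratios and the reconstructed ancestral
#' genome size. They are provided as *inputs* for arithmetic (unit
#' conversions, ratios, deltas) and as documentation of scale.
#'
#' The element `requires_original_data` flags the result families that
#' cannot be recomputed from this package alone: the full per-lineage
#' genome-proportion table, the shared-cluster regression coefficients, the
#' Rsf values and the ancestral 1C reconstruction all depend on the
#' original sequencing runs (SRA accessions SRR15208642 and SRR15208643)
#' and the external genus phylogeny. The package's seeded simulations
#' verify the *methods* at desk scale instead of reproducing those numbers.
#'
#' @return A list: `genome_size_mb`, `chromosome_number_2n`,
#'   `individual_reads`, `individual_coverage`, `comparative_reads`,
#'   `comparative_gp`, `satellite_gp_percent`, `helosat_gp_percent`,
#'   `helosat_monomer_bp`, `anc1c_mb`, `rsf`, `sra_accessions`,
#'   `requires_original_data`.
#' @export
heloniopsis_context <- function() {
  list(
    genome_size_mb = c(koreana = 2480, umbellata = 4680),
    chromosome_number_2n = c(koreana = 34, umbellata = 34),
    individual_reads = c(koreana = 410000, umbellata = 784993),
    individual_coverage = 0.015,
    comparative_reads = c(koreana = 349706, umbellata = 665294),
    comparative_gp = 0.013,
    satellite_gp_percent = c(koreana = 2.33, umbellata = 14.24),
    helosat_gp_percent = c(koreana = 0.83, umbellata = 10.20),
    helosat_monomer_bp = 26,
    anc1c_mb = 3022,
    rsf = c(angela_koreana = 11.41, retand_koreana = 4.22,
            angela_umbellata = 7.94, retand_umbellata = 3.88),
    sra_accessions = c(koreana = "SRR15208643", umbellata = "SRR15208642"),
    requires_original_data = c(per_lineage_gp_table = TRUE,
                               regression_table = TRUE,
                               rsf_values = TRUE,
                               anc1c_reconstruction = TRUE)
  )
}
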