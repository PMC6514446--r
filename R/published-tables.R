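#' Published SNP dosage tables for the sugarcane HP600 and CENP-C loci
#'
#' Per-SNP transcriptome coverage, variant coverage, genomic detection status
#' and missing-haplotype dosage hypotheses for two homeologous regions of the
#' sugarcane hybrid SP80-3280: the HP600 gene in Region01 (ploidy 8, seven
#' sequenced haplotypes) and the CENP-C gene (Region01/Region02; sites inside
#' the shared duplicated segment are flagged `in_duplication`). These tables
#' carry every input of the missing-haplotype dosage test, plus the reported
#' p-values and proportions (`reported_*` columns) for cross-checking;
#' [run_dosage_table()] recomputes the tests from the count columns alone.
#'
#' The `v_*`/`g_*` columns give, for each hypothesis, the genomic variant and
#' common dosages as published per site; they are passed to
#' [run_dosage_table()] as explicit overrides, so the null proportion is the
#' exact fraction `v / (v + g)`.
#'
#' @return A tibble with columns `snp`, `name`, `change`, `polymorphism_type`,
#'   `position` (1-based CDS coordinate), `coverage`, `variant_coverage`,
#'   `genomic_detected`, `in_duplication`, `reported_proportion`,
#'   `v_common`, `g_common`, `reported_p_common`, `v_variant`, `g_variant`,
#'   `reported_p_variant`.
#' @examples
#' run_dosage_table(cenpc_snps(), ploidy = 8) |> glance()
#' @export
hp600_snps <- function() {
  read_snp_table("hp600_region01_snps.tsv")
}

#' @rdname hp600_snps
#' @export
cenpc_snps <- function() {
  read_snp_table("cenpc_snps.tsv")
}

read_snp_table <- function(file) {
  path <- system.file("extdata", file, package = "polydosage", mustWork = TRUE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = "")
  tibble(
    snp = as.integer(raw$snp),
    name = raw$name,
    change = raw$change,
    polymorphism_type = raw$polymorphism_type,
    position = as.integer(raw$position),
    coverage = as.integer(raw$coverage),
    variant_coverage = as.integer(raw$variant_coverage),
    genomic_detected = raw$genomic_detected == "Yes",
    in_duplication = raw$in_duplication == "Yes",
    reported_proportion = as.numeric(raw$reported_proportion),
    v_common = as.integer(raw$v_common),
    g_common = as.integer(raw$g_common),
    reported_p_common = as.numeric(raw$reported_p_common),
    v_variant = as.integer(raw$v_variant),
    g_variant = as.integer(raw$g_variant),
    reported_p_variant = as.numeric(raw$reported_p_variant)
  )
}
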