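# End-to-end workflow wiring: simulate -> phase -> embryo PGT -> CNV ->
# NIPT-M -> splice verification, with on-disk artifacts and a manifest.

#' Run the full PGT-M demonstration workflow
#'
#' Simulates a nuclear family under the packaged study conditions, writes
#' the raw inputs (genotype TSV + VCF, pedigree, per-embryo coverage bins,
#' cfDNA table), then runs every analysis stage: reference-embryo phasing,
#' per-embryo biopsy genotyping with ADO noise, haplotype diagnosis with
#' the direct-test cross-check, CNV/mosaicism classification (which can
#' void linkage calls on non-euploid variant chromosomes), fetal haplotype
#' prediction from plasma, and the splice-effect transcript comparison.
#' Artifacts land in `outdir` together with a `manifest.json` recording
#' parameters, seeds, package version and the MD5 checksum of every output,
#' so identical configurations yield identical manifests.
#'
#' @param seed integer master seed.
#' @param outdir output directory (created if absent).
#' @param config optional [sim_config()]; defaults to `sim_config(seed)`.
#' @param window_bp,min_support,max_minority_fraction,alpha,beta,block_size
#'   stage parameters (documented defaults as in the stage functions).
#' @param noisy apply biopsy ADO/genotyping noise to embryo columns
#'   (default TRUE; the reference embryo is kept noise-free, matching its
#'   role as the lowest-ADO sample).
#' @return invisible list with every stage result plus `manifest`.
#' @export
run_demo <- function(seed = 1L, outdir = tempfile("pgthap_demo"),
                     config = NULL,
                     window_bp = 4e6, min_support = 3L,
                     max_minority_fraction = 0.15,
                     alpha = 1e-4, beta = 1e-4, block_size = 100L,
                     noisy = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- sim_config(seed = seed)
  fam <- simulate_family(config)
  truth <- fam$truth

  obs <- fam$genotypes
  if (noisy) {
    for (e in names(truth$embryos)) {
      obs$calls[, e] <- simulate_embryo_biopsy(
        truth, e, config$ado_rate, config$genotype_error_rate, config$seed)
    }
  }
  write_genotypes(obs, file.path(outdir, "genotypes.tsv"), "tsv")
  write_genotypes(obs, file.path(outdir, "genotypes.vcf"), "vcf")
  write_pedigree(fam$pedigree, file.path(outdir, "pedigree.tsv"))

  haps <- build_parental_haplotypes(obs, fam$pedigree,
                                    config$variant_chrom, config$variant_pos,
                                    window_bp = window_bp)
  write_haplotypes(haps, file.path(outdir, "haplotypes.tsv"))

  cnv <- list()
  for (e in names(truth$embryos)) {
    bins <- simulate_low_pass_counts(truth, e, config$n_bins,
                                     config$mean_reads_per_bin, config$seed)
    write_bins(bins, file.path(outdir, sprintf("bins_%s.tsv", e)))
    cnv[[e]] <- call_cnv(bins)
  }
  cnv_tab <- do.call(rbind, lapply(names(cnv), function(e) {
    calls <- cnv[[e]]$calls
    abn <- calls[calls$class != "euploid", , drop = FALSE]
    data.frame(embryo_id = e,
               normal_karyotype = cnv[[e]]$normal_karyotype,
               abnormal = if (nrow(abn)) paste(
                 sprintf("%s:%s(m=%.2f)", abn$chrom, abn$class, abn$m),
                 collapse = ";") else "",
               stringsAsFactors = FALSE)
  }))
  utils::write.table(cnv_tab, file.path(outdir, "cnv_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  diagnoses <- diagnose_embryos(obs, fam$pedigree, haps,
                                min_support, max_minority_fraction,
                                cnv_summaries = cnv)
  write_report(diagnoses, file.path(outdir, "embryo_report.tsv"))

  cf_raw <- simulate_cfdna(truth, config$fetal_fraction, config$cfdna_depth,
                           config$cfdna_error_rate, config$seed)
  write_cfdna(cf_raw, file.path(outdir, "cfdna.tsv"))
  cf <- prepare_cfdna(cf_raw, obs, fam$pedigree, haps)
  fetal <- diagnose_fetus(cf, config$variant_pos,
                          alpha = alpha, beta = beta, block_size = block_size)
  jsonlite::write_json(
    list(error_rate = fetal$error_rate, fetal_fraction = fetal$fetal_fraction,
         decision = fetal$decision, final_status = fetal$final_status,
         flanks_consistent = fetal$flanks_consistent, blocks = fetal$blocks),
    file.path(outdir, "fetal_call.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")

  # splice verification on a synthetic 400-nt CDS with the cryptic-splice
  # deletion of coding bases 279-299
  ref_cds <- random_cds(400, seed = config$seed)
  observed <- simulate_aberrant_transcript(ref_cds, c(279, 299))
  splice <- align_and_diff(ref_cds, observed)
  write_transcript_diff(splice, file.path(outdir, "splice_diff.json"))

  outputs <- sort(list.files(outdir, full.names = TRUE))
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "pgthap",
    version = as.character(utils::packageVersion("pgthap")),
    seed = config$seed,
    parameters = list(window_bp = window_bp, min_support = min_support,
                      max_minority_fraction = max_minority_fraction,
                      alpha = alpha, beta = beta, block_size = block_size,
                      ado_rate = config$ado_rate,
                      genotype_error_rate = config$genotype_error_rate,
                      fetal_fraction = config$fetal_fraction),
    checksums = as.list(tools::md5sum(outputs)))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(family = fam, observed = obs, haplotypes = haps,
                 cnv = cnv, diagnoses = diagnoses, fetal = fetal,
                 splice = splice, manifest = manifest, outdir = outdir))
}
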