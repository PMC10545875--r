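# Hand-built family truths with controlled haplotype structure, so tests can
# place informativeness, recombination and aneuploidy deterministically.

small_genome <- function(n_chrom = 4, len = 1e8) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)), length = len,
             stringsAsFactors = FALSE)
}

# truth over explicit haplotype allele vectors (alt dosage 0/1); the variant
# site (mother het, alt on M1, father hom ref) is appended at variant_pos
make_truth <- function(M1, M2, P1, P2, pos,
                       variant_pos = NULL, chrom = "chr14",
                       embryos = list(),
                       reference = embryo_spec("M1", "P1"),
                       fetus = embryo_spec("M2", "P2"),
                       genome = small_genome(),
                       add_variant_site = !is.null(variant_pos)) {
  stopifnot(length(M1) == length(pos))
  sites <- data.frame(
    site_id = sprintf("s%04d", seq_along(pos)), chrom = chrom, pos = pos,
    ref = "A", alt = "C", maf = 0.5, stringsAsFactors = FALSE)
  hap <- rbind(M1 = M1, M2 = M2, P1 = P1, P2 = P2)
  if (add_variant_site) {
    sites <- rbind(sites, data.frame(site_id = "pathogenic_variant",
                                     chrom = chrom, pos = variant_pos,
                                     ref = "T", alt = "G", maf = 0,
                                     stringsAsFactors = FALSE))
    hap <- cbind(hap, c(1L, 0L, 0L, 0L))
  }
  ord <- order(sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  hap <- hap[, ord, drop = FALSE]
  colnames(hap) <- sites$site_id
  vi <- which(sites$site_id == "pathogenic_variant")
  genome$chrom <- unique(c(chrom, genome$chrom))[seq_len(nrow(genome))]
  truth <- list(sites = sites, haplotypes = hap,
                variant_index = if (length(vi)) vi else NA_integer_,
                variant_chrom = chrom,
                variant_pos = if (is.null(variant_pos)) NA else variant_pos,
                genome = genome,
                embryos = embryos, reference_embryo = reference,
                fetus = fetus)
  class(truth) <- "family_truth"
  truth
}

# genotype matrix + pedigree from a truth, with optional noisy embryo calls
truth_to_matrix <- function(truth, embryo_calls = NULL) {
  g <- function(id) pgthap:::true_genotype(truth, id)$genotype
  samples <- c("father", "mother", "embryo_ref", names(truth$embryos))
  calls <- cbind(
    father = as.integer(truth$haplotypes["P1", ] + truth$haplotypes["P2", ]),
    mother = as.integer(truth$haplotypes["M1", ] + truth$haplotypes["M2", ]),
    embryo_ref = g("embryo_ref"))
  for (e in names(truth$embryos))
    calls <- cbind(calls, if (!is.null(embryo_calls[[e]]))
      embryo_calls[[e]] else g(e))
  colnames(calls) <- samples
  ref_carrier <- if (pgthap:::true_genotype(truth, "embryo_ref")$mat_source[
    truth$variant_index] == "M1") "carrier" else "non_carrier"
  ped <- pedigree(
    sample_id = samples,
    role = c("father", "mother", "reference_embryo",
             rep("embryo", length(truth$embryos))),
    carrier_status = c("non_carrier", "carrier", ref_carrier,
                       rep("unknown", length(truth$embryos))))
  list(matrix = genotype_matrix(
    truth$sites[, c("site_id", "chrom", "pos", "ref", "alt")], calls),
    pedigree = ped)
}

# a truth with n_inf maternally informative SNPs split evenly around the
# variant; father homozygous everywhere, haplotype alleles Bernoulli(0.5)
informative_truth <- function(n_inf = 22, variant_pos = 65271654,
                              spacing = 1.5e5, seed = 1,
                              embryos = list(),
                              reference = embryo_spec("M1", "P1"),
                              fetus = embryo_spec("M2", "P2")) {
  set.seed(seed)
  half <- n_inf / 2
  pos <- c(variant_pos - rev(seq_len(ceiling(half))) * spacing,
           variant_pos + seq_len(floor(half)) * spacing)
  M1 <- rbinom(n_inf, 1, 0.5)
  M2 <- 1L - M1
  P <- rbinom(n_inf, 1, 0.5)
  make_truth(M1, M2, as.integer(P), as.integer(P), pos,
             variant_pos = variant_pos, embryos = embryos,
             reference = reference, fetus = fetus)
}

# a cfDNA truth with dedicated site classes: informative (mother het,
# father hom), error-estimation (both parents hom ref) and fetal-fraction
# (mother hom ref, father hom alt) sites
cfdna_truth <- function(n_inf = 200, n_err = 400, n_ff = 400, seed = 1,
                        fetus = embryo_spec("M2", "P2")) {
  set.seed(seed)
  M1i <- rbinom(n_inf, 1, 0.5)
  M1 <- c(M1i, rep(0L, n_err + n_ff))
  M2 <- c(1L - M1i, rep(0L, n_err + n_ff))
  P <- c(rbinom(n_inf, 1, 0.5), rep(0L, n_err), rep(1L, n_ff))
  # scatter the site classes uniformly across the window
  perm <- sample(n_inf + n_err + n_ff)
  M1 <- M1[perm]; M2 <- M2[perm]; P <- P[perm]
  pos <- sort(sample(63e6:67e6, n_inf + n_err + n_ff))
  make_truth(as.integer(M1), as.integer(M2), as.integer(P), as.integer(P),
             pos, variant_pos = 65271654, fetus = fetus)
}

# simulate plasma from a truth and annotate it with genotypes and phase
annotated <- function(truth, ff, depth, e, seed) {
  tab <- simulate_cfdna(truth, ff, depth, e, seed)
  tm <- truth_to_matrix(truth)
  haps <- suppressWarnings(build_parental_haplotypes(
    tm$matrix, tm$pedigree, "chr14", 65271654, window_bp = 8e6,
    min_per_flank_warn = 1L))
  prepare_cfdna(tab, tm$matrix, tm$pedigree, haps)
}

# 400-nt CDS carrying the known 21-base cryptic-splice segment at coding
# positions 279-299, with the downstream boundary made unambiguous so the
# deletion interval has a unique placement
make_cds_fixture <- function(seed = 1) {
  ref <- random_cds(400, seed = seed)
  deleted <- "GGTGCTCTCTGGAGAGATGCT"
  substr(ref, 279, 299) <- deleted
  if (substr(ref, 300, 300) == substr(ref, 279, 279))
    substr(ref, 300, 300) <- "A"
  if (substr(ref, 278, 278) == substr(ref, 299, 299))
    substr(ref, 278, 278) <- "C"
  ref
}
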