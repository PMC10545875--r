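# GRCh38 autosome lengths (bp), the default simulation genome for
# low-pass coverage bins.
GENOME_AUTOSOMES <- data.frame(
  chrom = paste0("chr", 1:22),
  length = c(248956422, 242193529, 198295559, 190214555, 181538259,
             170805979, 159345973, 145138636, 138394717, 133797422,
             135086622, 133275309, 114364328, 107043718, 101991189,
             90338345, 83257441, 80373285, 58617616, 64444167,
             46709983, 50818468),
  stringsAsFactors = FALSE
)

#' Describe one embryo's inheritance truth
#'
#' @param maternal_hap `"M1"` or `"M2"`: the maternal haplotype inherited at
#'   the 5' end of the window (M1 carries the pathogenic variant).
#' @param paternal_hap `"P1"` or `"P2"`.
#' @param recombination_breakpoints bp positions at which the inherited
#'   maternal haplotype switches (explicit, so tests can place a switch
#'   deterministically).
#' @param trisomy `NULL`, or data.frame (chrom, m) of whole-chromosome
#'   mosaic trisomies with mosaic fraction `m` in `[0, 1]`.
#' @return list describing the embryo, for [sim_config()].
#' @export
embryo_spec <- function(maternal_hap, paternal_hap,
                        recombination_breakpoints = numeric(0),
                        trisomy = NULL) {
  stopifnot(maternal_hap %in% c("M1", "M2"), paternal_hap %in% c("P1", "P2"))
  if (!is.null(trisomy)) {
    stopifnot(is.data.frame(trisomy), all(c("chrom", "m") %in% names(trisomy)),
              all(trisomy$m >= 0 & trisomy$m <= 1))
  }
  list(maternal_hap = maternal_hap, paternal_hap = paternal_hap,
       recombination_breakpoints = sort(recombination_breakpoints),
       trisomy = trisomy)
}

default_embryo_truth <- function() {
  # five blastocysts mirroring the clinical scenario: two euploid
  # non-carriers (E2, E5), two mosaic-trisomy non-carriers (E1, E3 with
  # multiple mosaic chromosomes), and one carrier of the maternal risk
  # haplotype (E4, itself mosaic)
  list(
    E1 = embryo_spec("M2", "P1", trisomy = data.frame(chrom = "chr16", m = 0.4)),
    E2 = embryo_spec("M2", "P2"),
    E3 = embryo_spec("M2", "P1",
                     trisomy = data.frame(chrom = c("chr2", "chr7", "chr15"),
                                          m = c(0.3, 0.6, 0.5))),
    E4 = embryo_spec("M1", "P2", trisomy = data.frame(chrom = "chr20", m = 0.3)),
    E5 = embryo_spec("M2", "P1")
  )
}

#' Configuration for the synthetic family generator
#'
#' Collects every knob of the simulated nuclear family: a mother who is a
#' heterozygous carrier of an autosomal-dominant pathogenic variant, a
#' non-carrier father, a reference embryo of known carrier status used to
#' anchor phase, biopsied embryos with allele dropout (ADO) and genotyping
#' error, mosaic-trisomy low-pass count profiles, and maternal plasma cfDNA
#' with a stated fetal fraction.
#'
#' Defaults describe the study conditions the package is validated under:
#' 200 SNPs drawn in a 4-Mb window centred on the variant locus
#' (chr14:65,271,654), minor allele frequencies uniform on (0.2, 0.5),
#' ADO rate 0.05, genotyping error 0.005, five embryos, 1100 coverage bins
#' at a mean of 100 reads per bin, fetal fraction 0.10 at 100x plasma depth
#' with a 0.002 per-read error rate.
#'
#' @param seed integer; every downstream draw is a deterministic function of
#'   it, so identical configs reproduce bit-identical outputs.
#' @param n_snps number of SNP sites to simulate in the window (excluding the
#'   pathogenic variant site itself, which is always added).
#' @param window_bp total window width in bp centred on `variant_pos`.
#' @param variant_chrom,variant_pos locus of the pathogenic variant.
#' @param maf_range length-2 numeric in (0, 0.5]; site allele frequencies are
#'   drawn uniformly from this interval.
#' @param embryo_truth named list of per-embryo truths from [embryo_spec()]:
#'   which maternal (M1/M2) and paternal (P1/P2) haplotype each embryo
#'   inherits, explicit recombination breakpoints (bp), and optional mosaic
#'   trisomies as a data.frame of (chrom, m).
#' @param reference_embryo truth for the reference ("waste") embryo.
#' @param fetus truth for the ongoing pregnancy.
#' @param ado_rate probability that a heterozygous biopsy genotype is
#'   rendered homozygous by allele dropout.
#' @param genotype_error_rate probability a biopsy call is replaced by a
#'   random genotype.
#' @param n_bins total low-pass coverage bins partitioning the genome.
#' @param mean_reads_per_bin expected reads per diploid bin.
#' @param fetal_fraction fraction of plasma cfDNA of fetal origin, in (0, 1).
#' @param cfdna_depth reads per site in the plasma table.
#' @param cfdna_error_rate per-read sequencing error rate in plasma.
#' @param genome data.frame (chrom, length) describing the simulated genome
#'   used for coverage bins; defaults to the 22 human autosomes.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_snps = 200L,
                       window_bp = 4e6,
                       variant_chrom = "chr14",
                       variant_pos = 65271654,
                       maf_range = c(0.2, 0.5),
                       embryo_truth = default_embryo_truth(),
                       reference_embryo = embryo_spec("M1", "P1"),
                       fetus = embryo_spec("M2", "P2"),
                       ado_rate = 0.05,
                       genotype_error_rate = 0.005,
                       n_bins = 1100L,
                       mean_reads_per_bin = 100,
                       fetal_fraction = 0.10,
                       cfdna_depth = 100L,
                       cfdna_error_rate = 0.002,
                       genome = GENOME_AUTOSOMES) {
  probs <- c(ado_rate = ado_rate, genotype_error_rate = genotype_error_rate,
             fetal_fraction = fetal_fraction, cfdna_error_rate = cfdna_error_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (n_snps < 1) stop("n_snps must be positive")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (window_bp <= 0) stop("window_bp must be positive")
  half <- window_bp / 2
  if (variant_pos - half < 1)
    stop("window extends below position 1; variant_pos must lie inside it")
  if (!variant_chrom %in% genome$chrom)
    stop("variant_chrom must be a chromosome of the simulated genome")
  cfg <- list(seed = as.integer(seed), n_snps = as.integer(n_snps),
              window_bp = window_bp, variant_chrom = variant_chrom,
              variant_pos = variant_pos, maf_range = maf_range,
              embryo_truth = embryo_truth, reference_embryo = reference_embryo,
              fetus = fetus, ado_rate = ado_rate,
              genotype_error_rate = genotype_error_rate,
              n_bins = as.integer(n_bins),
              mean_reads_per_bin = mean_reads_per_bin,
              fetal_fraction = fetal_fraction,
              cfdna_depth = as.integer(cfdna_depth),
              cfdna_error_rate = cfdna_error_rate,
              genome = genome)
  class(cfg) <- "sim_config"
  cfg
}

# haplotype source per site after applying explicit breakpoints: the source
# toggles at every breakpoint crossed moving 5'->3'
hap_source <- function(start_hap, breakpoints, pos, haps) {
  n_cross <- vapply(pos, function(p) sum(breakpoints < p), integer(1))
  other <- setdiff(haps, start_hap)
  ifelse(n_cross %% 2L == 0L, start_hap, other)
}

truth_alleles <- function(truth, spec) {
  pos <- truth$sites$pos
  # breakpoints apply to the maternal chromosome carrying the variant;
  # paternal recombination is not simulated
  msrc <- hap_source(spec$maternal_hap, spec$recombination_breakpoints,
                     pos, c("M1", "M2"))
  psrc <- rep(spec$paternal_hap, length(pos))
  mat <- ifelse(msrc == "M1", truth$haplotypes["M1", ], truth$haplotypes["M2", ])
  pat <- ifelse(psrc == "P1", truth$haplotypes["P1", ], truth$haplotypes["P2", ])
  list(mat_source = msrc, pat_source = psrc,
       mat_allele = mat, pat_allele = pat,
       genotype = as.integer(mat + pat))
}

#' Simulate a nuclear family for PGT-M
#'
#' Draws SNP sites in the window around the pathogenic variant, assigns
#' allele frequencies uniformly from `maf_range`, builds the four founder
#' haplotypes (M1/M2 maternal, P1/P2 paternal) with Hardy-Weinberg founder
#' genotypes, places the pathogenic variant on M1 of the mother (father
#' homozygous reference), and derives every child's error-free genotype from
#' its configured inherited haplotypes. The returned genotype matrix is the
#' noise-free truth; amplification noise is added per embryo by
#' [simulate_embryo_biopsy()].
#'
#' @param config a [sim_config()].
#' @return list of class `sim_family` with elements `truth` (the
#'   `family_truth`: sites, founder haplotypes, per-sample inheritance),
#'   `genotypes` (a [genotype_matrix()] for father, mother, reference embryo
#'   and embryos) and `pedigree` (a [pedigree()], including the fetus).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, "family", {
    half <- config$window_bp / 2
    lo <- max(1, ceiling(config$variant_pos - half))
    hi <- floor(config$variant_pos + half)
    pos <- sort(sample(setdiff(seq(lo, hi), config$variant_pos),
                       config$n_snps))
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, config$n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    sites <- data.frame(
      site_id = sprintf("snp%04d", seq_len(config$n_snps)),
      chrom = config$variant_chrom, pos = pos, ref = ref, alt = alt,
      maf = maf, stringsAsFactors = FALSE)
    # insert the pathogenic variant site, mother het (alt on M1),
    # father hom ref; alleles kept single-base for the chip-style matrix
    vsite <- data.frame(site_id = "pathogenic_variant",
                        chrom = config$variant_chrom,
                        pos = config$variant_pos, ref = "T", alt = "G",
                        maf = 0, stringsAsFactors = FALSE)
    sites <- rbind(sites, vsite)
    sites <- sites[order(sites$pos), , drop = FALSE]
    rownames(sites) <- NULL
    n <- nrow(sites)
    hap <- matrix(0L, nrow = 4, ncol = n,
                  dimnames = list(c("M1", "M2", "P1", "P2"), sites$site_id))
    for (h in rownames(hap))
      hap[h, ] <- stats::rbinom(n, 1L, sites$maf)
    iv <- which(sites$site_id == "pathogenic_variant")
    hap["M1", iv] <- 1L; hap["M2", iv] <- 0L
    hap["P1", iv] <- 0L; hap["P2", iv] <- 0L

    truth <- list(sites = sites, haplotypes = hap, variant_index = iv,
                  variant_chrom = config$variant_chrom,
                  variant_pos = config$variant_pos,
                  genome = config$genome,
                  embryos = config$embryo_truth,
                  reference_embryo = config$reference_embryo,
                  fetus = config$fetus)
    class(truth) <- "family_truth"

    samples <- c("father", "mother", "embryo_ref", names(config$embryo_truth))
    calls <- matrix(NA_integer_, nrow = n, ncol = length(samples),
                    dimnames = list(sites$site_id, samples))
    calls[, "father"] <- as.integer(hap["P1", ] + hap["P2", ])
    calls[, "mother"] <- as.integer(hap["M1", ] + hap["M2", ])
    calls[, "embryo_ref"] <- truth_alleles(truth, config$reference_embryo)$genotype
    for (e in names(config$embryo_truth))
      calls[, e] <- truth_alleles(truth, config$embryo_truth[[e]])$genotype

    ref_carrier <- if (truth_alleles(truth, config$reference_embryo)$mat_source[iv] == "M1")
      "carrier" else "non_carrier"
    ped <- pedigree(
      sample_id = c(samples, "fetus"),
      role = c("father", "mother", "reference_embryo",
               rep("embryo", length(config$embryo_truth)), "fetus"),
      carrier_status = c("non_carrier", "carrier", ref_carrier,
                         rep("unknown", length(config$embryo_truth)), "unknown"))
    gm <- genotype_matrix(sites[, c("site_id", "chrom", "pos", "ref", "alt")],
                          calls)
    structure(list(truth = truth, genotypes = gm, pedigree = ped),
              class = "sim_family")
  })
}

true_genotype <- function(truth, sample_id) {
  spec <- if (sample_id == "embryo_ref") truth$reference_embryo
          else if (sample_id == "fetus") truth$fetus
          else truth$embryos[[sample_id]]
  if (is.null(spec)) stop(sprintf("unknown embryo_id '%s'", sample_id))
  truth_alleles(truth, spec)
}

#' Simulate a trophectoderm biopsy genotype column
#'
#' Applies the two error modes of single-cell whole-genome amplification to
#' an embryo's true genotypes: allele dropout (each heterozygous call is
#' rendered homozygous, dropping one allele uniformly, with probability
#' `ado_rate`) and genotyping error (each emitted call is independently
#' replaced by a uniformly random valid genotype with probability
#' `genotype_error_rate`; the replacement may coincide with the truth).
#'
#' @param truth a `family_truth`.
#' @param embryo_id name of an embryo in the truth (or `"embryo_ref"`).
#' @param ado_rate,genotype_error_rate probabilities in `[0, 1]`.
#' @param seed integer stream seed.
#' @return named integer vector of dosage calls over the truth's sites.
#' @export
simulate_embryo_biopsy <- function(truth, embryo_id, ado_rate,
                                   genotype_error_rate, seed) {
  stopifnot(inherits(truth, "family_truth"))
  g <- true_genotype(truth, embryo_id)$genotype
  with_stream(seed, paste0("biopsy:", embryo_id), {
    n <- length(g)
    het <- which(g == 1L)
    drop <- het[stats::runif(length(het)) < ado_rate]
    # dropping ref keeps alt (dosage 2); dropping alt keeps ref (dosage 0)
    g[drop] <- 2L * stats::rbinom(length(drop), 1L, 0.5)
    err <- which(stats::runif(n) < genotype_error_rate)
    g[err] <- sample(0:2, length(err), replace = TRUE)
    names(g) <- truth$sites$site_id
    g
  })
}

#' Simulate low-pass binned read counts for an embryo
#'
#' Partitions the simulated genome into `n_bins` equal-width bins and draws
#' each bin's read count from a Poisson law with mean
#' `mean_reads_per_bin * copy_number / 2`, where a chromosome carrying a
#' mosaic trisomy of fraction `m` has copy number `2 + m`.
#'
#' @inheritParams simulate_embryo_biopsy
#' @param n_bins total number of bins (allocated to chromosomes by length,
#'   largest-remainder rounding).
#' @param mean_reads_per_bin expected diploid count per bin.
#' @return data.frame (chrom, start, end, count); BED convention, 0-based
#'   half-open intervals.
#' @export
simulate_low_pass_counts <- function(truth, embryo_id, n_bins,
                                     mean_reads_per_bin, seed) {
  stopifnot(inherits(truth, "family_truth"))
  if (n_bins < 1) stop("n_bins must be positive")
  spec <- if (embryo_id == "embryo_ref") truth$reference_embryo
          else truth$embryos[[embryo_id]]
  if (is.null(spec)) stop(sprintf("unknown embryo_id '%s'", embryo_id))
  genome <- truth$genome
  share <- n_bins * genome$length / sum(genome$length)
  nb <- floor(share)
  rem <- n_bins - sum(nb)
  if (rem > 0) {
    extra <- order(share - nb, decreasing = TRUE)[seq_len(rem)]
    nb[extra] <- nb[extra] + 1L
  }
  nb <- pmax(nb, 1L)
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    k <- nb[i]
    edges <- round(seq(0, genome$length[i], length.out = k + 1))
    data.frame(chrom = genome$chrom[i], start = edges[-(k + 1)],
               end = edges[-1], stringsAsFactors = FALSE)
  }))
  cn <- rep(2, nrow(bins))
  if (!is.null(spec$trisomy)) {
    for (j in seq_len(nrow(spec$trisomy))) {
      sel <- bins$chrom == spec$trisomy$chrom[j]
      cn[sel] <- 2 + spec$trisomy$m[j]
    }
  }
  with_stream(seed, paste0("lowpass:", embryo_id), {
    bins$count <- stats::rpois(nrow(bins), mean_reads_per_bin * cn / 2)
    bins
  })
}

#' Simulate a maternal-plasma cfDNA allele-depth table
#'
#' For each SNP site, the expected alt-read fraction of the plasma mixture is
#' `(1 - ff) * g_mother/2 + ff * g_fetus/2`, perturbed toward the other
#' allele by the per-read error rate `e` (attenuation
#' `p' = e + (1 - 2e) * p`); the alt depth is binomial at the configured
#' fixed per-site depth.
#'
#' @inheritParams simulate_embryo_biopsy
#' @param fetal_fraction fetal cfDNA fraction in `(0, 1)`.
#' @param depth reads per site (must be positive).
#' @param cfdna_error_rate per-read error probability.
#' @return data.frame (chrom, pos, ref, alt, ref_depth, alt_depth).
#' @export
simulate_cfdna <- function(truth, fetal_fraction, depth, cfdna_error_rate,
                           seed) {
  stopifnot(inherits(truth, "family_truth"))
  if (depth < 1) stop("depth must be positive")
  g_m <- as.integer(truth$haplotypes["M1", ] + truth$haplotypes["M2", ])
  g_f <- true_genotype(truth, "fetus")$genotype
  p <- (1 - fetal_fraction) * g_m / 2 + fetal_fraction * g_f / 2
  p <- cfdna_error_rate + (1 - 2 * cfdna_error_rate) * p
  with_stream(seed, "cfdna", {
    alt <- stats::rbinom(length(p), depth, p)
    data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
               ref = truth$sites$ref, alt = truth$sites$alt,
               ref_depth = depth - alt, alt_depth = alt,
               stringsAsFactors = FALSE)
  })
}

#' Build an aberrant splice product by deleting a coding interval
#'
#' Removes the closed interval `skip_interval = c(c_start, c_end)` (1-based
#' HGVS c. coordinates on the provided CDS) from the reference coding
#' sequence, emulating a cryptic-splice-site deletion.
#'
#' @param ref_cds reference coding sequence (character or
#'   [Biostrings::DNAString]).
#' @param skip_interval integer pair `(start, end)`, `1 <= start <= end <=
#'   nchar(ref_cds)`.
#' @return character; the observed transcript sequence.
#' @export
simulate_aberrant_transcript <- function(ref_cds, skip_interval) {
  ref <- as.character(ref_cds)
  n <- nchar(ref)
  if (length(skip_interval) != 2)
    stop("skip_interval must be a (start, end) pair")
  a <- skip_interval[1]; b <- skip_interval[2]
  if (a > b) stop("skip_interval start must not exceed end")
  if (a < 1 || b > n) stop("skip_interval out of range of the reference")
  paste0(substr(ref, 1, a - 1), substr(ref, b + 1, n))
}

#' Generate a random coding sequence
#'
#' Convenience generator for synthetic CDS fixtures (uniform A/C/G/T).
#'
#' @param n sequence length in bases.
#' @param seed optional integer stream seed.
#' @return character of length 1.
#' @export
random_cds <- function(n, seed = NULL) {
  with_stream(seed, "cds",
              paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = ""))
}
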