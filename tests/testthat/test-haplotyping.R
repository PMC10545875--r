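trio_matrix <- function(mother, father, reference, pos = NULL,
                        chrom = "chr14") {
  n <- length(mother)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(site_id = sprintf("t%03d", seq_len(n)), chrom = chrom,
                      pos = pos, ref = "A", alt = "C",
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, cbind(father = father, mother = mother,
                               embryo_ref = reference))
}

trio_ped <- function(status = "carrier") {
  pedigree(c("father", "mother", "embryo_ref"),
           c("father", "mother", "reference_embryo"),
           c("non_carrier", "carrier", status))
}

test_that("site categories follow the single-parent-heterozygous rule", {
  #          MAT    PAT    BOTH   UNINF  UNINF  MISS
  mother <- c(1L,    0L,    1L,    0L,    2L,    NA)
  father <- c(0L,    1L,    1L,    0L,    2L,    1L)
  refg   <- c(0L,    0L,    1L,    0L,    2L,    1L)
  m <- trio_matrix(mother, father, refg)
  got <- classify_sites(m, trio_ped())
  expect_equal(got, c("MAT_INF", "PAT_INF", "BOTH_HET", "UNINFORMATIVE",
                      "UNINFORMATIVE", "MISSING"))
  # a parent-offspring impossibility overrides the genotype-pattern class
  m2 <- trio_matrix(0L, 0L, 2L)
  expect_equal(classify_sites(m2, trio_ped()), "MENDEL_INCONSISTENT")
})

test_that("the reference embryo pins down the transmitted maternal allele", {
  # mother A/B, father A/A: reference A/B -> B transmitted; A/A -> A;
  # B/B impossible (father cannot contribute B)
  expect_equal(phase_parent_by_reference(1L, 0L, 1L), 1L)
  expect_equal(phase_parent_by_reference(1L, 0L, 0L), 0L)
  expect_true(is.na(phase_parent_by_reference(1L, 0L, 2L)))
  # father B/B mirror
  expect_equal(phase_parent_by_reference(1L, 2L, 1L), 0L)
  expect_equal(phase_parent_by_reference(1L, 2L, 2L), 1L)
  expect_true(is.na(phase_parent_by_reference(1L, 2L, 0L)))
})

test_that("M1 anchoring follows the reference embryo's carrier status", {
  # two MAT_INF sites either side of the variant; reference receives alt at
  # both (transmitted allele = 1)
  mk <- function(status) {
    m <- trio_matrix(mother = c(1L, 1L, 1L), father = c(0L, 0L, 0L),
                     reference = c(1L, 1L, 1L),
                     pos = c(100L, 150L, 200L))
    m$sites$site_id[2] <- "pathogenic_variant"
    rownames(m$calls) <- m$sites$site_id
    build_parental_haplotypes(m, trio_ped(status), "chr14", 150L,
                              window_bp = 1000, min_per_flank_warn = 1L)
  }
  carrier <- mk("carrier")
  expect_equal(carrier$M1[carrier$site_id != "pathogenic_variant"], c(1L, 1L))
  expect_equal(carrier$M2[carrier$site_id != "pathogenic_variant"], c(0L, 0L))
  noncar <- mk("non_carrier")
  expect_equal(noncar$M1[noncar$site_id != "pathogenic_variant"], c(0L, 0L))
  expect_error(mk("unknown"), "unanchored")
})

test_that("phasing errors: no informative sites, empty flank, thin support", {
  m <- trio_matrix(mother = c(0L, 0L), father = c(0L, 0L),
                   reference = c(0L, 0L), pos = c(100L, 200L))
  expect_error(build_parental_haplotypes(m, trio_ped(), "chr14", 150L, 1000),
               "zero informative")
  # informative sites only upstream of the variant
  m2 <- trio_matrix(mother = c(1L, 1L, 0L), father = c(0L, 0L, 0L),
                    reference = c(0L, 0L, 0L), pos = c(100L, 120L, 200L))
  expect_error(build_parental_haplotypes(m2, trio_ped(), "chr14", 150L, 1000),
               "each flank")
  m3 <- trio_matrix(mother = rep(1L, 4), father = rep(0L, 4),
                    reference = rep(0L, 4), pos = c(100L, 120L, 180L, 200L))
  expect_warning(build_parental_haplotypes(m3, trio_ped(), "chr14", 150L,
                                           1000),
                 "thin phasing support")
})

test_that("error-free phasing reproduces the simulated truth exactly", {
  for (seed in c(2, 17, 301)) {
    fam <- simulate_family(sim_config(seed = seed, n_snps = 150))
    haps <- suppressWarnings(build_parental_haplotypes(
      fam$genotypes, fam$pedigree, "chr14", 65271654))
    phased <- !is.na(haps$M1)
    idx <- match(haps$site_id[phased], fam$truth$sites$site_id)
    expect_equal(haps$M1[phased], unname(fam$truth$haplotypes["M1", idx]))
    expect_equal(haps$M2[phased], unname(fam$truth$haplotypes["M2", idx]))
    pphased <- !is.na(haps$P1)
    expect_gt(sum(pphased), 0)
  }
})

test_that("phasing is invariant to input site order", {
  fam <- simulate_family(sim_config(seed = 8, n_snps = 80))
  gm <- fam$genotypes
  perm <- sample(nrow(gm$sites))
  shuffled <- genotype_matrix(gm$sites[perm, ], gm$calls[perm, ])
  a <- suppressWarnings(build_parental_haplotypes(gm, fam$pedigree,
                                                  "chr14", 65271654))
  b <- suppressWarnings(build_parental_haplotypes(shuffled, fam$pedigree,
                                                  "chr14", 65271654))
  expect_identical(a, b)
})

test_that("phasing agrees with exhaustive enumeration on small trios", {
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(4:10, 1)
    M1 <- rbinom(k, 1, 0.5); M2 <- rbinom(k, 1, 0.5)
    P1 <- rbinom(k, 1, 0.5); P2 <- rbinom(k, 1, 0.5)
    # force one maternally informative site per flank so phasing can run
    M1[1] <- 1L; M2[1] <- 0L; P1[1] <- P2[1] <- 0L
    M1[k] <- 0L; M2[k] <- 1L; P1[k] <- P2[k] <- 1L
    pos <- seq_len(k) * 100L
    vpos <- 150L
    mh <- sample(c("M1", "M2"), 1); ph <- sample(c("P1", "P2"), 1)
    truth <- make_truth(M1, M2, as.integer(P1), as.integer(P2), pos,
                        variant_pos = vpos,
                        reference = embryo_spec(mh, ph))
    tm <- truth_to_matrix(truth)
    haps <- suppressWarnings(build_parental_haplotypes(
      tm$matrix, tm$pedigree, "chr14", vpos, window_bp = 1e6,
      min_per_flank_warn = 1L))
    # oracle works on raw genotypes; reconstruct its M1 via carrier anchor
    oracle_tr <- phase_oracle(tm$matrix$calls[, "mother"],
                              tm$matrix$calls[, "father"],
                              tm$matrix$calls[, "embryo_ref"])
    carrier <- tm$pedigree$carrier_status[
      tm$pedigree$role == "reference_embryo"] == "carrier"
    mat_inf <- haps$category == "MAT_INF" & !is.na(haps$M1)
    ora <- oracle_tr[match(haps$site_id, tm$matrix$sites$site_id)]
    expect_true(all(!is.na(ora[mat_inf])))
    expected_m1 <- if (carrier) ora[mat_inf] else 1L - ora[mat_inf]
    expect_equal(haps$M1[mat_inf], as.integer(expected_m1))
  }
})
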