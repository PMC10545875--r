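test_that("identical config and seed reproduce the family bit-for-bit", {
  cfg <- sim_config(seed = 11, n_snps = 50)
  a <- simulate_family(cfg)
  b <- simulate_family(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$haplotypes, b$truth$haplotypes)
  # a different seed changes the draw
  c <- simulate_family(sim_config(seed = 12, n_snps = 50))
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("error-free construction is Mendelian-consistent and anchored", {
  fam <- simulate_family(sim_config(seed = 3, n_snps = 120))
  m <- fam$genotypes
  mo <- m$calls[, "mother"]; fa <- m$calls[, "father"]
  for (child in c("embryo_ref", names(fam$truth$embryos))) {
    ok <- pgthap:::mendel_consistent(m$calls[, child], mo, fa)
    expect_true(all(ok))
  }
  iv <- which(m$sites$site_id == "pathogenic_variant")
  expect_equal(unname(mo[iv]), 1L)  # mother heterozygous at the variant
  expect_equal(unname(fa[iv]), 0L)  # father homozygous reference
  expect_true(!is.unsorted(m$sites$pos))
  expect_equal(sum(fam$pedigree$role == "reference_embryo"), 1L)
})

test_that("maternal-informative fraction matches the Hardy-Weinberg closed form", {
  cfg <- sim_config(seed = 41, n_snps = 200, maf_range = c(0.2, 0.5))
  fam <- simulate_family(cfg)
  m <- fam$genotypes
  snp <- m$sites$site_id != "pathogenic_variant"
  obs <- mean(m$calls[snp, "mother"] == 1L & m$calls[snp, "father"] != 1L)
  p <- fam$truth$sites$maf[match(m$sites$site_id[snp],
                                 fam$truth$sites$site_id)]
  p_inf <- 2 * p * (1 - p) * ((1 - p)^2 + p^2)
  se <- sqrt(sum(p_inf * (1 - p_inf))) / length(p_inf)
  expect_lt(abs(obs - mean(p_inf)), 3 * se)
})

test_that("allele dropout renders heterozygotes homozygous at the binomial rate", {
  n <- 20000
  truth <- make_truth(M1 = rep(1L, n), M2 = rep(0L, n),
                      P1 = rep(0L, n), P2 = rep(0L, n),
                      pos = seq_len(n) * 100 + 6e7, variant_pos = 6e7 + 50,
                      embryos = list(E1 = embryo_spec("M1", "P1")))
  g_true <- pgthap:::true_genotype(truth, "E1")$genotype
  het <- which(g_true == 1L)
  expect_gt(length(het), 10000)  # embryo carries M1 over P=0: all SNP sites het

  # ado = 1 forces every het call homozygous
  g1 <- simulate_embryo_biopsy(truth, "E1", ado_rate = 1, 0, seed = 5)
  expect_true(all(g1[het] %in% c(0L, 2L)))
  # ado = 0, error = 0 is the identity
  g0 <- simulate_embryo_biopsy(truth, "E1", 0, 0, seed = 5)
  expect_identical(unname(g0), g_true)
  # binomial law at ado = 0.1
  g <- simulate_embryo_biopsy(truth, "E1", 0.1, 0, seed = 5)
  drop_frac <- mean(g[het] != 1L)
  expect_lt(abs(drop_frac - 0.1), 3 * sqrt(0.1 * 0.9 / length(het)))
  expect_error(simulate_embryo_biopsy(truth, "nope", 0.1, 0, 1), "unknown")
})

test_that("low-pass counts follow the mosaic copy-number Poisson model", {
  truth <- make_truth(M1 = 1L, M2 = 0L, P1 = 0L, P2 = 0L, pos = 6e7,
                      variant_pos = 6e7 + 50,
                      genome = small_genome(4, 1e8),
                      embryos = list(
                        EU = embryo_spec("M2", "P1"),
                        TRI = embryo_spec("M2", "P1",
                          trisomy = data.frame(chrom = "chr2", m = 1)),
                        MOS = embryo_spec("M2", "P1",
                          trisomy = data.frame(chrom = "chr2", m = 0.4))))
  bins <- simulate_low_pass_counts(truth, "EU", 1000, 100, seed = 2)
  expect_equal(nrow(bins), 1000)
  expect_lt(abs(mean(bins$count) - 100), 3 * sqrt(100 / 1000))

  tri <- simulate_low_pass_counts(truth, "TRI", 1000, 100, seed = 2)
  sel <- tri$chrom == "chr2"
  expect_lt(abs(mean(tri$count[sel]) / 100 - 1.5),
            3 * sqrt(150 / sum(sel)) / 100)

  mos <- simulate_low_pass_counts(truth, "MOS", 1000, 100, seed = 2)
  sel <- mos$chrom == "chr2"
  ratio <- mean(mos$count[sel]) / 100
  expect_lt(abs(ratio - 1.2), 3 * sd(mos$count[sel]) / sqrt(sum(sel)) / 100)
  expect_error(simulate_low_pass_counts(truth, "EU", 0, 100, 1), "n_bins")
})

test_that("cfDNA alt fractions follow the plasma mixture model", {
  n <- 1000
  # mother hom ref, father hom alt, fetus obligate het
  truth <- make_truth(M1 = rep(0L, n), M2 = rep(0L, n),
                      P1 = rep(1L, n), P2 = rep(1L, n),
                      pos = seq_len(n) * 1000 + 6e7, variant_pos = 6e7 + 50,
                      fetus = embryo_spec("M2", "P2"))
  tab <- simulate_cfdna(truth, fetal_fraction = 0.1, depth = 100,
                        cfdna_error_rate = 0, seed = 9)
  snp <- truth$sites$site_id != "pathogenic_variant"
  vaf <- tab$alt_depth[snp] / 100
  expect_lt(abs(mean(vaf) - 0.05), 3 * sqrt(0.05 * 0.95 / (n * 100)))

  # ff = 0, no error: plasma is purely maternal
  tab0 <- simulate_cfdna(truth, 0, 200, 0, seed = 9)
  expect_true(all(tab0$alt_depth[snp] == 0))     # mother hom ref
  expect_error(simulate_cfdna(truth, 0.1, 0, 0, 1), "depth")
})

test_that("aberrant transcript simulation removes the closed interval", {
  ref <- random_cds(400, seed = 21)
  out <- simulate_aberrant_transcript(ref, c(279, 299))
  expect_equal(nchar(out), 379)
  expect_equal(simulate_aberrant_transcript(ref, c(1, 1)),
               substr(ref, 2, 400))
  expect_equal(nchar(simulate_aberrant_transcript(ref, c(400, 400))), 399)
  expect_error(simulate_aberrant_transcript(ref, c(300, 299)), "start")
  expect_error(simulate_aberrant_transcript(ref, c(0, 10)), "range")
  expect_error(simulate_aberrant_transcript(ref, c(390, 401)), "range")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(ado_rate = 1.2), "probabilities")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_silent(sim_config())
})
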