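test_that("site origin deduction subtracts the forced paternal allele", {
  # mother A/B with M1 = B(alt), father A/A
  expect_equal(call_site_origin(1L, 1L, 0L, m1 = 1L, m2 = 0L), "M1")
  expect_equal(call_site_origin(0L, 1L, 0L, m1 = 1L, m2 = 0L), "M2")
  # embryo B/B lacks the obligate paternal A: single-dropout explanation
  expect_equal(call_site_origin(2L, 1L, 0L, m1 = 1L, m2 = 0L), "ADO_SUSPECT")
  # father B/B mirror
  expect_equal(call_site_origin(2L, 1L, 2L, m1 = 1L, m2 = 0L), "M1")
  expect_equal(call_site_origin(1L, 1L, 2L, m1 = 1L, m2 = 0L), "M2")
  expect_equal(call_site_origin(0L, 1L, 2L, m1 = 1L, m2 = 0L), "ADO_SUSPECT")
  # unphased, missing, or non-informative -> NO_CALL
  expect_equal(call_site_origin(1L, 1L, 0L, NA_integer_, NA_integer_), "NO_CALL")
  expect_equal(call_site_origin(NA_integer_, 1L, 0L, 1L, 0L), "NO_CALL")
  expect_equal(call_site_origin(1L, 1L, 1L, 1L, 0L), "NO_CALL")
})

test_that("flank voting calls unanimous haplotypes and tolerates one flip", {
  pos <- c(1:6, 8:12) * 100; vpos <- 700
  agg <- aggregate_embryo(rep("M2", 11), pos, vpos)
  expect_equal(agg$haplotype_call, "M2")
  expect_equal(agg$n_M2_up, 6); expect_equal(agg$n_M2_down, 5)

  # a single dropout- or error-induced flip cannot flip the call
  one_flip <- rep("M2", 11); one_flip[3] <- "M1"
  agg2 <- aggregate_embryo(one_flip, pos, vpos)
  expect_equal(agg2$haplotype_call, "M2")

  # ADO_SUSPECT and NO_CALL sites are not counted
  mixed <- c("M2", "ADO_SUSPECT", "M2", "NO_CALL", "M2", "M2",
             "M2", "M2", "INCONSISTENT", "M2", "M2")
  agg3 <- aggregate_embryo(mixed, pos, vpos)
  expect_equal(agg3$haplotype_call, "M2")
  expect_equal(agg3$n_M2_up + agg3$n_M2_down, 8)
})

test_that("below-support or conflicting patterns give NO_CALL", {
  pos <- c(100, 200, 800, 900); vpos <- 500
  agg <- aggregate_embryo(c("M1", "M2", "M1", "M2"), pos, vpos,
                          min_support = 3L)
  expect_equal(agg$haplotype_call, "NO_CALL")
  expect_equal(aggregate_embryo(character(0), numeric(0), vpos)$haplotype_call,
               "NO_CALL")
  # heavy minority fraction blocks a homogeneous call
  calls <- c(rep("M2", 4), "M1", rep("M2", 2), "M1", rep("M2", 3))
  agg2 <- aggregate_embryo(calls, c(1:6, 8:12) * 100, 700,
                           max_minority_fraction = 0.15)
  expect_equal(agg2$haplotype_call, "NO_CALL")
})

test_that("a constructed haplotype switch is called recombinant with a localized breakpoint", {
  pos <- c(1:6, 8:12) * 100; vpos <- 700
  calls <- c(rep("M1", 6), rep("M2", 5))
  agg <- aggregate_embryo(calls, pos, vpos)
  expect_equal(agg$haplotype_call, "RECOMBINANT")
  expect_equal(agg$breakpoints$left, 600)
  expect_equal(agg$breakpoints$right, 800)
  expect_true(is.na(agg$variant_hap))  # the gap straddles the variant

  # switch confined to the downstream flank: variant-proximal side decides
  calls2 <- c(rep("M1", 6), rep("M1", 3), "M2", "M2")
  agg2 <- aggregate_embryo(calls2, pos, vpos, min_support = 2L)
  expect_equal(agg2$haplotype_call, "RECOMBINANT")
  expect_equal(agg2$variant_hap, "M1")
  expect_equal(agg2$breakpoints$left, 1000)
  expect_equal(agg2$breakpoints$right, 1100)
})

test_that("diagnosis requires linkage/direct concordance", {
  pos <- c(1:4, 6:9) * 100; vpos <- 500
  m1_agg <- aggregate_embryo(rep("M1", 8), pos, vpos)
  m2_agg <- aggregate_embryo(rep("M2", 8), pos, vpos)

  d <- diagnose_embryo("E", m2_agg, "variant_absent")
  expect_equal(d$final_status, "non_carrier")
  expect_true(d$concordant)
  d <- diagnose_embryo("E", m1_agg, "variant_present")
  expect_equal(d$final_status, "carrier")
  d <- diagnose_embryo("E", m1_agg, "variant_absent")
  expect_equal(d$final_status, "no_call")
  expect_match(d$note, "discordance")
  d <- diagnose_embryo("E", m2_agg, "variant_present")
  expect_equal(d$final_status, "no_call")
  # missing direct test: linkage-only, flagged
  d <- diagnose_embryo("E", m1_agg, "missing")
  expect_equal(d$final_status, "carrier")
  expect_match(d$note, "lower confidence")
  # trisomy covering the variant chromosome voids the linkage call
  d <- diagnose_embryo("E", m1_agg, "variant_present", trisomy_override = TRUE)
  expect_equal(d$final_status, "no_call")
  expect_match(d$note, "euploid")
})

test_that("noise-free diagnosis recovers the simulated truth for every embryo", {
  for (seed in c(5, 23)) {
    embryos <- setNames(lapply(1:6, function(i)
      embryo_spec(sample(c("M1", "M2"), 1), sample(c("P1", "P2"), 1))),
      sprintf("E%d", 1:6))
    set.seed(seed)
    truth <- informative_truth(n_inf = 10, seed = seed, embryos = embryos)
    tm <- truth_to_matrix(truth)
    haps <- suppressWarnings(build_parental_haplotypes(
      tm$matrix, tm$pedigree, "chr14", 65271654, min_per_flank_warn = 1L))
    diag <- diagnose_embryos(tm$matrix, tm$pedigree, haps)
    want <- ifelse(vapply(truth$embryos, `[[`, "", "maternal_hap") == "M1",
                   "carrier", "non_carrier")
    expect_equal(diag$final_status, unname(want))
    expect_true(all(diag$concordant))
  }
})

test_that("the no-call rate does not decrease as ADO worsens", {
  n_emb <- 200
  embryos <- setNames(lapply(seq_len(n_emb), function(i)
    embryo_spec(c("M1", "M2")[1 + i %% 2], "P1")), sprintf("E%03d", seq_len(n_emb)))
  truth <- informative_truth(n_inf = 22, seed = 12, embryos = embryos)
  tm0 <- truth_to_matrix(truth)
  haps <- suppressWarnings(build_parental_haplotypes(
    tm0$matrix, tm0$pedigree, "chr14", 65271654))
  nocall_rate <- function(ado) {
    calls <- lapply(names(embryos), function(e)
      simulate_embryo_biopsy(truth, e, ado, 0, seed = 99))
    names(calls) <- names(embryos)
    tm <- truth_to_matrix(truth, embryo_calls = calls)
    diag <- diagnose_embryos(tm$matrix, tm$pedigree, haps)
    mean(diag$final_status == "no_call")
  }
  rates <- vapply(c(0, 0.1, 0.45), nocall_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
  expect_gt(rates[3], rates[1])
})
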