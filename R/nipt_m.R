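# NIPT-M: noninvasive fetal haplotype prediction from maternal plasma by
# relative haplotype dosage (RHDO) with a sequential probability ratio test.

#' Join a cfDNA depth table with parental genotypes and phase
#'
#' Annotates each plasma site with the parental genotypes and the phased
#' M1/M2 maternal alleles, keeping only sites present in both tables.
#'
#' @param tab cfDNA table (chrom, pos, ref, alt, ref_depth, alt_depth).
#' @param matrix parental [genotype_matrix()].
#' @param ped [pedigree()].
#' @param haps [build_parental_haplotypes()] output.
#' @return annotated data.frame of class `cfdna_table` with columns
#'   mother_gt, father_gt, M1, M2 appended.
#' @export
prepare_cfdna <- function(tab, matrix, ped, haps) {
  key_t <- paste(tab$chrom, tab$pos)
  key_m <- paste(matrix$sites$chrom, matrix$sites$pos)
  idx <- match(key_t, key_m)
  keep <- !is.na(idx)
  tab <- tab[keep, , drop = FALSE]
  idx <- idx[keep]
  tab$mother_gt <- matrix$calls[idx, ped_sample(ped, "mother")]
  tab$father_gt <- matrix$calls[idx, ped_sample(ped, "father")]
  key_h <- paste(haps$chrom, haps$pos)
  hidx <- match(key_t[keep], key_h)
  tab$M1 <- ifelse(is.na(hidx), NA_integer_, haps$M1[hidx])
  tab$M2 <- ifelse(is.na(hidx), NA_integer_, haps$M2[hidx])
  tab <- tab[order(chrom_rank(tab$chrom), tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("cfdna_table", "data.frame"))
}

#' Estimate the plasma sequencing error rate
#'
#' Over sites where both parents are homozygous reference (no true alt
#' allele can be present in mother or fetus), every alt read is an error:
#' `e` = total alt depth / total depth.
#'
#' @param tab annotated [prepare_cfdna()] table.
#' @return error rate in `[0, 1]`.
#' @export
estimate_error_rate <- function(tab) {
  sel <- !is.na(tab$mother_gt) & !is.na(tab$father_gt) &
    tab$mother_gt == 0L & tab$father_gt == 0L
  if (!any(sel)) stop("no double-homozygous-reference sites for error estimation")
  sum(tab$alt_depth[sel]) / sum(tab$alt_depth[sel] + tab$ref_depth[sel])
}

#' Estimate the fetal cfDNA fraction
#'
#' Paternal-specific-allele estimator: at sites where the mother is
#' homozygous reference and the father homozygous alternate, the fetus is
#' an obligate heterozygote and all alt reads are fetal, so the expected
#' alt fraction is `ff/2`. The estimate is `ff = 2 * (mean alt fraction -
#' e)`, error-corrected and clipped to `[0, 1]`.
#'
#' @param tab annotated [prepare_cfdna()] table.
#' @param e per-read error rate (default 0; supply [estimate_error_rate()]).
#' @return fetal fraction estimate.
#' @export
estimate_fetal_fraction <- function(tab, e = 0) {
  sel <- !is.na(tab$mother_gt) & !is.na(tab$father_gt) &
    tab$mother_gt == 0L & tab$father_gt == 2L
  if (!any(sel)) stop("no maternal-hom-ref / paternal-hom-alt sites for ff estimation")
  vaf <- tab$alt_depth[sel] / (tab$alt_depth[sel] + tab$ref_depth[sel])
  min(max(2 * (mean(vaf) - e), 0), 1)
}

#' Expected plasma alt fraction under a maternal transmission hypothesis
#'
#' At a maternally informative site (mother het, father hom) the plasma is a
#' mixture of maternal and fetal genomes: expected alt fraction
#' `(1 - ff) * g_m/2 + ff * g_f/2`, where the fetal genotype `g_f` is the
#' hypothesized transmitted maternal allele plus the father's obligate
#' allele. Sequencing error attenuates the expectation toward 0.5 as
#' `p' = e + (1 - 2e) p`. At `ff = 0` the expectation is 0.5 for either
#' hypothesis: the dosage signal vanishes.
#'
#' @param transmitted_allele alt dosage (0/1) of the maternal allele under
#'   the hypothesis.
#' @param father_gt paternal genotype (0 or 2).
#' @param ff fetal fraction.
#' @param e per-read error rate (default 0).
#' @return expected alt-read fraction; vectorized.
#' @export
site_dosage_expectation <- function(transmitted_allele, father_gt, ff, e = 0) {
  if (any(!(father_gt %in% c(0L, 2L)))) stop("father must be homozygous")
  g_f <- transmitted_allele + father_gt / 2L
  p <- (1 - ff) * 0.5 + ff * g_f / 2
  e + (1 - 2 * e) * p
}

#' SPRT classification of one haplotype block
#'
#' Accumulates, in site order, the binomial log-likelihood ratio of
#' "M1 transmitted" against "M2 transmitted" over maternally informative,
#' phased sites, and decides as soon as the cumulative ratio crosses
#' `log((1 - beta)/alpha)` (M1) or `log(beta/(1 - alpha))` (M2); sequences
#' that never cross either bound are `undecided`.
#'
#' @param tab annotated [prepare_cfdna()] block (mother het, father hom
#'   sites are selected internally).
#' @param ff fetal fraction (> 0).
#' @param e per-read error rate.
#' @param alpha,beta SPRT error bounds (default 1e-4 each).
#' @return list: `decision` (`"M1_transmitted"`, `"M2_transmitted"`,
#'   `"undecided"`), `llr` (final cumulative log-likelihood ratio),
#'   `n_sites`, `n_used` (sites consumed before the decision).
#' @export
sprt_classify_block <- function(tab, ff, e = 0, alpha = 1e-4, beta = 1e-4) {
  if (ff <= 0) stop("ff must be positive for dosage classification")
  sel <- !is.na(tab$mother_gt) & !is.na(tab$father_gt) &
    tab$mother_gt == 1L & tab$father_gt %in% c(0L, 2L) &
    !is.na(tab$M1) & !is.na(tab$M2) & tab$M1 != tab$M2
  b <- tab[sel, , drop = FALSE]
  if (nrow(b) == 0L) stop("no informative phased sites in block")
  depth <- b$ref_depth + b$alt_depth
  p1 <- site_dosage_expectation(b$M1, b$father_gt, ff, e)
  p2 <- site_dosage_expectation(b$M2, b$father_gt, ff, e)
  inc <- stats::dbinom(b$alt_depth, depth, p1, log = TRUE) -
    stats::dbinom(b$alt_depth, depth, p2, log = TRUE)
  cum <- cumsum(inc)
  up <- log((1 - beta) / alpha)
  lo <- log(beta / (1 - alpha))
  hit <- which(cum >= up | cum <= lo)
  if (length(hit) == 0L) {
    list(decision = "undecided", llr = cum[length(cum)],
         n_sites = nrow(b), n_used = nrow(b))
  } else {
    k <- hit[1]
    list(decision = if (cum[k] >= up) "M1_transmitted" else "M2_transmitted",
         llr = cum[k], n_sites = nrow(b), n_used = k)
  }
}

#' Predict the fetal carrier status from maternal plasma
#'
#' Runs the full NIPT-M flow on an annotated cfDNA table: estimates the
#' sequencing error rate and fetal fraction, splits the phased informative
#' sites into contiguous blocks of at most `block_size`, classifies each
#' block by SPRT, and takes the fetal status from the variant-proximal
#' block (the block whose span contains the variant, else the nearest):
#' M1 transmitted is a carrier, M2 a non-carrier, undecided a no-call.
#' Agreement of the flanking blocks is reported as a consistency check.
#'
#' @param tab annotated [prepare_cfdna()] table.
#' @param variant_pos position of the pathogenic variant.
#' @param ff,e optional; estimated from the table when `NULL`.
#' @param alpha,beta SPRT bounds.
#' @param block_size maximum informative sites per block (default 100).
#' @return list of class `fetal_call`: `error_rate`, `fetal_fraction`,
#'   `blocks` (data.frame), `variant_block`, `decision`, `final_status`,
#'   `flanks_consistent`.
#' @export
diagnose_fetus <- function(tab, variant_pos, ff = NULL, e = NULL,
                           alpha = 1e-4, beta = 1e-4, block_size = 100L) {
  if (is.null(e)) e <- estimate_error_rate(tab)
  if (is.null(ff)) ff <- estimate_fetal_fraction(tab, e)
  if (ff <= 0)
    return(structure(list(error_rate = e, fetal_fraction = ff,
                          blocks = NULL, variant_block = NA,
                          decision = "undecided", final_status = "no_call",
                          flanks_consistent = NA), class = "fetal_call"))
  inf <- which(!is.na(tab$mother_gt) & !is.na(tab$father_gt) &
                 tab$mother_gt == 1L & tab$father_gt %in% c(0L, 2L) &
                 !is.na(tab$M1) & !is.na(tab$M2) & tab$M1 != tab$M2)
  if (length(inf) == 0L) stop("no informative phased sites in the cfDNA table")
  grp <- ceiling(seq_along(inf) / block_size)
  blocks <- lapply(split(inf, grp), function(ix) {
    res <- sprt_classify_block(tab[ix, , drop = FALSE], ff, e, alpha, beta)
    data.frame(start = tab$pos[ix[1]], end = tab$pos[ix[length(ix)]],
               n_sites = res$n_sites, llr = res$llr,
               decision = res$decision, stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, blocks)
  rownames(blocks) <- NULL
  contains <- blocks$start <= variant_pos & blocks$end >= variant_pos
  vb <- if (any(contains)) which(contains)[1] else
    which.min(pmin(abs(blocks$start - variant_pos),
                   abs(blocks$end - variant_pos)))
  decision <- blocks$decision[vb]
  status <- switch(decision,
                   M1_transmitted = "carrier",
                   M2_transmitted = "non_carrier",
                   "no_call")
  others <- blocks$decision[-vb]
  others <- others[others != "undecided"]
  consistent <- if (length(others) == 0L) NA else all(others == decision)
  structure(list(error_rate = e, fetal_fraction = ff, blocks = blocks,
                 variant_block = vb, decision = decision,
                 final_status = status, flanks_consistent = consistent),
            class = "fetal_call")
}

#' @export
print.fetal_call <- function(x, ...) {
  cat(sprintf(
    "<fetal_call> status=%s (decision %s)\n  error_rate=%.4g fetal_fraction=%.3f blocks=%d flanks_consistent=%s\n",
    x$final_status, x$decision, x$error_rate, x$fetal_fraction,
    if (is.null(x$blocks)) 0L else nrow(x$blocks), x$flanks_consistent))
  invisible(x)
}
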