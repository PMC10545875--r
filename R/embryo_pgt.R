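ORIGIN_CALLS <- c("M1", "M2", "AMBIGUOUS", "ADO_SUSPECT", "INCONSISTENT",
                  "NO_CALL")

#' Call the maternal haplotype origin of an embryo genotype at one site
#'
#' At a phased, maternally informative site the father is homozygous, so the
#' paternal allele in the embryo is forced; subtracting it from the embryo
#' genotype leaves the maternal allele, which is matched against the phased
#' M1/M2 alleles. An embryo genotype that lacks the obligate paternal allele
#' (homozygous for the non-paternal allele) is explicable only by a single
#' allele dropout and is flagged `ADO_SUSPECT` rather than counted.
#' Genotypes impossible under any (haplotype, single-dropout) explanation
#' are `INCONSISTENT`; unphased sites or missing genotypes give `NO_CALL`.
#'
#' All arguments are vectorized over sites.
#'
#' @param embryo_gt,mother_gt,father_gt alt dosages (0/1/2, NA missing).
#' @param m1,m2 phased maternal alleles as alt dosages (0/1), `NA` where the
#'   site is unphased.
#' @return character vector of origin calls.
#' @export
call_site_origin <- function(embryo_gt, mother_gt, father_gt, m1, m2) {
  n <- length(embryo_gt)
  out <- rep("NO_CALL", n)
  ok <- !is.na(m1) & !is.na(m2) & !is.na(embryo_gt) &
    !is.na(father_gt) & !is.na(mother_gt) &
    mother_gt == 1L & father_gt %in% c(0L, 2L)
  pat <- father_gt / 2L                 # forced paternal allele
  mat <- embryo_gt - pat                # candidate maternal allele
  valid <- ok & mat %in% c(0L, 1L)
  out[valid & mat == m1] <- "M1"
  out[valid & mat == m2] <- "M2"
  # hom for the non-paternal allele: obligate paternal allele missing
  dropped <- ok & !(mat %in% c(0L, 1L)) & embryo_gt %in% c(0L, 2L) &
    (embryo_gt / 2L) != pat
  out[dropped] <- "ADO_SUSPECT"
  out[ok & !valid & !dropped] <- "INCONSISTENT"
  # phased sites where M1 == M2 cannot distinguish haplotypes
  out[valid & m1 == m2] <- "AMBIGUOUS"
  out
}

best_changepoint <- function(calls) {
  # best single switch between two different haplotypes over an ordered
  # M1/M2 call sequence; returns misfit count and segment sizes
  n <- length(calls)
  is1 <- cumsum(calls == "M1")
  is2 <- cumsum(calls == "M2")
  tot1 <- is1[n]; tot2 <- is2[n]
  ks <- seq_len(n - 1)
  # A = M1 then M2: misfit = (#M2 in 1..k) + (#M1 in k+1..n)
  mis12 <- is2[ks] + (tot1 - is1[ks])
  # A = M2 then M1
  mis21 <- is1[ks] + (tot2 - is2[ks])
  if (min(mis12) <= min(mis21)) {
    k <- ks[which.min(mis12)]
    list(k = k, first = "M1", second = "M2", misfit = min(mis12))
  } else {
    k <- ks[which.min(mis21)]
    list(k = k, first = "M2", second = "M1", misfit = min(mis21))
  }
}

#' Aggregate per-site origin calls into an embryo haplotype call
#'
#' Counts M1/M2 origin calls separately on the upstream and downstream
#' flanks of the variant. A homogeneous haplotype is called when each
#' flank's winning haplotype has at least `min_support` calls, both flanks
#' agree, and the pooled minority fraction does not exceed
#' `max_minority_fraction` (so isolated dropout- or error-induced flips
#' cannot flip a call). Otherwise a single-changepoint model is fitted over
#' the ordered calls; if a switch between the two haplotypes explains the
#' data with misfit fraction within `max_minority_fraction` and both
#' segments have at least `min_support` calls, the embryo is `RECOMBINANT`
#' with the breakpoint localized between the discordant pair of informative
#' sites. Anything else is `NO_CALL`.
#'
#' @param origin character vector of [call_site_origin()] results, ordered
#'   by position.
#' @param pos site positions (bp), same order.
#' @param variant_pos position of the pathogenic variant.
#' @param min_support minimum supporting calls per flank / per segment
#'   (default 3).
#' @param max_minority_fraction maximum tolerated fraction of discordant
#'   calls (default 0.15).
#' @return list with `haplotype_call` (`"M1"`, `"M2"`, `"RECOMBINANT"`,
#'   `"NO_CALL"`), `breakpoints` (data.frame left/right bp, zero rows unless
#'   recombinant), `variant_hap` (haplotype of the variant-proximal segment,
#'   `NA` when unresolvable), flank counts `n_M1_up`, `n_M2_up`,
#'   `n_M1_down`, `n_M2_down`, and `minority_fraction`.
#' @export
aggregate_embryo <- function(origin, pos, variant_pos,
                             min_support = 3L, max_minority_fraction = 0.15) {
  stopifnot(length(origin) == length(pos), !is.unsorted(pos))
  countable <- origin %in% c("M1", "M2")
  res <- list(haplotype_call = "NO_CALL",
              breakpoints = data.frame(left = numeric(0), right = numeric(0)),
              variant_hap = NA_character_,
              n_M1_up = sum(countable & origin == "M1" & pos < variant_pos),
              n_M2_up = sum(countable & origin == "M2" & pos < variant_pos),
              n_M1_down = sum(countable & origin == "M1" & pos > variant_pos),
              n_M2_down = sum(countable & origin == "M2" & pos > variant_pos),
              minority_fraction = NA_real_)
  calls <- origin[countable]
  cpos <- pos[countable]
  n <- length(calls)
  if (n == 0L) return(res)
  n1 <- sum(calls == "M1"); n2 <- n - n1
  maj <- if (n1 >= n2) "M1" else "M2"
  hom_misfit <- min(n1, n2)
  res$minority_fraction <- hom_misfit / n

  # homogeneous explanation: pooled minority small, each flank supports
  # the same winner
  up_w <- if (maj == "M1") res$n_M1_up else res$n_M2_up
  up_l <- if (maj == "M1") res$n_M2_up else res$n_M1_up
  dn_w <- if (maj == "M1") res$n_M1_down else res$n_M2_down
  dn_l <- if (maj == "M1") res$n_M2_down else res$n_M1_down
  hom_valid <- up_w >= min_support && dn_w >= min_support &&
    up_w >= up_l && dn_w >= dn_l &&
    res$minority_fraction <= max_minority_fraction

  # single-changepoint explanation
  cp <- NULL
  cp_valid <- FALSE
  if (n >= 2L) {
    cp <- best_changepoint(calls)
    cp_valid <- cp$misfit / n <= max_minority_fraction &&
      cp$k >= min_support && (n - cp$k) >= min_support
  }

  # prefer the explanation with fewer discordant calls; ties go to the
  # homogeneous (no-recombination) model
  if (cp_valid && (!hom_valid || cp$misfit < hom_misfit)) {
    left <- cpos[cp$k]; right <- cpos[cp$k + 1L]
    res$haplotype_call <- "RECOMBINANT"
    res$breakpoints <- data.frame(left = left, right = right)
    res$variant_hap <- if (right < variant_pos) cp$second
      else if (left > variant_pos) cp$first
      else NA_character_   # breakpoint gap straddles the variant
  } else if (hom_valid) {
    res$haplotype_call <- maj
    res$variant_hap <- maj
  }
  res
}

#' Combine linkage and direct-variant results into a diagnosis
#'
#' Clinical decision rule: the linkage haplotype at the variant locus and
#' the direct variant genotype must agree. `M1` (risk haplotype) with the
#' variant present is a carrier; `M2` with the variant absent is a
#' non-carrier. Any discordance (possible dropout at the variant site, or an
#' unresolved recombination) forces `no_call`. When the direct test is
#' missing the linkage call alone decides, flagged as lower confidence.
#'
#' @param embryo_id label for the report row.
#' @param aggregate result of [aggregate_embryo()].
#' @param direct_test `"variant_present"`, `"variant_absent"` or
#'   `"missing"`.
#' @param trisomy_override set `TRUE` when the chromosome carrying the
#'   variant is non-euploid for this embryo; diploid origin-calling
#'   assumptions then break and the linkage result is voided.
#' @return one-row data.frame of class `embryo_diagnosis`.
#' @export
diagnose_embryo <- function(embryo_id, aggregate, direct_test = "missing",
                            trisomy_override = FALSE) {
  stopifnot(direct_test %in% c("variant_present", "variant_absent", "missing"))
  hap <- aggregate$variant_hap
  note <- ""
  if (trisomy_override) {
    status <- "no_call"; concord <- NA
    note <- "variant chromosome not euploid; linkage voided"
    hap_call <- "NO_CALL"
  } else {
    hap_call <- aggregate$haplotype_call
    if (is.na(hap) || hap_call == "NO_CALL") {
      status <- "no_call"; concord <- NA
      if (hap_call == "RECOMBINANT")
        note <- "recombination breakpoint spans the variant locus"
    } else if (direct_test == "missing") {
      status <- if (hap == "M1") "carrier" else "non_carrier"
      concord <- NA
      note <- "direct test missing; linkage-only call (lower confidence)"
    } else {
      linked_present <- hap == "M1"
      direct_present <- direct_test == "variant_present"
      concord <- linked_present == direct_present
      if (concord) {
        status <- if (linked_present) "carrier" else "non_carrier"
      } else {
        status <- "no_call"
        note <- paste("linkage/direct discordance - possible ADO at the",
                      "variant site or recombination")
      }
    }
  }
  bp <- aggregate$breakpoints
  structure(data.frame(
    embryo_id = embryo_id,
    n_M1_up = aggregate$n_M1_up, n_M2_up = aggregate$n_M2_up,
    n_M1_down = aggregate$n_M1_down, n_M2_down = aggregate$n_M2_down,
    haplotype_call = hap_call,
    breakpoints = if (nrow(bp)) paste(sprintf("%.0f-%.0f", bp$left, bp$right),
                                      collapse = ";") else "",
    direct_test = direct_test,
    concordant = concord,
    final_status = status,
    note = note,
    stringsAsFactors = FALSE), class = c("embryo_diagnosis", "data.frame"))
}

#' Diagnose every embryo in a genotype matrix
#'
#' Convenience driver: for each pedigree embryo, calls per-site origins
#' against the phased maternal haplotypes, aggregates them with ADO
#' tolerance and recombination detection, reads the direct test from the
#' variant site's genotype, and issues the final diagnosis.
#'
#' @param matrix a [genotype_matrix()] with parental, reference and embryo
#'   columns (typically biopsy calls).
#' @param ped a [pedigree()].
#' @param haps phased [build_parental_haplotypes()] output.
#' @param min_support,max_minority_fraction see [aggregate_embryo()].
#' @param cnv_summaries optional named list (by embryo) of
#'   [classify_embryo_cnv()] results used to void linkage calls on
#'   non-euploid variant chromosomes.
#' @return data.frame with one diagnosis row per embryo.
#' @export
diagnose_embryos <- function(matrix, ped, haps,
                             min_support = 3L, max_minority_fraction = 0.15,
                             cnv_summaries = NULL) {
  variant_chrom <- attr(haps, "variant_chrom")
  variant_pos <- attr(haps, "variant_pos")
  key_m <- paste(matrix$sites$chrom, matrix$sites$pos)
  key_h <- paste(haps$chrom, haps$pos)
  idx <- match(key_h, key_m)
  if (anyNA(idx)) stop("phased sites missing from the genotype matrix")
  mo <- matrix$calls[idx, ped_sample(ped, "mother")]
  fa <- matrix$calls[idx, ped_sample(ped, "father")]
  vrow <- which(haps$chrom == variant_chrom & haps$pos == variant_pos)
  embryos <- ped$sample_id[ped$role == "embryo"]
  out <- lapply(embryos, function(e) {
    eg <- matrix$calls[idx, e]
    origin <- call_site_origin(eg, mo, fa, haps$M1, haps$M2)
    if (length(vrow) == 1L) origin[vrow] <- "NO_CALL"  # variant site is not a linkage marker
    agg <- aggregate_embryo(origin, haps$pos, variant_pos,
                            min_support, max_minority_fraction)
    direct <- if (length(vrow) == 1L) {
      vg <- matrix$calls[idx, e][vrow]
      if (is.na(vg)) "missing" else if (vg >= 1L) "variant_present" else "variant_absent"
    } else "missing"
    override <- FALSE
    if (!is.null(cnv_summaries) && !is.null(cnv_summaries[[e]])) {
      calls <- cnv_summaries[[e]]$calls
      row <- calls[calls$chrom == variant_chrom, , drop = FALSE]
      override <- nrow(row) > 0 && any(row$class != "euploid")
    }
    diagnose_embryo(e, agg, direct, trisomy_override = override)
  })
  do.call(rbind, out)
}
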