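SITE_CATEGORIES <- c("MAT_INF", "PAT_INF", "BOTH_HET", "UNINFORMATIVE",
                     "MENDEL_INCONSISTENT", "MISSING")

#' Classify SNP informativeness in a parent/reference trio
#'
#' A site is maternally informative (`MAT_INF`) when the mother is
#' heterozygous and the father homozygous, so the maternal allele a child
#' received can be deduced; `PAT_INF` is the mirror image. Sites where both
#' parents are heterozygous (`BOTH_HET`) carry no unambiguous single-parent
#' signal and are excluded from phasing. Sites with a missing parental call
#' are `MISSING`; sites where the reference embryo's genotype is impossible
#' under Mendelian inheritance from the parents are `MENDEL_INCONSISTENT`.
#'
#' @param matrix a [genotype_matrix()] containing at least the parents.
#' @param ped a [pedigree()].
#' @return character vector of categories, one per site.
#' @export
classify_sites <- function(matrix, ped) {
  fa <- sample_calls(matrix, ped_sample(ped, "father"))
  mo <- sample_calls(matrix, ped_sample(ped, "mother"))
  cat <- rep("UNINFORMATIVE", nrow(matrix$sites))
  cat[mo == 1L & fa != 1L] <- "MAT_INF"
  cat[fa == 1L & mo != 1L] <- "PAT_INF"
  cat[fa == 1L & mo == 1L] <- "BOTH_HET"
  cat[is.na(fa) | is.na(mo)] <- "MISSING"
  ref_id <- ped$sample_id[ped$role == "reference_embryo"]
  if (length(ref_id) == 1L && ref_id %in% colnames(matrix$calls)) {
    rg <- sample_calls(matrix, ref_id)
    ok <- mendel_consistent(rg, mo, fa)
    cat[!is.na(ok) & !ok] <- "MENDEL_INCONSISTENT"
  }
  cat
}

# is child dosage possible given parental dosages? NA where undecidable
mendel_consistent <- function(child, mother, father) {
  gam <- function(g) lapply(g, function(x) {
    if (is.na(x)) NA else switch(as.character(x), `0` = 0L, `1` = 0:1, `2` = 1L)
  })
  mg <- gam(mother); fg <- gam(father)
  mapply(function(cg, m, f) {
    if (is.na(cg) || all(is.na(m)) || all(is.na(f))) return(NA)
    cg %in% outer(m, f, `+`)
  }, child, mg, fg)
}

#' Deduce the transmitted parental allele at an informative site
#'
#' At a maternally informative site the father is homozygous, so his
#' contribution to the reference embryo is forced; subtracting it from the
#' reference genotype leaves the maternal allele the reference received.
#' Symmetric for paternally informative sites. Returns the transmitted
#' allele as an alt dosage (0 = ref, 1 = alt), or `NA` when the reference
#' genotype is incompatible with the parents (the site is then dropped from
#' phasing).
#'
#' @param het_gt genotype (dosage) of the heterozygous parent (must be 1).
#' @param hom_gt genotype of the homozygous parent (0 or 2).
#' @param reference_gt genotype of the reference embryo.
#' @return integer 0/1, or `NA_integer_` if incompatible or missing.
#' @export
phase_parent_by_reference <- function(het_gt, hom_gt, reference_gt) {
  forced <- hom_gt / 2L           # allele contributed by the homozygous parent
  transmitted <- reference_gt - forced
  transmitted[het_gt != 1L | !(hom_gt %in% c(0L, 2L))] <- NA_integer_
  transmitted[!(transmitted %in% c(0L, 1L))] <- NA_integer_
  as.integer(transmitted)
}

#' Phase parental haplotypes through the reference embryo
#'
#' Implements reference-embryo ("waste embryo as proband") phasing: within a
#' window centred on the pathogenic variant, every maternally informative
#' site is phased by Mendelian deduction of the allele the reference embryo
#' received, and the two maternal haplotypes are labelled so that **M1 is
#' the risk haplotype** — if the reference embryo carries the variant, the
#' haplotype it received is M1; otherwise the haplotype it did *not* receive
#' is M1. Paternal sites are phased the same way when requested, with P1
#' defined as the paternal haplotype transmitted to the reference embryo
#' (no paternal risk allele exists in this design).
#'
#' @param matrix a [genotype_matrix()] with father, mother and reference
#'   embryo columns.
#' @param ped a [pedigree()]; the reference embryo's `carrier_status` must
#'   be `carrier` or `non_carrier`.
#' @param variant_chrom,variant_pos locus of the pathogenic variant.
#' @param window_bp total window width (default 4 Mb, i.e. +/- 2 Mb).
#' @param phase_paternal also phase PAT_INF sites (default TRUE).
#' @param min_per_flank_warn warn when fewer phased maternal sites than this
#'   are available on either side of the variant (default 5); at least one
#'   phased site per flank is required.
#' @return data.frame of class `parental_haplotypes` with one row per site
#'   in the window: site_id, chrom, pos, ref, alt, category, M1, M2, P1, P2
#'   (alt dosages, `NA` where unphased), plus attributes `variant_chrom`,
#'   `variant_pos`, `window`, `phase_support` (total phased maternal sites)
#'   and `flank_support`.
#' @export
build_parental_haplotypes <- function(matrix, ped,
                                      variant_chrom, variant_pos,
                                      window_bp = 4e6,
                                      phase_paternal = TRUE,
                                      min_per_flank_warn = 5L) {
  ref_id <- ped$sample_id[ped$role == "reference_embryo"]
  if (length(ref_id) != 1L)
    stop("pedigree must name a reference embryo")
  status <- ped$carrier_status[ped$sample_id == ref_id]
  if (!status %in% c("carrier", "non_carrier"))
    stop("risk haplotype unanchored: reference embryo carrier_status unknown")
  half <- window_bp / 2
  inwin <- matrix$sites$chrom == variant_chrom &
    matrix$sites$pos >= variant_pos - half &
    matrix$sites$pos <= variant_pos + half
  if (!any(inwin)) stop("no sites inside the phasing window")
  sites <- matrix$sites[inwin, , drop = FALSE]
  calls <- matrix$calls[inwin, , drop = FALSE]
  sub <- genotype_matrix(sites, calls)  # re-validates ordering
  sites <- sub$sites; calls <- sub$calls

  fa <- calls[, ped_sample(ped, "father")]
  mo <- calls[, ped_sample(ped, "mother")]
  rg <- calls[, ref_id]
  category <- classify_sites(sub, ped)

  n <- nrow(sites)
  M1 <- M2 <- P1 <- P2 <- rep(NA_integer_, n)

  mat_idx <- which(category == "MAT_INF" & !is.na(rg))
  if (length(mat_idx)) {
    tr <- phase_parent_by_reference(mo[mat_idx], fa[mat_idx], rg[mat_idx])
    keep <- !is.na(tr)
    idx <- mat_idx[keep]; tr <- tr[keep]
    if (status == "carrier") {
      M1[idx] <- tr; M2[idx] <- 1L - tr
    } else {
      M2[idx] <- tr; M1[idx] <- 1L - tr
    }
  }
  if (phase_paternal) {
    pat_idx <- which(category == "PAT_INF" & !is.na(rg))
    if (length(pat_idx)) {
      tr <- phase_parent_by_reference(fa[pat_idx], mo[pat_idx], rg[pat_idx])
      keep <- !is.na(tr)
      idx <- pat_idx[keep]; tr <- tr[keep]
      P1[idx] <- tr; P2[idx] <- 1L - tr
    }
  }

  n_inf <- sum(category %in% c("MAT_INF", "PAT_INF"))
  if (n_inf == 0L) stop("zero informative sites in the window")
  phased <- which(!is.na(M1))
  up <- sum(sites$pos[phased] < variant_pos)
  down <- sum(sites$pos[phased] > variant_pos)
  if (up < 1L || down < 1L)
    stop("need at least one phased maternal site on each flank of the variant")
  if (up < min_per_flank_warn || down < min_per_flank_warn)
    warning(sprintf(
      "thin phasing support: %d upstream / %d downstream phased sites", up, down))

  out <- data.frame(sites[, c("site_id", "chrom", "pos", "ref", "alt")],
                    category = category, M1 = M1, M2 = M2, P1 = P1, P2 = P2,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("parental_haplotypes", "data.frame"),
            variant_chrom = variant_chrom, variant_pos = variant_pos,
            window = c(variant_pos - half, variant_pos + half),
            phase_support = length(phased),
            flank_support = c(up = up, down = down))
}

#' Write the phased-haplotype table
#'
#' TSV mirroring the per-site layout of a karyomap: site, category, and the
#' M1/M2/P1/P2 alleles written as actual bases (blank where unphased).
#'
#' @param haps a `parental_haplotypes` object.
#' @param path output path.
#' @export
write_haplotypes <- function(haps, path) {
  allele <- function(d, ref, alt) ifelse(is.na(d), "", ifelse(d == 1L, alt, ref))
  out <- data.frame(haps[, c("site_id", "chrom", "pos", "category")],
                    M1 = allele(haps$M1, haps$ref, haps$alt),
                    M2 = allele(haps$M2, haps$ref, haps$alt),
                    P1 = allele(haps$P1, haps$ref, haps$alt),
                    P2 = allele(haps$P2, haps$ref, haps$alt),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
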