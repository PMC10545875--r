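#' Normalize binned read counts to copy ratios
#'
#' Each bin's ratio is its count divided by the genome-wide median count
#' over unmasked autosomal bins (diploid ratio = 1). Zero-count bins are
#' masked (`NA` ratio) and excluded from the median.
#'
#' @param bins data.frame (chrom, start, end, count).
#' @return the input with `ratio` and `masked` columns added.
#' @export
normalize_counts <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(bins)))
  if (any(bins$count < 0)) stop("negative bin counts")
  masked <- bins$count == 0
  auto <- !(bins$chrom %in% c("chrX", "chrY", "X", "Y"))
  med <- stats::median(bins$count[auto & !masked])
  if (!isTRUE(med > 0)) stop("all bin counts are zero")
  bins$ratio <- ifelse(masked, NA_real_, bins$count / med)
  bins$masked <- masked
  bins
}

#' Estimate a mosaic aneuploidy fraction from a copy ratio
#'
#' A chromosome in which a fraction `m` of cells carries a third copy has a
#' mean copy number `2 + m` and hence a copy ratio `r = (2 + m)/2`;
#' inverting gives `m = 2(r - 1)` for gains and `m = 2(1 - r)` for losses,
#' clipped to `[0, 1]`. With `direction = "auto"` the direction is taken
#' from the sign of `r - 1`, with `"none"` (and `m = 0`) when `|r - 1|` is
#' below `noise_floor`.
#'
#' @param r mean copy ratio (> 0).
#' @param direction `"auto"`, `"gain"`, `"loss"` or `"none"`.
#' @param noise_floor minimum `|r - 1|` treated as signal under `"auto"`
#'   (default 0.05).
#' @return list with `m` and `direction`; vectorized over `r`.
#' @export
estimate_mosaic_fraction <- function(r, direction = "auto",
                                     noise_floor = 0.05) {
  stopifnot(all(r > 0))
  direction <- match.arg(direction, c("auto", "gain", "loss", "none"))
  if (direction == "auto") {
    dir <- ifelse(abs(r - 1) < noise_floor, "none",
                  ifelse(r > 1, "gain", "loss"))
  } else dir <- rep(direction, length(r))
  m <- ifelse(dir == "gain", 2 * (r - 1),
              ifelse(dir == "loss", 2 * (1 - r), 0))
  list(m = pmin(pmax(m, 0), 1), direction = dir)
}

#' Per-chromosome CNV calls from normalized bins
#'
#' Each chromosome's mean copy ratio is its mean unmasked bin count divided
#' by the median count of the *other* autosomes' unmasked bins
#' (leave-one-out reference), so an aneuploid chromosome cannot inflate its
#' own baseline; the ratio is then converted into a mosaic fraction and
#' direction. A fully masked chromosome yields no call and a warning.
#'
#' @param bins data.frame (chrom, start, end, count); normalized with
#'   [normalize_counts()] internally to obtain bin masks.
#' @inheritParams estimate_mosaic_fraction
#' @return data.frame (chrom, n_bins, n_masked, mean_ratio, direction, m).
#' @export
chromosome_cnv_calls <- function(bins, noise_floor = 0.05) {
  if (!"masked" %in% names(bins)) bins <- normalize_counts(bins)
  auto <- !(bins$chrom %in% c("chrX", "chrY", "X", "Y"))
  chroms <- unique(bins$chrom)
  rows <- lapply(chroms, function(ch) {
    b <- bins[bins$chrom == ch, ]
    other <- bins$count[auto & !bins$masked & bins$chrom != ch]
    med <- if (length(other)) stats::median(other) else
      stats::median(bins$count[auto & !bins$masked])
    r <- mean(b$count[!b$masked]) / med
    if (!is.finite(r)) {
      warning(sprintf("chromosome %s fully masked; no CNV call", ch))
      return(NULL)
    }
    est <- estimate_mosaic_fraction(r, "auto", noise_floor)
    data.frame(chrom = ch, n_bins = nrow(b), n_masked = sum(b$masked),
               mean_ratio = r, direction = est$direction, m = est$m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify per-chromosome mosaic fractions and summarize an embryo
#'
#' Standard PGT-A reporting bands: `m < euploid_max` is euploid,
#' `m > full_min` is a full aneuploidy, anything between is mosaic. The
#' embryo has a normal karyotype iff every called chromosome is euploid.
#'
#' @param calls data.frame from [chromosome_cnv_calls()].
#' @param euploid_max upper m bound for euploid (default 0.2).
#' @param full_min lower m bound for full aneuploidy (default 0.8).
#' @return list with `calls` (class column added), `normal_karyotype`
#'   (logical) and `n_abnormal`.
#' @export
classify_embryo_cnv <- function(calls, euploid_max = 0.2, full_min = 0.8) {
  cls <- ifelse(calls$m < euploid_max, "euploid",
                ifelse(calls$m > full_min, "full_aneuploid", "mosaic"))
  calls$class <- cls
  list(calls = calls,
       normal_karyotype = all(cls == "euploid"),
       n_abnormal = sum(cls != "euploid"))
}

#' One-step CNV calling from raw binned counts
#'
#' @param bins data.frame (chrom, start, end, count).
#' @inheritParams classify_embryo_cnv
#' @inheritParams estimate_mosaic_fraction
#' @return see [classify_embryo_cnv()].
#' @export
call_cnv <- function(bins, euploid_max = 0.2, full_min = 0.8,
                     noise_floor = 0.05) {
  classify_embryo_cnv(chromosome_cnv_calls(normalize_counts(bins),
                                           noise_floor),
                      euploid_max, full_min)
}
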