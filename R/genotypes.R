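# Genotype calls are stored as integer alt-allele dosages:
#   0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing ("NC"/"./.").
GT_CODES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
TSV_CODES <- c("AA" = 0L, "AB" = 1L, "BB" = 2L, "NC" = NA_integer_)

PED_ROLES <- c("father", "mother", "reference_embryo", "embryo", "fetus")
CARRIER_STATUSES <- c("carrier", "non_carrier", "unknown")

chrom_rank <- function(chrom) {
  # natural ordering: chr1 < chr2 < ... < chr22 < chrX < chrY < others
  key <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(key))
  num[key == "X"] <- 23L
  num[key == "Y"] <- 24L
  num[is.na(num)] <- 25L
  num
}

#' Construct a genotype matrix
#'
#' Bundles an ordered table of biallelic variant sites with a site-by-sample
#' grid of diploid genotype calls coded as alt-allele dosages (0 = hom ref,
#' 1 = het, 2 = hom alt, `NA` = missing). Sites are sorted by
#' (chromosome, position) and must be unique; positions are 1-based.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`, `ref`,
#'   `alt` (single-base alleles, `ref != alt`).
#' @param calls integer matrix, one row per site, one named column per sample,
#'   values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites` and `calls`.
#' @export
genotype_matrix <- function(sites, calls) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos", "ref", "alt") %in% names(sites)))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(sites))
    stop("calls must have one row per site")
  if (is.null(colnames(calls)))
    stop("calls must have sample names as column names")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  ord <- order(chrom_rank(sites$chrom), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) records")
  rownames(sites) <- NULL
  rownames(calls) <- sites$site_id
  structure(list(sites = sites, calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$calls),
              paste(colnames(x$calls), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), ncol(x$calls))

#' Construct and validate a pedigree
#'
#' A pedigree names the role each sample plays in the nuclear family and its
#' direct-test carrier status. Exactly one `father` and one `mother` are
#' required; at most one `reference_embryo` (the "waste embryo" proband used
#' to anchor parental phase) is allowed.
#'
#' @param sample_id character vector of sample names.
#' @param role one of `father`, `mother`, `reference_embryo`, `embryo`,
#'   `fetus` per sample.
#' @param carrier_status one of `carrier`, `non_carrier`, `unknown` per
#'   sample (recycled if length 1).
#' @return data.frame of class `pedigree`.
#' @export
pedigree <- function(sample_id, role, carrier_status = "unknown") {
  role <- match.arg(role, PED_ROLES, several.ok = TRUE)
  carrier_status <- rep_len(carrier_status, length(sample_id))
  if (!all(carrier_status %in% CARRIER_STATUSES))
    stop("carrier_status must be carrier/non_carrier/unknown")
  if (sum(role == "father") != 1L || sum(role == "mother") != 1L)
    stop("pedigree must contain exactly one father and one mother")
  if (sum(role == "reference_embryo") > 1L)
    stop("pedigree may contain at most one reference_embryo")
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in pedigree")
  structure(data.frame(sample_id = as.character(sample_id),
                       role = role,
                       carrier_status = carrier_status,
                       stringsAsFactors = FALSE),
            class = c("pedigree", "data.frame"))
}

ped_sample <- function(ped, role) {
  ids <- ped$sample_id[ped$role == role]
  if (length(ids) == 0L) stop(sprintf("pedigree has no sample with role '%s'", role))
  ids
}

sample_calls <- function(mat, sample) {
  if (!sample %in% colnames(mat$calls))
    stop(sprintf("sample '%s' not present in genotype matrix", sample))
  mat$calls[, sample]
}

# deterministic per-operation RNG stream: a small multiplicative hash of
# (seed, tag) keeps stages independent of each other's draw counts
derive_seed <- function(seed, tag) {
  s <- as.double(as.integer(seed) %% 2147483647L)
  for (ch in utf8ToInt(tag)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

with_stream <- function(seed, tag, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(derive_seed(seed, tag))
  }
  expr
}
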