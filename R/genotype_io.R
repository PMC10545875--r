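# File formats:
#   genotype TSV   : snp_id chrom pos ref alt <sample...>, calls AA/AB/BB/NC
#   minimal VCF    : CHROM POS ID REF ALT QUAL FILTER INFO FORMAT(GT) samples
#   pedigree TSV   : sample_id role carrier_status
#   coverage TSV   : chrom start end count (BED convention, no header)
#   cfDNA TSV      : chrom pos ref alt ref_depth alt_depth
# Variant coordinates are 1-based inclusive (VCF convention); coverage bins
# are 0-based half-open (BED convention).

#' Read a genotype matrix
#'
#' Reads either the chip-export TSV dialect (genotypes coded `AA`/`AB`/`BB`/
#' `NC` relative to the ref allele) or a minimal VCF in which only CHROM,
#' POS, ID, REF, ALT and the GT field are honoured (`0/1` and `1/0` are both
#' heterozygous; `./.` is missing). Unknown genotype codes become missing
#' with a warning stating how many were seen. Records must be biallelic and
#' unique by (chrom, pos).
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param ped optional [pedigree()]; if given, the file's sample columns must
#'   match its non-fetus samples.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"), ped = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("snp_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df))) stop("genotype TSV lacks required columns")
    samples <- setdiff(names(df), need)
    if (length(samples) == 0) stop("genotype TSV has no sample columns")
    raw <- as.matrix(df[, samples, drop = FALSE])
    unknown <- !(raw %in% names(TSV_CODES))
    if (any(unknown))
      warning(sprintf("%d unknown genotype codes set to missing", sum(unknown)))
    calls <- matrix(TSV_CODES[match(raw, names(TSV_CODES))],
                    nrow = nrow(raw), dimnames = list(NULL, samples))
    sites <- data.frame(site_id = df$snp_id, chrom = df$chrom,
                        pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
                        stringsAsFactors = FALSE)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))   # single-record files come back as a bare vector
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
      stop("non-biallelic VCF record")
    gt <- vcfR::extract.gt(v, element = "GT")
    norm <- function(x) {
      x <- gsub("|", "/", x, fixed = TRUE)
      out <- rep(NA_integer_, length(x))
      out[x %in% c("0/0")] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x %in% c("1/1")] <- 2L
      known <- is.na(x) | x %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
      attr(out, "n_unknown") <- sum(!known)
      out
    }
    cols <- lapply(seq_len(ncol(gt)), function(j) norm(gt[, j]))
    n_unknown <- sum(vapply(cols, function(x) attr(x, "n_unknown"), numeric(1)))
    if (n_unknown > 0)
      warning(sprintf("%d unknown genotype codes set to missing", n_unknown))
    calls <- do.call(cbind, lapply(cols, as.integer))
    colnames(calls) <- colnames(gt)
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    sites <- data.frame(site_id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  }
  if (!is.null(ped)) {
    expect <- ped$sample_id[ped$role != "fetus"]
    if (!setequal(colnames(calls), expect))
      stop("sample columns do not match the pedigree")
  }
  genotype_matrix(sites, calls)
}

#' Write a genotype matrix
#'
#' @param mat a [genotype_matrix()].
#' @param path output file.
#' @param dialect `"tsv"` (chip-export dialect) or `"vcf"` (minimal GT-only
#'   VCF 4.2).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(mat, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mat, "genotype_matrix"))
  if (dialect == "tsv") {
    codes <- matrix(names(TSV_CODES)[match(mat$calls, TSV_CODES)],
                    nrow = nrow(mat$calls),
                    dimnames = dimnames(mat$calls))
    codes[is.na(mat$calls)] <- "NC"
    out <- cbind(data.frame(snp_id = mat$sites$site_id,
                            chrom = mat$sites$chrom, pos = mat$sites$pos,
                            ref = mat$sites$ref, alt = mat$sites$alt,
                            stringsAsFactors = FALSE),
                 as.data.frame(codes, stringsAsFactors = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix(gt_str[as.character(mat$calls)], nrow = nrow(mat$calls))
    gt[is.na(mat$calls)] <- "./."
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(mat$calls)), collapse = "\t"))
    body <- apply(cbind(mat$sites$chrom, mat$sites$pos, mat$sites$site_id,
                        mat$sites$ref, mat$sites$alt, ".", ".", ".", "GT",
                        gt), 1, paste, collapse = "\t")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read/write a pedigree table
#'
#' Tab-separated with header `sample_id`, `role`, `carrier_status`.
#'
#' @param path file path.
#' @return [pedigree()] for the reader; `path` invisibly for the writer.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pedigree(df$sample_id, df$role, df$carrier_status)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write binned coverage (BED-like)
#'
#' Four tab-separated columns without header: chrom, start, end, count;
#' 0-based half-open intervals.
#'
#' @param path file path.
#' @return data.frame (chrom, start, end, count) for the reader.
#' @export
read_bins <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "count"),
                          stringsAsFactors = FALSE)
  if (any(df$count < 0)) stop("negative bin counts")
  df
}

#' @rdname read_bins
#' @param bins data.frame (chrom, start, end, count).
#' @export
write_bins <- function(bins, path) {
  utils::write.table(bins[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write a cfDNA allele-depth table
#'
#' Tab-separated with header: chrom, pos, ref, alt, ref_depth, alt_depth.
#'
#' @param path file path.
#' @return data.frame for the reader.
#' @export
read_cfdna <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "ref_depth", "alt_depth")
  if (!all(need %in% names(df))) stop("cfDNA table lacks required columns")
  if (any(df$ref_depth < 0 | df$alt_depth < 0)) stop("negative depths")
  df[, need]
}

#' @rdname read_cfdna
#' @param tab cfDNA table.
#' @export
write_cfdna <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an embryo diagnosis report
#'
#' Writes a per-embryo TSV (one row per embryo: flank support counts,
#' haplotype call, direct-test result, concordance, final status) and a
#' machine-readable JSON twin alongside it (same path with `.json`
#' extension).
#'
#' @param diagnoses data.frame of embryo diagnoses
#'   (see [diagnose_embryos()]); may have zero rows.
#' @param path output TSV path.
#' @return character vector of the two paths written, invisibly.
#' @export
write_report <- function(diagnoses, path) {
  cols <- c("embryo_id", "n_M1_up", "n_M2_up", "n_M1_down", "n_M2_down",
            "haplotype_call", "breakpoints", "direct_test", "concordant",
            "final_status", "note")
  df <- as.data.frame(diagnoses)
  for (cc in setdiff(cols, names(df))) df[[cc]] <- character(0)
  df <- df[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jpath <- sub("\\.tsv$", "", path)
  jpath <- paste0(jpath, ".json")
  jsonlite::write_json(df, jpath, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(path, jpath))
}
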