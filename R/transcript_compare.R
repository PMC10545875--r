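# Splice-effect verification: global alignment of an observed transcript
# against the reference CDS, deletion calling in HGVS c. coordinates, and
# reading-frame classification.

#' Align an observed transcript to a reference CDS and call the difference
#'
#' Performs a global (Needleman-Wunsch) alignment with unit costs (match
#' +1, mismatch -1, gap -1 per base, no opening penalty) via
#' [Biostrings::pairwiseAlignment()], then classifies the difference:
#' identical sequences; a single contiguous gap in the observed sequence
#' (a clean deletion, reported as a 1-based closed interval of coding
#' coordinates, normalized 3'-most per HGVS convention when the flanking
#' sequence makes the placement ambiguous); anything else (substitutions,
#' insertions, multiple gaps) is `other` with a difference list.
#'
#' @param ref_cds reference coding sequence (uppercase DNA).
#' @param observed observed transcript sequence (uppercase DNA).
#' @return object of class `transcript_diff`: list with `kind`
#'   (`"identical"`, `"deletion"`, `"other"`), `c_start`, `c_end` (interval,
#'   `NA` unless a deletion), `length`, `frame` (`"in_frame"` or
#'   `"frameshift"`, `NA` for identical), `deleted_sequence`, and `diffs`
#'   (data.frame describing non-deletion differences when `kind = "other"`).
#' @export
align_and_diff <- function(ref_cds, observed) {
  ref <- toupper(as.character(ref_cds))
  obs <- toupper(as.character(observed))
  if (nchar(ref) == 0L || nchar(obs) == 0L) stop("sequences must be non-empty")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", obs))
    stop("sequences must contain only A, C, G, T")
  if (identical(ref, obs))
    return(new_transcript_diff("identical", NA, NA, 0L, NA_character_, ""))

  # A pure single-interval deletion is characterized exactly by the longest
  # common prefix p and suffix s covering the observed sequence
  # (p + s >= length(observed)); among the equivalent placements the
  # 3'-most representative (HGVS rule) is (p + 1, p + L). This is the
  # optimal unit-cost alignment for such pairs and avoids tie-breaking
  # among co-optimal gap placements.
  n_ref <- nchar(ref); n_obs <- nchar(obs)
  if (n_obs < n_ref) {
    L <- n_ref - n_obs
    p <- common_prefix(ref, obs)
    s <- common_suffix(ref, obs)
    if (p + s >= n_obs) {
      a <- p + 1L; b <- p + L
      return(new_transcript_diff("deletion", a, b, L,
                                 substr(ref, a, b), ""))
    }
  }

  # general case: global alignment, unit mismatch/gap costs with a
  # one-unit opening penalty so contiguous gaps are preferred among
  # co-optimal paths
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(obs), subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = sm,
    gapOpening = 1, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  ref_pos <- cumsum(s != "-")          # coding coordinate at each column
  del_col <- p == "-" & s != "-"       # base present in ref, absent in observed
  ins_col <- s == "-" & p != "-"
  sub_col <- p != "-" & s != "-" & p != s

  runs <- rle(del_col)
  n_del_runs <- sum(runs$values)
  if (n_del_runs == 1L && !any(ins_col) && !any(sub_col)) {
    cols <- which(del_col)
    a <- ref_pos[cols[1]]
    b <- ref_pos[cols[length(cols)]]
    shifted <- shift_deletion_3p(ref, a, b)
    return(new_transcript_diff("deletion", shifted[1], shifted[2],
                               b - a + 1L,
                               substr(ref, shifted[1], shifted[2]), ""))
  }
  diffs <- data.frame(
    type = c(rep("deletion", sum(del_col)), rep("insertion", sum(ins_col)),
             rep("substitution", sum(sub_col))),
    ref_pos = c(ref_pos[del_col], ref_pos[ins_col], ref_pos[sub_col]),
    ref = c(s[del_col], rep("-", sum(ins_col)), s[sub_col]),
    obs = c(rep("-", sum(del_col)), p[ins_col], p[sub_col]),
    stringsAsFactors = FALSE)
  new_transcript_diff("other", NA, NA, sum(del_col), NA_character_, diffs)
}

common_prefix <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  xs <- utf8ToInt(substr(x, 1, n)); ys <- utf8ToInt(substr(y, 1, n))
  d <- which(xs != ys)
  if (length(d) == 0L) n else d[1] - 1L
}

common_suffix <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  xs <- rev(utf8ToInt(x))[seq_len(n)]; ys <- rev(utf8ToInt(y))[seq_len(n)]
  d <- which(xs != ys)
  if (length(d) == 0L) n else d[1] - 1L
}

# HGVS: an ambiguously placed deletion is shifted to the most 3' position
shift_deletion_3p <- function(ref, a, b) {
  n <- nchar(ref)
  while (b < n && substr(ref, a, a) == substr(ref, b + 1, b + 1)) {
    a <- a + 1L
    b <- b + 1L
  }
  c(a, b)
}

new_transcript_diff <- function(kind, c_start, c_end, len, deleted, diffs) {
  structure(list(kind = kind,
                 c_start = as.integer(c_start), c_end = as.integer(c_end),
                 length = as.integer(len),
                 frame = if (kind == "identical") NA_character_
                   else if (len %% 3L == 0L) "in_frame" else "frameshift",
                 deleted_sequence = deleted,
                 diffs = diffs),
            class = "transcript_diff")
}

#' @export
print.transcript_diff <- function(x, ...) {
  if (x$kind == "deletion") {
    cat(sprintf("<transcript_diff> %s %s (%d bp, %s): %s\n", x$kind,
                diff_to_hgvs(x), x$length, x$frame, x$deleted_sequence))
  } else {
    cat(sprintf("<transcript_diff> %s\n", x$kind))
  }
  invisible(x)
}

#' Format a deletion call as an HGVS c. description
#'
#' `c.{start}_{end}del`, collapsing to `c.{start}del` for a single deleted
#' base.
#'
#' @param diff a `transcript_diff` with `kind == "deletion"`.
#' @return character HGVS string.
#' @export
diff_to_hgvs <- function(diff) {
  if (!inherits(diff, "transcript_diff") || diff$kind != "deletion")
    stop("diff_to_hgvs requires a deletion transcript_diff")
  if (diff$c_start == diff$c_end) sprintf("c.%ddel", diff$c_start)
  else sprintf("c.%d_%ddel", diff$c_start, diff$c_end)
}

#' Write a transcript diff as JSON
#'
#' @param diff a `transcript_diff`.
#' @param path output path.
#' @export
write_transcript_diff <- function(diff, path) {
  x <- unclass(diff)
  if (diff$kind == "deletion") x$hgvs <- diff_to_hgvs(diff)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
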