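# Independent oracles used to cross-check the implementation.

# Brute-force single-deletion oracle: enumerate every interval of length L
# whose removal from ref yields obs; return the 3'-most (HGVS) interval,
# or NULL if obs is not a single-interval deletion of ref.
deletion_oracle <- function(ref, obs) {
  L <- nchar(ref) - nchar(obs)
  if (L <= 0) return(NULL)
  hits <- list()
  for (a in seq_len(nchar(obs) + 1)) {
    b <- a + L - 1
    if (b > nchar(ref)) break
    cand <- paste0(substr(ref, 1, a - 1), substr(ref, b + 1, nchar(ref)))
    if (identical(cand, obs)) hits[[length(hits) + 1]] <- c(a, b)
  }
  if (length(hits) == 0) return(NULL)
  hits[[length(hits)]]  # intervals scanned left to right; last is 3'-most
}

# Needleman-Wunsch global alignment score with unit costs (match +1,
# mismatch -1, gap -1 per base); independent check of alignment optimality.
nw_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- -(0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- -i
    for (j in seq_len(m)) {
      cur[j + 1] <- max(prev[j] + ifelse(x[i] == y[j], 1, -1),
                        prev[j + 1] - 1, cur[j] - 1)
    }
    prev <- cur
  }
  prev[m + 1]
}

# Exhaustive-phasing oracle. Given trio dosage genotypes and which maternal
# haplotype the reference received (via carrier status + the variant site),
# enumerate every assignment of the mother's het-site alleles to (M1, M2)
# jointly with the transmitted-haplotype choice, keep the Mendelian-
# consistent ones, and return the transmitted maternal allele per site where
# it is unique (NA elsewhere).
phase_oracle <- function(mother, father, reference) {
  k <- length(mother)
  het <- which(mother == 1L)
  father_gam <- lapply(father, function(f)
    switch(as.character(f), `0` = 0L, `1` = 0:1, `2` = 1L))
  consistent_transmitted <- list()
  n_assign <- 2^length(het)
  for (mask in seq_len(max(n_assign, 1)) - 1) {
    hapA <- ifelse(mother == 2L, 1L, 0L)   # allele on haplotype A
    if (length(het))
      hapA[het] <- as.integer(bitwAnd(bitwShiftR(mask, seq_along(het) - 1), 1))
    hapB <- mother - hapA                  # multiset {A,B} = genotype
    if (any(hapB < 0 | hapB > 1)) next
    for (transmitted in list(hapA, hapB)) {
      ok <- all(vapply(seq_len(k), function(i) {
        any(transmitted[i] + father_gam[[i]] == reference[i])
      }, logical(1)))
      if (ok)
        consistent_transmitted[[length(consistent_transmitted) + 1]] <- transmitted
    }
  }
  if (length(consistent_transmitted) == 0) return(rep(NA_integer_, k))
  tr <- do.call(rbind, consistent_transmitted)
  out <- rep(NA_integer_, k)
  for (i in seq_len(k)) {
    u <- unique(tr[, i])
    if (length(u) == 1) out[i] <- u
  }
  out
}
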