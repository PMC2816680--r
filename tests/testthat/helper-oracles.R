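# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately written straight-line, without reusing the
# package's internal helpers, so the oracles stay independent of the code
# paths they check.

STD_CODE <- local({
  x <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(x), names(x))
})

# Random valid CDS: ATG start, random sense codons, one stop, no internal
# stops. Uses its own RNG draws from the caller's stream.
random_cds <- function(n_codons) {
  sense <- names(STD_CODE)[STD_CODE != "*"]
  stops <- names(STD_CODE)[STD_CODE == "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

split3 <- function(seq) {
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

# pooled GC by explicit per-base tabulation
oracle_pooled_gc <- function(seqs) {
  bases <- unlist(strsplit(seqs, ""))
  sum(bases %in% c("G", "C")) / length(bases)
}

oracle_window_gc <- function(seq, start, end) {
  b <- strsplit(substr(seq, start, end), "")[[1]]
  mean(b %in% c("G", "C"))
}

# straight-line Wright ENC (standard code, neighbor interpolation for a
# missing 3-fold class, overall-mean fallback)
oracle_enc <- function(seq) {
  cods <- split3(seq)
  aa <- STD_CODE[cods]
  cods <- cods[aa != "*"]
  aa <- aa[aa != "*"]
  fam <- split(names(STD_CODE)[STD_CODE != "*"], STD_CODE[STD_CODE != "*"])
  fs <- ks <- numeric(0)
  for (a in names(fam)) {
    n <- sum(aa == a)
    if (n < 2) next
    p <- as.numeric(table(factor(cods[aa == a], levels = fam[[a]]))) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    fs <- c(fs, f)
    ks <- c(ks, length(fam[[a]]))
  }
  if (!length(fs)) return(NA_real_)
  fbar <- sapply(c(2, 3, 4, 6), function(k)
    if (any(ks == k)) mean(fs[ks == k]) else NA_real_)
  if (is.na(fbar[2]) && !is.na(fbar[1]) && !is.na(fbar[3])) {
    fbar[2] <- (fbar[1] + fbar[3]) / 2
  }
  fbar[is.na(fbar)] <- mean(fs)
  min(2 + 9 / fbar[1] + 1 / fbar[2] + 5 / fbar[3] + 3 / fbar[4], 61)
}

# dinucleotide counts by explicit substring tabulation
oracle_dinuc <- function(seq) {
  n <- nchar(seq)
  d <- substring(seq, 1:(n - 1), 2:n)
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(d, levels = lv))
}

# all distinct permutations of a vector, own recursion
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (x in unique(v)) {
    for (rest in oracle_perms(v[-match(x, v)])) {
      out[[length(out) + 1]] <- c(x, rest)
    }
  }
  out
}

# brute-force enumeration of all synonymous arrangements of a CDS (terminal
# stop fixed), returned as a character vector of unique sequences
oracle_all_synonymous <- function(seq) {
  cods <- split3(seq)
  n <- length(cods)
  idx <- seq_len(n)
  if (STD_CODE[cods[n]] == "*") idx <- idx[-n]
  groups <- split(idx, STD_CODE[cods[idx]])
  arrangements <- list(cods)
  for (pos in groups) {
    pieces <- list()
    for (perm in oracle_perms(cods[pos])) {
      for (a in arrangements) {
        a[pos] <- perm
        pieces[[length(pieces) + 1]] <- a
      }
    }
    arrangements <- pieces
  }
  unique(vapply(arrangements, paste, character(1), collapse = ""))
}

# valid dicodon-shuffle outputs: synonymous arrangements with identical
# dinucleotide counts
oracle_dicodon_set <- function(seq) {
  all_arr <- oracle_all_synonymous(seq)
  ref <- oracle_dinuc(seq)
  all_arr[vapply(all_arr, function(s) identical(oracle_dinuc(s), ref),
                 logical(1))]
}

# naive window scan: explicit loops, no memoization; shares only the null
# set and the backend with the implementation under test
oracle_scan_z <- function(seq, gene_id, n_perm, seed,
                          width = 30, step = 10, nwin = 13) {
  perms <- generate_null_set(seq, gene_id,
                             shuffle_config(n_perm, seed = seed))
  backend <- fold_backend("nnfold")
  k <- min(nwin, (nchar(seq) - width) %/% step + 1)
  z_dg <- z_gc <- numeric(k)
  for (i in seq_len(k)) {
    s <- (i - 1) * step + 1
    e <- s + width - 1
    dg_wt <- fold_mfe(substr(seq, s, e), backend)$delta_g
    dg_p <- vapply(perms, function(p)
      fold_mfe(substr(p, s, e), backend)$delta_g, numeric(1))
    z_dg[i] <- if (sd(dg_p) == 0) NA_real_ else
      (dg_wt - mean(dg_p)) / sd(dg_p)
    gc_wt <- oracle_window_gc(seq, s, e)
    gc_p <- vapply(perms, function(p) oracle_window_gc(p, s, e), numeric(1))
    z_gc[i] <- if (sd(gc_p) == 0) NA_real_ else
      (gc_wt - mean(gc_p)) / sd(gc_p)
  }
  list(z_dg = z_dg, z_gc = z_gc)
}

write_fasta_lines <- function(ids, seqs, path) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
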