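#' Synonymous codon shuffle
#'
#' Randomly permutes codons among positions that encode the same amino acid,
#' preserving the protein sequence, the per-amino-acid codon multiset (hence
#' codon usage bias) and the gene's base composition. The terminal stop codon
#' is never moved; within every amino acid's positions the arrangement is a
#' uniformly random permutation. Uses the caller's RNG stream (wrap in
#' [generate_null_set()] for deterministic per-gene seeding).
#'
#' @param seq CDS nucleotide string (DNA alphabet, length a multiple of 3).
#' @param code a [genetic_code()] object.
#' @return The shuffled CDS string. A gene with no synonymous freedom is
#'   returned unchanged.
#' @export
codon_shuffle <- function(seq, code = genetic_code()) {
  cods <- split_codons(normalize_nt(seq))
  shuffle_codons(cods, code)
}

# Shuffle a codon vector in place; terminal stop (if any) fixed.
shuffle_codons <- function(cods, code) {
  n <- length(cods)
  if (n == 0L) return("")
  shuffleable <- seq_len(n)
  if (cods[n] %in% code$stop_codons) shuffleable <- shuffleable[-n]
  aa <- code$codon_to_aa[cods]
  for (a in unique(aa[shuffleable])) {
    pos <- shuffleable[aa[shuffleable] == a]
    if (length(pos) > 1L) cods[pos] <- cods[sample(pos)]
  }
  paste(cods, collapse = "")
}

#' Dinucleotide-preserving synonymous shuffle (dicodon shuffle)
#'
#' A synonymous codon shuffle additionally constrained to preserve the
#' sequence's 16-entry dinucleotide count vector, including the dinucleotides
#' spanning codon junctions. Candidates are drawn uniformly from the
#' synonymous-shuffle space and accepted when the dinucleotide counts match
#' the input exactly, which yields a uniform sample over the valid
#' arrangements. When the synonymous arrangement space is small enough to
#' enumerate (at most \code{enumerate_limit} arrangements) the valid set is
#' built exactly and sampled without rejection; otherwise, if no valid
#' alternative is found within \code{max_attempts} draws, the input is
#' returned (self-permutation).
#'
#' @inheritParams codon_shuffle
#' @param max_attempts rejection-sampling budget (default 2000).
#' @param enumerate_limit enumerate the arrangement space exactly when it has
#'   at most this many members (default 5000).
#' @return Shuffled CDS string with identical dinucleotide composition.
#' @export
dicodon_shuffle <- function(seq, code = genetic_code(), max_attempts = 2000L,
                            enumerate_limit = 5000L) {
  seq <- normalize_nt(seq)
  target <- dinucleotide_counts(seq)
  cods <- split_codons(seq)
  cand_all <- enumerate_synonymous(cods, code, enumerate_limit)
  if (!is.null(cand_all)) {
    valid <- cand_all[vapply(cand_all, function(s)
      identical(dinucleotide_counts(s), target), logical(1))]
    if (!length(valid)) return(seq)
    return(valid[[sample.int(length(valid), 1L)]])
  }
  for (k in seq_len(max_attempts)) {
    cand <- shuffle_codons(cods, code)
    if (identical(dinucleotide_counts(cand), target)) return(cand)
  }
  seq
}

# All distinct orderings of a multiset (rows of a matrix); used for exact
# enumeration of small synonymous spaces.
perms_multiset <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- lapply(unique(v), function(x) {
    sub <- perms_multiset(v[-match(x, v)])
    cbind(x, sub, deparse.level = 0)
  })
  do.call(rbind, out)
}

# All synonymous arrangements of a codon vector (terminal stop fixed), or
# NULL when the space exceeds `limit`. Returns a list of CDS strings.
enumerate_synonymous <- function(cods, code, limit) {
  n <- length(cods)
  idx <- seq_len(n)
  if (n > 0L && cods[n] %in% code$stop_codons) idx <- idx[-n]
  aa <- code$codon_to_aa[cods]
  by_aa <- split(idx, aa[idx])
  by_aa <- Filter(function(p) length(p) > 1L &&
                    length(unique(cods[p])) > 1L, by_aa)
  n_arr <- prod(vapply(by_aa, function(p) {
    cnt <- table(cods[p])
    exp(lfactorial(length(p)) - sum(lfactorial(cnt)))
  }, numeric(1)))
  if (n_arr > limit) return(NULL)
  arrangements <- list(cods)
  for (p in by_aa) {
    pm <- perms_multiset(cods[p])
    arrangements <- unlist(lapply(arrangements, function(a) {
      lapply(seq_len(nrow(pm)), function(r) {
        a[p] <- pm[r, ]
        a
      })
    }), recursive = FALSE)
  }
  unique(vapply(arrangements, paste, character(1), collapse = ""))
}

#' Shuffle configuration
#'
#' @param n_permutations number of permuted sequences per gene (default 1000).
#' @param method \code{"codon_shuffle"} (default) or \code{"dicodon_shuffle"}.
#' @param seed master seed; per-gene streams are derived from
#'   \code{(seed, gene_id)} so results do not depend on processing order.
#' @param max_attempts rejection budget for the dicodon method.
#' @return A list of class \code{"shuffle_config"}.
#' @export
shuffle_config <- function(n_permutations = 1000L,
                           method = c("codon_shuffle", "dicodon_shuffle"),
                           seed = 1L, max_attempts = 2000L) {
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1L)
  structure(
    list(n_permutations = n_permutations, method = match.arg(method),
         seed = as.integer(seed), max_attempts = as.integer(max_attempts)),
    class = "shuffle_config"
  )
}

#' Generate the permutation null set for one gene
#'
#' Produces \code{n_permutations} synonymously permuted sequences for a gene,
#' reproducibly: the RNG stream is derived from \code{(config$seed, gene_id)},
#' so the same gene always receives the same null set regardless of the order
#' in which genes are processed, and different genes get independent streams.
#'
#' @param seq CDS nucleotide string.
#' @param gene_id gene identifier (seeds the per-gene stream).
#' @param config a [shuffle_config()].
#' @param code a [genetic_code()] object.
#' @return Character vector of \code{n_permutations} permuted sequences.
#' @export
generate_null_set <- function(seq, gene_id, config = shuffle_config(),
                              code = genetic_code()) {
  seq <- normalize_nt(seq)
  shuf <- switch(config$method,
    codon_shuffle = function() codon_shuffle(seq, code),
    dicodon_shuffle = function() dicodon_shuffle(seq, code, config$max_attempts)
  )
  with_preserved_seed(gene_stream_seed(config$seed, gene_id), {
    vapply(seq_len(config$n_permutations), function(i) shuf(), character(1))
  })
}
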