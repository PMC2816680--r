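# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (local seed, like the classic withr idiom).
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-gene substream seed from (master seed, gene_id), so that
# results are independent of the order in which genes are processed.
# FNV-1a over the id bytes, folded with the master seed, kept below 2^31.
gene_stream_seed <- function(seed, gene_id) {
  stopifnot(length(gene_id) == 1L)
  h <- 2166136261 %% 2^31
  for (b in utf8ToInt(as.character(gene_id))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Normalize a nucleotide string: uppercase, RNA U mapped to DNA T.
normalize_nt <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

# Split a CDS into codons. Length must be a multiple of 3.
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# G+C count / fraction of a string.
gc_count <- function(seq) {
  nchar(gsub("[^GCgc]", "", seq))
}

gc_fraction <- function(seq) {
  gc_count(seq) / nchar(seq)
}

# 16-entry dinucleotide count vector (overlapping, within one sequence).
dinucleotide_counts <- function(seq) {
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  counts <- integer(16)
  names(counts) <- dinucs
  n <- nchar(seq)
  if (n >= 2L) {
    d <- substring(seq, 1:(n - 1L), 2:n)
    tab <- table(factor(d, levels = dinucs))
    counts[] <- as.integer(tab)
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
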