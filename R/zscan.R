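#' Sliding-window specification
#'
#' Windows are placed relative to the first nucleotide of the start codon:
#' window i (1-based) spans nucleotides \code{(i-1)*step + 1} to
#' \code{(i-1)*step + width}, inclusive. The defaults (width 30 nt, step
#' 10 nt, 13 windows) scan the first 150 nt of the coding sequence; every
#' gene longer than 50 codons covers all 13 windows.
#'
#' @param width window width in nt (default 30; 20 and 40 are the usual
#'   alternatives).
#' @param step step between window starts in nt (default 10).
#' @param n_windows maximum number of windows (default 13); use \code{Inf}
#'   for "as many as fit".
#' @return An object of class \code{"window_spec"}.
#' @export
window_spec <- function(width = 30L, step = 10L, n_windows = 13L) {
  stopifnot(width >= 1, step >= 1, n_windows >= 1)
  structure(list(width = as.integer(width), step = as.integer(step),
                 n_windows = n_windows),
            class = "window_spec")
}

#' Enumerate sliding windows over a sequence
#'
#' @param seq_length sequence length in nt.
#' @param spec a [window_spec()].
#' @return Data frame with columns \code{window_index}, \code{start},
#'   \code{end} (1-based, inclusive). Empty (with a warning) when the
#'   sequence is shorter than one window.
#' @examples
#' enumerate_windows(153, window_spec())   # 13 windows, last (121, 150)
#' @export
enumerate_windows <- function(seq_length, spec = window_spec()) {
  if (seq_length < spec$width) {
    warning("sequence shorter than one window (", seq_length, " < ",
            spec$width, " nt)")
    return(data.frame(window_index = integer(0), start = integer(0),
                      end = integer(0)))
  }
  k <- min(spec$n_windows, (seq_length - spec$width) %/% spec$step + 1L)
  i <- seq_len(k)
  data.frame(window_index = i,
             start = (i - 1L) * spec$step + 1L,
             end = (i - 1L) * spec$step + spec$width)
}

#' Permutation Z-score
#'
#' Standardized deviation of an observed value from its permutation null:
#' \code{(wt - mean(perm)) / sd(perm)}, with the sample (N-1) standard
#' deviation. Applied to window folding energies this gives the stability
#' Z-score (positive = wild type less stable than expected, i.e. a less
#' negative MFE) and to window GC fractions the GC Z-score.
#'
#' @param wt observed (wild-type) value.
#' @param perm_values numeric vector of the same statistic over permuted
#'   sequences (length >= 2).
#' @return The Z-score, or \code{NA} (undefined) when the null is degenerate
#'   (\code{sd == 0}).
#' @export
zscore <- function(wt, perm_values) {
  if (length(perm_values) < 2L) stop("need at least 2 permutation values")
  s <- stats::sd(perm_values)
  if (s == 0) return(NA_real_)
  (wt - mean(perm_values)) / s
}

#' Scan one gene: per-window folding-energy and GC Z-scores
#'
#' Generates the gene's permutation null set once (the same permuted
#' sequences serve every window), folds the wild-type and permuted windows at
#' identical coordinates, and computes per-window Z-scores of folding energy
#' and GC content. Window folding is memoized across the whole batch, so
#' permutations that leave a window's sequence unchanged cost nothing extra.
#'
#' @param seq CDS nucleotide string.
#' @param gene_id gene identifier (drives the per-gene RNG stream).
#' @param spec a [window_spec()].
#' @param shuffle a [shuffle_config()].
#' @param backend a [fold_backend()].
#' @param code a [genetic_code()] object.
#' @return Data frame, one row per window: \code{gene_id},
#'   \code{window_index}, \code{start}, \code{end}, \code{dg_wt},
#'   \code{dg_perm_mean}, \code{dg_perm_sd}, \code{z_dg}, \code{gc_wt},
#'   \code{gc_perm_mean}, \code{gc_perm_sd}, \code{z_gc}, \code{n_perm}.
#'   Z columns are \code{NA} where the null is degenerate.
#' @export
scan_gene <- function(seq, gene_id, spec = window_spec(),
                      shuffle = shuffle_config(), backend = fold_backend(),
                      code = genetic_code()) {
  seq <- normalize_nt(seq)
  win <- enumerate_windows(nchar(seq), spec)
  if (nrow(win) == 0L) return(cbind(gene_id = character(0), win))
  perms <- generate_null_set(seq, gene_id, shuffle, code)
  n_perm <- length(perms)

  # windows x (wt + perms), folded in one memoized batch
  wt_win <- substring(seq, win$start, win$end)
  perm_win <- lapply(seq_len(nrow(win)),
                     function(i) substring(perms, win$start[i], win$end[i]))
  dg <- fold_batch(c(wt_win, unlist(perm_win)), backend)
  dg_wt <- dg[seq_len(nrow(win))]
  dg_perm <- matrix(dg[-seq_len(nrow(win))], nrow = n_perm)

  width <- win$end - win$start + 1L
  gc_wt <- gc_count(wt_win) / width
  gc_perm <- vapply(perm_win, gc_count, integer(n_perm)) /
    rep(width, each = n_perm)
  dim(gc_perm) <- c(n_perm, nrow(win))

  data.frame(
    gene_id = gene_id,
    win,
    dg_wt = dg_wt,
    dg_perm_mean = colMeans(dg_perm),
    dg_perm_sd = apply(dg_perm, 2L, stats::sd),
    z_dg = vapply(seq_len(nrow(win)),
                  function(i) zscore(dg_wt[i], dg_perm[, i]), numeric(1)),
    gc_wt = gc_wt,
    gc_perm_mean = colMeans(gc_perm),
    gc_perm_sd = apply(gc_perm, 2L, stats::sd),
    z_gc = vapply(seq_len(nrow(win)),
                  function(i) zscore(gc_wt[i], gc_perm[, i]), numeric(1)),
    n_perm = n_perm,
    row.names = NULL
  )
}

#' Genome-wide sliding-window stability scan
#'
#' The central analysis: for every gene, per-window folding-energy and GC
#' Z-scores against a synonymous-permutation null ([scan_gene()]), aggregated
#' into per-species window summaries ([summarize_genome()]). Returns a classed
#' object with \code{print}, \code{summary} and \code{plot} methods.
#'
#' @param genes gene table (data frame with \code{gene_id}, \code{species_id},
#'   \code{seq}), e.g. from [read_cds_fasta()] or [generate_genome()].
#' @inheritParams scan_gene
#' @return An object of class \code{"zscan"}: a list with \code{profiles}
#'   (per gene x window data frame), \code{summary} (per species x window),
#'   \code{skipped} (data frame of genes skipped on backend failure),
#'   \code{spec}, \code{shuffle} and \code{backend}.
#' @examples
#' \donttest{
#' g <- generate_genome(synth_genome_config(n_genes = 5, seed = 1))
#' fit <- zscan(g$genes, shuffle = shuffle_config(n_permutations = 20))
#' summary(fit)
#' }
#' @export
zscan <- function(genes, spec = window_spec(), shuffle = shuffle_config(),
                  backend = fold_backend(), code = genetic_code()) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L)
  if (is.null(genes$species_id)) genes$species_id <- NA_character_
  prof <- vector("list", nrow(genes))
  skipped <- list()
  for (i in seq_len(nrow(genes))) {
    p <- tryCatch(
      scan_gene(genes$seq[i], genes$gene_id[i], spec, shuffle, backend, code),
      error = function(e) e
    )
    if (inherits(p, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = genes$gene_id[i], reason = conditionMessage(p))
    } else if (nrow(p) > 0L) {
      p$species_id <- genes$species_id[i]
      prof[[i]] <- p
    }
  }
  profiles <- do.call(rbind, prof)
  structure(
    list(
      profiles = profiles,
      summary = summarize_genome(profiles),
      skipped = if (length(skipped)) do.call(rbind, skipped) else
        data.frame(gene_id = character(0), reason = character(0)),
      spec = spec, shuffle = shuffle, backend = backend
    ),
    class = "zscan"
  )
}

#' Per-genome window summary
#'
#' For each species and window: the mean and standard error of the per-gene
#' stability Z-scores, a two-sided one-sample t-test of the mean against 0,
#' the mean raw folding energy, and the mean GC Z-score. Genes whose Z is
#' undefined (degenerate null) are excluded, with the exclusion count
#' reported.
#'
#' @param profiles per gene x window data frame from [scan_gene()] rows bound
#'   together, with a \code{species_id} column.
#' @return Data frame, one row per species x window: \code{species_id},
#'   \code{window_index}, \code{mean_z_dg}, \code{se_z_dg}, \code{n_genes},
#'   \code{t_stat}, \code{p_value}, \code{mean_dg}, \code{mean_z_gc},
#'   \code{n_undefined}. Test fields are \code{NA} when fewer than 2 usable
#'   genes or the Z values are constant.
#' @export
summarize_genome <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L) {
    return(data.frame(species_id = character(0), window_index = integer(0),
                      mean_z_dg = numeric(0), se_z_dg = numeric(0),
                      n_genes = integer(0), t_stat = numeric(0),
                      p_value = numeric(0), mean_dg = numeric(0),
                      mean_z_gc = numeric(0), n_undefined = integer(0)))
  }
  if (is.null(profiles$species_id)) profiles$species_id <- NA_character_
  groups <- split(profiles,
                  list(profiles$species_id, profiles$window_index),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    z <- g$z_dg[!is.na(g$z_dg)]
    n <- length(z)
    tt <- if (n >= 2L && stats::sd(z) > 0) stats::t.test(z, mu = 0) else NULL
    data.frame(
      species_id = g$species_id[1], window_index = g$window_index[1],
      mean_z_dg = if (n > 0) mean(z) else NA_real_,
      se_z_dg = if (n >= 2L) stats::sd(z) / sqrt(n) else NA_real_,
      n_genes = n,
      t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value,
      mean_dg = mean(g$dg_wt),
      mean_z_gc = mean(g$z_gc, na.rm = TRUE),
      n_undefined = sum(is.na(g$z_dg))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species_id, out$window_index), ]
  rownames(out) <- NULL
  out
}

#' @export
print.zscan <- function(x, ...) {
  ns <- length(unique(x$summary$species_id))
  ng <- length(unique(x$profiles$gene_id))
  cat(sprintf(paste0(
    "Sliding-window mRNA stability scan (zscan)\n",
    "  %d gene(s), %d species, windows of %d nt / step %d nt, N = %d permutations\n",
    "  folding backend: %s\n"),
    ng, ns, x$spec$width, x$spec$step, x$shuffle$n_permutations,
    x$backend$name))
  if (nrow(x$skipped)) cat("  skipped genes:", nrow(x$skipped), "\n")
  w1 <- x$summary[x$summary$window_index == 1L, ]
  if (nrow(w1)) {
    cat("  window-1 mean stability Z by species:\n")
    for (i in seq_len(nrow(w1))) {
      cat(sprintf("    %s: %+0.3f (SE %0.3f, n = %d, p = %.3g)\n",
                  w1$species_id[i], w1$mean_z_dg[i], w1$se_z_dg[i],
                  w1$n_genes[i], w1$p_value[i]))
    }
  }
  invisible(x)
}

#' @export
summary.zscan <- function(object, ...) {
  object$summary
}

#' Plot the per-window mean stability Z-score profile
#'
#' Mean stability Z per window with +/- 1 SE bars, one panel series per
#' species, with the zero line marked — the genome-level profile in which a
#' positive window-1 excess indicates reduced stability at the
#' translation-initiation region.
#'
#' @param x a [zscan()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.zscan <- function(x, ...) {
  s <- x$summary
  species <- unique(s$species_id)
  wmax <- max(s$window_index)
  m <- sapply(species, function(sp) {
    ss <- s[s$species_id == sp, ]
    ss$mean_z_dg[match(seq_len(wmax), ss$window_index)]
  })
  m <- matrix(m, nrow = wmax)
  graphics::matplot(seq_len(wmax), m, type = "b", pch = 16, lty = 1,
                    xlab = "window index", ylab = "mean stability Z", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  if (length(species) == 1L) {
    se <- s$se_z_dg[order(s$window_index)]
    graphics::arrows(seq_len(wmax), m[, 1] - se, seq_len(wmax), m[, 1] + se,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
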