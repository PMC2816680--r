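#' Effective number of codons (ENC)
#'
#' Wright's summary of codon usage bias: ranges from 20 (one codon per amino
#' acid, maximal bias) to 61 (uniform synonymous usage). Computed as
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}
#' where \eqn{\bar F_k} is the mean codon homozygosity
#' \eqn{F = (n \sum p^2 - 1)/(n - 1)} over the amino acids of degeneracy
#' class k (2-, 3-, 4- and 6-fold; Leu, Ser and Arg are treated as single
#' 6-fold families). Stop codons are excluded. Amino acids observed fewer
#' than twice, or with non-positive F, do not contribute; a class with no
#' contributing amino acid is patched according to \code{missing_class}.
#'
#' @param seq CDS nucleotide string.
#' @param code a [genetic_code()] object.
#' @param missing_class how to patch a degeneracy class with no usable F:
#'   \code{"interpolate"} (default; F3 is estimated as the mean of F2 and F4,
#'   other classes fall back to the mean F over observed classes) or
#'   \code{"drop"} (the class's codon count is removed from the formula).
#' @return ENC in \[20, 61\] (capped), or \code{NA} if no class is estimable.
#' @export
enc <- function(seq, code = genetic_code(),
                missing_class = c("interpolate", "drop")) {
  missing_class <- match.arg(missing_class)
  cods <- split_codons(normalize_nt(seq))
  cods <- cods[!(cods %in% code$stop_codons)]
  if (length(cods) == 0L) return(NA_real_)
  counts <- table(factor(cods, levels = code$sense_codons))
  aa_of <- code$codon_to_aa[code$sense_codons]

  # per-amino-acid homozygosity F
  f_by_aa <- lapply(names(code$families), function(a) {
    fam <- code$families[[a]]
    n <- sum(counts[fam])
    if (n < 2L) return(NULL)
    p <- as.numeric(counts[fam]) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) return(NULL)
    list(k = length(fam), f = f)
  })
  f_by_aa <- Filter(Negate(is.null), f_by_aa)
  if (!length(f_by_aa)) return(NA_real_)
  ks <- vapply(f_by_aa, `[[`, numeric(1), "k")
  fs <- vapply(f_by_aa, `[[`, numeric(1), "f")

  deg <- code$degeneracy
  class_sizes <- table(deg[deg > 1])  # standard code: 2:9, 3:1, 4:5, 6:3
  class_sizes <- stats::setNames(as.numeric(class_sizes), names(class_sizes))
  fbar <- vapply(names(class_sizes), function(k)
    if (any(ks == as.numeric(k))) mean(fs[ks == as.numeric(k)]) else NA_real_,
    numeric(1))

  if (anyNA(fbar)) {
    if (missing_class == "interpolate") {
      if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
        fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
      }
      fbar[is.na(fbar)] <- mean(fs)
    } else {
      class_sizes <- class_sizes[!is.na(fbar)]
      fbar <- fbar[!is.na(fbar)]
      if (!length(fbar)) return(NA_real_)
    }
  }
  n_single <- sum(deg == 1)  # Met and Trp under the standard code
  value <- n_single + sum(class_sizes / fbar)
  # "drop" rescales to the full 61-codon range so values stay comparable
  if (missing_class == "drop") {
    attainable <- n_single + sum(class_sizes * as.numeric(names(class_sizes)))
    full <- n_single + sum(table(deg[deg > 1]) * as.numeric(names(table(deg[deg > 1]))))
    value <- value * full / attainable
  }
  min(value, 61)
}

#' Spearman rank correlation
#'
#' Thin wrapper around [stats::cor.test()] with the conventions used
#' throughout the comparative analyses: average ranks for ties, two-sided
#' asymptotic p-value, pairwise-complete observations only.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with \code{rho}, \code{p_value} and \code{n} (complete
#'   pairs); \code{rho} is \code{NA} when fewer than 3 complete pairs or
#'   either variable is constant.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Cross-species determinants of 5' stability
#'
#' Correlates per-genome window summaries with genome-level covariates:
#' \enumerate{
#'   \item rho(genomic GC, mean window-1 stability Z), excluding the taxa in
#'     \code{exclude_taxa} (default plants, birds and mammals, whose isochore
#'     structure breaks the genome-level relation);
#'   \item the same correlation for every window (the per-window profile);
#'   \item rho(genomic GC, mean window-1 GC Z);
#'   \item for prokaryotes with temperature data: rho(optimal growth
#'     temperature, window-1 Z), rho(temperature, genomic GC);
#'   \item raw-energy analogues: rho(genomic GC, mean window-1 MFE) and
#'     rho(genomic GC, mean window-1 MFE minus mean window-10 MFE).
#' }
#'
#' @param summaries per species x window data frame from [summarize_genome()]
#'   (or a [zscan()] object).
#' @param metadata species metadata with \code{species_id},
#'   \code{taxon_group}, \code{genomic_gc} and optionally
#'   \code{optimal_growth_temperature} (see [read_metadata()];
#'   \code{genomic_gc} from [compute_genomic_gc()]).
#' @param exclude_taxa taxon groups excluded from the GC correlations.
#' @return Data frame with columns \code{analysis}, \code{window_index},
#'   \code{rho}, \code{p_value}, \code{n}. Rows with too few species have
#'   \code{NA} statistics.
#' @export
cross_species_analysis <- function(summaries, metadata,
                                   exclude_taxa = c("plants", "birds",
                                                    "mammals")) {
  if (inherits(summaries, "zscan")) summaries <- summaries$summary
  stopifnot(all(c("species_id", "window_index", "mean_z_dg") %in%
                  names(summaries)))
  if (is.null(metadata$optimal_growth_temperature)) {
    metadata$optimal_growth_temperature <- NA_real_
  }
  s <- merge(summaries, metadata, by = "species_id")
  keep <- !(s$taxon_group %in% exclude_taxa)
  prok <- s$taxon_group %in% c("bacteria", "archaea")

  row_of <- function(analysis, window_index, sub, xcol, ycol) {
    r <- spearman(sub[[xcol]], sub[[ycol]])
    data.frame(analysis = analysis, window_index = window_index,
               rho = r$rho, p_value = r$p_value, n = r$n)
  }
  w1 <- s[s$window_index == 1L & keep, ]
  out <- list(
    row_of("gc_vs_z5", 1L, w1, "genomic_gc", "mean_z_dg"),
    row_of("gc_vs_zgc5", 1L, w1, "genomic_gc", "mean_z_gc")
  )
  for (w in sort(unique(s$window_index))) {
    out[[length(out) + 1L]] <-
      row_of("gc_vs_z_profile", w, s[s$window_index == w & keep, ],
             "genomic_gc", "mean_z_dg")
  }
  pw1 <- s[s$window_index == 1L & prok, ]
  out[[length(out) + 1L]] <-
    row_of("temperature_vs_z5", 1L, pw1, "optimal_growth_temperature",
           "mean_z_dg")
  out[[length(out) + 1L]] <-
    row_of("temperature_vs_gc", 1L, pw1, "optimal_growth_temperature",
           "genomic_gc")
  out[[length(out) + 1L]] <-
    row_of("gc_vs_dg5", 1L, w1, "genomic_gc", "mean_dg")
  w10 <- s[s$window_index == 10L & keep, ]
  if (nrow(w10)) {
    diffd <- merge(w1[, c("species_id", "genomic_gc", "mean_dg")],
                   w10[, c("species_id", "mean_dg")],
                   by = "species_id", suffixes = c("_w1", "_w10"))
    diffd$dg_diff <- diffd$mean_dg_w1 - diffd$mean_dg_w10
    out[[length(out) + 1L]] <-
      row_of("gc_vs_dg_diff_1_10", NA_integer_, diffd, "genomic_gc",
             "dg_diff")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene annotations for within-genome analyses
#'
#' Combines whole-CDS GC content, ENC, optional expression, and the gene's
#' window-1 stability Z (z5) into the table consumed by [stratify()] and
#' [pc_regression()].
#'
#' @param genes gene table (\code{gene_id}, \code{seq}).
#' @param profiles per gene x window profiles (from a [zscan()] object or
#'   [scan_gene()]).
#' @param expression optional expression table ([read_expression()]).
#' @param code a [genetic_code()] object.
#' @return Data frame with columns \code{gene_id}, \code{gc}, \code{enc},
#'   \code{expression}, \code{z5}.
#' @export
gene_annotations <- function(genes, profiles, expression = NULL,
                             code = genetic_code()) {
  if (inherits(profiles, "zscan")) profiles <- profiles$profiles
  w1 <- profiles[profiles$window_index == 1L, c("gene_id", "z_dg")]
  ann <- data.frame(
    gene_id = genes$gene_id,
    gc = gc_fraction(genes$seq),
    enc = vapply(genes$seq, enc, numeric(1), code = code, USE.NAMES = FALSE)
  )
  ann <- merge(ann, w1, by = "gene_id", all.x = TRUE)
  names(ann)[names(ann) == "z_dg"] <- "z5"
  if (!is.null(expression)) {
    ann <- merge(ann, expression, by = "gene_id", all.x = TRUE)
  } else {
    ann$expression <- NA_real_
  }
  ann[, c("gene_id", "gc", "enc", "expression", "z5")]
}

#' Compare extreme gene groups (top vs bottom 5 percent)
#'
#' Splits genes on a criterion (gene GC content, ENC, or expression level)
#' and compares the mean window-1 stability Z between the top and bottom
#' \code{fraction} of genes (default 5 percent) with a two-sample t-test.
#' For ENC the "top" group is the most biased one, i.e. the genes with the
#' lowest ENC.
#'
#' @param annotations data frame from [gene_annotations()].
#' @param criterion \code{"gc"}, \code{"enc"} or \code{"expression"}.
#' @param fraction tail fraction per group (default 0.05).
#' @return One-row data frame: \code{criterion}, \code{n_per_group},
#'   \code{top_mean_z5}, \code{bottom_mean_z5}, \code{difference},
#'   \code{test_p}.
#' @export
stratify <- function(annotations, criterion = c("gc", "enc", "expression"),
                     fraction = 0.05) {
  criterion <- match.arg(criterion)
  a <- annotations[!is.na(annotations[[criterion]]) &
                     !is.na(annotations$z5), ]
  n <- nrow(a)
  if (n < 40L) stop("too few genes for ", fraction * 100,
                    "% stratification (", n, " usable, need >= 40)")
  k <- max(1L, floor(fraction * n))
  # stable order: ties at the cut resolved by gene_id
  decreasing <- criterion != "enc"   # low ENC = strong bias = "top"
  ord <- order(a[[criterion]], a$gene_id, decreasing = c(decreasing, FALSE),
               method = "radix")
  top <- a$z5[ord[seq_len(k)]]
  bottom <- a$z5[rev(ord)[seq_len(k)]]
  tt <- if (k >= 2L && (stats::sd(top) > 0 || stats::sd(bottom) > 0)) {
    stats::t.test(top, bottom)
  } else NULL
  data.frame(
    criterion = criterion, n_per_group = k,
    top_mean_z5 = mean(top), bottom_mean_z5 = mean(bottom),
    difference = mean(top) - mean(bottom),
    test_p = if (is.null(tt)) NA_real_ else tt$p.value
  )
}

#' Principal component regression of 5' stability on gene covariates
#'
#' Regresses the window-1 stability Z on the principal components of the
#' three standardized predictors (gene GC, ENC, log expression), maps the
#' component coefficients back to the original predictors, and allocates the
#' explained variance by the Pratt product measure (standardized coefficient
#' times marginal correlation). The allocation sums exactly to the model R
#' squared and reduces to the classical squared-correlation decomposition
#' when the predictors are orthogonal; under strong collinearity individual
#' shares can be negative, which is reported as-is. Expression is
#' log-transformed after adding the smallest positive observed value as a
#' pseudo-count.
#'
#' @param annotations data frame from [gene_annotations()]; needs >= 50 genes
#'   with all three predictors and z5.
#' @return List with \code{contributions} (named vector, per-predictor share
#'   of explained variance, summing to \code{r_squared}), \code{r_squared},
#'   \code{pc_variance} (per-PC explained variance in z5), \code{loadings}
#'   and \code{n}.
#' @export
pc_regression <- function(annotations) {
  a <- annotations[stats::complete.cases(
    annotations[, c("gc", "enc", "expression", "z5")]), ]
  if (nrow(a) < 50L) stop("need at least 50 genes with all predictors ",
                          "and z5 (got ", nrow(a), ")")
  pos <- a$expression[a$expression > 0]
  if (!length(pos)) stop("expression is zero for all genes")
  x <- cbind(gc = a$gc, enc = a$enc,
             expression = log(a$expression + min(pos)))
  keep <- apply(x, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no non-constant predictors")
  xs <- scale(x)
  ys <- as.vector(scale(a$z5))
  pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  pcs <- pca$x
  fit <- stats::lm(ys ~ pcs)
  # PCs are orthogonal: total R^2 decomposes exactly over components
  r2_k <- vapply(seq_len(ncol(pcs)), function(k)
    stats::cor(ys, pcs[, k])^2, numeric(1))
  # back-transformed standardized coefficients; Pratt allocation
  beta <- as.vector(pca$rotation %*% stats::coef(fit)[-1])
  marg <- as.vector(stats::cor(xs, ys))
  contrib <- stats::setNames(beta * marg, colnames(x))
  list(contributions = contrib,
       r_squared = summary(fit)$r.squared,
       pc_variance = stats::setNames(r2_k, colnames(pcs)),
       loadings = pca$rotation,
       n = nrow(a))
}
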