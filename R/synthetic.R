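#' Configuration for a synthetic genome
#'
#' Describes one synthetic species: a set of coding sequences with
#' controllable pooled GC content, codon usage bias strength, gene length
#' range, and an injectable 5' destabilization signal. The signal
#' (\code{delta5}) re-weights synonymous codon choice toward AT-richer codons
#' within the first \code{delta5_span_nt} nucleotides, mimicking the causal
#' pathway under study (GC-poor, weakly folding sequence right after the
#' start codon) while leaving the amino-acid sequence untouched — so any
#' stability Z-score signal in generated data is attributable to synonymous
#' structure alone.
#'
#' @param species_id species label.
#' @param n_genes number of genes.
#' @param length_codons integer range (min, max) of gene lengths in codons,
#'   start and stop included; minimum must exceed 51 so every gene passes the
#'   default length filter and covers the default 13 windows.
#' @param target_gc target pooled GC fraction of the generated coding
#'   sequences; codon weights are tuned analytically to hit it in
#'   expectation.
#' @param codon_bias_strength concentration of codon usage bias (>= 0): each
#'   synonymous family gets one randomly chosen preferred codon whose
#'   log-weight is raised by this amount. 0 (default) = no preferred codon.
#' @param delta5 5' destabilization strength (>= 0): the per-gene mean of the
#'   extra AT log-weight applied to synonymous choices within the first
#'   \code{delta5_span_nt} nt. Per-gene strengths vary around this mean
#'   (gamma distributed, CV 0.5) so that expression can be coupled to them.
#' @param delta5_span_nt extent of the destabilized region (default 30 nt).
#' @param expression_coupling correlation (on the log scale) between the
#'   simulated expression level and the gene's realized 5' signal strength.
#' @param seed RNG seed for this genome.
#' @return An object of class \code{"synth_genome_config"}.
#' @export
synth_genome_config <- function(species_id = "synth", n_genes = 100L,
                                length_codons = c(60L, 300L),
                                target_gc = 0.5, codon_bias_strength = 0,
                                delta5 = 0, delta5_span_nt = 30L,
                                expression_coupling = 0, seed = 1L) {
  stopifnot(n_genes >= 1L, length(length_codons) == 2L,
            length_codons[1] > 50L, length_codons[1] <= length_codons[2],
            target_gc > 0, target_gc < 1, codon_bias_strength >= 0,
            delta5 >= 0, delta5_span_nt >= 3L,
            abs(expression_coupling) <= 1)
  structure(
    list(species_id = species_id, n_genes = as.integer(n_genes),
         length_codons = as.integer(length_codons), target_gc = target_gc,
         codon_bias_strength = codon_bias_strength, delta5 = delta5,
         delta5_span_nt = as.integer(delta5_span_nt),
         expression_coupling = expression_coupling, seed = as.integer(seed)),
    class = "synth_genome_config"
  )
}

# Solve the GC weight exponent so the expected per-codon GC over uniformly
# drawn amino acids matches the target; warns and clamps when unattainable.
solve_gc_exponent <- function(families, ngc, pref_bonus, target_gc) {
  expected_gc <- function(gamma) {
    per_aa <- vapply(names(families), function(a) {
      cods <- families[[a]]
      w <- exp(gamma * ngc[cods] + pref_bonus[cods])
      sum(w * ngc[cods]) / sum(w) / 3
    }, numeric(1))
    mean(per_aa)
  }
  lo <- -30; hi <- 30
  glo <- expected_gc(lo); ghi <- expected_gc(hi)
  if (target_gc <= glo) {
    if (glo - target_gc > 0.005) {
      warning("target_gc ", target_gc, " unattainable; using closest ",
              round(glo, 3))
    }
    return(lo)
  }
  if (target_gc >= ghi) {
    if (target_gc - ghi > 0.005) {
      warning("target_gc ", target_gc, " unattainable; using closest ",
              round(ghi, 3))
    }
    return(hi)
  }
  stats::uniroot(function(g) expected_gc(g) - target_gc, c(lo, hi),
                 tol = 1e-8)$root
}

#' Generate a synthetic genome
#'
#' Draws \code{n_genes} coding sequences under a [synth_genome_config()]:
#' amino acids i.i.d. uniform over the 20, codons sampled within each
#' synonymous family from GC-tuned weights (optionally biased toward one
#' preferred codon per family), genes starting with ATG, ending with a stop
#' codon and containing no internal stops. Within the first
#' \code{delta5_span_nt} nucleotides the synonymous weights are shifted
#' toward AT-richer codons with per-gene strength recorded in the truth
#' table. Byte-identical output for identical config.
#'
#' @param config a [synth_genome_config()].
#' @param code a [genetic_code()] object.
#' @return List with \code{genes} (data frame: \code{gene_id},
#'   \code{species_id}, \code{seq}, \code{n_codons}) and \code{truth} (data
#'   frame: \code{gene_id}, \code{gc}, \code{delta}, \code{expression}).
#' @export
generate_genome <- function(config, code = genetic_code()) {
  stopifnot(inherits(config, "synth_genome_config"))
  families <- code$families
  ngc <- vapply(code$sense_codons, gc_count, integer(1))
  aas <- names(families)
  # Independent derived RNG streams so that protein sequences depend only on
  # (seed, gene index): changing delta5, bias or coupling re-decides the
  # synonymous codons of the same proteins, never the proteins themselves.
  stream <- function(label) gene_stream_seed(config$seed, label)

  pref_bonus <- stats::setNames(numeric(length(code$sense_codons)),
                                code$sense_codons)
  if (config$codon_bias_strength > 0) {
    with_preserved_seed(stream("bias"), {
      for (a in aas) {
        fam <- families[[a]]
        if (length(fam) > 1L) {
          pref_bonus[sample(fam, 1L)] <- config$codon_bias_strength
        }
      }
    })
  }
  gamma <- solve_gc_exponent(families, ngc, pref_bonus, config$target_gc)
  base_w <- lapply(families, function(fam)
    exp(gamma * ngc[fam] + pref_bonus[fam]))

  deltas <- if (config$delta5 > 0) {
    with_preserved_seed(stream("delta5"),
      config$delta5 * stats::rgamma(config$n_genes, shape = 4, rate = 4))
  } else {
    numeric(config$n_genes)
  }
  span_codons <- config$delta5_span_nt %/% 3L

  seqs <- character(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    protein <- with_preserved_seed(stream(paste0("aa", g)), {
      len <- sample(config$length_codons[1]:config$length_codons[2], 1L)
      list(aa_seq = sample(aas, len - 2L, replace = TRUE),
           stop = sample(code$stop_codons, 1L))
    })
    five_w <- lapply(families, function(fam)
      exp((gamma - deltas[g]) * ngc[fam] + pref_bonus[fam]))
    cods <- with_preserved_seed(stream(paste0("codons", g)), {
      vapply(seq_along(protein$aa_seq), function(j) {
        fam <- families[[protein$aa_seq[j]]]
        # j + 1 = codon position in the gene (position 1 is ATG)
        w <- if (j + 1L <= span_codons) five_w[[protein$aa_seq[j]]] else
          base_w[[protein$aa_seq[j]]]
        if (length(fam) == 1L) fam else sample(fam, 1L, prob = w)
      }, character(1))
    })
    seqs[g] <- paste0("ATG", paste(cods, collapse = ""), protein$stop)
  }

  expr <- with_preserved_seed(stream("expression"), {
    z_delta <- if (isTRUE(stats::sd(deltas) > 0)) as.vector(scale(deltas))
      else stats::rnorm(config$n_genes)
    rho <- config$expression_coupling
    exp(rho * z_delta + sqrt(1 - rho^2) * stats::rnorm(config$n_genes))
  })

  gene_id <- sprintf("%s_g%04d", config$species_id, seq_len(config$n_genes))
  list(
    genes = data.frame(gene_id = gene_id, species_id = config$species_id,
                       seq = seqs, n_codons = nchar(seqs) %/% 3L),
    truth = data.frame(gene_id = gene_id, gc = gc_fraction(seqs),
                       delta = deltas, expression = expr)
  )
}

#' Generate a synthetic multi-species panel
#'
#' Builds \code{n_species} synthetic genomes whose GC contents are spread
#' over \code{gc_range} and whose 5' destabilization strength is coupled to
#' GC with the given slope (\code{delta5 = delta_slope * (gc -
#' gc_range[1])}). When \code{temperature_model} is on, prokaryote-tagged
#' species are assigned an optimal growth temperature with a negative
#' coupling to their destabilization strength (colder species destabilize
#' more), emulating the cross-species comparative setting.
#'
#' @param n_species number of species (>= 3).
#' @param gc_range range of target genomic GC fractions.
#' @param delta_slope coupling of the 5' signal to GC (default 2).
#' @param n_genes genes per species.
#' @param taxon_groups taxon labels recycled over species (default all
#'   bacteria, so temperatures apply to every species).
#' @param temperature_model assign growth temperatures (default TRUE).
#' @param seed master seed; each species gets an independent derived stream.
#' @param ... further arguments passed to [synth_genome_config()]
#'   (e.g. \code{length_codons}, \code{expression_coupling}).
#' @return List with \code{genes} (all species pooled), \code{metadata}
#'   (species_id, taxon_group, optimal_growth_temperature, genomic_gc,
#'   delta5), \code{expression} and \code{truth}.
#' @export
generate_species_panel <- function(n_species = 20L, gc_range = c(0.3, 0.62),
                                   delta_slope = 2, n_genes = 100L,
                                   taxon_groups = "bacteria",
                                   temperature_model = TRUE, seed = 1L,
                                   ...) {
  stopifnot(n_species >= 3L)
  species_id <- sprintf("sp%02d", seq_len(n_species))
  gc <- seq(gc_range[1], gc_range[2], length.out = n_species)
  delta <- pmax(0, delta_slope * (gc - gc_range[1]))
  taxon <- rep_len(taxon_groups, n_species)
  prok <- taxon %in% c("bacteria", "archaea")

  temperature <- rep(NA_real_, n_species)
  if (temperature_model && any(prok)) {
    span <- diff(range(delta[prok]))
    rel <- if (span > 0) (delta[prok] - min(delta[prok])) / span else
      rep(0.5, sum(prok))
    temperature[prok] <- with_preserved_seed(seed, {
      pmax(4, 80 - 60 * rel + stats::rnorm(sum(prok), sd = 4))
    })
  }

  pieces <- lapply(seq_len(n_species), function(s) {
    cfg <- synth_genome_config(
      species_id = species_id[s], n_genes = n_genes, target_gc = gc[s],
      delta5 = delta[s], seed = gene_stream_seed(seed, species_id[s]), ...
    )
    generate_genome(cfg)
  })
  genes <- do.call(rbind, lapply(pieces, `[[`, "genes"))
  truth <- do.call(rbind, lapply(pieces, function(p)
    cbind(p$truth, species_id = p$genes$species_id[1])))
  metadata <- data.frame(
    species_id = species_id, taxon_group = taxon,
    optimal_growth_temperature = temperature,
    genomic_gc = vapply(pieces, function(p) compute_genomic_gc(p$genes),
                        numeric(1)),
    delta5 = delta
  )
  list(genes = genes, metadata = metadata,
       expression = truth[, c("gene_id", "expression")], truth = truth)
}
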