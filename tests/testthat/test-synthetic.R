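test_that("generated genomes are valid, reproducible coding sequences", {
  cfg <- synth_genome_config(n_genes = 40, target_gc = 0.5, seed = 17)
  g1 <- generate_genome(cfg)
  # every gene passes validation with zero rejections
  res <- filter_cds(g1$genes)
  expect_equal(nrow(res$genes), 40L)
  expect_equal(nrow(res$report), 0L)  # no rejections, no warnings
  expect_true(all(substr(g1$genes$seq, 1, 3) == "ATG"))
  # byte-identical regeneration
  g2 <- generate_genome(cfg)
  expect_identical(g1$genes$seq, g2$genes$seq)
  expect_identical(g1$truth, g2$truth)
  # different seed, different genome
  g3 <- generate_genome(synth_genome_config(n_genes = 40, seed = 18))
  expect_false(identical(g1$genes$seq, g3$genes$seq))
})

test_that("pooled GC tracks the target across the attainable range", {
  for (target in c(0.35, 0.5, 0.6)) {
    g <- generate_genome(synth_genome_config(
      n_genes = 500, target_gc = target, seed = round(100 * target)
    ))
    expect_lt(abs(compute_genomic_gc(g$genes) - target), 0.02)
  }
  expect_warning(
    generate_genome(synth_genome_config(n_genes = 5, target_gc = 0.98,
                                        seed = 1)),
    "unattainable"
  )
})

test_that("without a 5' signal the start region looks like the rest of the gene", {
  g <- generate_genome(synth_genome_config(n_genes = 500, delta5 = 0,
                                           seed = 71))
  # sampled codons only (positions 2-11 vs 32-41); the fixed ATG start is
  # common to every gene and is not part of the synonymous signal
  gc_w1 <- vapply(g$genes$seq, function(s) oracle_window_gc(s, 4, 33),
                  numeric(1))
  gc_w10 <- vapply(g$genes$seq, function(s) oracle_window_gc(s, 94, 123),
                   numeric(1))
  expect_gt(t.test(gc_w1, gc_w10)$p.value, 0.01)
  expect_true(all(g$truth$delta == 0))
})

test_that("a strong 5' signal depresses start-region GC only", {
  g <- generate_genome(synth_genome_config(n_genes = 300, delta5 = 1.5,
                                           seed = 72))
  gc_w1 <- vapply(g$genes$seq, function(s) oracle_window_gc(s, 4, 33),
                  numeric(1))
  gc_w10 <- vapply(g$genes$seq, function(s) oracle_window_gc(s, 94, 123),
                   numeric(1))
  expect_lt(mean(gc_w1), mean(gc_w10))
  expect_lt(t.test(gc_w1, gc_w10)$p.value, 1e-6)
  expect_true(all(g$truth$delta > 0))
})

test_that("the signal acts on synonymous choice only, not amino acids", {
  g0 <- generate_genome(synth_genome_config(n_genes = 200, delta5 = 0,
                                            seed = 55))
  g1 <- generate_genome(synth_genome_config(n_genes = 200, delta5 = 2,
                                            seed = 55))
  # same seed: identical amino-acid sequences, signal or not
  expect_equal(vapply(g1$genes$seq, translate_cds, "", USE.NAMES = FALSE),
               vapply(g0$genes$seq, translate_cds, "", USE.NAMES = FALSE))
})

test_that("codon bias strength raises usage concentration (lowers ENC)", {
  g_flat <- generate_genome(synth_genome_config(n_genes = 60, seed = 5,
                                                codon_bias_strength = 0))
  g_bias <- generate_genome(synth_genome_config(n_genes = 60, seed = 5,
                                                codon_bias_strength = 3))
  enc_flat <- mean(vapply(g_flat$genes$seq, enc, 0, USE.NAMES = FALSE))
  enc_bias <- mean(vapply(g_bias$genes$seq, enc, 0, USE.NAMES = FALSE))
  expect_lt(enc_bias, enc_flat - 5)
})

test_that("expression coupling is realized in the truth table", {
  g <- generate_genome(synth_genome_config(n_genes = 400, delta5 = 1,
                                           expression_coupling = 0.8,
                                           seed = 91))
  expect_gt(cor(log(g$truth$expression), g$truth$delta,
                method = "spearman"), 0.5)
})

test_that("species panels couple the 5' signal to GC and temperature", {
  p <- generate_species_panel(n_species = 10, gc_range = c(0.3, 0.62),
                              delta_slope = 2, n_genes = 5, seed = 3)
  expect_equal(nrow(p$metadata), 10L)
  expect_equal(p$metadata$delta5,
               pmax(0, 2 * (seq(0.3, 0.62, length.out = 10) - 0.3)))
  expect_gt(cor(p$metadata$genomic_gc, p$metadata$delta5), 0.9)
  expect_lt(cor(p$metadata$optimal_growth_temperature, p$metadata$delta5),
            -0.7)
  # slope 0: no signal anywhere
  p0 <- generate_species_panel(n_species = 5, delta_slope = 0, n_genes = 5,
                               seed = 4)
  expect_true(all(p0$metadata$delta5 == 0))
  # non-prokaryotes get no temperature
  p2 <- generate_species_panel(n_species = 6, n_genes = 5, seed = 5,
                               taxon_groups = c("bacteria", "fungi"))
  expect_true(all(is.na(
    p2$metadata$optimal_growth_temperature[p2$metadata$taxon_group == "fungi"]
  )))
})
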