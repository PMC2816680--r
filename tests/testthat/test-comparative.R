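test_that("ENC hits its theoretical extremes", {
  code <- genetic_code()
  # one codon per amino acid, each used many times: maximal bias, ENC = 20
  one_per_aa <- vapply(code$families, `[`, character(1), 1L)
  g_biased <- paste(rep(one_per_aa, 10), collapse = "")
  expect_equal(enc(g_biased), 20)

  # perfectly uniform usage within every family: ENC capped at 61
  g_uniform <- paste(rep(unlist(code$families), 8), collapse = "")
  expect_equal(enc(g_uniform), 61)
})

test_that("ENC matches an independent Wright-formula implementation", {
  set.seed(19)
  for (i in 1:5) {
    g <- random_cds(300)
    expect_equal(enc(g), oracle_enc(g), tolerance = 1e-12)
  }
})

test_that("ENC is invariant under synonymous shuffling and handles edge cases", {
  set.seed(3)
  g <- random_cds(120)
  e0 <- enc(g)
  for (i in 1:5) expect_equal(enc(codon_shuffle(g)), e0)
  # too short to define any F
  expect_true(is.na(enc("ATGTGG")))
  # missing 3-fold class (no Ile): interpolation vs drop both in [20, 61]
  cods <- split3(g)
  cods[cods %in% c("ATT", "ATC", "ATA")] <- "ATG"
  g_no_ile <- paste(cods, collapse = "")
  for (m in c("interpolate", "drop")) {
    v <- enc(g_no_ile, missing_class = m)
    expect_true(v >= 20 && v <= 61)
  }
})

test_that("spearman follows rank-correlation conventions", {
  x <- 1:10
  expect_equal(spearman(x, x^3)$rho, 1)        # monotone transform
  expect_equal(spearman(x, -x)$rho, -1)
  # tied example against explicit average-rank computation
  set.seed(6)
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 8, 7, 7)
  manual <- cor(rank(xt, ties.method = "average"),
                rank(yt, ties.method = "average"))
  expect_equal(spearman(xt, yt)$rho, manual)
  # rank invariance and pairwise-complete handling
  expect_equal(spearman(rank(xt), rank(yt))$rho, spearman(xt, yt)$rho)
  expect_equal(spearman(c(xt, NA), c(yt, 1))$n, 10)
  expect_true(is.na(spearman(c(1, 2), c(3, 4))$rho))
})

make_summaries <- function(z5, species, window = 1L, dg = NULL, zgc = NULL) {
  data.frame(species_id = species, window_index = window, mean_z_dg = z5,
             se_z_dg = 0.1, n_genes = 50, t_stat = 1, p_value = 0.5,
             mean_dg = dg %||% -z5, mean_z_gc = zgc %||% -z5,
             n_undefined = 0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cross-species correlations recover constructed relations", {
  sp <- sprintf("s%02d", 1:6)
  md <- data.frame(species_id = sp, taxon_group = "bacteria",
                   optimal_growth_temperature = c(80, 70, 50, 40, 20, 10),
                   genomic_gc = seq(0.3, 0.7, length.out = 6))
  s1 <- rbind(make_summaries(seq(0.1, 0.9, length.out = 6), sp),
              make_summaries(seq(0.1, 0.9, length.out = 6) / 2, sp,
                             window = 10L))
  tab <- cross_species_analysis(s1, md)
  expect_equal(tab$rho[tab$analysis == "gc_vs_z5"], 1)
  expect_equal(tab$rho[tab$analysis == "temperature_vs_z5"], -1)
  expect_true("gc_vs_dg_diff_1_10" %in% tab$analysis)
  expect_true(all(c("gc_vs_zgc5", "gc_vs_dg5", "temperature_vs_gc",
                    "gc_vs_z_profile") %in% tab$analysis))

  # taxon exclusions: two mammal outliers would destroy the monotone relation
  md2 <- md
  md2$taxon_group[5:6] <- "mammals"
  s2 <- make_summaries(c(0.1, 0.2, 0.3, 0.4, -5, -9), sp)
  tab2 <- cross_species_analysis(s2, md2)
  expect_equal(tab2$rho[tab2$analysis == "gc_vs_z5"], 1)
  expect_equal(tab2$n[tab2$analysis == "gc_vs_z5"], 4)
  # mammals are not prokaryotes: temperature rows use bacteria only
  expect_equal(tab2$n[tab2$analysis == "temperature_vs_z5"], 4)

  # absent temperatures give undefined temperature rows
  md$optimal_growth_temperature <- NA_real_
  tab3 <- cross_species_analysis(s1, md)
  expect_true(is.na(tab3$rho[tab3$analysis == "temperature_vs_z5"]))
})

test_that("stratification compares the extreme tails with stable ties", {
  ann <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    gc = seq(0.2, 0.8, length.out = 100),
                    enc = seq(61, 30, length.out = 100),
                    expression = rep(1, 100),
                    z5 = seq(-1, 3, length.out = 100))
  s <- stratify(ann, "gc")
  expect_equal(s$n_per_group, 5L)
  expect_equal(s$top_mean_z5, mean(tail(ann$z5, 5)))
  expect_equal(s$bottom_mean_z5, mean(head(ann$z5, 5)))
  expect_gt(s$difference, 0)
  # low ENC = strong bias = "top"
  s_enc <- stratify(ann, "enc")
  expect_equal(s_enc$top_mean_z5, mean(tail(ann$z5, 5)))
  # reordering genes changes nothing
  s_rev <- stratify(ann[sample(1:100), ], "gc")
  expect_equal(s_rev$top_mean_z5, s$top_mean_z5)
  expect_error(stratify(ann[1:30, ], "gc"), "too few genes")
})

test_that("null stratification shows no systematic difference", {
  set.seed(10)
  ann <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    gc = runif(200), enc = runif(200, 20, 61),
                    expression = rexp(200), z5 = rnorm(200))
  s <- stratify(ann, "gc")
  se <- sqrt(2 / s$n_per_group)   # z5 ~ N(0,1) in both groups
  expect_lt(abs(s$difference), 3 * se)
})

test_that("principal component regression allocates variance sensibly", {
  set.seed(22)
  n <- 300
  # orthogonalized predictors; z5 driven by GC alone
  gc <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  enc_v <- residuals(lm(e1 ~ gc))
  expr_v <- exp(residuals(lm(e2 ~ gc + enc_v)))
  ann <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    gc = gc, enc = enc_v, expression = expr_v,
                    z5 = 2 * as.vector(scale(gc)))
  # exact construction: lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(pc_regression(ann))
  expect_gt(fit$contributions[["gc"]], 0.95)
  expect_lt(sum(fit$contributions[c("enc", "expression")]), 0.05)
  # contributions sum to the explained variance
  expect_equal(sum(fit$contributions), fit$r_squared, tolerance = 1e-9)

  # pure noise: nothing explained
  ann$z5 <- rnorm(n)
  expect_lt(pc_regression(ann)$r_squared, 0.1)

  # constant predictor dropped with a warning
  ann$enc <- 45
  expect_warning(fit2 <- pc_regression(ann), "constant predictor")
  expect_false("enc" %in% names(fit2$contributions))
})

test_that("equal independent effects share contributions roughly equally", {
  set.seed(33)
  reps <- replicate(8, {
    n <- 400
    x <- matrix(rnorm(3 * n), ncol = 3)
    ann <- data.frame(gene_id = sprintf("g%04d", 1:n),
                      gc = x[, 1], enc = x[, 2], expression = exp(x[, 3]),
                      z5 = rowSums(scale(x)) + rnorm(n, sd = 0.5))
    pc_regression(ann)$contributions / sum(pc_regression(ann)$contributions)
  })
  expect_true(all(abs(rowMeans(reps) - 1 / 3) < 0.1))
})

test_that("gene annotations join GC, ENC, expression and window-1 z", {
  set.seed(2)
  genes <- data.frame(gene_id = c("a", "b"), species_id = "sp",
                      seq = c(random_cds(60), random_cds(60)))
  prof <- data.frame(gene_id = c("a", "a", "b", "b"),
                     window_index = c(1L, 2L, 1L, 2L),
                     z_dg = c(1.5, 0, -0.5, 0))
  expr <- data.frame(gene_id = "a", expression = 2)
  ann <- gene_annotations(genes, prof, expr)
  expect_equal(ann$z5[ann$gene_id == "a"], 1.5)
  expect_equal(ann$z5[ann$gene_id == "b"], -0.5)
  expect_equal(ann$expression, c(2, NA))
  expect_equal(ann$gc[1], oracle_pooled_gc(genes$seq[1]))
})
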