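test_that("window enumeration follows the 1-based sliding grid", {
  w <- enumerate_windows(153, window_spec())
  expect_equal(nrow(w), 13L)
  expect_equal(w$start[1], 1L)
  expect_equal(unlist(w[13, c("start", "end")], use.names = FALSE),
               c(121L, 150L))

  expect_equal(nrow(enumerate_windows(150, window_spec())), 13L)
  w1 <- enumerate_windows(30, window_spec())
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(1L, 30L))
  expect_equal(nrow(enumerate_windows(149, window_spec())), 12L)
  expect_equal(nrow(enumerate_windows(1000, window_spec(n_windows = Inf))),
               (1000 - 30) %/% 10 + 1)
  expect_warning(out <- enumerate_windows(20, window_spec()), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("z-score arithmetic matches direct computation and flags degeneracy", {
  expect_equal(zscore(-5, c(-10, -8, -6)), 1.5)   # mean -8, sample sd 2
  expect_equal(zscore(3, c(2, 4, 3, 3)), 0)
  expect_true(is.na(zscore(5, c(5, 5, 5))))
  expect_error(zscore(1, 2), "at least 2")
  # sign convention: wild type less stable (less negative dG) => positive z
  expect_gt(zscore(-1, c(-6, -5, -4)), 0)
})

test_that("a gene with no synonymous freedom yields undefined z everywhere", {
  g <- paste0("ATG", strrep("TGG", 55), "TGA")  # Met + Trp only
  prof <- scan_gene(g, "rigid", shuffle = shuffle_config(10, seed = 4))
  expect_equal(nrow(prof), 13L)
  expect_true(all(is.na(prof$z_dg)))
  expect_true(all(is.na(prof$z_gc)))
  expect_equal(unique(prof$n_perm), 10L)
})

test_that("scan_gene matches the naive straight-line reimplementation", {
  set.seed(77)
  g <- random_cds(70)
  prof <- scan_gene(g, "gX", shuffle = shuffle_config(50, seed = 123))
  ora <- oracle_scan_z(g, "gX", 50, 123)
  expect_equal(prof$z_dg, ora$z_dg, tolerance = 1e-9)
  expect_equal(prof$z_gc, ora$z_gc, tolerance = 1e-9)
})

test_that("permutation GC summaries equal direct counts and conserve gene GC", {
  set.seed(31)
  g <- random_cds(60)
  cfg <- shuffle_config(40, seed = 8)
  prof <- scan_gene(g, "gY", shuffle = cfg)
  perms <- generate_null_set(g, "gY", cfg)
  # same-coordinate window GC, counted independently
  for (w in c(1L, 5L, 13L)) {
    s <- (w - 1) * 10 + 1
    gc_p <- vapply(perms, function(p) oracle_window_gc(p, s, s + 29),
                   numeric(1))
    expect_equal(prof$gc_perm_mean[w], mean(gc_p))
    expect_equal(prof$gc_wt[w], oracle_window_gc(g, s, s + 29))
  }
  # shuffle-set conservation: gene-wide GC preserved exactly
  expect_true(all(vapply(perms, oracle_pooled_gc, numeric(1)) ==
                    oracle_pooled_gc(g)))
})

test_that("window GC z-scores are invariant under equal-GC synonymous recoding", {
  # CGT <-> CGA have equal GC, so every permuted arrangement keeps identical
  # window GC; the same per-gene stream then yields identical z_gc
  base <- paste0("ATG", strrep("CGTGAAAAA", 8), strrep("GAA", 30), "TAA")
  recoded <- gsub("CGT", "CGA", base)
  cfg <- shuffle_config(30, seed = 5)
  p1 <- scan_gene(base, "g", shuffle = cfg)
  p2 <- scan_gene(recoded, "g", shuffle = cfg)
  expect_equal(p1$z_gc, p2$z_gc)
})

test_that("genome summaries aggregate correctly", {
  prof <- data.frame(
    gene_id = rep(c("a", "b"), each = 1), species_id = "sp",
    window_index = 1L, dg_wt = c(-5, -7), z_dg = c(1, -1),
    z_gc = c(0.5, 0.5)
  )
  s <- summarize_genome(prof)
  expect_equal(s$mean_z_dg, 0)
  expect_equal(s$t_stat, 0)
  expect_equal(s$mean_dg, -6)

  # constant z: degenerate test flagged, mean still reported
  prof$z_dg <- c(0.5, 0.5)
  s2 <- summarize_genome(prof)
  expect_equal(s2$mean_z_dg, 0.5)
  expect_true(is.na(s2$t_stat))

  # arithmetic oracle on a larger synthetic profile table
  set.seed(12)
  big <- data.frame(
    gene_id = rep(sprintf("g%03d", 1:200), each = 3),
    species_id = "sp",
    window_index = rep(1:3, 200),
    dg_wt = rnorm(600, -8, 2),
    z_dg = c(rnorm(598), NA, NA),
    z_gc = rnorm(600)
  )
  s3 <- summarize_genome(big)
  for (w in 1:3) {
    z <- big$z_dg[big$window_index == w]
    z <- z[!is.na(z)]
    expect_equal(s3$mean_z_dg[s3$window_index == w], mean(z))
    expect_equal(s3$se_z_dg[s3$window_index == w], sd(z) / sqrt(length(z)))
    expect_equal(s3$n_genes[s3$window_index == w], length(z))
    expect_equal(s3$p_value[s3$window_index == w],
                 t.test(z, mu = 0)$p.value)
  }
  expect_equal(sum(s3$n_undefined), 2)
})

test_that("zscan returns a classed object, skips failing genes, and methods run", {
  set.seed(41)
  genes <- data.frame(
    gene_id = c("good1", "good2", "bad"),
    species_id = "sp",
    seq = c(random_cds(55), random_cds(60), strrep("N", 180))
  )
  fit <- zscan(genes, shuffle = shuffle_config(15, seed = 2))
  expect_s3_class(fit, "zscan")
  expect_setequal(unique(fit$profiles$gene_id), c("good1", "good2"))
  expect_equal(fit$skipped$gene_id, "bad")
  expect_output(print(fit), "window-1 mean stability Z")
  expect_s3_class(summary(fit), "data.frame")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
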