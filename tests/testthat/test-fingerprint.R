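test_that("fingerprint assembly is complete, ordered and order-invariant", {
  sim <- small_sim(seed = 51)
  sc <- score_genes(sim$dataset)
  fp <- build_fingerprint(sim$dataset, sc)
  expect_equal(dim(fp), c(40, 7))
  expect_false(anyNA(fp))
  expect_equal(rownames(fp), sort(unique(sc$gene)))
  expect_equal(colnames(fp), sort(unique(sc$sample_id)))
  expect_named(attr(fp, "cell_class"), colnames(fp))

  # permuting input rows leaves the matrix unchanged
  d2 <- sim$dataset
  set.seed(1)
  d2$measurements <- d2$measurements[sample(nrow(d2$measurements)), ]
  fp2 <- build_fingerprint(d2, score_genes(d2))
  expect_equal(fp2, fp, tolerance = 1e-12)

  expect_error(build_fingerprint(sim$dataset, sc[-1, ]), "missing")
})

test_that("sample correlation matrices are symmetric with unit diagonal", {
  set.seed(52)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  r <- sample_correlations(m)
  expect_equal(r, t(r))
  expect_equal(diag(r), setNames(rep(1, 4), letters[1:4]))
  # brute-force oracle
  for (i in 1:4) for (j in 1:4) {
    x <- m[, i] - mean(m[, i]); y <- m[, j] - mean(m[, j])
    expect_equal(r[i, j], sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
                 tolerance = 1e-12)
  }
  dup <- cbind(a = m[, 1], b = m[, 1], c = -m[, 1])
  rd <- sample_correlations(dup)
  expect_equal(rd["a", "b"], 1)
  expect_equal(rd["a", "c"], -1)
  const <- cbind(m, e = rep(2, 10))
  expect_error(sample_correlations(const), "e")
})

test_that("same-donor preparations are grouped before testing", {
  sim <- small_sim(seed = 53)
  sc <- score_genes(sim$dataset)
  fp <- build_fingerprint(sim$dataset, sc)
  gr <- group_samples(fp, sim$dataset$samples)
  expect_equal(unname(as.vector(gr$n_by_class[c("MSC", "fibroblast")])), c(2, 4))
  # MSC1A/MSC1B average into donor D1's profile
  expect_equal(gr$profiles[, "D1"], rowMeans(fp[, c("MSC1A", "MSC1B")]),
               tolerance = 1e-12)
  expect_equal(gr$profiles[, "D2"], fp[, "MSC2"], tolerance = 1e-12)

  # no shared donors -> grouping is the identity
  fib <- fp[, c("pHF1", "pHF2", "HFF", "HS68")]
  gr2 <- group_samples(fib, sim$dataset$samples)
  expect_equal(unname(gr2$profiles), unname(fib))
})

test_that("the two-sample t-test matches the pooled-variance hand formula", {
  tt <- ttest_two_sample(c(1.0, 1.2), c(0.0, 0.1, -0.1, 0.2))
  # pooled variance (0.02 + 0.05)/4 = 0.0175
  expect_equal(tt$t, 1.05 / sqrt(0.0175 * (1 / 2 + 1 / 4)), tolerance = 1e-12)
  expect_equal(tt$t, 9.165151, tolerance = 1e-6)
  expect_equal(tt$df, 4)

  same <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(ttest_two_sample(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(ttest_two_sample(1, c(1, 2)), "at least 2")
})

test_that("post-hoc power follows the noncentral t distribution", {
  expect_equal(posthoc_power(0), 0.05, tolerance = 1e-9)
  expect_equal(posthoc_power(0, alpha = 0.01), 0.01, tolerance = 1e-9)
  expect_gt(posthoc_power(100), 0.999)
  # strictly increasing in d and in each group size
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(posthoc_power(d)) > 0))
  expect_gt(posthoc_power(1.5, n1 = 3, n2 = 4), posthoc_power(1.5, n1 = 2, n2 = 4))
  expect_gt(posthoc_power(1.5, n1 = 2, n2 = 6), posthoc_power(1.5, n1 = 2, n2 = 4))
  p <- posthoc_power(d)
  expect_true(all(p >= 0.05 - 1e-12 & p <= 1))
  expect_error(posthoc_power(-1), "d must")
  expect_error(posthoc_power(1, n1 = 1), "invalid power")
})

test_that("differential panels are invariant to gene order and class labels", {
  set.seed(55)
  profiles <- matrix(rnorm(50 * 6, sd = 0.2), 50, 6,
                     dimnames = list(sprintf("g%02d", 1:50),
                                     c("D1", "D2", "D3", "D4", "D5", "D6")))
  profiles[1:5, 1:2] <- profiles[1:5, 1:2] - 1  # strong MSC-specific kill
  gr <- structure(list(profiles = profiles,
                       cell_class = c("MSC", "MSC", rep("fibroblast", 4)),
                       donor_id = colnames(profiles),
                       n_by_class = table(c("MSC", "MSC", rep("fibroblast", 4)))),
                  class = "grouped_profiles")
  pan <- differential_panel(gr)
  expect_true(all(c("g01", "g02", "g03", "g04", "g05") %in%
                    pan$gene[pan$selected]))
  expect_true(all(pan$cluster[match(c("g01", "g02"), pan$gene)] == "MSC"))
  expect_true(all(diff(pan$p) >= 0))
  expect_true(all(pan$power[pan$selected] >= 0.05))

  # permuting genes changes nothing but the (re-sorted) order
  gr2 <- gr
  perm <- sample(50)
  gr2$profiles <- gr2$profiles[perm, ]
  pan2 <- differential_panel(gr2)
  expect_equal(pan2[order(pan2$gene), ], pan[order(pan$gene), ],
               ignore_attr = TRUE)

  # swapping which columns are MSC flips t but keeps p and selection
  gr3 <- gr
  gr3$profiles <- gr3$profiles[, c(3:6, 1:2)]
  gr3$cell_class <- c(rep("fibroblast", 4), "MSC", "MSC")
  pan3 <- differential_panel(gr3)
  expect_equal(pan3$p[order(pan3$gene)], pan$p[order(pan$gene)],
               tolerance = 1e-12)

  # a gene with identical class values is degenerate, flagged, not selected
  gr4 <- gr
  gr4$profiles[7, ] <- 0.3
  expect_warning(pan4 <- differential_panel(gr4), "zero pooled variance")
  expect_false(pan4$selected[pan4$gene == "g07"])
  expect_true(pan4$degenerate[pan4$gene == "g07"])
})

test_that("null profiles are selected at about the significance level", {
  set.seed(56)
  profiles <- matrix(rnorm(5000 * 6, sd = 0.2), 5000, 6,
                     dimnames = list(sprintf("g%04d", 1:5000), paste0("D", 1:6)))
  cls <- c("MSC", "MSC", rep("fibroblast", 4))
  gr <- structure(list(profiles = profiles, cell_class = cls,
                       donor_id = paste0("D", 1:6), n_by_class = table(cls)),
                  class = "grouped_profiles")
  pan <- differential_panel(gr)
  expect_gt(mean(pan$selected), 0.03)
  expect_lt(mean(pan$selected), 0.07)
  # Benjamini-Hochberg correction only shrinks the selection
  panc <- differential_panel(gr, correct = TRUE)
  expect_lte(sum(panc$selected), sum(pan$selected))
})

test_that("clearly separated planted effects are recovered from simulations", {
  # planted |delta| >= 0.8 log2 keeps per-gene power comfortably above
  # 0.85 at N = 2 vs 4, so recovery is reliable over a few seeds
  rec <- c()
  for (s in 1:3) {
    sim <- simulate_screen(simulation_config(seed = 60 + s,
                                             delta_range = c(0.8, 1.0)))
    sc <- score_genes(sim$dataset)
    fp <- build_fingerprint(sim$dataset, sc)
    pan <- differential_panel(group_samples(fp, sim$dataset$samples))
    tr <- planted_panel(sim$truth)
    rec <- c(rec, mean(tr$gene %in% pan$gene[pan$selected]))
    # cluster side agrees with the planted side for recovered genes
    hit <- pan[pan$selected & pan$gene %in% tr$gene, ]
    side <- tr$cluster[match(hit$gene, tr$gene)]
    expect_gt(mean(hit$cluster == side), 0.9)
  }
  expect_gte(mean(rec), 0.8)
})
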