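test_that("relative viability scales wells by the control-well mean", {
  tp <- toy_plate(lib = c(500, 1500), neg = c(900, 1100), nt = c(950, 1050))
  out <- relative_viability(tp$plate, tp$layout)
  expect_equal(out$rel_viability[out$rlu == 500], 0.5)
  # denominator wells are transformed too
  expect_equal(mean(out$rel_viability[out$role != "library"]), 1)

  flat <- toy_plate(lib = c(1000, 1000), neg = c(1000, 1000),
                    nt = c(1000, 1000))
  expect_equal(relative_viability(flat$plate, flat$layout)$rel_viability,
               rep(1, 6))

  zero <- toy_plate(lib = c(10, 20), neg = c(0, 0), nt = c(0, 0))
  expect_error(relative_viability(zero$plate, zero$layout), "degenerate control")
  expect_error(relative_viability(tp$plate, tp$layout, character(0)),
               "non-empty")
  expect_error(relative_viability(tp$plate, tp$layout, "pos_control"),
               "no well")
})

test_that("multiplicative normalization centers the library log2 median at 0", {
  tp <- toy_plate(lib = c(100, 200, 400), neg = c(150, 250))
  out <- multiplicative_normalize(tp$plate, tp$layout)
  expect_equal(out$log2_ratio[out$role == "library"], c(-1, 0, 1))
  expect_equal(median(out$log2_ratio[out$role == "library"]), 0)

  # scale invariance: multiplying the whole plate by 7 changes nothing
  tp7 <- tp
  tp7$plate$rlu <- tp7$plate$rlu * 7
  out7 <- multiplicative_normalize(tp7$plate, tp7$layout)
  expect_equal(out7$log2_ratio, out$log2_ratio, tolerance = 1e-12)

  dead <- toy_plate(lib = c(0, 0), neg = c(100, 100))
  expect_error(multiplicative_normalize(dead$plate, dead$layout),
               "degenerate plate")
})

test_that("control log2 normalization is exact on simple ratios", {
  tp <- toy_plate(lib = c(1000, 2000, 250), neg = c(900, 1100))
  out <- control_log2_normalize(tp$plate, tp$layout)
  lib <- out$log2_ctrl[out$role == "library"]
  expect_equal(lib, c(0, 1, -2))

  zero <- toy_plate(lib = c(10, 20), neg = c(0, 0))
  expect_error(control_log2_normalize(zero$plate, zero$layout), "control")
})

test_that("variance adjustment brings every experiment to robust scale 1", {
  set.seed(42)
  mk <- function(scale, sample) {
    tp <- toy_plate(lib = 2^(rnorm(50, 0, scale)) * 1000, neg = c(1000, 1000))
    tp$plate$sample_id <- sample
    multiplicative_normalize(tp$plate, tp$layout)
  }
  plates <- rbind(mk(0.5, "a"), mk(2.0, "b"))
  adj <- adjust_variance_by_experiment(plates)
  for (s in c("a", "b")) {
    x <- adj$log2_ratio[adj$sample_id == s & adj$role == "library"]
    expect_equal(mad(x), 1, tolerance = 1e-9)
  }
  # idempotence: a second pass leaves values unchanged
  adj2 <- adjust_variance_by_experiment(adj)
  expect_equal(adj2$log2_ratio, adj$log2_ratio, tolerance = 1e-12)

  const <- mk(0.5, "c")
  const$log2_ratio <- 0
  expect_error(adjust_variance_by_experiment(const), "degenerate variance")
})

test_that("replicate summarization is the median", {
  expect_equal(summarize_replicates(c(0.8, 1.0)), 0.9)
  expect_equal(summarize_replicates(5.5), 5.5)
  expect_equal(summarize_replicates(c(1, 2, 100)), 2)
  expect_error(summarize_replicates(numeric(0)), "no replicate")
  expect_error(summarize_replicates(NA_real_), "no replicate")
})

test_that("plate z-scores standardize each plate to mean 0, sd 1", {
  expect_equal(plate_zscore(c(-1, 0, 1), rep("p", 3)), c(-1, 0, 1))
  expect_error(plate_zscore(c(2, 2, 2), rep("p", 3)), "degenerate plate")

  set.seed(7)
  x <- rnorm(320)
  z <- plate_zscore(x, rep("p", 320))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  # two plates standardized independently
  plate <- rep(c("p1", "p2"), each = 160)
  z2 <- plate_zscore(c(x[1:160] * 3 + 5, x[161:320]), plate)
  for (p in c("p1", "p2")) {
    expect_equal(mean(z2[plate == p]), 0, tolerance = 1e-9)
    expect_equal(sd(z2[plate == p]), 1, tolerance = 1e-9)
  }
})

test_that("zero-noise zero-effect screens normalize to exactly no phenotype", {
  sim <- simulate_screen(flat_config())
  prof <- replicate_profiles(sim$dataset)
  expect_true(all(abs(prof) < 1e-9))
  # relative viability 1 everywhere (positive control effect disabled here)
  norm <- relative_viability(
    sim$dataset$measurements[sim$dataset$measurements$sample_id == "MSC1A" &
                               sim$dataset$measurements$replicate_id == "R1", ],
    sim$dataset$layouts)
  expect_equal(norm$rel_viability, rep(1, nrow(norm)), tolerance = 1e-12)
})

test_that("the scoring pipeline is invariant to per-plate scale factors", {
  sim <- small_sim(seed = 21)
  sc1 <- score_genes(sim$dataset)
  d2 <- sim$dataset
  # multiply each plate instance of one screen by a different constant
  key <- interaction(d2$measurements$plate_id, d2$measurements$sample_id,
                     d2$measurements$replicate_id, drop = TRUE)
  mult <- (as.integer(key) %% 5) + 1
  d2$measurements$rlu <- d2$measurements$rlu * mult
  sc2 <- score_genes(d2)
  expect_equal(sc2$log2_score, sc1$log2_score, tolerance = 1e-9)
  expect_equal(sc2$zscore, sc1$zscore, tolerance = 1e-9)
  expect_equal(sc2$log2_ctrl, sc1$log2_ctrl, tolerance = 1e-9)
})

test_that("scored tables have one finite row per gene and sample", {
  sim <- small_sim(seed = 22)
  sc <- score_genes(sim$dataset)
  expect_equal(nrow(sc), 40 * 7)
  expect_false(any(duplicated(sc[, c("gene", "sample_id")])))
  expect_true(all(is.finite(sc$zscore)))
  expect_true(all(sc$rel_viability >= 0))
  expect_true(all(sc$n_replicates == 2))
  # per plate-by-sample group, z-scores are standardized
  grp <- interaction(sc$plate_id, sc$sample_id)
  for (g in levels(grp)) {
    expect_equal(mean(sc$zscore[grp == g]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$zscore[grp == g]), 1, tolerance = 1e-9)
  }
})
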