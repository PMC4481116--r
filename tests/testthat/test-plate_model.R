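test_that("well addresses follow the letter-row convention", {
  expect_equal(well_name("G", 4), "G04")
  expect_equal(well_name("P", 24), "P24")
  expect_equal(parse_well("G04"), data.frame(row = "G", column = 4L))
  expect_length(all_wells(), 384)
  expect_equal(all_wells()[1:3], c("A01", "A02", "A03"))
  expect_error(well_name("Q", 1), "row")
  expect_error(well_name("A", 25), "column")
  expect_error(parse_well("G4"), "malformed")
  expect_error(parse_well("G25"), "malformed")
})

test_that("kinome layout fills columns 5-24 row-major with fixed controls", {
  genes <- sprintf("KIN%03d", 1:778)
  lay <- default_kinome_layout(genes)
  expect_equal(length(unique(lay$plate_id)), 3)
  counts <- table(lay$plate_id[lay$role == "library"])
  expect_equal(sort(as.integer(counts), decreasing = TRUE), c(320, 320, 138))
  # library wells enumerate gene ids exactly once, in order
  expect_equal(lay$target[lay$role == "library"], genes)
  # every control position present with its role on every plate
  for (pid in unique(lay$plate_id)) {
    p <- lay[lay$plate_id == pid, ]
    expect_equal(nrow(p), 384)
    expect_setequal(p$well[p$role == "neg_control"], c("G04", "H04", "I04", "J04"))
    expect_setequal(p$well[p$role == "pos_control"], c("F03", "G03", "H03", "I03"))
    expect_setequal(p$well[p$role == "untreated"], c("K03", "L03", "M03", "N03"))
    expect_true(all(p$target[p$role == "neg_control"] == "Rluc"))
    expect_true(all(p$target[p$role == "pos_control"] == "UBC"))
    # library block confined to columns 5-24
    expect_true(all(parse_well(p$well[p$role == "library"])$column >= 5))
  }
  # row-major fill: first library wells are A05, A06, ...
  p1 <- lay[lay$plate_id == "plate1" & lay$role == "library", ]
  expect_equal(p1$well[match(genes[1:3], p1$target)], c("A05", "A06", "A07"))

  expect_equal(length(unique(default_kinome_layout(genes[1:320])$plate_id)), 1)
  lay2 <- default_kinome_layout(genes[1:321])
  expect_equal(length(unique(lay2$plate_id)), 2)
  p2lib <- lay2[lay2$plate_id == "plate2" & lay2$role == "library", ]
  expect_equal(p2lib$well, "A05")
  # deterministic
  expect_identical(lay, default_kinome_layout(genes))

  expect_error(default_kinome_layout(character(0)), "at least one")
  expect_error(default_kinome_layout(c("a", "a")), "distinct")
})

test_that("screen datasets round-trip through TSV files", {
  sim <- small_sim(seed = 11)
  dir <- withr::local_tempdir()
  write_screen(sim$dataset, dir)
  back <- read_screen(file.path(dir, "measurements.tsv"),
                      file.path(dir, "layout.tsv"),
                      file.path(dir, "samples.tsv"))
  expect_equal(back$samples, sim$dataset$samples)
  expect_equal(back$layouts, sim$dataset$layouts)
  expect_equal(back$measurements$well, sim$dataset$measurements$well)
  expect_equal(back$measurements$rlu, sim$dataset$measurements$rlu,
               tolerance = 1e-12)
})

test_that("dataset validation names the offending record", {
  sim <- small_sim(seed = 12)
  d <- sim$dataset

  bad <- d$measurements
  bad$rlu[bad$well == "A05"][1] <- -5
  expect_error(screen_dataset(d$samples, d$layouts, bad), "A05")

  short_layout <- d$layouts[d$layouts$well != "P24", ]
  expect_error(screen_dataset(d$samples, short_layout, d$measurements),
               "incomplete layout")

  bad2 <- d$measurements
  bad2$sample_id[1] <- "nobody"
  expect_error(screen_dataset(d$samples, d$layouts, bad2), "nobody")

  # dropping one plate of one screen breaks library coverage
  two <- small_sim(seed = 13, n_genes = 330)$dataset
  drop <- two$measurements
  drop <- drop[!(drop$sample_id == "MSC1A" & drop$replicate_id == "R1" &
                   drop$plate_id == "plate1"), ]
  expect_error(screen_dataset(two$samples, two$layouts, drop), "cover")
})

test_that("score tables are written deterministically and round-trip", {
  scores <- data.frame(
    gene = c("g2", "g1", "g2", "g1"),
    sample_id = c("s1", "s2", "s2", "s1"),
    plate_id = "p1",
    rel_viability = c(0.5, 1.123456789012345, 2, 3),
    log2_ctrl = c(-1, 0.1, 1, 1.5),
    log2_score = c(-1, 0.1, 1, 1.5),
    zscore = c(-2, 0.3, 1, 2),
    n_replicates = 2L, stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  write_scores(scores, path)
  lines <- readLines(path)
  expect_length(lines, 5)  # header + one row per (gene, sample)
  back <- read_scores(path)
  expect_equal(back$gene, c("g1", "g1", "g2", "g2"))
  expect_equal(back$sample_id, c("s1", "s2", "s1", "s2"))
  expect_equal(back$rel_viability[2], 1.123456789012345, tolerance = 1e-12)

  expect_error(write_scores(scores[0, ], path), "empty")
})
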