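test_that("quantification reports internal-standard-relative main-ion areas", {
  is_tg <- d8_naphthalene_target(rt = 0.2)
  spA <- random_spectrum(11, 12); spB <- random_spectrum(12, 15)
  cmps <- list(planted_compound("A", spA, 0.6, 0.02, 4e5),
               planted_compound("B", spB, 0.62, 0.02, 2e5))
  cfg <- sim_config(duration = 1, seed = 3, baseline = 5, noise_sd = 20)
  sim <- simulate_run(cmps, cfg, internal_standard = is_tg,
                      is_abundance = 3e5)
  ab <- quantify(sim$run, truth_library(cmps), internal_standard = is_tg)
  expect_true(all(ab > 0))
  # reported ratio tracks the planted main-ion area ratio within 5%
  fracA <- max(spA$intensity) / sum(spA$intensity)
  fracB <- max(spB$intensity) / sum(spB$intensity)
  expected <- (4e5 * fracA) / (2e5 * fracB)
  expect_equal(unname(ab["A"] / ab["B"]), expected, tolerance = 0.05)
})

test_that("an absent analyte quantifies to zero; a missing IS is an error", {
  is_tg <- d8_naphthalene_target(rt = 0.2)
  present <- planted_compound("A", random_spectrum(31, 12), 0.6, 0.02, 4e5)
  ghost <- target_compound("ghost", random_spectrum(32, 12), rt = 0.4)
  cfg <- sim_config(duration = 1, seed = 6, baseline = 5, noise_sd = 20)
  sim <- simulate_run(list(present), cfg, internal_standard = is_tg)
  lib <- target_library(list(
    target_compound("A", present$spectrum, rt = 0.6), ghost))
  ab <- quantify(sim$run, lib, internal_standard = is_tg)
  expect_equal(unname(ab["ghost"]), 0)
  expect_gt(unname(ab["A"]), 0)

  no_is <- simulate_run(list(present), cfg)   # IS not spiked
  expect_error(quantify(no_is$run, lib, internal_standard = is_tg),
               "internal standard")
})

test_that("detection thresholds reproduce the printed zero pattern", {
  tab <- tables_fixture()
  pres0 <- detect(tab, 0)
  expect_identical(pres0, tab$values > 0)
  # at the instrument's >5000-unit rule one printed survivor drops out
  pres5000 <- detect(tab, 5000)
  expect_true(pres0["2-phenylbut-2-enal", "Green AAA"])
  expect_false(pres5000["2-phenylbut-2-enal", "Green AAA"])
  # an all-zero row would be absent everywhere
  expect_true(all(rowSums(pres0[rowSums(tab$values) == 0, , drop = FALSE]) == 0))
})

test_that("Venn partitioning assigns each detected compound to one region", {
  tab <- tables_fixture()
  vp <- venn_partition(detect(tab))
  expect_equal(sum(lengths(vp$regions)), 227)
  expect_length(venn_region(vp, "Green AAA"), 24)
  expect_length(venn_region(vp, "Green AA"), 1)
  expect_length(venn_region(vp, "Roast AAA"), 74)
  expect_length(venn_region(vp, "Roast AA"), 56)
  expect_length(venn_region(vp, colnames(tab$values)), 72)

  # a compound absent everywhere is excluded from the partition
  m <- matrix(c(1, 0, 1, 0), nrow = 2,
              dimnames = list(c("here", "nowhere"), c("s1", "s2")))
  vp2 <- venn_partition(m > 0)
  expect_equal(sum(lengths(vp2$regions)), 1)
  expect_equal(venn_region(vp2, c("s1", "s2")), "here")
})

test_that("fold changes reproduce the printed green-to-green ratios", {
  tab <- tables_fixture()
  folds <- list(
    list("hexadecanoic acid", "Green AAA", "Green AA", 179L),
    list("nonanal", "Green AAA", "Green AA", 43L),
    list("pyridine", "Green AAA", "Green AA", 38L),
    list("2-methyl-1-(1,1-dimethylethyl)-2-methyl-1,3-propanediyl ester",
         "Green AAA", "Green AA", 27L),
    list("2-ethenyl-6-methylpyrazine", "Green AAA", "Green AA", 23L),
    list("benzophenone", "Green AAA", "Green AA", 19L),
    list("2-ethenyl-5-methylpyrazine", "Green AAA", "Green AA", 14L),
    list("5-methylfuran-2-carbaldehyde", "Green AAA", "Green AA", 12L),
    list("2-ethylpyrazine", "Green AA", "Green AAA", 13L),
    list("2-phenylbut-2-enal", "Green AA", "Green AAA", 12L))
  for (f in folds) {
    row <- fold_change(tab, f[[1]], f[[2]], f[[3]])
    expect_equal(row$rounded_fold, f[[4]], info = f[[1]])
  }
})

test_that("fold changes invert exactly and handle zero denominators", {
  tab <- tables_fixture()
  a <- fold_change(tab, "pyridine", "Green AAA", "Green AA")
  b <- fold_change(tab, "pyridine", "Green AA", "Green AAA")
  expect_equal(a$ratio * b$ratio, 1)
  z <- fold_change(tab, "nerol oxide", "Green AAA", "Green AA")
  expect_true(z$infinite)
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound,S1,S2", "both0,0,0", "x,1,1"), f)
  t2 <- read_abundance_table(f)
  expect_warning(expect_null(fold_change(t2, "both0", "S1", "S2")), "omitted")
  eq <- fold_change(t2, "x", "S1", "S2")
  expect_equal(eq$ratio, 1)
  expect_equal(eq$rounded_fold, 1L)
})

test_that("the roast-enrichment count over survivors matches the table", {
  tab <- tables_fixture()
  surv <- rownames(tab$values)[tab$annotations$group == "survivors"]
  expect_equal(count_fold_threshold(tab, "Roast AAA", "Green AAA", 2, surv), 48)
  expect_equal(count_fold_threshold(tab, "Roast AAA", "Green AAA", 2,
                                    character(0)), 0L)
})

test_that("fold-threshold counts are monotone non-increasing in k", {
  tab <- tables_fixture()
  surv <- rownames(tab$values)[tab$annotations$group == "survivors"]
  ks <- c(1, 1.5, 2, 3, 5, 10, 50)
  counts <- vapply(ks, function(k)
    count_fold_threshold(tab, "Roast AAA", "Green AAA", k, surv), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the four-sample comparison report reproduces the set counts", {
  tab <- tables_fixture()
  roles <- list(green_high = "Green AAA", green_low = "Green AA",
                roast_high = "Roast AAA", roast_low = "Roast AA")
  rep <- comparison_report(tab, roles)
  expect_equal(nrow(rep$survivors), 72)
  expect_equal(nrow(rep$unique[["Roast AA"]]), 56)
  expect_equal(unname(rep$counts["n_detected"]), 227)
  expect_equal(unname(rep$counts["n_survivor_fold2_roast_high_vs_green_high"]), 48)
  expect_error(comparison_report(tab, roles[1:3]), "roles")

  # file outputs land where asked
  out <- file.path(tempdir(), "cmp_report")
  comparison_report(tab, roles, out_dir = out)
  expect_true(file.exists(file.path(out, "venn.json")))
  expect_true(file.exists(file.path(out, "survivors.csv")))
})
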