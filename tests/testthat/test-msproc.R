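# Chromatogram peak detection, spectrum extraction and m/z matching.

test_that("mass spectra enforce ordering, positivity and uniqueness", {
  s <- mass_spectrum(c(300, 100, 200), c(1, 2, 3))
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(2, 3, 1))
  expect_error(mass_spectrum(c(-1, 2), c(1, 1)), "positive")
  expect_error(mass_spectrum(c(100, 100 + 1e-9), c(1, 1)), "duplicate")
  expect_error(mass_spectrum(c(100), c(-1)), "non-negative")
})

test_that("three separated Gaussian peaks integrate to the injected ratios", {
  species <- list(
    list(rt = 0.5, width = 0.04, response = 1.0,
         sticks = data.frame(mz = 201, rel = 1)),
    list(rt = 1.2, width = 0.04, response = 0.6,
         sticks = data.frame(mz = 301, rel = 1)),
    list(rt = 1.9, width = 0.04, response = 0.2,
         sticks = data.frame(mz = 401, rel = 1)))
  run <- make_gradient_run(species)
  pk <- detect_chrom_peaks(run)
  expect_equal(nrow(pk), 3L)
  expect_equal(pk$apex, c(0.5, 1.2, 1.9), tolerance = 0.02)
  # equal widths: areas proportional to responses
  expect_equal(pk$relative_area, c(1, 0.6, 0.2) / 1.8, tolerance = 0.02)
  expect_true(all(pk$start < pk$apex & pk$apex < pk$end))
  expect_equal(sum(pk$relative_area), 1, tolerance = 1e-9)
})

test_that("an all-zero trace yields no peaks", {
  run <- lcms_run("gradient", c(0, 1, 2),
                  replicate(3, mass_spectrum(numeric(0), numeric(0)),
                            simplify = FALSE))
  expect_equal(nrow(detect_chrom_peaks(run)), 0L)
})

test_that("peaks closer than min_separation merge into one", {
  species <- list(
    list(rt = 1.00, width = 0.03, response = 1,
         sticks = data.frame(mz = 201, rel = 1)),
    list(rt = 1.03, width = 0.03, response = 0.9,
         sticks = data.frame(mz = 301, rel = 1)))
  run <- make_gradient_run(species)
  expect_equal(nrow(detect_chrom_peaks(run, min_separation = 0.1)), 1L)
})

test_that("peak areas never exceed the total trace area", {
  set.seed(11)
  for (i in 1:5) {
    n_sp <- sample(1:4, 1)
    species <- lapply(seq_len(n_sp), function(k) {
      list(rt = runif(1, 0.3, 2.2), width = runif(1, 0.02, 0.08),
           response = runif(1, 0.3, 1),
           sticks = data.frame(mz = 100 + 100 * k, rel = 1))
    })
    run <- make_gradient_run(species)
    pk <- detect_chrom_peaks(run)
    total <- sum(diff(run$times) *
                   (run$tic[-1] + run$tic[-length(run$tic)]) / 2)
    expect_lte(sum(pk$area), total + 1e-9)
  }
})

test_that("direct-injection runs refuse chromatographic peak detection", {
  run <- lcms_run("direct_injection", c(0.1, 0.2),
                  replicate(2, mass_spectrum(500, 1), simplify = FALSE))
  expect_error(detect_chrom_peaks(run), "direct injection")
})

test_that("peak-spectrum extraction averages scans", {
  s1 <- mass_spectrum(c(100, 200), c(2, 4))
  run1 <- lcms_run("gradient", 1, list(s1))
  pk <- data.frame(apex = 1, start = 1, end = 1)
  expect_equal(extract_peak_spectrum(run1, pk)$intensity, c(2, 4))

  run2 <- lcms_run("gradient", c(1, 2), list(s1, s1))
  pk2 <- data.frame(apex = 1.5, start = 1, end = 2)
  expect_equal(extract_peak_spectrum(run2, pk2)$intensity, c(2, 4))

  # disjoint peaks: union at half intensity
  s2 <- mass_spectrum(c(300, 400), c(6, 8))
  run3 <- lcms_run("gradient", c(1, 2), list(s1, s2))
  got <- extract_peak_spectrum(run3, pk2)
  expect_equal(got$mz, c(100, 200, 300, 400))
  expect_equal(got$intensity, c(1, 2, 3, 4))

  expect_error(extract_peak_spectrum(run3, data.frame(apex = 5, start = 4.5,
                                                      end = 5.5)),
               "no scans")
})

test_that("main peaks are those above the relative-area floor", {
  pk <- structure(data.frame(apex = 1:4, start = 0:3, end = 2:5,
                             area = c(7, 2, 1, 0),
                             relative_area = c(0.7, 0.2, 0.1, 0)),
                  class = c("chrom_peaks", "data.frame"))
  expect_equal(nrow(main_peaks(pk, 0.10)), 3L)
  expect_equal(nrow(main_peaks(pk, 0)), 4L)
  two <- structure(data.frame(apex = 1:2, start = 0:1, end = 2:3,
                              area = c(1, 1),
                              relative_area = c(0.5, 0.5)),
                   class = c("chrom_peaks", "data.frame"))
  expect_equal(nrow(main_peaks(two, 1.0)), 0L)
})

test_that("targeted matching finds the product ion in a main peak", {
  prod_mz <- 175.0866
  species <- list(
    list(rt = 0.8, width = 0.05, response = 1,
         sticks = data.frame(mz = c(prod_mz, 197.0685), rel = c(1, 0.3))),
    list(rt = 1.6, width = 0.05, response = 0.5,
         sticks = data.frame(mz = 251.2, rel = 1)))
  run <- make_gradient_run(species)
  expected <- data.frame(label = c("[M+H]+", "[M+Na]+"),
                         mz = c(175.0866, 197.0685))
  res <- match_targeted(run, expected, tol = 0.5)
  expect_true(res$passed)
  expect_true(all(c("[M+H]+", "[M+Na]+") %in% res$matches$label))

  # same ion present only in a sub-threshold chromatographic peak
  species2 <- list(
    list(rt = 0.8, width = 0.05, response = 1,
         sticks = data.frame(mz = 351.1, rel = 1)),
    list(rt = 1.6, width = 0.05, response = 0.02,
         sticks = data.frame(mz = prod_mz, rel = 1)))
  run2 <- make_gradient_run(species2)
  res2 <- match_targeted(run2, expected, tol = 0.5)
  expect_false(res2$passed)

  expect_error(match_targeted(run, data.frame()), "empty")
})

test_that("matching an empty run fails with zero matches", {
  run <- lcms_run("gradient", c(0, 1, 2),
                  replicate(3, mass_spectrum(numeric(0), numeric(0)),
                            simplify = FALSE))
  res <- match_targeted(run, data.frame(label = "x", mz = 100))
  expect_false(res$passed)
  expect_equal(nrow(res$matches), 0L)
})

make_small_table <- function() {
  py <- building_block("24", "carbonyl_pyridine", "C6H5NO")
  trit <- building_block("28", "polytopic_amine", "C6H18N4", topicity = 3)
  zn <- building_block("Zn", "metal_ion", "Zn+2", capacity = 3)
  otf <- building_block("OTf", "counterion", "CF3O3S-1")
  build_lookup_table(list(py), list(trit), list(zn), otf, max_metals = 5L)
}

test_that("assembly matching needs two charge states of one entry", {
  tab <- make_small_table()
  entry <- tab$entries$entry_id[tab$entries$m == 4]
  lad <- tab$ladders[tab$ladders$entry_id == entry, ]
  two <- mass_spectrum(sort(lad$mz[lad$z %in% c(8, 4)]), c(1, 1))
  res <- match_assembly_table(two, tab, tol = 0.5)
  expect_true(res$passed)
  expect_gte(res$charge_state_counts[[as.character(entry)]], 2L)

  one <- mass_spectrum(lad$mz[lad$z == 8], 1)
  res1 <- match_assembly_table(one, tab, tol = 0.5)
  expect_false(res1$passed)

  resE <- match_assembly_table(mass_spectrum(numeric(0), numeric(0)), tab)
  expect_false(resE$passed)
  expect_equal(nrow(resE$matches), 0L)

  expect_error(
    match_assembly_table(two, structure(list(
      entries = data.frame(), ladders = data.frame(), tol = 0.5),
      class = "mz_table")), "empty")
})

test_that("matching is tolerance-monotone and agrees with brute force", {
  tab <- make_small_table()
  set.seed(5)
  obs <- sort(c(sample(tab$ladders$mz, 6) + runif(6, -0.4, 0.4),
                runif(40, 100, 3000)))
  obs <- obs[c(TRUE, diff(obs) > 1e-3)]
  spec <- mass_spectrum(obs, runif(length(obs), 0.5, 1))
  prev <- character(0)
  for (tol in c(0.05, 0.2, 0.5, 1.0)) {
    res <- match_assembly_table(spec, tab, tol = tol,
                                min_charge_states = 2L)
    keys <- paste(res$matches$entry_id, res$matches$z)
    expect_true(all(prev %in% keys), label = paste("tol", tol))
    prev <- keys
    oracle <- table_match_oracle(spec$mz, tab$ladders, tol)
    got <- res$charge_state_counts
    expect_identical(unname(got[names(got)]),
                     unname(oracle$counts[names(got)]))
    expect_identical(res$passed, oracle$passed)
    # entries with zero matches are absent from the result counts
    expect_true(all(oracle$counts[setdiff(names(oracle$counts),
                                          names(got))] == 0))
  }
})

test_that("LC-MS CSV round trip preserves the run to 1e-9", {
  species <- list(list(rt = 1, width = 0.05, response = 1,
                       sticks = data.frame(mz = c(175.0866, 197.0685),
                                           rel = c(1, 0.3))))
  run <- make_gradient_run(species, run_length = 2, scan_interval = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lcms(run, path)
  back <- read_lcms(path)
  expect_equal(back$mode, run$mode)
  expect_equal(back$times, run$times, tolerance = 1e-9)
  for (i in seq_along(run$scans)) {
    expect_equal(back$scans[[i]]$mz, run$scans[[i]]$mz, tolerance = 1e-9)
    expect_equal(back$scans[[i]]$intensity, run$scans[[i]]$intensity,
                 tolerance = 1e-9)
  }
})
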