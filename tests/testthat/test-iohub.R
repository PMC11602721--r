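# File dialects, campaign configuration and the CLI.

test_that("NMR CSV round trip is identical to 1e-9", {
  s <- gen_nmr(data.frame(position = c(2, 7.5), height = c(1, 0.4)),
               seed = 1, grid = seq(0, 12, 0.01))
  s$masks <- list(c(3.2, 3.4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_nmr(s, path)
  back <- read_nmr(path)
  expect_equal(back$ppm, s$ppm, tolerance = 1e-9)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-9)
  expect_equal(back$field, s$field)
  expect_equal(back$masks, s$masks)
})

test_that("descending-ppm files are normalized to ascending", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# field_mhz: 80", "ppm,intensity", "3,30", "2,20", "1,10"),
             path)
  s <- read_nmr(path)
  expect_equal(s$ppm, c(1, 2, 3))
  expect_equal(s$intensity, c(10, 20, 30))
})

test_that("empty and malformed NMR files are parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_nmr(path), "empty")
  writeLines(c("ppm,intensity", "a,b"), path)
  expect_error(read_nmr(path), "malformed")
  expect_error(read_nmr(file.path(tempdir(), "absent.csv")), "no such")
})

test_that("JCAMP-DX XYDATA round trip preserves the spectrum", {
  s <- gen_nmr(data.frame(position = c(2, 7.5), height = c(1, 0.4)),
               seed = 2, grid = seq(0, 12, 0.01))
  path <- withr::local_tempfile(fileext = ".jdx")
  write_nmr(s, path, dialect = "jcamp")
  back <- read_nmr(path) # dialect inferred from extension
  expect_equal(back$ppm, s$ppm, tolerance = 1e-6)
  # ordinates are stored as scaled integers: absolute error within YFACTOR
  expect_lt(max(abs(back$intensity - s$intensity)),
            1e-5 * max(abs(s$intensity)))
  expect_equal(back$field, 80)
})

test_that("JCAMP NTUPLES real-part data tables are readable", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE= synthetic ntuples fixture",
    "##JCAMP-DX= 6.00",
    "##ORIGIN= synthetic fixture",
    "##DATA CLASS= NTUPLES",
    "##.OBSERVE FREQUENCY= 80",
    "##FIRSTX= 0",
    "##LASTX= 4",
    "##NPOINTS= 5",
    "##YFACTOR= 0.5",
    "##DATA TABLE= (X++(R..R)), XYDATA",
    "0 2 4 6",
    "3 8 10",
    "##END="), path)
  expect_warning(s <- read_nmr(path), "skipping")
  expect_equal(s$ppm, 0:4)
  expect_equal(s$intensity, c(1, 2, 3, 4, 5))
})

test_that("LC-MS CSV reader enforces scan ordering and handles empties", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# mode: gradient", "scan_time,mz,intensity",
               "0.2,100,5", "0.1,100,5"), path)
  expect_error(read_lcms(path), "out of time order")
  writeLines(c("# mode: direct_injection", "scan_time,mz,intensity",
               "0.1,500.25,7"), path)
  run <- read_lcms(path)
  expect_equal(run$mode, "direct_injection")
  expect_equal(length(run$scans), 1L)
  expect_equal(run$scans[[1]]$mz, 500.25)
})

write_test_config <- function(path, type = "supramolecular") {
  yaml::write_yaml(list(
    campaign = list(type = type, replicate_count = 6,
                    guests = list("g1", "g2")),
    blocks = list(
      list(id = "24", role = "carbonyl_pyridine", formula = "C6H5NO"),
      list(id = "28", role = "polytopic_amine", formula = "C6H18N4",
           topicity = 3),
      list(id = "29", role = "polytopic_amine", formula = "C13H14N2",
           topicity = 2),
      list(id = "Zn", role = "metal_ion", formula = "Zn+2", capacity = 3),
      list(id = "OTf", role = "counterion", formula = "CF3O3S-1"),
      list(id = "g1", role = "guest", formula = "C6H6"),
      list(id = "g2", role = "guest", formula = "C7H8")),
    assembly = list(counterion = "OTf", max_metals = list(Zn = 10)),
    thresholds = list(tol = 0.5)), path)
  path
}

test_that("campaign configs validate and hash their semantic content", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_test_config(path)
  cfg <- read_campaign_config(path)
  expect_s3_class(cfg$blocks[["Zn"]], "building_block")
  expect_equal(cfg$campaign$replicate_count, 6L)
  h1 <- cfg$hash

  # cosmetic rewrite: same semantics, same hash
  cfg2 <- read_campaign_config(write_test_config(
    withr::local_tempfile(fileext = ".yaml")))
  expect_identical(cfg2$hash, h1)

  # semantic change: different hash
  path3 <- withr::local_tempfile(fileext = ".yaml")
  write_test_config(path3)
  txt <- readLines(path3)
  writeLines(gsub("tol: 0.5", "tol: 0.25", txt), path3)
  expect_false(identical(read_campaign_config(path3)$hash, h1))
})

test_that("config validation lists the offending keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    campaign = list(type = "supramolecular"),
    blocks = list(list(id = "Zn", role = "metal_ion", formula = "Zn+2",
                       capacity = 3)),
    assembly = list()), path)
  expect_error(read_campaign_config(path), "counterion")
  yaml::write_yaml(list(
    campaign = list(type = "nope"),
    blocks = list(list(id = "x", role = "guest", formula = "C6H6")),
    assembly = list()), path)
  expect_error(read_campaign_config(path), "campaign.type")
})

test_that("the mztable command writes one CSV row per ladder rung", {
  cfgp <- write_test_config(withr::local_tempfile(fileext = ".yaml"))
  outp <- withr::local_tempfile(fileext = ".csv")
  status <- run_cli(c("mztable", "--config", cfgp, "--out", outp))
  expect_identical(status, 0L)
  tab <- utils::read.csv(outp)
  expect_identical(names(tab),
                   c("entry_id", "combination", "m", "l", "Q", "z", "n",
                     "mz"))
  # 1 pyridine x (tritopic: 10 entries, ditopic: 5 entries) x Zn
  expect_equal(length(unique(tab$entry_id)), 15L)
  expect_equal(nrow(tab), sum(tapply(tab$Q, tab$entry_id, max)))
})

test_that("the CLI rejects unknown commands and missing flags", {
  expect_identical(suppressMessages(run_cli(c("frobnicate"))), 1L)
  expect_identical(suppressMessages(run_cli(character(0))), 1L)
  expect_identical(suppressMessages(run_cli(c("mztable"))), 1L)
})

test_that("decide and plan round-trip verdicts through JSON", {
  nmrj <- withr::local_tempfile(fileext = ".json")
  msj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(passed = TRUE), nmrj, auto_unbox = TRUE)
  jsonlite::write_json(list(passed = TRUE), msj, auto_unbox = TRUE)
  outd <- withr::local_tempfile(fileext = ".json")
  status <- run_cli(c("decide", "--stage", "screen", "--reaction", "r1",
                      "--nmr-json", nmrj, "--ms-json", msj,
                      "--out", outd))
  expect_identical(status, 0L)
  d <- jsonlite::read_json(outd, simplifyVector = TRUE)
  expect_true(d$overall)

  decs <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(reaction_id = "r1", stage = "screen", overall = TRUE),
    list(reaction_id = "r2", stage = "screen", overall = FALSE)),
    decs, auto_unbox = TRUE)
  outp <- withr::local_tempfile(fileext = ".json")
  status <- run_cli(c("plan", "--decisions", decs, "--type",
                      "supramolecular", "--out", outp))
  expect_identical(status, 0L)
  instr <- jsonlite::read_json(outp, simplifyVector = TRUE)
  expect_equal(nrow(instr), 6L)
  expect_true(all(instr$reaction_id == "r1"))
})

test_that("run-campaign reproduces the planted truth from a seed", {
  outdir <- withr::local_tempdir()
  status <- suppressMessages(
    run_cli(c("run-campaign", "--scenario", "divergent", "--seed", "3",
              "--out", outdir)))
  expect_identical(status, 0L)
  summary <- jsonlite::read_json(file.path(outdir, "summary.json"),
                                 simplifyVector = TRUE)
  expect_identical(sort(summary$screen_hits), sort(summary$truth_hits))
  log <- readLines(file.path(outdir, "decisions.jsonl"))
  expect_gte(length(log), 6L)
  rec <- jsonlite::fromJSON(log[1])
  expect_true(all(c("reaction_id", "stage", "overall", "evidence_digest")
                  %in% names(rec)))
})

test_that("centroided MS1 mzML files are readable through mzR", {
  hdr <- data.frame(
    seqNum = 1:2, acquisitionNum = 1:2, msLevel = 1L, polarity = 1L,
    peaksCount = 2L, totIonCurrent = c(3, 7), retentionTime = c(6, 12),
    basePeakMZ = c(200, 250), basePeakIntensity = c(2, 4),
    collisionEnergy = 0, ionisationEnergy = 0, lowMZ = c(100, 150),
    highMZ = c(200, 250), precursorScanNum = 0L, precursorMZ = 0,
    precursorCharge = 0L, precursorIntensity = 0, mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0, filterString = "",
    spectrumId = c("scan=1", "scan=2"), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  pk <- list(matrix(c(100, 200, 1, 2), ncol = 2),
             matrix(c(150, 250, 3, 4), ncol = 2))
  path <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(pk, path, header = hdr)
  run <- read_lcms(path) # dialect inferred from extension
  expect_equal(run$times, c(0.1, 0.2)) # seconds -> minutes
  expect_equal(run$scans[[1]]$mz, c(100, 200))
  expect_equal(run$scans[[2]]$intensity, c(3, 4))
  expect_equal(run$tic, c(3, 7))
})
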