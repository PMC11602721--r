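# Seeded generators of synthetic benchtop NMR spectra, LC-MS runs and whole
# ground-truth campaigns. The generators emulate the measurement layer of an
# autonomous screening platform just closely enough that every decision
# heuristic in the package can be exercised end to end: Lorentzian 1H
# lineshapes on an 80 MHz-like grid, Gaussian chromatographic envelopes over
# a 2.5 min gradient window, stick mass spectra, additive Gaussian noise.
# One bundle seed reproduces an entire campaign; each generated object uses
# a substream seed derived from it.

.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + as.double(k) * 9176 + 17) %% 2147483399L) + 1L
}

# Rejection-sample n positions in [range], pairwise >= min_sep apart and
# >= avoid_dist away from every position in avoid.
.rand_positions <- function(n, range = c(0.5, 9.5), min_sep = 0.15,
                            avoid = numeric(0), avoid_dist = 0) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 20000L) stop("cannot place ", n, " peaks under constraints")
    p <- stats::runif(1, range[1], range[2])
    if (length(out) && min(abs(p - out)) < min_sep) next
    if (length(avoid) && min(abs(p - avoid)) < avoid_dist) next
    out <- c(out, p)
  }
  sort(out)
}

#' Generate a synthetic 1H NMR spectrum
#'
#' Sum of Lorentzian lines on the standard comparison grid plus additive
#' Gaussian noise scaled to the noiseless maximum. Deterministic per seed.
#'
#' @param peaks data.frame with columns `position` (ppm), `height`
#'   (relative) and optionally `fwhm_hz` (default 2 Hz per line).
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   (default 0.01).
#' @param field Spectrometer frequency in MHz (default 80).
#' @param grid ppm axis (default [default_nmr_grid()]).
#' @return An `nmr_spectrum` (raw; preprocess before comparison).
#' @export
gen_nmr <- function(peaks, seed = 1L, noise_sd = 0.01, field = 80,
                    grid = default_nmr_grid()) {
  set.seed(seed)
  y <- numeric(length(grid))
  if (nrow(peaks)) {
    fw <- if ("fwhm_hz" %in% names(peaks)) peaks$fwhm_hz else
      rep(2, nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      gam <- (fw[i] / field) / 2 # half width at half maximum, ppm
      y <- y + peaks$height[i] * gam^2 /
        ((grid - peaks$position[i])^2 + gam^2)
    }
  }
  top <- max(y, 1e-12)
  y <- y + stats::rnorm(length(grid), 0, noise_sd * top)
  nmr_spectrum(grid, y, field = field)
}

#' Generate a synthetic LC-MS run
#'
#' Gradient mode: each species elutes as a Gaussian chromatographic envelope
#' and each scan carries the species' m/z stick pattern scaled by that
#' envelope. Direct-injection mode: a flat envelope (column bypassed), so the
#' time-averaged spectrum equals the summed stick pattern. Multiplicative
#' Gaussian noise per stick; deterministic per seed.
#'
#' @param species List of species, each
#'   `list(rt = minutes, width = minutes, response = relative intensity,
#'   sticks = data.frame(mz, rel))`. For direct injection `rt`/`width` are
#'   ignored.
#' @param seed Integer seed.
#' @param mode `"gradient"` or `"direct_injection"`.
#' @param noise_sd Relative intensity noise (default 0.01).
#' @param run_length Run length in minutes (default 2.5).
#' @param scan_interval Scan spacing in minutes (default 0.02).
#' @return An `lcms_run`.
#' @export
gen_lcms <- function(species, seed = 1L, mode = c("gradient",
                                                  "direct_injection"),
                     noise_sd = 0.01, run_length = 2.5,
                     scan_interval = 0.02) {
  mode <- match.arg(mode)
  set.seed(seed)
  times <- seq(scan_interval, run_length, by = scan_interval)
  scans <- vector("list", length(times))
  for (ti in seq_along(times)) {
    mz <- numeric(0); inten <- numeric(0)
    for (sp in species) {
      env <- if (mode == "gradient") {
        exp(-(times[ti] - sp$rt)^2 / (2 * sp$width^2))
      } else {
        1
      }
      if (env < 1e-4) next
      h <- sp$response * env * sp$sticks$rel *
        pmax(0, 1 + stats::rnorm(nrow(sp$sticks), 0, noise_sd))
      mz <- c(mz, sp$sticks$mz); inten <- c(inten, h)
    }
    if (length(mz)) {
      o <- order(mz)
      mz <- mz[o]; inten <- inten[o]
      # merge coincident sticks from different species
      grp <- cumsum(c(TRUE, diff(mz) >= 1e-6))
      inten <- as.numeric(tapply(inten, grp, sum))
      mz <- as.numeric(tapply(mz, grp, mean))
    }
    scans[[ti]] <- mass_spectrum(mz, inten)
  }
  lcms_run(mode, times, scans)
}

#' Building blocks of the divergent-synthesis scenario
#'
#' Three terminal alkyne amines, a phenyl isothiocyanate and isocyanate, an
#' aryl bromide and an azide-bearing diversification partner. Formulas are
#' plausible stand-ins; ids follow the campaign's numbering.
#'
#' @return Named list of `building_block`s.
#' @export
divergent_blocks <- function() {
  bl <- list(
    building_block("1", "alkyne_amine", "C3H5N"),
    building_block("2", "alkyne_amine", "C4H7N"),
    building_block("3", "alkyne_amine", "C5H9N"),
    building_block("4", "isothiocyanate", "C7H5NS"),
    building_block("5", "isocyanate", "C7H5NO"),
    building_block("12", "aryl_halide", "C5H4BrN"),
    building_block("18", "azide", "C10H13N5O4")
  )
  stats::setNames(bl, vapply(bl, `[[`, character(1), "id"))
}

#' Building blocks of the supramolecular scenario
#'
#' Three carbonyl-bearing pyridines, two ditopic and one tritopic polyamine,
#' Zn2+ (octahedral, three bidentate pyridyl-imine chelates, up to 10 ions)
#' and Cu+ (tetrahedral, two chelates, up to 12 ions), a triflate counterion
#' and six small-molecule guests. Formulas are plausible stand-ins.
#'
#' @return Named list of `building_block`s.
#' @export
supramolecular_blocks <- function() {
  bl <- list(
    building_block("24", "carbonyl_pyridine", "C6H5NO"),
    building_block("25", "carbonyl_pyridine", "C7H7NO"),
    building_block("26", "carbonyl_pyridine", "C10H7NO"),
    building_block("27", "polytopic_amine", "C2H8N2", topicity = 2),
    building_block("28", "polytopic_amine", "C6H18N4", topicity = 3),
    building_block("29", "polytopic_amine", "C13H14N2", topicity = 2),
    building_block("Zn", "metal_ion", "Zn+2", capacity = 3),
    building_block("Cu", "metal_ion", "Cu+1", capacity = 2),
    building_block("OTf", "counterion", "CF3O3S-1"),
    building_block("g1", "guest", "C6H6"),
    building_block("g2", "guest", "C6H5Cl"),
    building_block("g3", "guest", "C7H8"),
    building_block("g4", "guest", "C6H12"),
    building_block("g5", "guest", "C10H8"),
    building_block("g6", "guest", "C4H8O")
  )
  stats::setNames(bl, vapply(bl, `[[`, character(1), "id"))
}

#' Divergent campaign scenario (ground truth)
#'
#' The truth labels of a parallel (thio)urea synthesis campaign: which of
#' the six screening condensations form product (default five of six),
#' and which diversification branches yield an ion matching the expected
#' product mass (default three of five Sonogashira, four of five CuAAC).
#'
#' @param failed_screen Reaction ids (amine+electrophile) that fail the
#'   screen.
#' @param failed_sonogashira,failed_cuaac Parent reaction ids whose
#'   diversification fails.
#' @param noise_sd Noise envelope for all generated spectra/runs.
#' @return A `scenario` list.
#' @export
divergent_scenario <- function(failed_screen = "3+4",
                               failed_sonogashira = c("1+4", "2+4"),
                               failed_cuaac = "1+5",
                               noise_sd = 0.01) {
  blocks <- divergent_blocks()
  rules <- standard_rules()
  reactions <- list()
  for (am in c("1", "2", "3")) {
    for (el in c("4", "5")) {
      rule <- if (el == "4") rules$thiourea else rules$urea
      prod <- apply_transform(rule, list(blocks[[am]], blocks[[el]]))
      rid <- prod$id
      reactions[[rid]] <- list(id = rid, sm_ids = c(am, el),
                               product = prod,
                               success = !(rid %in% failed_screen))
    }
  }
  list(type = "divergent", blocks = blocks, rules = rules,
       reactions = reactions,
       diversifications = c(sonogashira = "12", cuaac = "18"),
       failed_diversify = list(sonogashira = failed_sonogashira,
                               cuaac = failed_cuaac),
       noise_sd = noise_sd)
}

#' Supramolecular campaign scenario (ground truth)
#'
#' The truth labels of a 3 pyridines x 3 amines x 2 metals assembly screen
#' (18 combinations): which combinations self-assemble (default the
#' tetrahedral cage 24/28/Zn at m = 4, l = 4 and the helicate 24/29/Zn at
#' m = 2, l = 3), and which guests each resulting host binds (default the
#' cage binds guests g1-g3, the helicate none).
#'
#' @param hits Named list of planted assemblies: each element
#'   `list(pyridine, amine, metal, m, l)` keyed by reaction id
#'   `"py/amine/metal"`.
#' @param binding Named list: host reaction id -> character vector of bound
#'   guest ids.
#' @param noise_sd Noise envelope for all generated spectra/runs.
#' @return A `scenario` list.
#' @export
supramolecular_scenario <- function(
    hits = list(
      "24/28/Zn" = list(pyridine = "24", amine = "28", metal = "Zn",
                        m = 4, l = 4),
      "24/29/Zn" = list(pyridine = "24", amine = "29", metal = "Zn",
                        m = 2, l = 3)),
    binding = list("24/28/Zn" = c("g1", "g2", "g3"),
                   "24/29/Zn" = character(0)),
    noise_sd = 0.01) {
  blocks <- supramolecular_blocks()
  for (h in names(hits)) {
    sp <- hits[[h]]
    cap <- blocks[[sp$metal]]$capacity
    top <- blocks[[sp$amine]]$topicity
    if (sp$m * cap != sp$l * top) {
      stop("planted assembly ", h, " is not coordination balanced")
    }
  }
  if (!all(names(binding) %in% names(hits))) {
    stop("binding truth refers to non-hit host(s)")
  }
  list(type = "supramolecular", blocks = blocks, hits = hits,
       binding = binding,
       pyridine_ids = c("24", "25", "26"),
       amine_ids = c("27", "28", "29"),
       metal_ids = c("Zn", "Cu"),
       counterion_id = "OTf",
       max_metals = c(Zn = 10L, Cu = 12L),
       guest_ids = paste0("g", 1:6),
       noise_sd = noise_sd)
}

# Deterministic per-block starting-material peak sets for one bundle.
.sm_peak_table <- function(block_ids, seed, n_range = c(3L, 5L)) {
  out <- list()
  for (i in seq_along(block_ids)) {
    set.seed(.derive_seed(seed, 100L + i))
    n <- sample(seq(n_range[1], n_range[2]), 1L)
    pos <- .rand_positions(n, c(0.8, 9.2), min_sep = 0.2)
    out[[block_ids[i]]] <- data.frame(
      position = pos, height = stats::runif(n, 0.4, 1))
  }
  out
}

# Product peak set: about as many peaks as the starting materials combined,
# every peak placed well away from all SM peaks so that an actual chemical
# change registers as one (DTW cannot cheaply absorb the new pattern and the
# shift criterion of the symmetric-product test is met with margin). At
# least three peaks land in the aromatic window so guest assays have
# resonances to perturb. If the exclusion zones leave no room the avoid
# distance is relaxed geometrically, never below 0.1 ppm.
.product_peaks <- function(sm_positions, n, seed, aromatic_min = 3L,
                           avoid_dist = 0.65) {
  set.seed(seed)
  n_arom <- min(n, aromatic_min)
  place <- function(n, range, min_sep, avoid, ad) {
    repeat {
      got <- tryCatch(.rand_positions(n, range, min_sep, avoid, ad),
                      error = function(e) NULL)
      if (!is.null(got)) return(got)
      ad <- ad * 0.6
      if (ad < 0.1) stop("cannot place product peaks")
    }
  }
  arom <- place(n_arom, c(6.5, 9.2), 0.35, sm_positions, avoid_dist)
  rest <- if (n > n_arom) {
    place(n - n_arom, c(0.8, 5.5), 0.2, c(sm_positions, arom), avoid_dist)
  } else {
    numeric(0)
  }
  pos <- sort(c(arom, rest))
  data.frame(position = pos, height = stats::runif(length(pos), 0.7, 1))
}

# Junk m/z sticks at least `clearance` daltons away from every table value.
.junk_sticks <- function(n, table_mz, seed, mz_range = c(150, 2000),
                         clearance = 1.0) {
  set.seed(seed)
  mz <- numeric(0)
  tries <- 0L
  while (length(mz) < n) {
    tries <- tries + 1L
    if (tries > 50000L) stop("cannot place junk peaks clear of the table")
    cand <- stats::runif(1, mz_range[1], mz_range[2])
    if (length(table_mz) && min(abs(cand - table_mz)) < clearance) next
    if (length(mz) && min(abs(cand - mz)) < 0.5) next
    mz <- c(mz, cand)
  }
  data.frame(mz = sort(mz), rel = stats::runif(n, 0.05, 0.3))
}

#' Generate a full campaign dataset bundle
#'
#' Produces, per reaction of the scenario, an NMR spectrum and an LC-MS run
#' consistent with its planted truth: successful condensations show product
#' resonances shifted away from the starting materials and the product ion
#' among the main UPLC peaks; true assemblies show a symmetric product-like
#' peak count and at least three rungs of their counterion charge ladder in
#' the direct-injection spectrum; failures show the unreacted
#' starting-material sum and no table-matching ions. Scale-up, replicate,
#' diversification and guest-assay measurements are generated for the
#' planted hits. Deterministic per seed.
#'
#' @param scenario From [divergent_scenario()] or
#'   [supramolecular_scenario()].
#' @param seed Integer bundle seed.
#' @return A `campaign_bundle` list with elements `type`, `seed`, `blocks`,
#'   `sm_spectra`, `reactions` (each with `nmr`, `lcms`, truth fields) and,
#'   depending on type, `scaleups`/`diversify_runs` or
#'   `replicates`/`guest_assays`, plus `truth`.
#' @export
gen_campaign <- function(scenario, seed = 1L) {
  switch(scenario$type,
         divergent = .gen_divergent(scenario, seed),
         supramolecular = .gen_supramolecular(scenario, seed),
         stop("unknown scenario type ", sQuote(scenario$type)))
}

.gen_divergent <- function(sc, seed) {
  blocks <- sc$blocks
  sm_ids <- c("1", "2", "3", "4", "5")
  sm_tab <- .sm_peak_table(sm_ids, seed)
  noise <- sc$noise_sd
  sm_spectra <- list()
  for (i in seq_along(sm_ids)) {
    sm_spectra[[sm_ids[i]]] <- gen_nmr(sm_tab[[sm_ids[i]]],
                                       seed = .derive_seed(seed, 200L + i),
                                       noise_sd = noise)
  }
  reactions <- list()
  k <- 0L
  for (rid in names(sc$reactions)) {
    k <- k + 1L
    rx <- sc$reactions[[rid]]
    sm_pos <- unlist(lapply(sm_tab[rx$sm_ids], `[[`, "position"))
    n_sm <- sum(vapply(sm_tab[rx$sm_ids], nrow, integer(1)))
    if (rx$success) {
      pk <- .product_peaks(sm_pos, n_sm + 2L, .derive_seed(seed, 300L + k))
      sticks <- adduct_mz(rx$product)
      species <- list(list(rt = 0.4 + 0.25 * k, width = 0.05, response = 1,
                           sticks = data.frame(mz = sticks$mz,
                                               rel = c(1, 0.3, 0.2))))
    } else {
      pk <- do.call(rbind, sm_tab[rx$sm_ids]) # unreacted mixture
      species <- lapply(seq_along(rx$sm_ids), function(j) {
        b <- blocks[[rx$sm_ids[j]]]
        list(rt = 0.3 + 0.3 * j, width = 0.05, response = 0.8,
             sticks = data.frame(mz = .block_mass(b) + .PROTON_MASS,
                                 rel = 1))
      })
    }
    nmr <- gen_nmr(pk, seed = .derive_seed(seed, 400L + k), noise_sd = noise)
    run <- gen_lcms(species, seed = .derive_seed(seed, 500L + k),
                    mode = "gradient", noise_sd = noise)
    scale_nmr <- scale_run <- NULL
    if (rx$success) { # scale-up reproduces the screening outcome
      scale_nmr <- gen_nmr(pk, seed = .derive_seed(seed, 600L + k),
                           noise_sd = noise)
      scale_run <- gen_lcms(species, seed = .derive_seed(seed, 700L + k),
                            mode = "gradient", noise_sd = noise)
    }
    reactions[[rid]] <- list(id = rid, sm_ids = rx$sm_ids,
                             product = rx$product, success = rx$success,
                             nmr = nmr, lcms = run, peaks = pk,
                             scaleup_nmr = scale_nmr,
                             scaleup_lcms = scale_run)
  }
  # diversification runs for planted screen hits
  diversify_runs <- list()
  k <- 0L
  for (rid in names(reactions)) {
    rx <- reactions[[rid]]
    if (!rx$success) next
    for (branch in names(sc$diversifications)) {
      k <- k + 1L
      partner <- blocks[[sc$diversifications[[branch]]]]
      dp <- apply_transform(standard_rules()[[branch]],
                            list(rx$product, partner))
      ok <- !(rid %in% sc$failed_diversify[[branch]])
      species <- if (ok) {
        ad <- adduct_mz(dp)
        list(list(rt = 1.2, width = 0.05, response = 1,
                  sticks = data.frame(mz = ad$mz, rel = c(1, 0.3, 0.2))))
      } else { # unconsumed precursor only
        ad <- adduct_mz(rx$product)
        list(list(rt = 0.8, width = 0.05, response = 0.8,
                  sticks = data.frame(mz = ad$mz[1], rel = 1)))
      }
      diversify_runs[[paste0(rid, ":", branch)]] <- list(
        parent = rid, branch = branch, product = dp, success = ok,
        lcms = gen_lcms(species, seed = .derive_seed(seed, 800L + k),
                        mode = "gradient", noise_sd = sc$noise_sd))
    }
  }
  structure(
    list(type = "divergent", seed = seed, blocks = blocks,
         sm_spectra = sm_spectra, sm_peaks = sm_tab,
         reactions = reactions, diversify_runs = diversify_runs,
         diversifications = sc$diversifications,
         truth = list(
           screen_hits = names(Filter(function(r) r$success, sc$reactions)),
           diversify_hits = names(Filter(function(d) d$success,
                                         diversify_runs)))),
    class = "campaign_bundle")
}

.gen_supramolecular <- function(sc, seed) {
  blocks <- sc$blocks
  noise <- sc$noise_sd
  table <- build_lookup_table(
    blocks[sc$pyridine_ids], blocks[sc$amine_ids], blocks[sc$metal_ids],
    blocks[[sc$counterion_id]], max_metals = sc$max_metals)
  sm_ids <- c(sc$pyridine_ids, sc$amine_ids)
  sm_tab <- .sm_peak_table(sm_ids, seed)
  sm_spectra <- list()
  for (i in seq_along(sm_ids)) {
    sm_spectra[[sm_ids[i]]] <- gen_nmr(sm_tab[[sm_ids[i]]],
                                       seed = .derive_seed(seed, 200L + i),
                                       noise_sd = noise)
  }
  reactions <- list(); replicates <- list()
  k <- 0L
  for (py in sc$pyridine_ids) for (am in sc$amine_ids) {
    for (me in sc$metal_ids) {
      k <- k + 1L
      rid <- paste(py, am, me, sep = "/")
      hit <- sc$hits[[rid]]
      sm_pos <- c(sm_tab[[py]]$position, sm_tab[[am]]$position)
      n_sm <- nrow(sm_tab[[py]]) + nrow(sm_tab[[am]])
      if (!is.null(hit)) {
        asm <- assembly_species(blocks[[py]], blocks[[am]], blocks[[me]],
                                hit$m, hit$l)
        pk <- .product_peaks(sm_pos, n_sm, .derive_seed(seed, 300L + k))
        lad <- mz_series(asm, blocks[[sc$counterion_id]])
        set.seed(.derive_seed(seed, 350L + k))
        rungs <- lad[sample(nrow(lad), min(3L, nrow(lad))), ]
        sticks <- rbind(
          data.frame(mz = rungs$mz, rel = stats::runif(nrow(rungs), 0.5, 1)),
          .junk_sticks(4L, table$ladders$mz, .derive_seed(seed, 360L + k)))
        sticks <- sticks[order(sticks$mz), ]
        assembly <- asm
      } else {
        pk <- rbind(sm_tab[[py]], sm_tab[[am]]) # unreacted
        sticks <- .junk_sticks(6L, table$ladders$mz,
                               .derive_seed(seed, 360L + k))
        assembly <- NULL
      }
      nmr <- gen_nmr(pk, seed = .derive_seed(seed, 400L + k),
                     noise_sd = noise)
      run <- gen_lcms(list(list(sticks = sticks, response = 1)),
                      seed = .derive_seed(seed, 500L + k),
                      mode = "direct_injection", noise_sd = noise,
                      run_length = 0.2, scan_interval = 0.04)
      reactions[[rid]] <- list(id = rid, sm_ids = c(py, am, me),
                               assembly = assembly,
                               success = !is.null(hit), nmr = nmr,
                               lcms = run, peaks = pk)
      if (!is.null(hit)) {
        reps <- list()
        for (r in 1:6) {
          reps[[r]] <- list(
            nmr = gen_nmr(pk, seed = .derive_seed(seed, 1000L + 10L * k + r),
                          noise_sd = noise),
            lcms = gen_lcms(list(list(sticks = sticks, response = 1)),
                            seed = .derive_seed(seed, 2000L + 10L * k + r),
                            mode = "direct_injection", noise_sd = noise,
                            run_length = 0.2, scan_interval = 0.04))
        }
        replicates[[rid]] <- reps
      }
    }
  }
  # guest assays: host spectrum vs host-plus-guest spectrum
  guest_assays <- list()
  k <- 0L
  for (rid in names(sc$hits)) {
    host_peaks <- reactions[[rid]]$peaks
    per_guest <- list()
    for (g in sc$guest_ids) {
      k <- k + 1L
      bound <- g %in% sc$binding[[rid]]
      pk <- host_peaks
      if (bound) { # perturb aromatic-region host resonances
        arom <- pk$position >= 6 & pk$position <= 9.5
        pk$position[arom] <- pk$position[arom] + 0.08
      }
      per_guest[[g]] <- gen_nmr(pk, seed = .derive_seed(seed, 3000L + k),
                                noise_sd = noise)
    }
    guest_assays[[rid]] <- per_guest
  }
  truth_binding <- lapply(stats::setNames(names(sc$hits), names(sc$hits)),
                          function(h) sc$binding[[h]])
  structure(
    list(type = "supramolecular", seed = seed, blocks = blocks,
         lookup_table = table, counterion_id = sc$counterion_id,
         sm_spectra = sm_spectra, sm_peaks = sm_tab,
         reactions = reactions, replicates = replicates,
         guest_assays = guest_assays, guest_ids = sc$guest_ids,
         truth = list(screen_hits = names(sc$hits),
                      binding = truth_binding)),
    class = "campaign_bundle")
}

#' @export
print.campaign_bundle <- function(x, ...) {
  cat(sprintf("<campaign bundle> %s, %d reaction(s), seed %d\n", x$type,
              length(x$reactions), x$seed))
  invisible(x)
}
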