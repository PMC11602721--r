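# Transform rules, route enumeration, assemblies and m/z ladders.

rules <- standard_rules()
am1 <- building_block("1", "alkyne_amine", "C3H5N")
am2 <- building_block("2", "alkyne_amine", "C4H7N")
am3 <- building_block("3", "alkyne_amine", "C5H9N")
iso <- building_block("5", "isocyanate", "C7H5NO")
itc <- building_block("4", "isothiocyanate", "C7H5NS")
arx <- building_block("12", "aryl_halide", "C5H4BrN")
azd <- building_block("18", "azide", "C10H13N5O4")

test_that("urea formation is a pure formula addition", {
  p <- apply_transform(rules$urea, list(am1, iso))
  expect_true(p$formula == chem_formula("C10H10N2O"))
  expect_equal(p$mass, 174.0793, tolerance = 1e-4)
  expect_equal(p$provenance$rule, "urea")
  expect_equal(p$provenance$reactants, c("1", "5"))
})

test_that("imine condensation loses one water per bond", {
  tren <- building_block("28", "polytopic_amine", "C6H18N4", topicity = 3)
  pyald <- building_block("24", "carbonyl_pyridine", "C6H5NO")
  total <- Reduce(fml_add, list(tren$formula, pyald$formula, pyald$formula,
                                pyald$formula))
  expected <- total
  for (i in 1:3) expected <- fml_subtract(expected, chem_formula("H2O"))
  lig <- apply_transform(
    transform_rule("imine3", c("polytopic_amine", "carbonyl_pyridine",
                               "carbonyl_pyridine", "carbonyl_pyridine"),
                   loss = "H2O", per_bond = TRUE),
    list(tren, pyald, pyald, pyald))
  expect_true(lig$formula == expected)
  expect_equal(formula_mass(lig$formula),
               formula_mass(total) - 3 * formula_mass(chem_formula("H2O")),
               tolerance = 1e-9)
})

test_that("coupling rules apply their fixed deltas", {
  urea <- apply_transform(rules$urea, list(am1, iso))
  sono <- apply_transform(rules$sonogashira, list(urea, arx))
  expect_true(sono$formula ==
                fml_subtract(fml_add(urea$formula, arx$formula),
                             chem_formula("HBr")))
  click <- apply_transform(rules$cuaac, list(urea, azd))
  expect_true(click$formula == fml_add(urea$formula, azd$formula))
})

test_that("role mismatches and impossible deltas are rejected", {
  expect_error(apply_transform(rules$urea, list(iso, am1)), "roles")
  bad <- transform_rule("impossible", c("alkyne_amine", "isocyanate"),
                        loss = "S")
  expect_error(apply_transform(bad, list(am1, iso)), "negative")
})

test_that("mass is conserved through every transform (property)", {
  set.seed(7)
  for (i in 1:50) {
    a <- building_block("a", "alkyne_amine", random_formula())
    b <- building_block("b", "isocyanate", random_formula())
    p <- apply_transform(rules$urea, list(a, b))
    expect_equal(p$mass, formula_mass(a$formula) + formula_mass(b$formula),
                 tolerance = 1e-6)
  }
})

divergent_stages <- list(
  list(list(rule = rules$urea, partner_role = "isocyanate"),
       list(rule = rules$thiourea, partner_role = "isothiocyanate")),
  list(list(rule = rules$sonogashira, partner_role = "aryl_halide"),
       list(rule = rules$cuaac, partner_role = "azide"))
)

test_that("route enumeration matches the closed-form combinatorics", {
  blocks <- list(am1, am2, am3, iso, itc, arx, azd)
  g <- enumerate_route(blocks, divergent_stages)
  expect_equal(route_stage_counts(g), c(6L, 12L))
  expect_equal(length(route_products(g)), 12L)
  # closed form: products per stage = sum over branches of |seeds| x |partners|
  g1 <- enumerate_route(list(am1, iso),
                        list(list(list(rule = rules$urea,
                                       partner_role = "isocyanate"))))
  expect_equal(route_stage_counts(g1), 1L)
})

test_that("route enumeration errors on missing roles and duplicate ids", {
  expect_error(enumerate_route(list(am1),
                               list(list(list(rule = rules$urea,
                                              partner_role = "isocyanate")))),
               "isocyanate")
  expect_error(enumerate_route(list(am1, am1), divergent_stages),
               "duplicate")
})

py <- building_block("24", "carbonyl_pyridine", "C6H5NO")
dit <- building_block("29", "polytopic_amine", "C13H14N2", topicity = 2)
trit <- building_block("28", "polytopic_amine", "C6H18N4", topicity = 3)
zn <- building_block("Zn", "metal_ion", "Zn+2", capacity = 3)
cu <- building_block("Cu", "metal_ion", "Cu+1", capacity = 2)
otf <- building_block("OTf", "counterion", "CF3O3S-1")

test_that("assembly charge is metal count times metal charge", {
  expect_equal(assembly_charge(4, 2), 8L)
  expect_equal(assembly_charge(2, 2), 4L)
  expect_equal(assembly_charge(1, 1), 1L)
  expect_error(assembly_charge(0, 2), ">= 1")
  expect_error(assembly_charge(2, 0), ">= 1")
})

test_that("assembly formula follows the imine-condensation bookkeeping", {
  cage <- assembly_species(py, trit, zn, 4, 4)
  expect_equal(cage$Q, 8L)
  manual <- fml_add(
    fml_multiply(zn$formula, 4),
    fml_multiply(Reduce(fml_subtract,
                        c(list(Reduce(fml_add,
                                      c(list(trit$formula),
                                        rep(list(py$formula), 3)))),
                          rep(list(chem_formula("H2O")), 3))), 4))
  expect_true(cage$formula == manual)
  expect_error(assembly_species(py, trit, zn, 2, 3), "imbalance")
})

test_that("assembly series are the multiples of the minimal solution", {
  ser <- enumerate_assemblies(py, dit, zn, max_metals = 10)
  expect_equal(lapply(ser, function(s) c(s$m, s$l)),
               list(c(2L, 3L), c(4L, 6L), c(6L, 9L), c(8L, 12L),
                    c(10L, 15L)))
  ser3 <- enumerate_assemblies(py, trit, zn, max_metals = 10)
  expect_equal(vapply(ser3, `[[`, integer(1), "m"), 1:10)
  expect_equal(vapply(ser3, `[[`, integer(1), "l"), 1:10)
  expect_equal(enumerate_assemblies(py, dit, zn, max_metals = 0), list())
  expect_equal(length(enumerate_assemblies(py, dit, zn, 10,
                                           include_mononuclear = FALSE)),
               5L) # minimal solution already has m = 2
  ser_cu3 <- enumerate_assemblies(py, trit, cu, max_metals = 12)
  expect_equal(vapply(ser_cu3, `[[`, integer(1), "m"), c(3L, 6L, 9L, 12L))
})

test_that("every enumerated assembly is coordination balanced (property)", {
  for (amine in list(dit, trit)) for (metal in list(zn, cu)) {
    for (s in enumerate_assemblies(py, amine, metal, 12)) {
      expect_identical(s$m * metal$capacity, s$l * amine$topicity)
      expect_identical(s$Q, s$m * metal$charge)
    }
  }
})

test_that("enumeration agrees with exhaustive double-loop search", {
  pys <- list(py,
              building_block("25", "carbonyl_pyridine", "C7H7NO"),
              building_block("26", "carbonyl_pyridine", "C10H7NO"))
  ams <- list(building_block("27", "polytopic_amine", "C2H8N2",
                             topicity = 2), trit, dit)
  mets <- list(zn, cu)
  maxm <- c(Zn = 10L, Cu = 12L)
  for (p in pys) for (a in ams) for (m in mets) {
    got <- enumerate_assemblies(p, a, m, maxm[[m$id]])
    got_ml <- vapply(got, function(s) paste(s$m, s$l), character(1))
    brute <- character(0)
    for (mm in 1:maxm[[m$id]]) for (ll in 1:(3 * maxm[[m$id]])) {
      if (mm * m$capacity == ll * a$topicity) {
        brute <- c(brute, paste(mm, ll))
      }
    }
    expect_identical(sort(got_ml), sort(brute),
                     label = paste("grid", p$id, a$id, m$id))
  }
})

test_that("m/z ladders have Q rungs, z + n = Q, and decrease in z", {
  lad <- mz_series(list(mass = 3000, Q = 8L), 100)
  expect_equal(nrow(lad), 8L)
  expect_true(all(lad$z + lad$n == 8L))
  expect_equal(lad$mz[lad$z == 8], 375)
  expect_equal(lad$mz[lad$z == 4], 850)
  expect_true(all(diff(lad$mz[order(lad$z)]) < 0))
  one <- mz_series(list(mass = 500, Q = 1L), 100)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mz, 500)
  expect_error(mz_series(list(mass = 500, Q = 0L), 100), "positive")
})

test_that("adduct m/z uses the standard positive-mode offsets", {
  a <- adduct_mz(list(mass = 174.0793))
  expect_equal(a$mz[a$adduct == "[M+H]+"], 175.0866, tolerance = 1e-4)
  expect_equal(a$mz[a$adduct == "[M+Na]+"] - a$mz[a$adduct == "[M+H]+"],
               21.9819, tolerance = 1e-4)
  expect_error(adduct_mz(list(mass = 0)), "positive")
  expect_error(adduct_mz(list(mass = 100), numeric(0)), "empty")
})

test_that("the lookup table covers the grid with complete ladders", {
  pys <- list(py, building_block("25", "carbonyl_pyridine", "C7H7NO"),
              building_block("26", "carbonyl_pyridine", "C10H7NO"))
  ams <- list(building_block("27", "polytopic_amine", "C2H8N2",
                             topicity = 2), trit, dit)
  tab <- build_lookup_table(pys, ams, list(zn, cu), otf,
                            max_metals = c(Zn = 10L, Cu = 12L))
  expect_equal(length(unique(tab$entries$combination)), 18L)
  # ladder completeness: Q rungs per entry
  per_entry <- tapply(tab$ladders$z, tab$ladders$entry_id,
                      function(z) length(unique(z)))
  expect_identical(as.integer(per_entry[as.character(tab$entries$entry_id)]),
                   as.integer(tab$entries$Q))
  expect_equal(unname(mz_table_size(tab)[["mz_values"]]),
               sum(tab$entries$Q))
  # single-combination table agrees with enumerate + series by construction
  small <- build_lookup_table(list(py), list(trit), list(zn), otf,
                              max_metals = 10L)
  expect_equal(unname(mz_table_size(small)[["entries"]]), 10L)
  expect_equal(unname(mz_table_size(small)[["mz_values"]]),
               sum(2L * (1:10)))
  empty <- build_lookup_table(list(), list(), list(), otf)
  expect_equal(unname(mz_table_size(empty)[["entries"]]), 0L)
  expect_error(build_lookup_table(list(py, py), list(trit), list(zn), otf),
               "duplicate")
})
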