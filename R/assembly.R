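#' Net charge of a metal-organic assembly
#'
#' With neutral imine ligands the net cationic charge of an assembly is
#' carried entirely by its metals: Q = m x c for m metal ions of charge +c.
#' A tetrahedral Zn4L4 cage is therefore 8+ and a Zn2L3 helicate 4+.
#'
#' @param metal_count Number of metal ions m (>= 1).
#' @param metal_charge Charge per metal ion c (>= 1).
#' @return Integer net charge Q.
#' @examples
#' assembly_charge(4, 2) # Zn4 cage -> 8+
#' assembly_charge(2, 2) # Zn2 helicate -> 4+
#' @export
assembly_charge <- function(metal_count, metal_charge) {
  m <- as.integer(metal_count); c <- as.integer(metal_charge)
  if (m < 1L) stop("metal_count must be >= 1")
  if (c < 1L) stop("metal_charge must be >= 1")
  m * c
}

#' Construct one assembly species
#'
#' A homoleptic imine-based assembly of m metal ions and l ligands, each
#' ligand formed in situ by condensing one polytopic amine with
#' topicity-many carbonyl pyridines (losing one water per imine bond).
#' Coordination balance m x capacity = l x topicity must hold exactly;
#' the net charge is m x metal charge.
#'
#' @param pyridine,amine,metal `building_block`s with roles
#'   `carbonyl_pyridine`, `polytopic_amine`, `metal_ion`.
#' @param m,l Metal and ligand counts.
#' @return An `assembly_species` with fields `m`, `l`, `Q`, `formula`,
#'   `mass` (monoisotopic), `mass_avg`, `combination`.
#' @export
assembly_species <- function(pyridine, amine, metal, m, l) {
  stopifnot(pyridine$role == "carbonyl_pyridine",
            amine$role == "polytopic_amine",
            metal$role == "metal_ion")
  m <- as.integer(m); l <- as.integer(l)
  if (m < 1L || l < 1L) stop("m and l must be >= 1")
  if (m * metal$capacity != l * amine$topicity) {
    stop("coordination imbalance: ", m, " x ", metal$capacity, " != ",
         l, " x ", amine$topicity)
  }
  t <- amine$topicity
  ligand <- Reduce(fml_add, c(list(amine$formula),
                              rep(list(pyridine$formula), t)))
  for (i in seq_len(t)) ligand <- fml_subtract(ligand, chem_formula("H2O"))
  formula <- fml_add(fml_multiply(metal$formula, m), fml_multiply(ligand, l))
  Q <- assembly_charge(m, metal$charge)
  structure(
    list(metal_id = metal$id, pyridine_id = pyridine$id, amine_id = amine$id,
         m = m, l = l, Q = Q, formula = formula,
         mass = formula_mass(formula),
         mass_avg = formula_mass(formula, "average"),
         combination = paste0(pyridine$id, "/", amine$id, "/", metal$id)),
    class = "assembly_species"
  )
}

#' @export
print.assembly_species <- function(x, ...) {
  cat(sprintf("<assembly> [%s_%d(%s,%s)_%d]%d+  %s  %.2f Da\n",
              x$metal_id, x$m, x$pyridine_id, x$amine_id, x$l, x$Q,
              format(x$formula), x$mass))
  invisible(x)
}

#' Enumerate chemically meaningful assemblies for one combination
#'
#' Lists every homoleptic, coordination-balanced assembly of one metal, one
#' carbonyl pyridine and one polytopic amine under maximal site occupancy:
#' all (m, l) with m x capacity = l x topicity, i.e. the integer-multiple
#' series of the minimal balanced solution, for 1 <= m <= `max_metals`.
#' Mononuclear (m = 1) members, which arise when capacity equals topicity,
#' are included by default; set `include_mononuclear = FALSE` to restrict to
#' polynuclear architectures.
#'
#' @inheritParams assembly_species
#' @param max_metals Largest metal count considered (e.g. 10 for Zn2+, 12
#'   for Cu+).
#' @param include_mononuclear Keep m = 1 species?
#' @return List of `assembly_species` (possibly empty).
#' @examples
#' py <- building_block("24", "carbonyl_pyridine", "C6H4N2O")
#' am <- building_block("29", "polytopic_amine", "C4H12N2", topicity = 2)
#' zn <- building_block("Zn", "metal_ion", "Zn+2", capacity = 3)
#' length(enumerate_assemblies(py, am, zn, max_metals = 10)) # (2,3)...(10,15)
#' @export
enumerate_assemblies <- function(pyridine, amine, metal, max_metals = 10L,
                                 include_mononuclear = TRUE) {
  max_metals <- as.integer(max_metals)
  if (max_metals < 1L) return(list())
  cap <- metal$capacity; top <- amine$topicity
  g <- .gcd(cap, top)
  m0 <- top %/% g; l0 <- cap %/% g
  out <- list()
  k <- 1L
  while (k * m0 <= max_metals) {
    m <- k * m0; l <- k * l0
    if (m > 1L || include_mononuclear) {
      out[[length(out) + 1L]] <- assembly_species(pyridine, amine, metal, m, l)
    }
    k <- k + 1L
  }
  out
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Charge-state / counterion m/z ladder of a charged species
#'
#' For a species of net charge Q observed in positive-mode ESI, the ion at
#' charge state z retains n = Q - z counterions, giving
#' m/z = (species mass + n x counterion mass) / z for z = 1..Q: the full
#' ladder has exactly Q rungs and m/z strictly decreases as z grows.
#'
#' @param species An `assembly_species`, or any list with `mass` and `Q`.
#' @param counterion `building_block` with role `counterion` (mass taken
#'   monoisotopic), or a bare numeric mass in daltons.
#' @return data.frame with columns `z`, `n`, `mz`.
#' @examples
#' mz_series(list(mass = 3000, Q = 8), 100) # z = 8 -> 375, z = 4 -> 850
#' @export
mz_series <- function(species, counterion) {
  Q <- species$Q
  if (is.null(Q) || Q < 1L) stop("species must carry a positive net charge Q")
  cmass <- if (is.numeric(counterion)) counterion else .block_mass(counterion)
  if (cmass <= 0) stop("counterion mass must be positive")
  z <- seq_len(Q)
  n <- Q - z
  data.frame(z = z, n = n, mz = (species$mass + n * cmass) / z)
}

#' Positive-mode adduct m/z values for a neutral species
#'
#' Singly charged adduct ions of a neutral molecule M. The default adduct set
#' is protonation, sodiation and ammonium addition.
#'
#' @param species A `species` (or any list with a numeric `mass` > 0).
#' @param adducts Named numeric vector of adduct masses in daltons; defaults
#'   to `[M+H]+`, `[M+Na]+`, `[M+NH4]+`.
#' @return data.frame with columns `adduct`, `mz`.
#' @examples
#' adduct_mz(list(mass = 174.0793))
#' @export
adduct_mz <- function(species, adducts = .DEFAULT_ADDUCTS) {
  if (is.null(species$mass) || species$mass <= 0) {
    stop("species must have positive mass")
  }
  if (length(adducts) == 0L) stop("adduct set must not be empty")
  if (is.null(names(adducts)) || any(names(adducts) == "")) {
    stop("adducts must be a named numeric vector")
  }
  data.frame(adduct = names(adducts), mz = species$mass + unname(adducts),
             stringsAsFactors = FALSE)
}

#' Precalculated m/z lookup table over a screening grid
#'
#' Enumerates every coordination-balanced assembly over the full screening
#' grid (each carbonyl pyridine x each polytopic amine x each metal) and
#' attaches the complete counterion charge ladder of each, yielding the
#' lookup table that direct-injection mass spectra are matched against.
#'
#' @param pyridines,amines,metals Lists of `building_block`s.
#' @param counterion `building_block` (role `counterion`) or numeric mass.
#' @param max_metals Named integer vector of per-metal-id maxima, or a single
#'   number applied to all metals.
#' @param include_mononuclear Keep m = 1 species?
#' @param tol Matching tolerance carried with the table (daltons).
#' @return An `mz_table`: list with `entries` (data.frame of species) and
#'   `ladders` (long data.frame: entry_id, combination, m, l, Q, z, n, mz).
#' @export
build_lookup_table <- function(pyridines, amines, metals, counterion,
                               max_metals = 10L, include_mononuclear = TRUE,
                               tol = 0.5) {
  all_ids <- c(vapply(pyridines, `[[`, character(1), "id"),
               vapply(amines, `[[`, character(1), "id"),
               vapply(metals, `[[`, character(1), "id"))
  if (anyDuplicated(all_ids)) {
    stop("duplicate building-block ids in grid: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  entries <- list(); ladders <- list(); eid <- 0L
  for (metal in metals) {
    mm <- if (length(max_metals) > 1L || !is.null(names(max_metals))) {
      got <- max_metals[[metal$id]]
      if (is.null(got)) stop("no max_metals entry for metal ", metal$id)
      got
    } else {
      max_metals
    }
    for (py in pyridines) for (am in amines) {
      for (sp in enumerate_assemblies(py, am, metal, mm,
                                      include_mononuclear)) {
        eid <- eid + 1L
        entries[[eid]] <- data.frame(
          entry_id = eid, combination = sp$combination, metal = sp$metal_id,
          pyridine = sp$pyridine_id, amine = sp$amine_id,
          m = sp$m, l = sp$l, Q = sp$Q, mass = sp$mass,
          formula = format(sp$formula), stringsAsFactors = FALSE)
        lad <- mz_series(sp, counterion)
        lad$entry_id <- eid
        lad$combination <- sp$combination
        lad$m <- sp$m; lad$l <- sp$l; lad$Q <- sp$Q
        ladders[[eid]] <- lad[, c("entry_id", "combination", "m", "l", "Q",
                                  "z", "n", "mz")]
      }
    }
  }
  structure(
    list(entries = if (eid) do.call(rbind, entries) else
           data.frame(entry_id = integer(0)),
         ladders = if (eid) do.call(rbind, ladders) else
           data.frame(entry_id = integer(0), mz = numeric(0)),
         tol = tol),
    class = "mz_table"
  )
}

#' Size of an m/z lookup table
#' @param table An `mz_table`.
#' @return Named integer vector: number of species entries and total number
#'   of m/z values.
#' @export
mz_table_size <- function(table) {
  stopifnot(inherits(table, "mz_table"))
  c(entries = nrow(table$entries), mz_values = nrow(table$ladders))
}

#' @export
print.mz_table <- function(x, ...) {
  sz <- mz_table_size(x)
  cat("<m/z lookup table> ", sz[["entries"]], " entries, ",
      sz[["mz_values"]], " m/z values (tol ", x$tol, " Da)\n", sep = "")
  invisible(x)
}

#' Export an m/z lookup table
#'
#' @param table An `mz_table`.
#' @param path Output file.
#' @param format `"csv"` (long ladder table: entry_id, combination, m, l, Q,
#'   z, n, mz) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_mz_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "mz_table"))
  if (format == "csv") {
    utils::write.csv(table$ladders, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(entries = table$entries, ladders = table$ladders, tol = table$tol),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
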