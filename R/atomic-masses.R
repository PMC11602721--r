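# Static registry of atomic masses (IUPAC). Monoisotopic = mass of the most
# abundant isotope; average = standard atomic weight. Unit-resolution
# single-quadrupole matching never needs more elements than these; unknown
# symbols are rejected with an explicit error rather than silently dropped.

.ATOMIC_MASSES <- local({
  tab <- rbind(
    c("H",  1.0078250319, 1.008),
    c("B",  11.0093054,   10.811),
    c("C",  12.0,         12.011),
    c("N",  14.0030740052, 14.007),
    c("O",  15.9949146221, 15.999),
    c("F",  18.9984032,   18.998403),
    c("Na", 22.98976928,  22.98976928),
    c("Mg", 23.9850417,   24.305),
    c("Al", 26.98153853,  26.9815385),
    c("Si", 27.97692653,  28.085),
    c("P",  30.97376199,  30.973762),
    c("S",  31.97207117,  32.06),
    c("Cl", 34.96885268,  35.45),
    c("K",  38.96370649,  39.0983),
    c("Ca", 39.96259086,  40.078),
    c("Ti", 47.94794198,  47.867),
    c("Cr", 51.94050623,  51.9961),
    c("Mn", 54.93804391,  54.938044),
    c("Fe", 55.93493633,  55.845),
    c("Co", 58.93319429,  58.933194),
    c("Ni", 57.93534241,  58.6934),
    c("Cu", 62.92959772,  63.546),
    c("Zn", 63.92914201,  65.38),
    c("Ga", 68.9255735,   69.723),
    c("Se", 79.9165218,   78.971),
    c("Br", 78.9183376,   79.904),
    c("Ag", 106.9050916,  107.8682),
    c("Cd", 113.90336509, 112.414),
    c("Sn", 119.90220163, 118.71),
    c("I",  126.9044719,  126.90447),
    c("Pd", 105.9034804,  106.42),
    c("Pt", 194.9647917,  195.084),
    c("Au", 196.96656879, 196.966569),
    c("Hg", 201.9706434,  200.592),
    c("Pb", 207.9766525,  207.2)
  )
  data.frame(
    element = tab[, 1],
    monoisotopic = as.numeric(tab[, 2]),
    average = as.numeric(tab[, 3]),
    stringsAsFactors = FALSE
  )
})

# Mass of a proton / common singly charged positive-mode adducts, in daltons.
# Adduct masses include the loss of one electron.
.PROTON_MASS <- 1.007276466
.ELECTRON_MASS <- 0.000548579909

.DEFAULT_ADDUCTS <- c(
  "[M+H]+"   = 1.007276466,
  "[M+Na]+"  = 22.989218,
  "[M+NH4]+" = 18.033823
)

#' Elements known to the mass registry
#'
#' @return Character vector of element symbols for which monoisotopic and
#'   average masses are available.
#' @export
known_elements <- function() .ATOMIC_MASSES$element

.atomic_mass <- function(symbols, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  idx <- match(symbols, .ATOMIC_MASSES$element)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .ATOMIC_MASSES[[mode]][idx]
}
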