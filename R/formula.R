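#' Molecular formulas
#'
#' A `chem_formula` is a named integer vector of element counts (all counts
#' >= 1, elements restricted to the registry of [known_elements()]) with an
#' integer `charge` attribute. Formulas print in Hill order (C, H, then other
#' elements alphabetically) and compare equal iff their element-count mappings
#' and charges are equal.
#'
#' `parse_formula()` accepts Hill-order strings with optional parenthesized
#' groups and an optional trailing charge written as `+`, `-`, `+n` or `-n`,
#' e.g. `"C10H10N2O"`, `"Zn+2"`, `"(C6H5)2CO"`.
#'
#' @param x A formula string, a named numeric vector of counts, or a
#'   `chem_formula`.
#' @param charge Integer net charge; overrides any charge in the string when
#'   supplied.
#' @return A `chem_formula` object.
#' @examples
#' chem_formula("C3H5N")
#' chem_formula("Zn+2")
#' chem_formula(c(H = 2, O = 1))
#' @export
chem_formula <- function(x, charge = NULL) {
  if (inherits(x, "chem_formula")) {
    if (!is.null(charge)) attr(x, "charge") <- as.integer(charge)
    return(x)
  }
  if (is.character(x)) {
    if (length(x) != 1L) stop("a single formula string is required")
    parsed <- .parse_formula_string(x)
    counts <- parsed$counts
    if (is.null(charge)) charge <- parsed$charge
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
    if (is.null(charge)) charge <- 0L
  } else {
    stop("cannot interpret 'x' as a molecular formula")
  }
  .new_formula(counts, charge)
}

#' @rdname chem_formula
#' @export
parse_formula <- function(x, charge = NULL) chem_formula(x, charge)

.new_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) {
    stop("empty formula: at least one atom is required")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be positive integers")
  }
  .atomic_mass(names(counts)) # validates symbols
  counts <- counts[order(names(counts))]
  storage.mode(counts) <- "integer"
  structure(counts, charge = as.integer(charge), class = "chem_formula")
}

.parse_formula_string <- function(s) {
  s0 <- gsub("\\s+", "", s)
  charge <- 0L
  m <- regmatches(s0, regexec("([+-])([0-9]*)$", s0))[[1]]
  if (length(m) == 3L) {
    n <- if (m[3] == "") 1L else as.integer(m[3])
    charge <- if (m[2] == "+") n else -n
    s0 <- sub("([+-])([0-9]*)$", "", s0)
  }
  if (s0 == "") stop("empty formula string: ", sQuote(s))
  counts <- .parse_group(s0, s)
  list(counts = counts, charge = charge)
}

# Recursive-descent over one bracketed level at a time.
.parse_group <- function(s, orig) {
  counts <- numeric(0)
  add <- function(el, n) {
    counts[el] <<- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  i <- 1L
  chars <- strsplit(s, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- 1L; j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > length(chars)) stop("unbalanced parentheses in ", sQuote(orig))
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
      }
      inner <- .parse_group(paste(chars[(i + 1L):(j - 1L)], collapse = ""), orig)
      i <- j + 1L
      num <- ""
      while (i <= length(chars) && grepl("[0-9]", chars[i])) {
        num <- paste0(num, chars[i]); i <- i + 1L
      }
      mult <- if (num == "") 1L else as.integer(num)
      for (el in names(inner)) add(el, inner[[el]] * mult)
    } else if (grepl("[A-Z]", ch)) {
      el <- ch; i <- i + 1L
      while (i <= length(chars) && grepl("[a-z]", chars[i])) {
        el <- paste0(el, chars[i]); i <- i + 1L
      }
      num <- ""
      while (i <= length(chars) && grepl("[0-9]", chars[i])) {
        num <- paste0(num, chars[i]); i <- i + 1L
      }
      add(el, if (num == "") 1L else as.integer(num))
    } else {
      stop("unexpected character ", sQuote(ch), " in formula ", sQuote(orig))
    }
  }
  counts
}

#' @export
format.chem_formula <- function(x, ...) {
  counts <- unclass(x)
  attr(counts, "charge") <- NULL
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  body <- paste0(vapply(hill, function(el) {
    n <- counts[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
  q <- attr(x, "charge")
  if (is.null(q) || q == 0L) return(body)
  paste0(body, if (q > 0) "+" else "-", if (abs(q) > 1) abs(q) else "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.4f", formula_mass(x)),
      " Da monoisotopic)\n", sep = "")
  invisible(x)
}

#' @export
as.character.chem_formula <- function(x, ...) format(x)

#' Formula charge
#' @param x A `chem_formula`.
#' @return Integer net charge.
#' @export
formula_charge <- function(x) {
  q <- attr(x, "charge")
  if (is.null(q)) 0L else q
}

#' Formula arithmetic
#'
#' Element-wise addition, subtraction and integer scaling of formulas, used to
#' compose reaction products and assembly stoichiometries. Subtraction that
#' would drive any element count negative is an error (a transform can never
#' remove atoms that are not there). Charges add.
#'
#' @param a,b `chem_formula` objects (or things coercible by [chem_formula()]).
#' @param k Non-negative integer multiplier.
#' @return A `chem_formula`.
#' @export
fml_add <- function(a, b) {
  a <- chem_formula(a); b <- chem_formula(b)
  counts <- .counts_of(a)
  for (el in names(.counts_of(b))) {
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + .counts_of(b)[[el]]
  }
  .new_formula(counts, formula_charge(a) + formula_charge(b))
}

#' @rdname fml_add
#' @export
fml_subtract <- function(a, b) {
  a <- chem_formula(a); b <- chem_formula(b)
  counts <- .counts_of(a)
  for (el in names(.counts_of(b))) {
    have <- if (el %in% names(counts)) counts[[el]] else 0L
    counts[el] <- have - .counts_of(b)[[el]]
  }
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop("subtraction yields negative count for element(s): ",
         paste(bad, collapse = ", "))
  }
  .new_formula(counts, formula_charge(a) - formula_charge(b))
}

#' @rdname fml_add
#' @export
fml_multiply <- function(a, k) {
  a <- chem_formula(a)
  k <- as.integer(k)
  if (k < 1L) stop("multiplier must be a positive integer")
  .new_formula(.counts_of(a) * k, formula_charge(a) * k)
}

.counts_of <- function(x) {
  counts <- unclass(x)
  attributes(counts) <- list(names = names(counts))
  counts
}

#' Molecular mass of a formula
#'
#' Sums per-element atomic masses from the embedded IUPAC registry.
#' Monoisotopic masses (default) drive all m/z prediction; average masses are
#' carried for molar-mass reporting. Electron mass is ignored: at the
#' unit-resolution tolerances used for matching (>= 0.1 Da) it is immaterial.
#'
#' @param formula A `chem_formula` (or string coercible to one).
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass in daltons.
#' @examples
#' formula_mass(chem_formula("H2O")) # 18.0106
#' @export
formula_mass <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  formula <- chem_formula(formula)
  counts <- .counts_of(formula)
  sum(counts * .atomic_mass(names(counts), mode))
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  a <- .counts_of(chem_formula(e1)); b <- .counts_of(chem_formula(e2))
  identical(a[order(names(a))], b[order(names(b))]) &&
    formula_charge(e1) == formula_charge(e2)
}
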