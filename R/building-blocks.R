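.BLOCK_ROLES <- c(
  "alkyne_amine", "isocyanate", "isothiocyanate", "aryl_halide", "azide",
  "carbonyl_pyridine", "polytopic_amine", "metal_ion", "counterion", "guest"
)

#' Chemical building blocks
#'
#' A building block is a reagent, metal ion, counterion or guest taking part
#' in a campaign: a short id, a role from the fixed vocabulary, a molecular
#' formula, a topicity (number of reactive or binding arms: primary amines for
#' polytopic amines, chelation sites per metal for metal ions) and a signed
#' charge. Metal ions additionally carry a chelate `capacity` (number of
#' bidentate pyridyl-imine arms the ion accepts: 3 for octahedral Zn2+, 2 for
#' tetrahedral Cu+).
#'
#' @param id Short label, e.g. `"24"`.
#' @param role One of `alkyne_amine`, `isocyanate`, `isothiocyanate`,
#'   `aryl_halide`, `azide`, `carbonyl_pyridine`, `polytopic_amine`,
#'   `metal_ion`, `counterion`, `guest`.
#' @param formula A `chem_formula` or formula string.
#' @param topicity Non-negative integer; must be >= 1 for `polytopic_amine`
#'   and `metal_ion`.
#' @param charge Signed integer charge; defaults to the formula's charge.
#'   Must be 0 for neutral organic roles and -1 for counterions.
#' @param capacity Chelate capacity, metal ions only.
#' @return A `building_block` object.
#' @examples
#' building_block("28", "polytopic_amine", "C6H15N3", topicity = 3)
#' building_block("Zn", "metal_ion", "Zn+2", capacity = 3)
#' @export
building_block <- function(id, role, formula, topicity = 0L, charge = NULL,
                           capacity = NULL) {
  role <- match.arg(role, .BLOCK_ROLES)
  formula <- chem_formula(formula)
  if (is.null(charge)) charge <- formula_charge(formula)
  charge <- as.integer(charge)
  topicity <- as.integer(topicity)
  neutral_roles <- c("alkyne_amine", "isocyanate", "isothiocyanate",
                     "aryl_halide", "azide", "carbonyl_pyridine",
                     "polytopic_amine", "guest")
  if (role %in% neutral_roles && charge != 0L) {
    stop("role ", sQuote(role), " must be neutral, got charge ", charge)
  }
  if (role == "counterion" && charge != -1L) {
    stop("counterions must carry charge -1, got ", charge)
  }
  if (role == "metal_ion") {
    # for a metal ion the chelate capacity is its topicity; accept either
    if (is.null(capacity) && topicity >= 1L) capacity <- topicity
    if (is.null(capacity)) stop("metal ions require a chelate 'capacity'")
    capacity <- as.integer(capacity)
    if (capacity < 1L) stop("chelate capacity must be >= 1")
    topicity <- capacity
  }
  if (role %in% c("polytopic_amine", "metal_ion") && topicity < 1L) {
    stop("topicity must be >= 1 for role ", sQuote(role))
  }
  structure(
    list(id = as.character(id), role = role, formula = formula,
         topicity = topicity, charge = charge, capacity = capacity),
    class = "building_block"
  )
}

#' @export
print.building_block <- function(x, ...) {
  cat("<building block> ", x$id, " [", x$role, "] ", format(x$formula),
      if (x$topicity > 0) paste0("  topicity=", x$topicity) else "",
      if (!is.null(x$capacity)) paste0("  capacity=", x$capacity) else "",
      "\n", sep = "")
  invisible(x)
}

.block_mass <- function(block, mode = "monoisotopic") {
  formula_mass(block$formula, mode)
}

#' Reaction transform rules
#'
#' A transform rule composes product formulas from reactant formulas: the
#' product is the element-wise sum of the reactants plus a signed formula
#' delta (e.g. loss of one water per imine condensation bond, loss of HBr in
#' a Sonogashira coupling, zero delta for pure additions such as (thio)urea
#' formation or CuAAC). When `per_bond` is set the delta is applied once per
#' condensation bond, the bond count being the topicity of the polytopic
#' reactant.
#'
#' @param name Rule label.
#' @param reactant_roles Character vector of roles, in order. The role
#'   `"product"` stands for the carried-forward product of an earlier stage.
#' @param gain Formula gained (string or `chem_formula`), or `NULL`.
#' @param loss Formula lost per application, or `NULL`.
#' @param per_bond Apply the delta once per condensation bond?
#' @return A `transform_rule`.
#' @examples
#' transform_rule("urea", c("alkyne_amine", "isocyanate"))
#' transform_rule("imine", c("polytopic_amine", "carbonyl_pyridine"),
#'                loss = "H2O", per_bond = TRUE)
#' @export
transform_rule <- function(name, reactant_roles, gain = NULL, loss = NULL,
                           per_bond = FALSE) {
  stopifnot(length(reactant_roles) >= 1L)
  structure(
    list(name = name, reactant_roles = reactant_roles,
         gain = if (!is.null(gain)) chem_formula(gain),
         loss = if (!is.null(loss)) chem_formula(loss),
         per_bond = isTRUE(per_bond)),
    class = "transform_rule"
  )
}

#' Built-in transform rules
#'
#' The condensation and coupling chemistries of the divergent-synthesis
#' campaign: urea and thiourea formation (pure additions), imine condensation
#' (loss of one water per C=N bond formed), Sonogashira coupling with an aryl
#' bromide (loss of HBr) and CuAAC click addition (no delta).
#'
#' @return A named list of `transform_rule` objects.
#' @export
standard_rules <- function() {
  list(
    urea = transform_rule("urea", c("alkyne_amine", "isocyanate")),
    thiourea = transform_rule("thiourea", c("alkyne_amine", "isothiocyanate")),
    imine = transform_rule("imine", c("polytopic_amine", "carbonyl_pyridine"),
                           loss = "H2O", per_bond = TRUE),
    sonogashira = transform_rule("sonogashira", c("product", "aryl_halide"),
                                 loss = "HBr"),
    cuaac = transform_rule("cuaac", c("product", "azide"))
  )
}

#' Apply a transform rule to reactants
#'
#' Forms the product species: formula = sum of reactant formulas + the rule's
#' delta (times the bond count for per-bond rules). Reactant roles must match
#' the rule's `reactant_roles` in order (`"product"` matches any species that
#' itself came out of a transform). Provenance (the reactant ids and the rule
#' name) is recorded on the product.
#'
#' @param rule A `transform_rule`.
#' @param reactants List of `building_block`s and/or earlier `species`
#'   products.
#' @param bonds Number of condensation bonds for `per_bond` rules; defaults
#'   to the topicity of the first polytopic reactant.
#' @return A `species` object with fields `id`, `formula`, `mass`,
#'   `provenance`.
#' @examples
#' rules <- standard_rules()
#' am <- building_block("1", "alkyne_amine", "C3H5N")
#' iso <- building_block("5", "isocyanate", "C7H5NO")
#' apply_transform(rules$urea, list(am, iso))
#' @export
apply_transform <- function(rule, reactants, bonds = NULL) {
  stopifnot(inherits(rule, "transform_rule"))
  roles <- vapply(reactants, .species_role, character(1))
  want <- rule$reactant_roles
  if (length(roles) != length(want) ||
      !all(roles == want | want == "product")) {
    stop("reactant roles (", paste(roles, collapse = ", "),
         ") do not match rule ", sQuote(rule$name), " (",
         paste(want, collapse = ", "), ")")
  }
  total <- Reduce(fml_add, lapply(reactants, .species_formula))
  if (is.null(bonds)) {
    tops <- vapply(reactants, function(r) {
      if (inherits(r, "building_block")) r$topicity else 0L
    }, integer(1))
    bonds <- if (any(tops > 0L)) max(tops) else 1L
  }
  n_apply <- if (rule$per_bond) bonds else 1L
  if (!is.null(rule$gain)) {
    total <- Reduce(fml_add, c(list(total), rep(list(rule$gain), n_apply)))
  }
  if (!is.null(rule$loss)) {
    for (i in seq_len(n_apply)) total <- fml_subtract(total, rule$loss)
  }
  ids <- vapply(reactants, .species_id, character(1))
  structure(
    list(id = paste(ids, collapse = "+"),
         formula = total,
         mass = formula_mass(total),
         provenance = list(rule = rule$name, reactants = ids, bonds = bonds)),
    class = "species"
  )
}

.species_role <- function(x) {
  if (inherits(x, "building_block")) x$role else "product"
}
.species_formula <- function(x) x$formula
.species_id <- function(x) x$id

#' @export
print.species <- function(x, ...) {
  cat("<species> ", x$id, "  ", format(x$formula), "  ",
      sprintf("%.4f Da", x$mass), "\n", sep = "")
  invisible(x)
}

#' Enumerate a divergent synthetic route
#'
#' Builds the full combinatorial route graph: stage 1 crosses seed building
#' blocks with partner blocks under each listed rule branch; every later stage
#' crosses all products of the previous stage with that stage's partners. The
#' result records every species formed, with per-stage counts and full
#' provenance, as an acyclic graph.
#'
#' @param blocks List of `building_block`s (ids must be unique).
#' @param stages List of stages; each stage is a list of branches, each branch
#'   `list(rule = <transform_rule>, partner_role = <role>)` (or
#'   `partner_ids =` to restrict to specific blocks). Stage 1 branches must
#'   name their seed role as the first element of the rule's reactant roles.
#' @return A `route_graph` with `nodes` (data.frame: id, stage, formula, mass,
#'   rule) and `edges` (data.frame: from, to, rule).
#' @examples
#' rules <- standard_rules()
#' blocks <- list(
#'   building_block("1", "alkyne_amine", "C3H5N"),
#'   building_block("5", "isocyanate", "C7H5NO")
#' )
#' enumerate_route(blocks, list(list(list(rule = rules$urea,
#'                                        partner_role = "isocyanate"))))
#' @export
enumerate_route <- function(blocks, stages) {
  ids <- vapply(blocks, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate building-block ids")
  names(blocks) <- ids
  by_role <- split(blocks, vapply(blocks, `[[`, character(1), "role"))

  pick_partners <- function(branch) {
    if (!is.null(branch$partner_ids)) {
      missing <- setdiff(branch$partner_ids, ids)
      if (length(missing)) stop("unknown partner id(s): ",
                                paste(missing, collapse = ", "))
      return(blocks[branch$partner_ids])
    }
    got <- by_role[[branch$partner_role]]
    if (is.null(got) || !length(got)) {
      stop("no building blocks with role ", sQuote(branch$partner_role))
    }
    got
  }

  nodes <- list(); edges <- list()
  current <- NULL # species carried into the next stage
  for (k in seq_along(stages)) {
    stage <- stages[[k]]
    produced <- list()
    for (branch in stage) {
      rule <- branch$rule
      partners <- pick_partners(branch)
      seeds <- if (k == 1L) {
        seed_role <- rule$reactant_roles[[1L]]
        got <- by_role[[seed_role]]
        if (is.null(got) || !length(got)) {
          stop("no building blocks with role ", sQuote(seed_role))
        }
        got
      } else {
        current
      }
      for (s in seeds) for (p in partners) {
        prod <- apply_transform(rule, list(s, p))
        produced[[length(produced) + 1L]] <- prod
        nodes[[length(nodes) + 1L]] <- data.frame(
          id = prod$id, stage = k, formula = format(prod$formula),
          mass = prod$mass, rule = rule$name, stringsAsFactors = FALSE)
        edges[[length(edges) + 1L]] <- data.frame(
          from = c(.species_id(s), .species_id(p)), to = prod$id,
          rule = rule$name, stringsAsFactors = FALSE)
      }
    }
    current <- produced
  }
  structure(
    list(nodes = do.call(rbind, nodes), edges = do.call(rbind, edges),
         species = current, n_stages = length(stages)),
    class = "route_graph"
  )
}

#' Per-stage product counts of a route graph
#' @param graph A `route_graph`.
#' @return Integer vector, one count per stage.
#' @export
route_stage_counts <- function(graph) {
  stopifnot(inherits(graph, "route_graph"))
  as.integer(table(factor(graph$nodes$stage, levels = seq_len(graph$n_stages))))
}

#' Terminal products of a route graph
#' @param graph A `route_graph`.
#' @return List of `species` produced by the final stage.
#' @export
route_products <- function(graph) {
  stopifnot(inherits(graph, "route_graph"))
  graph$species
}

#' @export
print.route_graph <- function(x, ...) {
  counts <- route_stage_counts(x)
  cat("<route graph> ", x$n_stages, " stage(s); products per stage: ",
      paste(counts, collapse = ", "), "\n", sep = "")
  invisible(x)
}
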