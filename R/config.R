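#' Read and validate a campaign configuration
#'
#' Campaign YAML schema (all sections validated, all cross-references
#' resolved):
#'
#' ```yaml
#' campaign:
#'   type: supramolecular        # or divergent
#'   replicate_count: 6
#'   replicate_rule: all         # or majority
#'   guests: [g1, g2, g3]
#'   diversifications: [sonogashira, cuaac]
#' blocks:
#'   - {id: "24", role: carbonyl_pyridine, formula: C6H5NO}
#'   - {id: "28", role: polytopic_amine, formula: C6H18N4, topicity: 3}
#'   - {id: Zn,   role: metal_ion, formula: Zn+2, capacity: 3}
#'   - {id: OTf,  role: counterion, formula: CF3O3S-1}
#' assembly:
#'   counterion: OTf
#'   max_metals: {Zn: 10, Cu: 12}
#'   include_mononuclear: true
#' thresholds:
#'   change_threshold: 0.009
#'   parity_threshold: 0.006
#'   tol: 0.5
#' masks:
#'   - [3.2, 3.4]
#' ```
#'
#' @param path YAML file path.
#' @return A `campaign_config`: list with `campaign`, `blocks` (named list
#'   of `building_block`s), `assembly`, `thresholds`, `masks` and `hash`
#'   (MD5 of the semantic content).
#' @export
read_campaign_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  if (is.null(raw$blocks) || !length(raw$blocks)) note("blocks: empty")
  blocks <- list()
  for (b in raw$blocks %||% list()) {
    if (is.null(b$id) || is.null(b$role) || is.null(b$formula)) {
      note("blocks: each entry needs id, role, formula")
      next
    }
    bb <- tryCatch(
      building_block(b$id, b$role, b$formula,
                     topicity = b$topicity %||% 0L,
                     charge = b$charge,
                     capacity = b$capacity),
      error = function(e) {
        note("blocks[", b$id, "]: ", conditionMessage(e))
        NULL
      })
    if (!is.null(bb)) {
      if (bb$id %in% names(blocks)) note("blocks: duplicate id ", bb$id)
      blocks[[bb$id]] <- bb
    }
  }

  camp <- raw$campaign %||% list()
  type <- camp$type %||% "divergent"
  if (!type %in% c("divergent", "supramolecular")) {
    note("campaign.type: must be divergent or supramolecular")
  }
  for (g in camp$guests %||% character(0)) {
    if (!g %in% names(blocks)) note("campaign.guests: unknown block ", g)
  }

  assembly <- raw$assembly %||% list()
  if (type == "supramolecular") {
    ci <- assembly$counterion
    if (is.null(ci)) {
      note("assembly.counterion: required (no default chemical identity)")
    } else if (!ci %in% names(blocks)) {
      note("assembly.counterion: unknown block ", ci)
    }
    for (mid in names(assembly$max_metals %||% list())) {
      if (!mid %in% names(blocks)) {
        note("assembly.max_metals: unknown metal ", mid)
      }
    }
  }

  masks <- lapply(raw$masks %||% list(), function(mk) {
    mk <- as.numeric(mk)
    if (length(mk) != 2L || mk[1] >= mk[2]) note("masks: need [lo, hi] pairs")
    mk
  })

  if (length(problems)) {
    stop("invalid campaign config ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }

  cfg <- list(campaign = list(
                type = type,
                replicate_count = as.integer(camp$replicate_count %||% 6L),
                replicate_rule = camp$replicate_rule %||% "all",
                guests = as.character(camp$guests %||% character(0)),
                diversifications =
                  as.character(camp$diversifications %||% character(0))),
              blocks = blocks,
              assembly = assembly,
              thresholds = raw$thresholds %||% list(),
              masks = masks)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "campaign_config"
  cfg
}

#' Hash of the semantic content of a configuration
#'
#' MD5 over the canonical JSON serialization of the configuration (block
#' definitions, stage thresholds, assembly parameters, masks). Any semantic
#' change to the configuration changes the hash; it is recorded with every
#' decision-log line so logged decisions stay attributable to the exact
#' rule set that produced them.
#'
#' @param cfg A `campaign_config` or plain list.
#' @return Hex MD5 string.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  canon <- rapply(unclass(cfg), function(x) {
    if (inherits(x, "chem_formula")) format(x) else x
  }, how = "replace", classes = "ANY")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = 12,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf("<campaign config> %s, %d block(s), hash %s\n",
              x$campaign$type, length(x$blocks), substr(x$hash, 1, 8)))
  invisible(x)
}
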