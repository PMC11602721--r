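.STAGES <- c("screen", "scaleup_parity", "replicate", "diversify",
             "guest_assay")
.NMR_MODES <- c("dtw", "peak_count", "shift_perturbation", "none")
.MS_MODES <- c("targeted", "assembly_table", "none")

#' Per-stage decision criteria
#'
#' The rule bundle for one campaign stage: which NMR heuristic and which MS
#' heuristic apply, their threshold parameters, and how the two orthogonal
#' verdicts combine. The default combination is a strict AND: a reaction is
#' a hit only if it passes both analyses. A weighted combination
#' (w_nmr * s_nmr + w_ms * s_ms >= 1 over the applicable branches, each
#' score 0 or 1) is available; the default weights of one half each make it
#' identical to AND.
#'
#' @param stage One of `screen`, `scaleup_parity`, `replicate`, `diversify`,
#'   `guest_assay`.
#' @param nmr_mode One of `dtw`, `peak_count`, `shift_perturbation`, `none`.
#' @param ms_mode One of `targeted`, `assembly_table`, `none`.
#' @param thresholds Named list of stage parameters (passed through to the
#'   analysis functions by the campaign driver).
#' @param combine `"AND"` or `"weighted"`.
#' @param weights Length-2 numeric `c(nmr, ms)` for weighted combination.
#' @return A `stage_criteria`.
#' @export
stage_criteria <- function(stage, nmr_mode = "dtw", ms_mode = "targeted",
                           thresholds = list(), combine = c("AND", "weighted"),
                           weights = c(nmr = 0.5, ms = 0.5)) {
  stage <- match.arg(stage, .STAGES)
  nmr_mode <- match.arg(nmr_mode, .NMR_MODES)
  ms_mode <- match.arg(ms_mode, .MS_MODES)
  combine <- match.arg(combine)
  if (nmr_mode == "none" && ms_mode == "none") {
    stop("at least one of nmr_mode/ms_mode must be active")
  }
  structure(list(stage = stage, nmr_mode = nmr_mode, ms_mode = ms_mode,
                 thresholds = thresholds, combine = combine,
                 weights = weights),
            class = "stage_criteria")
}

#' Grade one reaction at one stage
#'
#' Combines the binary NMR and MS verdicts for a reaction into the overall
#' stage decision. Each piece of evidence is any object with a logical
#' `passed` element (the outputs of [chemical_change()], [parity_check()],
#' [symmetric_product_test()], [guest_binding_test()], [match_targeted()],
#' [match_assembly_table()] all qualify). A branch whose mode is `none` is
#' not applicable and does not constrain the outcome; a branch with an
#' active mode but missing evidence is an error.
#'
#' @param reaction_id Reaction identifier.
#' @param nmr,ms Evidence objects (or `NULL` where the mode is `none`).
#' @param criteria A `stage_criteria`.
#' @return A `stage_decision`: reaction_id, stage, nmr_pass, ms_pass (logical
#'   or `NA` where not applicable), overall, evidence, timestamp.
#' @export
grade <- function(reaction_id, nmr = NULL, ms = NULL, criteria) {
  stopifnot(inherits(criteria, "stage_criteria"))
  get_pass <- function(mode, evidence, branch) {
    if (mode == "none") return(NA)
    if (is.null(evidence)) {
      stop("criteria require ", branch, " evidence (mode ", sQuote(mode),
           ") but none was supplied")
    }
    if (is.null(evidence$passed) || !is.logical(evidence$passed)) {
      stop(branch, " evidence must carry a logical 'passed' element")
    }
    isTRUE(evidence$passed)
  }
  nmr_pass <- get_pass(criteria$nmr_mode, nmr, "NMR")
  ms_pass <- get_pass(criteria$ms_mode, ms, "MS")
  applicable <- c(nmr = !is.na(nmr_pass), ms = !is.na(ms_pass))
  scores <- c(nmr = isTRUE(nmr_pass), ms = isTRUE(ms_pass))
  overall <- if (criteria$combine == "AND") {
    all(scores[applicable])
  } else {
    w <- criteria$weights[c("nmr", "ms")]
    w <- w[applicable] / sum(w[applicable]) # renormalize over active branches
    sum(w * scores[applicable]) >= 1 - 1e-12
  }
  structure(list(reaction_id = as.character(reaction_id),
                 stage = criteria$stage, nmr_pass = nmr_pass,
                 ms_pass = ms_pass, overall = overall,
                 evidence = list(nmr = nmr, ms = ms),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")),
            class = "stage_decision")
}

#' @export
print.stage_decision <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "n/a" else if (p) "pass" else "fail"
  cat(sprintf("<decision> %s @ %s: NMR %s, MS %s => %s\n", x$reaction_id,
              x$stage, fmt(x$nmr_pass), fmt(x$ms_pass),
              if (x$overall) "HIT" else "FAIL"))
  invisible(x)
}

#' Campaign definitions
#'
#' A staged campaign: its type (`divergent` goes screen -> scale-up parity ->
#' diversification; `supramolecular` goes screen -> replication -> guest
#' assay), the per-stage criteria, the replicate count, the configured
#' diversification branches and the guest library. The decision log is
#' append-only.
#'
#' @param type `"divergent"` or `"supramolecular"`.
#' @param criteria Named list of `stage_criteria` keyed by stage.
#' @param replicate_count Replicates per screening hit (default 6).
#' @param diversifications Character vector of diversification branch labels.
#' @param guests Character vector of guest ids.
#' @param replicate_rule `"all"` (every replicate must pass) or
#'   `"majority"`.
#' @return A `campaign`.
#' @export
campaign <- function(type = c("divergent", "supramolecular"),
                     criteria = list(), replicate_count = 6L,
                     diversifications = character(0),
                     guests = character(0),
                     replicate_rule = c("all", "majority")) {
  type <- match.arg(type)
  replicate_rule <- match.arg(replicate_rule)
  structure(list(type = type, criteria = criteria,
                 replicate_count = as.integer(replicate_count),
                 diversifications = diversifications, guests = guests,
                 replicate_rule = replicate_rule, log = list()),
            class = "campaign")
}

#' Plan the next experimental stage
#'
#' Translates the decisions of the current stage into the instruction list
#' for the synthesis platform: screening hits are scaled up (divergent
#' campaigns) or replicated `replicate_count` times each (supramolecular);
#' scale-up-parity hits spawn every configured diversification; replication
#' hits (aggregated per [aggregate_replicates()]) spawn one guest-binding
#' assay per guest. Failed reactions generate no instructions.
#'
#' @param campaign A `campaign`.
#' @param decisions List of `stage_decision`s, all from the same stage.
#' @return An `instruction_list` data.frame: action, reaction_id, detail.
#' @export
plan_next <- function(campaign, decisions) {
  stopifnot(inherits(campaign, "campaign"))
  if (!length(decisions)) {
    return(.instruction_df())
  }
  stages <- unique(vapply(decisions, `[[`, character(1), "stage"))
  if (length(stages) != 1L) {
    stop("decisions span multiple stages: ", paste(stages, collapse = ", "))
  }
  stage <- stages
  if (!stage %in% .STAGES) stop("unknown stage ", sQuote(stage))
  hits <- Filter(function(d) isTRUE(d$overall), decisions)
  rows <- list()
  add <- function(action, id, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(
      action = action, reaction_id = id, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (stage == "screen") {
    for (d in hits) {
      if (campaign$type == "divergent") {
        add("scale_up", d$reaction_id, "")
      } else {
        for (r in seq_len(campaign$replicate_count)) {
          add("replicate", d$reaction_id, paste0("replicate_", r))
        }
      }
    }
  } else if (stage == "scaleup_parity") {
    for (d in hits) for (dv in campaign$diversifications) {
      add("diversify", d$reaction_id, dv)
    }
  } else if (stage == "replicate") {
    for (d in hits) for (g in campaign$guests) {
      add("guest_assay", d$reaction_id, g)
    }
  } else {
    # diversify / guest_assay are terminal stages: nothing to plan
  }
  out <- if (length(rows)) do.call(rbind, rows) else .instruction_df()
  structure(out, class = c("instruction_list", "data.frame"))
}

.instruction_df <- function() {
  structure(data.frame(action = character(0), reaction_id = character(0),
                       detail = character(0), stringsAsFactors = FALSE),
            class = c("instruction_list", "data.frame"))
}

#' Aggregate replicate decisions per parent reaction
#'
#' Collapses the per-replicate stage decisions into one decision per parent
#' reaction, under the all-pass rule (default) or majority voting.
#'
#' @param decisions List of replicate-stage `stage_decision`s whose
#'   reaction ids are `<parent>:<replicate>`.
#' @param rule `"all"` or `"majority"`.
#' @return List of synthetic `stage_decision`s, one per parent, stage
#'   `"replicate"`.
#' @export
aggregate_replicates <- function(decisions, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (!length(decisions)) return(list())
  parents <- sub(":[^:]*$", "", vapply(decisions, `[[`, character(1),
                                       "reaction_id"))
  out <- list()
  for (p in unique(parents)) {
    ok <- vapply(decisions[parents == p], `[[`, logical(1), "overall")
    passed <- if (rule == "all") all(ok) else mean(ok) > 0.5
    out[[length(out) + 1L]] <- structure(
      list(reaction_id = p, stage = "replicate", nmr_pass = NA,
           ms_pass = NA, overall = passed,
           evidence = list(replicate_overall = ok),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")),
      class = "stage_decision")
  }
  out
}

#' Host-guest binding matrix
#'
#' Assembles the grid of per-pair guest-binding verdicts into a boolean
#' hosts x guests matrix with per-host bound-guest counts. The grid must be
#' complete: any missing (host, guest) cell is an error naming the cells.
#'
#' @param assays data.frame with columns `host`, `guest`, `bound` (logical),
#'   one row per pair.
#' @param hosts,guests Expected row/column ids (default: those present).
#' @return List with `matrix` (logical, hosts x guests) and `bound_counts`
#'   (named integer row sums).
#' @export
binding_matrix <- function(assays, hosts = unique(assays$host),
                           guests = unique(assays$guest)) {
  stopifnot(all(c("host", "guest", "bound") %in% names(assays)))
  want <- expand.grid(host = hosts, guest = guests,
                      stringsAsFactors = FALSE)
  key <- function(h, g) paste(h, g, sep = "\r")
  have <- key(assays$host, assays$guest)
  missing <- !key(want$host, want$guest) %in% have
  if (any(missing)) {
    stop("missing binding assay cell(s): ",
         paste(paste0("(", want$host[missing], ", ", want$guest[missing],
                      ")"), collapse = ", "))
  }
  m <- matrix(FALSE, length(hosts), length(guests),
              dimnames = list(hosts, guests))
  for (i in seq_len(nrow(assays))) {
    if (assays$host[i] %in% hosts && assays$guest[i] %in% guests) {
      m[assays$host[i], assays$guest[i]] <- isTRUE(assays$bound[i])
    }
  }
  list(matrix = m, bound_counts = rowSums(m))
}

#' Append decisions to a JSONL log
#'
#' Writes one JSON line per decision (reaction, stage, verdicts, an evidence
#' digest and the campaign config hash), append-only, so an entire campaign
#' remains traceable including its failed reactions.
#'
#' @param decisions List of `stage_decision`s.
#' @param path Log file path (created if absent).
#' @param config_hash Hash string identifying the campaign configuration.
#' @return `path`, invisibly.
#' @export
log_decisions <- function(decisions, path, config_hash = "") {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (d in decisions) {
    rec <- list(reaction_id = d$reaction_id, stage = d$stage,
                nmr_pass = if (is.na(d$nmr_pass)) "n/a" else d$nmr_pass,
                ms_pass = if (is.na(d$ms_pass)) "n/a" else d$ms_pass,
                overall = d$overall,
                evidence_digest = .evidence_digest(d$evidence),
                config_hash = config_hash, timestamp = d$timestamp)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

.evidence_digest <- function(evidence) {
  ev <- rapply(evidence, function(x) {
    if (is.numeric(x)) signif(x, 10) else x
  }, how = "replace")
  ev$nmr$evidence <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = 10,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
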