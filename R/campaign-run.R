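#' Default stage criteria for the two campaign types
#'
#' Divergent campaigns grade screening and scale-up by DTW chemical change /
#' parity plus targeted MS, and diversification by MS alone (low-field 1H
#' spectra of the elaborated products are too congested to grade).
#' Supramolecular campaigns grade screening by the symmetric-product peak
#' count plus the assembly lookup table, replication by NMR parity plus the
#' table, and the guest assay by chemical-shift perturbation alone.
#'
#' @param thresholds Named list of threshold overrides merged over the
#'   defaults (`change_threshold`, `parity_threshold`, `tol`,
#'   `rel_area_min`, `count_tolerance`, `shift_min`, `lb`,
#'   `min_charge_states`, ...).
#' @return Named list of `stage_criteria`.
#' @export
divergent_criteria <- function(thresholds = list()) {
  th <- utils::modifyList(
    list(change_threshold = 0.009, parity_threshold = 0.006, tol = 0.5,
         rel_area_min = 0.10, rel_intensity_min = 0.02), thresholds)
  list(
    screen = stage_criteria("screen", "dtw", "targeted", th),
    scaleup_parity = stage_criteria("scaleup_parity", "dtw", "targeted", th),
    diversify = stage_criteria("diversify", "none", "targeted", th)
  )
}

#' @rdname divergent_criteria
#' @export
supramolecular_criteria <- function(thresholds = list()) {
  th <- utils::modifyList(
    list(change_threshold = 0.009, parity_threshold = 0.006, tol = 0.5,
         count_tolerance = 2, shift_min = 0.02, min_shifted_frac = 0.5,
         lb = 10, aromatic_window = c(6.0, 9.5), min_charge_states = 2L,
         rel_intensity_min = 0.02, height_min = 0.1,
         min_separation = 0.05), thresholds)
  list(
    screen = stage_criteria("screen", "peak_count", "assembly_table", th),
    replicate = stage_criteria("replicate", "dtw", "assembly_table", th),
    guest_assay = stage_criteria("guest_assay", "shift_perturbation",
                                 "none", th)
  )
}

#' Run a full campaign over a dataset bundle
#'
#' Drives every stage of the decision-maker over a (typically synthetic)
#' campaign bundle: grades each screening reaction from its NMR and MS
#' evidence, plans the follow-up experiments for the hits, grades those, and
#' so on to the terminal stage. All decisions are logged (append-only JSONL)
#' when `log_path` is given; reactions that fail generate no follow-up but
#' are still logged.
#'
#' @param bundle A `campaign_bundle` from [gen_campaign()].
#' @param criteria Named list of `stage_criteria`; defaults per bundle type.
#' @param log_path Optional JSONL decision-log path.
#' @param config_hash Hash recorded with each log line.
#' @return A `campaign_result`: per-stage decisions, instruction lists and
#'   (supramolecular) the binding matrix.
#' @export
run_campaign <- function(bundle, criteria = NULL, log_path = NULL,
                         config_hash = "") {
  stopifnot(inherits(bundle, "campaign_bundle"))
  if (bundle$type == "divergent") {
    .run_divergent(bundle, criteria %||% divergent_criteria(), log_path,
                   config_hash)
  } else {
    .run_supramolecular(bundle, criteria %||% supramolecular_criteria(),
                        log_path, config_hash)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_maybe <- function(decisions, log_path, config_hash) {
  if (!is.null(log_path)) log_decisions(decisions, log_path, config_hash)
}

.run_divergent <- function(bundle, criteria, log_path, config_hash) {
  th <- criteria$screen$thresholds
  pp <- lapply(bundle$sm_spectra, nmr_preprocess)
  camp <- campaign("divergent", criteria,
                   diversifications = names(bundle$diversifications))

  screen <- list()
  screen_pp <- list()
  for (rid in names(bundle$reactions)) {
    rx <- bundle$reactions[[rid]]
    ref <- combine_references(pp[rx$sm_ids])
    rxn_pp <- nmr_preprocess(rx$nmr)
    screen_pp[[rid]] <- rxn_pp
    nmr_ev <- chemical_change(rxn_pp, ref,
                              threshold = th$change_threshold)
    expected <- adduct_mz(rx$product)
    names(expected)[names(expected) == "adduct"] <- "label"
    ms_ev <- match_targeted(rx$lcms, expected, tol = th$tol,
                            rel_area_min = th$rel_area_min,
                            rel_intensity_min = th$rel_intensity_min)
    screen[[rid]] <- grade(rid, nmr_ev, ms_ev, criteria$screen)
  }
  .log_maybe(screen, log_path, config_hash)
  scaleup_instr <- plan_next(camp, screen)

  parity <- list()
  for (rid in scaleup_instr$reaction_id) {
    rx <- bundle$reactions[[rid]]
    if (is.null(rx$scaleup_nmr)) {
      stop("no scale-up measurement available for ", rid)
    }
    su_pp <- nmr_preprocess(rx$scaleup_nmr)
    nmr_ev <- parity_check(screen_pp[[rid]], su_pp,
                           parity_threshold = th$parity_threshold,
                           change_threshold = th$change_threshold)
    expected <- adduct_mz(rx$product)
    names(expected)[names(expected) == "adduct"] <- "label"
    ms_ev <- match_targeted(rx$scaleup_lcms, expected, tol = th$tol,
                            rel_area_min = th$rel_area_min,
                            rel_intensity_min = th$rel_intensity_min)
    parity[[rid]] <- grade(rid, nmr_ev, ms_ev, criteria$scaleup_parity)
  }
  .log_maybe(parity, log_path, config_hash)
  diversify_instr <- plan_next(camp, parity)

  diversify <- list()
  for (i in seq_len(nrow(diversify_instr))) {
    key <- paste0(diversify_instr$reaction_id[i], ":",
                  diversify_instr$detail[i])
    dv <- bundle$diversify_runs[[key]]
    if (is.null(dv)) next # measurement not available in this bundle
    expected <- adduct_mz(dv$product)
    names(expected)[names(expected) == "adduct"] <- "label"
    ms_ev <- match_targeted(dv$lcms, expected, tol = th$tol,
                            rel_area_min = th$rel_area_min,
                            rel_intensity_min = th$rel_intensity_min)
    diversify[[key]] <- grade(key, nmr = NULL, ms = ms_ev,
                              criteria$diversify)
  }
  .log_maybe(diversify, log_path, config_hash)

  structure(
    list(type = "divergent",
         decisions = list(screen = screen, scaleup_parity = parity,
                          diversify = diversify),
         instructions = list(scale_up = scaleup_instr,
                             diversify = diversify_instr),
         screen_hits = names(Filter(function(d) d$overall, screen)),
         diversify_hits = names(Filter(function(d) d$overall, diversify))),
    class = "campaign_result")
}

.run_supramolecular <- function(bundle, criteria, log_path, config_hash) {
  th <- criteria$screen$thresholds
  pp <- lapply(bundle$sm_spectra, nmr_preprocess)
  sm_picked <- lapply(pp, pick_peaks, height_min = th$height_min,
                      min_separation = th$min_separation)
  camp <- campaign("supramolecular", criteria, guests = bundle$guest_ids)

  screen <- list()
  screen_pp <- list()
  for (rid in names(bundle$reactions)) {
    rx <- bundle$reactions[[rid]]
    rxn_pp <- nmr_preprocess(rx$nmr)
    screen_pp[[rid]] <- rxn_pp
    rxn_peaks <- pick_peaks(rxn_pp, height_min = th$height_min,
                            min_separation = th$min_separation)
    nmr_ev <- symmetric_product_test(
      rxn_peaks, sm_picked[rx$sm_ids[1:2]],
      count_tolerance = th$count_tolerance, shift_min = th$shift_min,
      min_shifted_frac = th$min_shifted_frac)
    ms_ev <- match_assembly_table(
      average_spectrum(rx$lcms), bundle$lookup_table, tol = th$tol,
      min_charge_states = th$min_charge_states,
      rel_intensity_min = th$rel_intensity_min)
    screen[[rid]] <- grade(rid, nmr_ev, ms_ev, criteria$screen)
  }
  .log_maybe(screen, log_path, config_hash)
  replicate_instr <- plan_next(camp, screen)

  rep_decisions <- list()
  for (i in seq_len(nrow(replicate_instr))) {
    rid <- replicate_instr$reaction_id[i]
    rep_id <- replicate_instr$detail[i]
    r <- as.integer(sub("replicate_", "", rep_id))
    rep <- bundle$replicates[[rid]][[r]]
    if (is.null(rep)) stop("no replicate measurement for ", rid, " #", r)
    nmr_ev <- parity_check(screen_pp[[rid]], nmr_preprocess(rep$nmr),
                           parity_threshold = th$parity_threshold,
                           change_threshold = th$change_threshold)
    ms_ev <- match_assembly_table(
      average_spectrum(rep$lcms), bundle$lookup_table, tol = th$tol,
      min_charge_states = th$min_charge_states,
      rel_intensity_min = th$rel_intensity_min)
    key <- paste0(rid, ":", rep_id)
    rep_decisions[[key]] <- grade(key, nmr_ev, ms_ev, criteria$replicate)
  }
  .log_maybe(rep_decisions, log_path, config_hash)
  aggregated <- aggregate_replicates(rep_decisions, camp$replicate_rule)
  assay_instr <- plan_next(camp, aggregated)

  assay_decisions <- list(); assay_rows <- list()
  for (i in seq_len(nrow(assay_instr))) {
    host <- assay_instr$reaction_id[i]
    guest <- assay_instr$detail[i]
    mix <- bundle$guest_assays[[host]][[guest]]
    if (is.null(mix)) stop("no guest-assay spectrum for ", host, " + ", guest)
    ev <- guest_binding_test(screen_pp[[host]], nmr_preprocess(mix),
                             window = th$aromatic_window, lb = th$lb,
                             shift_min = th$shift_min,
                             height_min = th$height_min,
                             min_separation = th$min_separation)
    key <- paste0(host, "+", guest)
    assay_decisions[[key]] <- grade(key, nmr = ev, ms = NULL,
                                    criteria$guest_assay)
    assay_rows[[key]] <- data.frame(host = host, guest = guest,
                                    bound = ev$passed,
                                    stringsAsFactors = FALSE)
  }
  .log_maybe(assay_decisions, log_path, config_hash)
  binding <- if (length(assay_rows)) {
    binding_matrix(do.call(rbind, assay_rows))
  } else {
    NULL
  }

  structure(
    list(type = "supramolecular",
         decisions = list(screen = screen, replicate = rep_decisions,
                          replicate_aggregated = aggregated,
                          guest_assay = assay_decisions),
         instructions = list(replicate = replicate_instr,
                             guest_assay = assay_instr),
         screen_hits = names(Filter(function(d) d$overall, screen)),
         binding = binding),
    class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat("<campaign result> ", x$type, "\n", sep = "")
  for (st in names(x$decisions)) {
    ds <- x$decisions[[st]]
    n_hit <- sum(vapply(ds, function(d) isTRUE(d$overall), logical(1)))
    cat("  ", st, ": ", n_hit, "/", length(ds), " pass\n", sep = "")
  }
  if (!is.null(x$binding)) {
    cat("  bound guests per host: ",
        paste(names(x$binding$bound_counts), x$binding$bound_counts,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
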