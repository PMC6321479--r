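# Evidence aggregation: combines per-modality results into the two headline
# verdicts for a candidate domain — is it disordered, and does it
# self-associate?

.evidence_item <- function(modality, verdict, detail, payload = list()) {
  list(modality = modality, verdict = verdict, detail = detail,
       payload = payload)
}

#' Aggregate modality results into disorder and oligomerization verdicts
#'
#' Disorder rules: the denaturation verdict must be non-cooperative; when
#' DOSY is present, the measured Stokes radius must fall inside the
#' unfolded-scaling prediction band and above the folded-scaling upper
#' bound; when SAXS is present, the Flory exponent must classify in the
#' globule-to-coil range with Rg above the hydrated-sphere prediction.
#' All available probes must agree for "IDP-like"; if all point the other
#' way the verdict is "folded-like"; contradictions yield "mixed evidence",
#' never a silent resolution. Oligomerization: "self-associating" fires
#' when any oligomer assignment has order >= 2, or the Ksv trend flags
#' self-association, or the ITC fit shows dissociation heats.
#'
#' @param seq_report A [sequence_report()] (required when `dosy_rs` or
#'   `saxs` evidence is supplied; provides the radius reference frame).
#' @param denaturation A [classify_denaturation()] verdict.
#' @param dosy_rs Measured Stokes radius, Angstrom (e.g. from
#'   [rs_from_reference()]).
#' @param saxs A [fit_ggc()] result (or list with `rg` and `nu`).
#' @param quenching A [ksv_trend()] result.
#' @param oligomers List of [oligomer_order()] assignments.
#' @param itc A [fit_dimer_dissociation()] result.
#' @return An object of class `evidence_report` with `disorder_verdict`,
#'   `oligomer_verdict` and the itemized `evidence` list.
#' @export
build_report <- function(seq_report = NULL, denaturation = NULL,
                         dosy_rs = NULL, saxs = NULL, quenching = NULL,
                         oligomers = NULL, itc = NULL) {
  if (is.null(denaturation) && is.null(dosy_rs) && is.null(saxs) &&
      is.null(quenching) && is.null(oligomers) && is.null(itc))
    stop("no module reports supplied")
  items <- list()

  # -- disorder evidence --------------------------------------------------
  if (!is.null(denaturation)) {
    stopifnot(inherits(denaturation, "denaturation_verdict"))
    v <- switch(denaturation$verdict,
                "non-cooperative (IDP-like)" = "supports_disorder",
                "cooperative" = "supports_order",
                "neutral")
    items <- c(items, list(.evidence_item(
      "denaturation", v, paste("two-state fits:", denaturation$verdict),
      list(verdict = denaturation$verdict))))
  }
  if (!is.null(dosy_rs)) {
    if (is.null(seq_report))
      stop("dosy_rs evidence needs a sequence_report reference frame")
    unf <- seq_report$radii$unfolded; fol <- seq_report$radii$folded
    v <- if (dosy_rs >= unf$lower && dosy_rs <= unf$upper &&
             dosy_rs > fol$upper) "supports_disorder"
    else if (dosy_rs >= fol$lower && dosy_rs <= fol$upper &&
             dosy_rs < unf$lower) "supports_order"
    else "neutral"
    items <- c(items, list(.evidence_item(
      "dosy", v,
      sprintf("measured Rs %.1f A vs folded [%.1f, %.1f] / unfolded [%.1f, %.1f]",
              dosy_rs, fol$lower, fol$upper, unf$lower, unf$upper),
      list(rs = dosy_rs))))
  }
  if (!is.null(saxs)) {
    if (is.null(seq_report))
      stop("saxs evidence needs a sequence_report reference frame")
    rg <- saxs$rg; nu <- saxs$nu
    cls <- classify_compaction(nu)$class
    hyd <- seq_report$radii$hydrated$value
    v <- if (cls %in% c("globule", "theta_coil") && rg > hyd)
      "supports_disorder"
    else if (rg <= hyd) "supports_order"
    else "neutral"
    items <- c(items, list(.evidence_item(
      "saxs", v,
      sprintf("Rg %.1f A (%s, nu = %.2f) vs hydrated sphere %.1f A",
              rg, cls, nu, hyd),
      list(rg = rg, nu = nu, class = cls))))
  }

  # -- oligomerization evidence -------------------------------------------
  if (!is.null(oligomers)) {
    if (inherits(oligomers, "oligomer_assignment")) oligomers <- list(oligomers)
    for (o in oligomers) {
      stopifnot(inherits(o, "oligomer_assignment"))
      items <- c(items, list(.evidence_item(
        o$source, if (o$order >= 2) "supports_oligomer" else "neutral",
        sprintf("apparent %.3g kDa -> order %d", o$apparent_mass, o$order),
        list(order = o$order, apparent_mass = o$apparent_mass))))
    }
  }
  if (!is.null(quenching)) {
    stopifnot(inherits(quenching, "ksv_trend"))
    items <- c(items, list(.evidence_item(
      "quenching",
      if (quenching$self_association) "supports_oligomer" else "neutral",
      paste("Ksv trend:", quenching$verdict),
      list(ksv = quenching$ksv))))
  }
  if (!is.null(itc)) {
    stopifnot(inherits(itc, "itc_fit"))
    has_heat <- !("no_signal" %in% itc$flags)
    items <- c(items, list(.evidence_item(
      "itc", if (has_heat) "supports_oligomer" else "neutral",
      if (has_heat) {
        if (itc$adequate) "dissociation heats, dimer model adequate"
        else "dissociation heats, dimer model inadequate (higher-order equilibria)"
      } else "no dissociation heat signal",
      list(kd = itc$kd_dis, dh = itc$dh_dis, adequate = itc$adequate))))
  }

  dis <- vapply(items, `[[`, character(1), "verdict")
  dis_items <- dis[dis %in% c("supports_disorder", "supports_order")]
  disorder_verdict <- if (length(dis_items) == 0L) "indeterminate"
  else if (all(dis_items == "supports_disorder") &&
           (is.null(denaturation) ||
            denaturation$verdict == "non-cooperative (IDP-like)")) "IDP-like"
  else if (all(dis_items == "supports_order")) "folded-like"
  else "mixed evidence"

  olig_fired <- any(dis == "supports_oligomer")
  olig_present <- !is.null(oligomers) || !is.null(quenching) || !is.null(itc)
  oligomer_verdict <- if (!olig_present) "indeterminate"
  else if (olig_fired) "self-associating"
  else "monomeric"

  structure(list(disorder_verdict = disorder_verdict,
                 oligomer_verdict = oligomer_verdict,
                 evidence = items),
            class = "evidence_report")
}

#' @export
print.evidence_report <- function(x, ...) {
  cat("Evidence report\n")
  cat("  disorder verdict:  ", x$disorder_verdict, "\n")
  cat("  oligomer verdict:  ", x$oligomer_verdict, "\n")
  cat("  evidence:\n")
  for (it in x$evidence)
    cat(sprintf("    [%-13s] %-18s %s\n", it$modality, it$verdict, it$detail))
  invisible(x)
}
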