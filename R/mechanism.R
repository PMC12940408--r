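#' Default thresholds for the mechanism decision tree
#'
#' All numeric thresholds of the classifier in one configurable block:
#' `ddg_significant` (kcal/mol, |ddG| at or above which a state change is
#' significant, symmetric, bounds inclusive), `pam30_nonconservative`
#' (replacements scoring strictly below this are nonconservative),
#' `hydrophobicity_drop` (Kyte-Doolittle delta at or below which a
#' membrane-exposed substitution is disruptive).
#'
#' @param ddg_significant default 1.8.
#' @param pam30_nonconservative default 0.
#' @param hydrophobicity_drop default -2.0.
#' @return A named list of thresholds.
#' @export
mechanism_rules <- function(ddg_significant = 1.8,
                            pam30_nonconservative = 0,
                            hydrophobicity_drop = -2.0) {
  list(ddg_significant = ddg_significant,
       pam30_nonconservative = pam30_nonconservative,
       hydrophobicity_drop = hydrophobicity_drop)
}

MECHANISM_CATEGORIES <- c("atp_binding", "ligand_binding",
                          "membrane_interactions", "regulation",
                          "conformational_dynamics", "functional_stability",
                          "uncategorized")

#' Classify one variant's mechanistic impact
#'
#' Order-of-specificity decision tree over six essential transporter
#' functions; the first matching rule wins. Pocket-specific rules come
#' before global ones: (1) ATP binding - nonconservative replacement or
#' any-state destabilization of an ATP-pocket residue; (2) ligand
#' binding - the same pattern at a substrate-pocket residue;
#' (3) regulation - nonconservative replacement at a regulatory/PTM-
#' proximal residue; (4) membrane interactions - lipid-exposed residue
#' losing hydrophobicity or changing charge; (5) conformational
#' dynamics - a significant stability shift (|ddG| >= 1.8 kcal/mol) in
#' exactly one state, impairing movement between conformations;
#' (6) functional stability - significant shifts in two or more states,
#' or loss of a charged residue (R/K/D/E to uncharged, nonconservative)
#' at an inter-domain interface. No rule firing leaves the variant
#' uncategorized.
#'
#' @param variant one-row data.frame (or list) with `position`,
#'   `ref_aa`, `alt_aa`.
#' @param ctx the [build_residue_context()] row for the variant's
#'   position (list or one-row data.frame).
#' @param profile the stability row for the variant
#'   ([load_stability_table()]), or NULL when no stability data exist;
#'   annotation-only rules still run and the call carries a `no-data`
#'   note.
#' @param rules a [mechanism_rules()] list.
#' @return A `mechanism_call` list: `category`, `triggered_rules`
#'   (character), `metrics` (named list), `note`.
#' @export
classify_variant <- function(variant, ctx, profile = NULL,
                             rules = mechanism_rules()) {
  ref <- variant$ref_aa; alt <- variant$alt_aa
  if (!is.null(profile) && !is.null(profile$pam30)) {
    pam30 <- profile$pam30
    dhyd <- profile$delta_hydrophobicity
  } else {
    s <- substitution_scores(ref, alt)
    pam30 <- s$pam30; dhyd <- s$delta_hydrophobicity
  }
  ddg <- if (!is.null(profile))
    c(profile$ddg_state1, profile$ddg_state2, profile$ddg_state3) else NULL
  note <- if (is.null(ddg)) "no-data: stability profile missing" else ""

  nonconservative <- pam30 < rules$pam30_nonconservative
  thr <- rules$ddg_significant
  n_sig <- if (is.null(ddg)) 0L else sum(abs(ddg) >= thr)
  any_destab <- !is.null(ddg) && any(ddg >= thr)
  charge_change <- (ref %in% CHARGED_AA) != (alt %in% CHARGED_AA) ||
    (ref %in% c("D", "E") && alt %in% c("R", "K")) ||
    (ref %in% c("R", "K") && alt %in% c("D", "E"))
  charged_loss <- ref %in% CHARGED_AA && !(alt %in% CHARGED_AA)

  fired <- character(); category <- "uncategorized"
  metrics <- list(pam30 = pam30, delta_hydrophobicity = dhyd, ddg = ddg,
                  n_significant_states = n_sig)

  if (isTRUE(ctx$atp_pocket) && (nonconservative || any_destab)) {
    category <- "atp_binding"
    fired <- c(if (nonconservative) "atp_nonconservative",
               if (any_destab) "atp_destabilizing")
  } else if (isTRUE(ctx$ligand_pocket) && (nonconservative || any_destab)) {
    category <- "ligand_binding"
    fired <- c(if (nonconservative) "ligand_nonconservative",
               if (any_destab) "ligand_destabilizing")
  } else if (isTRUE(ctx$regulatory) && nonconservative) {
    category <- "regulation"
    fired <- "regulatory_nonconservative"
  } else if (isTRUE(ctx$membrane_exposed) &&
             (dhyd <= rules$hydrophobicity_drop || charge_change)) {
    category <- "membrane_interactions"
    fired <- c(if (dhyd <= rules$hydrophobicity_drop) "membrane_hydrophobicity_loss",
               if (charge_change) "membrane_charge_change")
  } else if (n_sig == 1L) {
    category <- "conformational_dynamics"
    fired <- "state_specific_stability_shift"
  } else if (n_sig >= 2L) {
    category <- "functional_stability"
    fired <- "multi_state_stability_shift"
  } else if (isTRUE(ctx$interface) && charged_loss && nonconservative) {
    category <- "functional_stability"
    fired <- "interface_charge_loss"
  }

  structure(list(category = category, triggered_rules = fired,
                 metrics = metrics, note = note),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("mechanism_call:", x$category)
  if (length(x$triggered_rules) > 0L)
    cat(" [", paste(x$triggered_rules, collapse = ", "), "]")
  if (nzchar(x$note)) cat(" (", x$note, ")")
  cat("\n")
  invisible(x)
}

#' Classify a whole variant cohort
#'
#' @param variants a [variant_set()].
#' @param context a [build_residue_context()] table covering every
#'   variant position.
#' @param stability a [load_stability_table()] (may be empty; variants
#'   without a profile are classified on annotation-only rules and
#'   flagged).
#' @param rules a [mechanism_rules()] list.
#' @return A `mechanism_calls` data.frame: variant keys, `category`,
#'   `triggered_rules`, `note`. `summary()` tabulates category by
#'   significance class.
#' @export
classify_cohort <- function(variants, context,
                            stability = load_stability_table(data.frame()),
                            rules = mechanism_rules()) {
  n <- nrow(variants)
  category <- character(n); rulestr <- character(n); note <- character(n)
  for (i in seq_len(n)) {
    pos <- variants$position[i]
    j <- match(pos, context$residue)
    if (is.na(j))
      stop("no residue context for position ", pos, call. = FALSE)
    prof <- stability_lookup(stability, pos, variants$alt_aa[i])
    call <- classify_variant(variants[i, ], context[j, ], prof, rules)
    category[i] <- call$category
    rulestr[i] <- paste(call$triggered_rules, collapse = ",")
    note[i] <- call$note
  }
  out <- data.frame(position = variants$position, ref_aa = variants$ref_aa,
                    alt_aa = variants$alt_aa, hgvs_p = variants$hgvs_p,
                    significance = variants$significance,
                    phenotype = variants$phenotype,
                    category = category, triggered_rules = rulestr,
                    note = note, stringsAsFactors = FALSE)
  class(out) <- c("mechanism_calls", "data.frame")
  out
}

#' @export
summary.mechanism_calls <- function(object, ...) {
  table(category = factor(object$category, levels = MECHANISM_CATEGORIES),
        significance = object$significance)
}

#' Agreement of mechanism calls with reference damaging labels
#'
#' Treats any categorized variant (category != uncategorized) as
#' "predicted damaging" and compares against binary reference labels.
#' Optionally scores external predictor columns at their recommended
#' thresholds (CADD >= 20, REVEL >= 0.5, PolyPhen2 >= 0.5,
#' AlphaMissense >= 0.564, SIFT <= 0.05).
#'
#' @param calls a [classify_cohort()] table.
#' @param labels logical vector (TRUE = damaging) along the rows of
#'   `calls`, or a character vector mappable via significance
#'   (pathogenic-like = damaging, benign-like = not).
#' @param external optional data.frame of score columns named among
#'   `cadd`, `revel`, `polyphen2`, `alphamissense`, `sift`.
#' @return List of per-method lists with `accuracy`, `precision`,
#'   `recall`, `n`.
#' @export
concordance_metrics <- function(calls, labels, external = NULL) {
  if (is.character(labels)) {
    labels <- normalize_significance(labels) %in%
      c("pathogenic", "likely_pathogenic")
  }
  keep <- !is.na(labels)
  if (!any(keep)) stop("no overlap between calls and labels", call. = FALSE)
  truth <- labels[keep]
  score <- function(pred) {
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    list(accuracy = (tp + tn) / length(truth),
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         n = length(truth))
  }
  out <- list(mechanism = score((calls$category != "uncategorized")[keep]))
  if (!is.null(external)) {
    cuts <- list(cadd = c(20, 1), revel = c(0.5, 1), polyphen2 = c(0.5, 1),
                 alphamissense = c(0.564, 1), sift = c(0.05, -1))
    for (nm in intersect(names(external), names(cuts))) {
      v <- external[[nm]][keep]
      pred <- if (cuts[[nm]][2] > 0) v >= cuts[[nm]][1] else v <= cuts[[nm]][1]
      ok <- !is.na(pred)
      tp <- sum(pred[ok] & truth[ok]); fp <- sum(pred[ok] & !truth[ok])
      fn <- sum(!pred[ok] & truth[ok]); tn <- sum(!pred[ok] & !truth[ok])
      out[[nm]] <- list(accuracy = (tp + tn) / sum(ok),
                        precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
                        recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
                        n = sum(ok))
    }
  }
  out
}
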