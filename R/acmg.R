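ACMG_LINES <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

#' Construct an ACMG evidence vector
#'
#' Named logical vector over the full ACMG-2015 line registry (PVS1,
#' PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7), all FALSE by default.
#'
#' @param ... line names to set TRUE, e.g. `evidence_vector("PM1","PP3")`,
#'   or named logicals (`PM1 = TRUE`).
#' @return An `evidence_vector`.
#' @export
evidence_vector <- function(...) {
  ev <- stats::setNames(rep(FALSE, length(ACMG_LINES)), ACMG_LINES)
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!is.null(nm) && nzchar(nm[i])) {
      line <- nm[i]; val <- isTRUE(args[[i]])
    } else {
      line <- as.character(args[[i]]); val <- TRUE
    }
    for (l in line) {
      if (!(l %in% ACMG_LINES))
        stop("undefined ACMG evidence line: ", l, call. = FALSE)
      ev[l] <- val
    }
  }
  class(ev) <- "evidence_vector"
  ev
}

evidence_counts <- function(ev) {
  list(pvs = sum(ev[["PVS1"]]),
       ps = sum(ev[paste0("PS", 1:4)]),
       pm = sum(ev[paste0("PM", 1:6)]),
       pp = sum(ev[paste0("PP", 1:5)]),
       ba = sum(ev[["BA1"]]),
       bs = sum(ev[paste0("BS", 1:4)]),
       bp = sum(ev[paste0("BP", 1:7)]))
}

## The published 2015 combining rules, on evidence counts.
combine_from_counts <- function(pvs, ps, pm, pp, ba = 0, bs = 0, bp = 0) {
  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps == 1 && pm >= 1) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2
  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) {
    list(class = "vus", rule = "conflicting_evidence")
  } else if (pathogenic) {
    list(class = "pathogenic", rule = "pathogenic_combination")
  } else if (likely_pathogenic) {
    rule <- if (pvs >= 1) "lp_pvs1_pm" else if (ps == 1 && pm >= 1) "lp_ps_pm"
    else if (ps == 1) "lp_ps_pp" else if (pm >= 3) "lp_3pm"
    else if (pm == 2) "lp_2pm_2pp" else "lp_1pm_4pp"
    list(class = "likely_pathogenic", rule = rule)
  } else if (benign) {
    list(class = "benign", rule = "benign_combination")
  } else if (likely_benign) {
    list(class = "likely_benign", rule = "lb_combination")
  } else {
    list(class = "vus", rule = "insufficient_evidence")
  }
}

#' Combine ACMG evidence lines into a classification
#'
#' Applies the complete published 2015 combining table (pathogenic,
#' likely pathogenic, benign and likely benign combinations; conflicting
#' pathogenic and benign evidence yields VUS; anything else defaults to
#' VUS).
#'
#' @param ev an [evidence_vector()].
#' @return An `acmg_call` list: `combined_class`, `satisfied_rule`,
#'   `lines_to_lp` (minimum additional PM/PP lines needed to reach
#'   likely pathogenic; 0 iff already pathogenic or likely pathogenic).
#' @export
combine_acmg <- function(ev) {
  cnt <- evidence_counts(ev)
  res <- do.call(combine_from_counts, cnt)
  structure(list(combined_class = res$class, satisfied_rule = res$rule,
                 lines_to_lp = evidence_gap(ev)),
            class = "acmg_call")
}

#' @export
print.acmg_call <- function(x, ...) {
  cat("acmg_call:", x$combined_class, "(", x$satisfied_rule, "),",
      x$lines_to_lp, "line(s) to likely pathogenic\n")
  invisible(x)
}

#' Evidence gap to a likely-pathogenic classification
#'
#' Minimum number of additional true lines - each one unit, added at
#' moderate (PM) or supporting (PP) strength, in any mix - needed for
#' the combined class to reach likely pathogenic or pathogenic. Zero when
#' the vector already combines to likely pathogenic or stronger.
#'
#' @param ev an [evidence_vector()].
#' @return Integer >= 0 (Inf if unreachable, e.g. overwhelming benign
#'   evidence).
#' @export
evidence_gap <- function(ev) {
  cnt <- evidence_counts(ev)
  reaches <- function(a, b) {
    res <- combine_from_counts(cnt$pvs, cnt$ps, cnt$pm + a, cnt$pp + b,
                               cnt$ba, cnt$bs, cnt$bp)
    res$class %in% c("pathogenic", "likely_pathogenic")
  }
  for (k in 0:8) {
    for (a in 0:k) {
      if (reaches(a, k - a)) return(k)
    }
  }
  Inf
}

#' Assign ACMG evidence lines from pipeline outputs
#'
#' PM1: the residue lies in a conserved nucleotide-binding motif
#' (Walker A/B, signature, H-loop, Q-loop) or in a 3D variant hotspot.
#' PM2: present in ClinVar but absent from gnomAD, or allele frequency
#' below 0.33\% at a position past residue 250 (the early region is
#' excluded for poor population-database coverage).
#' PM5: a different pathogenic missense change is known at the same
#' residue. PP3: the mechanism classifier assigned a category. PP4: the
#' reported phenotype is disease-specific (PXE, GACI or both).
#'
#' @param variant one row of a [variant_set()].
#' @param ctx the residue-context row for the variant's position.
#' @param hotspot_members integer vector of hotspot residues (union over
#'   states and weightings).
#' @param call the variant's `mechanism_call` (or its category string).
#' @param pathogenic_positions named list: position -> character vector
#'   of alt residues with a pathogenic/likely-pathogenic report.
#' @param af_threshold PM2 allele-frequency cutoff (strict <), default
#'   0.0033.
#' @param min_position PM2 positional cutoff (strict >), default 250.
#' @return An [evidence_vector()].
#' @export
assign_evidence <- function(variant, ctx, hotspot_members, call,
                            pathogenic_positions = list(),
                            af_threshold = 0.0033, min_position = 250) {
  category <- if (is.character(call)) call else call$category
  pm1 <- ctx$motif %in% c("walker_a", "walker_b", "signature",
                          "h_loop", "q_loop") ||
    variant$position %in% hotspot_members
  af <- variant$allele_frequency
  pm2 <- (isTRUE(variant$in_clinvar) && !isTRUE(variant$in_gnomad)) ||
    (!is.na(af) && af < af_threshold && variant$position > min_position)
  known <- pathogenic_positions[[as.character(variant$position)]]
  pm5 <- !is.null(known) && length(setdiff(known, variant$alt_aa)) > 0L
  pp3 <- category != "uncategorized"
  pp4 <- variant$phenotype %in% c("pxe", "gaci", "both")
  evidence_vector(PM1 = pm1, PM2 = pm2, PM5 = pm5, PP3 = pp3, PP4 = pp4)
}

#' Read an evidence-override table
#'
#' Replays published per-variant evidence flags instead of deriving them
#' from the pipeline. Expected columns: `variant` plus any of the ACMG
#' line names (case-insensitive); values "Yes"/"-" (or logical).
#'
#' @param path TSV path.
#' @return Named list of [evidence_vector()]s keyed by variant.
#' @export
read_evidence_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  lines <- intersect(toupper(names(df)), ACMG_LINES)
  out <- list()
  for (i in seq_len(nrow(df))) {
    ev <- evidence_vector()
    for (l in lines) {
      v <- df[[which(toupper(names(df)) == l)[1]]][i]
      ev[l] <- isTRUE(v) || (is.character(v) && tolower(v) %in% c("yes", "y", "true", "1"))
    }
    out[[df$variant[i]]] <- ev
  }
  out
}

#' Reclassification summary over a cohort
#'
#' Counts how many VUS-like variants reach likely pathogenic under the
#' combined evidence, how many are one line of evidence away, and the
#' percent increase the reclassifications represent relative to the
#' existing pathogenic/likely-pathogenic count (rounded to the nearest
#' integer percent).
#'
#' @param variants a [variant_set()] (used for significance classes);
#'   may be NULL when `evidence` keys carry no cohort context.
#' @param evidence named list of [evidence_vector()]s (one per variant).
#' @param existing_plp_count number of already pathogenic/likely
#'   pathogenic variants forming the denominator.
#' @return List with `per_variant` (data.frame: variant, combined_class,
#'   satisfied_rule, lines_to_lp), `n_reclassified`, `n_one_away`,
#'   `percent_increase`.
#' @export
reclassification_report <- function(variants = NULL, evidence,
                                    existing_plp_count) {
  rows <- lapply(names(evidence), function(k) {
    call <- combine_acmg(evidence[[k]])
    data.frame(variant = k, combined_class = call$combined_class,
               satisfied_rule = call$satisfied_rule,
               lines_to_lp = call$lines_to_lp, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows) %||%
    data.frame(variant = character(), combined_class = character(),
               satisfied_rule = character(), lines_to_lp = numeric())
  n_re <- sum(per$combined_class %in% c("pathogenic", "likely_pathogenic"))
  n_one <- sum(per$lines_to_lp == 1)
  pct <- if (existing_plp_count > 0)
    round(100 * n_re / existing_plp_count) else NA_real_
  list(per_variant = per, n_reclassified = n_re, n_one_away = n_one,
       percent_increase = pct)
}
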