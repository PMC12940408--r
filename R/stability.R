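#' Load a per-variant, per-state stability table
#'
#' Consumes externally computed folding free-energy changes (e.g. FoldX
#' output), one row per variant with three per-state ddG columns and
#' optional per-state frustration columns. ddG is in kcal/mol; positive
#' values are destabilizing.
#'
#' @param rows data.frame with columns `variant` (key such as "G1302R"
#'   or an HGVS p. string), `ddg_state1`..`ddg_state3`, optionally
#'   `frustration_state1`..`frustration_state3`.
#' @return A `stability_table` data.frame keyed by `(position, alt_aa)`
#'   with columns `position`, `ref_aa`, `alt_aa`, `ddg_state1..3`,
#'   `frustration_state1..3`, `pam30`, `delta_hydrophobicity`.
#' @export
load_stability_table <- function(rows) {
  need <- c("variant", "ddg_state1", "ddg_state2", "ddg_state3")
  if (nrow(rows) == 0L) {
    out <- data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), ddg_state1 = numeric(),
                      ddg_state2 = numeric(), ddg_state3 = numeric(),
                      frustration_state1 = numeric(),
                      frustration_state2 = numeric(),
                      frustration_state3 = numeric(),
                      pam30 = integer(), delta_hydrophobicity = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("stability_table", "data.frame")
    return(out)
  }
  stopifnot(all(need %in% names(rows)))
  parsed <- lapply(rows$variant, parse_hgvs_p)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("unparsable variant key(s): ",
         paste(rows$variant[bad], collapse = ", "), call. = FALSE)
  ddg <- as.matrix(rows[, c("ddg_state1", "ddg_state2", "ddg_state3")])
  incomplete <- rowSums(is.finite(ddg)) < 3L
  if (any(incomplete))
    stop("fewer than 3 ddG values for key(s): ",
         paste(rows$variant[incomplete], collapse = ", "), call. = FALSE)
  out <- data.frame(
    position = vapply(parsed, `[[`, integer(1), "position"),
    ref_aa = vapply(parsed, `[[`, character(1), "ref"),
    alt_aa = vapply(parsed, `[[`, character(1), "alt"),
    ddg_state1 = ddg[, 1], ddg_state2 = ddg[, 2], ddg_state3 = ddg[, 3],
    stringsAsFactors = FALSE)
  for (k in 1:3) {
    col <- paste0("frustration_state", k)
    out[[col]] <- if (col %in% names(rows)) as.numeric(rows[[col]]) else NA_real_
  }
  subs <- mapply(function(r, a) substitution_scores(r, a),
                 out$ref_aa, out$alt_aa, SIMPLIFY = FALSE)
  out$pam30 <- vapply(subs, `[[`, numeric(1), "pam30")
  out$delta_hydrophobicity <- vapply(subs, `[[`, numeric(1),
                                     "delta_hydrophobicity")
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Signed extremum of per-state ddG values
#'
#' Returns the entry with the largest absolute value, keeping its sign:
#' the "largest score across states". On an exact magnitude tie between a
#' stabilizing and a destabilizing value, the positive (destabilizing)
#' value is returned.
#'
#' @param ddg numeric vector of three per-state values, kcal/mol.
#' @return One signed value.
#' @export
largest_across_states <- function(ddg) {
  stopifnot(length(ddg) == 3L, all(is.finite(ddg)))
  m <- max(abs(ddg))
  cand <- ddg[abs(ddg) == m]
  if (any(cand > 0)) max(cand) else cand[1]
}

#' Classify a stability change against a symmetric threshold
#'
#' Destabilizing when `x >= threshold`, stabilizing when
#' `x <= -threshold` (both bounds inclusive), neutral otherwise. The
#' default threshold is 1.8 kcal/mol.
#'
#' @param x ddG value(s), kcal/mol.
#' @param threshold positive threshold, kcal/mol.
#' @return Character vector in \{"stabilizing","neutral","destabilizing"\}.
#' @export
stability_class <- function(x, threshold = 1.8) {
  stopifnot(threshold > 0)
  out <- rep("neutral", length(x))
  out[x >= threshold] <- "destabilizing"
  out[x <= -threshold] <- "stabilizing"
  out
}

## Fetch the stability row for a variant, or NULL.
stability_lookup <- function(tab, position, alt_aa) {
  i <- which(tab$position == position & tab$alt_aa == alt_aa)
  if (length(i) == 0L) return(NULL)
  tab[i[1], , drop = FALSE]
}
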