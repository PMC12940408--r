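#' @keywords internal
"_PACKAGE"

## Canonical one-letter amino acid alphabet used throughout.
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
         Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
         L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
         S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

AA3TO1 <- stats::setNames(names(AA3), toupper(AA3))

## Kyte-Doolittle hydropathy scale (kcal/mol-free units, published values).
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

## Side chains carrying formal charge at physiological pH (His treated
## as uncharged; its pKa sits below 7).
CHARGED_AA <- c("R", "K", "D", "E")

.pam30 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("PAM30", package = "Biostrings", envir = e)
      cache <<- e$PAM30
    }
    cache
  }
})

#' Substitution biochemistry for an amino-acid replacement
#'
#' Looks up the PAM30 log-odds score for replacing `ref_aa` with `alt_aa`
#' and the change in Kyte-Doolittle side-chain hydropathy (alt minus ref).
#' Negative PAM30 scores mark disfavoured (nonconservative) replacements;
#' a negative hydropathy delta marks a substitution toward a more polar
#' side chain.
#'
#' @param ref_aa,alt_aa One-letter codes of the reference and replacement
#'   amino acids (canonical 20 only).
#' @return A list with elements `pam30` (integer) and
#'   `delta_hydrophobicity` (numeric, Kyte-Doolittle units).
#' @examples
#' substitution_scores("G", "R")
#' @export
substitution_scores <- function(ref_aa, alt_aa) {
  for (aa in c(ref_aa, alt_aa)) {
    if (!is.character(aa) || length(aa) != 1L || !(aa %in% AA1)) {
      stop("non-canonical amino acid letter: '", aa, "'", call. = FALSE)
    }
  }
  list(
    pam30 = unname(.pam30()[ref_aa, alt_aa]),
    delta_hydrophobicity = unname(KYTE_DOOLITTLE[alt_aa] - KYTE_DOOLITTLE[ref_aa])
  )
}

## Parse a protein HGVS string such as "NP_001162.5:p.Gly1302Arg",
## "p.G1302R" or "G1302R". Returns list(position, ref, alt) or NULL if the
## string is not a simple missense substitution.
parse_hgvs_p <- function(x) {
  s <- sub("^[^:]*:", "", trimws(x))
  s <- sub("^p\\.", "", s)
  s <- gsub("[()]", "", s)
  m <- regmatches(s, regexec("^([A-Za-z]{3}|[A-Z])([0-9]+)([A-Za-z]{3}|[A-Z*=])$", s))[[1]]
  if (length(m) == 0L) return(NULL)
  to1 <- function(a) {
    if (nchar(a) == 1L) return(toupper(a))
    unname(AA3TO1[toupper(a)])
  }
  ref <- to1(m[2]); alt <- to1(m[4])
  if (is.na(ref) || is.na(alt) || !(ref %in% AA1) || !(alt %in% AA1)) return(NULL)
  list(position = as.integer(m[3]), ref = ref, alt = alt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## TRUE where pos falls in any [start, end] row of an interval data.frame.
in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  out
}
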