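#' Variant set container
#'
#' A `variant_set` is a data.frame with one row per distinct missense
#' variant, keyed by `(position, alt_aa)`, sorted by position then
#' alternate residue. Canonical columns: `position`, `ref_aa`, `alt_aa`,
#' `hgvs_p`, `allele_frequency`, `allele_count`, `significance`,
#' `phenotype`, `in_clinvar`, `in_gnomad`.
#'
#' @param df data.frame carrying at least position/ref_aa/alt_aa.
#' @param provenance optional character vector of source release labels.
#' @return A `variant_set`.
#' @export
variant_set <- function(df = NULL, provenance = character()) {
  cols <- c("position", "ref_aa", "alt_aa", "hgvs_p", "allele_frequency",
            "allele_count", "significance", "phenotype", "in_clinvar",
            "in_gnomad")
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(position = integer(), ref_aa = character(),
                     alt_aa = character(), hgvs_p = character(),
                     allele_frequency = numeric(), allele_count = integer(),
                     significance = character(), phenotype = character(),
                     in_clinvar = logical(), in_gnomad = logical(),
                     stringsAsFactors = FALSE)
  } else {
    if (!"hgvs_p" %in% names(df))
      df$hgvs_p <- paste0("p.", df$ref_aa, df$position, df$alt_aa)
    if (!"allele_frequency" %in% names(df)) df$allele_frequency <- NA_real_
    if (!"allele_count" %in% names(df)) df$allele_count <- NA_integer_
    if (!"significance" %in% names(df)) df$significance <- "unannotated"
    if (!"phenotype" %in% names(df)) df$phenotype <- "none"
    if (!"in_clinvar" %in% names(df)) df$in_clinvar <- FALSE
    if (!"in_gnomad" %in% names(df)) df$in_gnomad <- FALSE
    df <- df[cols]
  }
  stopifnot(all(df$position >= 1L), all(df$ref_aa != df$alt_aa))
  af <- df$allele_frequency
  if (any(!is.na(af) & (af <= 0 | af > 1)))
    stop("allele_frequency must lie in (0, 1]", call. = FALSE)
  if (any(!df$in_clinvar & !df$in_gnomad))
    stop("every variant must come from at least one source", call. = FALSE)
  key <- paste0(df$position, df$alt_aa)
  if (anyDuplicated(key))
    stop("duplicate (position, alt_aa) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  df <- df[order(df$position, df$alt_aa), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("variant_set", "data.frame"),
            provenance = provenance)
}

variant_key <- function(vs) paste0(vs$position, vs$alt_aa)

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x), "missense variants")
  if (nrow(x) > 0L)
    cat(" over positions", min(x$position), "-", max(x$position))
  cat("\n  significance:",
      paste(names(table(x$significance)), table(x$significance),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

SIGNIFICANCE_LEVELS <- c("pathogenic", "likely_pathogenic", "vus",
                         "conflicting", "likely_benign", "benign",
                         "unannotated")

## Map free-text clinical significance to the controlled vocabulary.
normalize_significance <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep("unannotated", length(s))
  out[grepl("conflicting", s)] <- "conflicting"
  out[grepl("uncertain", s) | s == "vus"] <- "vus"
  lb <- grepl("likely benign|likely_benign", s)
  b <- grepl("benign", s) & !lb
  out[b] <- "benign"
  out[lb] <- "likely_benign"
  lp <- grepl("likely pathogenic|likely_pathogenic", s)
  p <- grepl("pathogenic", s) & !lp
  ## compound "Pathogenic/Likely pathogenic" labels carry both words;
  ## they pool with the pathogenic class
  out[lp] <- "likely_pathogenic"
  out[p] <- "pathogenic"
  out[grepl("pathogenic/likely", s)] <- "pathogenic"
  out[s %in% c("", "na", "-", "none")] <- "unannotated"
  out
}

## Keyword mapping of free-text condition fields to the two phenotypes.
normalize_phenotype <- function(x) {
  s <- tolower(as.character(x))
  pxe <- grepl("pseudoxanthoma|\\bpxe\\b", s)
  gaci <- grepl("arterial calcification|\\bgaci\\b", s)
  out <- rep("none", length(s))
  out[pxe & !gaci] <- "pxe"
  out[gaci & !pxe] <- "gaci"
  out[pxe & gaci] <- "both"
  out[s %in% c("pxe", "gaci", "both", "none")] <- s[s %in% c("pxe", "gaci", "both", "none")]
  out
}

#' Parse a table of variant rows from one source
#'
#' Accepts a data.frame in a ClinVar- or gnomAD-like dialect. Rows are
#' identified as missense via an HGVS p. column (`hgvs_p`) or explicit
#' `position`/`ref_aa`/`alt_aa` columns; non-missense rows (nonsense,
#' synonymous, frameshift, unparsable) are dropped with a message giving
#' the count. Duplicate rows agreeing on `(position, alt_aa)` are merged;
#' duplicates disagreeing on clinical significance within the one source
#' are an error.
#'
#' @param rows data.frame of raw rows.
#' @param source `"clinvar"` or `"gnomad"`; sets the presence flag and
#'   decides whether significance/phenotype (ClinVar) or allele
#'   frequency/count (gnomAD) are read.
#' @param column_map optional named list mapping canonical column names
#'   (`hgvs_p`, `allele_frequency`, `allele_count`, `significance`,
#'   `phenotype`, `position`, `ref_aa`, `alt_aa`) to the table's names.
#' @return A [variant_set()].
#' @export
parse_variant_rows <- function(rows, source = c("clinvar", "gnomad"),
                               column_map = NULL) {
  source <- match.arg(source)
  getcol <- function(nm) {
    actual <- column_map[[nm]] %||% nm
    if (actual %in% names(rows)) rows[[actual]] else NULL
  }
  n <- nrow(rows)
  if (n == 0L) return(variant_set())

  pos <- getcol("position"); ref <- getcol("ref_aa"); alt <- getcol("alt_aa")
  hgvs <- getcol("hgvs_p")
  if (is.null(hgvs) && (is.null(pos) || is.null(ref) || is.null(alt)))
    stop("rows need an hgvs_p column or position/ref_aa/alt_aa columns",
         call. = FALSE)

  keep <- rep(TRUE, n)
  if (is.null(pos)) {
    pos <- integer(n); ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      pr <- parse_hgvs_p(hgvs[i])
      if (is.null(pr)) {
        ## distinguish a non-missense consequence (drop) from a garbled
        ## string that claims to be missense (error)
        s <- as.character(hgvs[i])
        if (grepl("^\\s*$|Ter$|\\*$|=$|fs|del|ins|dup", s) ||
            grepl("^[^:]*:?p?\\.?[A-Za-z]{3}[0-9]+(Ter|=)", s)) {
          keep[i] <- FALSE
        } else if (grepl("[0-9]", s) && grepl("^[A-Za-z]", sub("^[^:]*:", "", sub("^p\\.", "", s)))) {
          stop("unparsable HGVS p. string at row ", i, ": '", s, "'",
               call. = FALSE)
        } else {
          keep[i] <- FALSE
        }
        next
      }
      pos[i] <- pr$position; ref[i] <- pr$ref; alt[i] <- pr$alt
    }
  } else {
    pos <- as.integer(pos); ref <- toupper(ref); alt <- toupper(alt)
    ref3 <- nchar(ref) == 3L
    ref[ref3] <- AA3TO1[ref[ref3]]
    alt3 <- nchar(alt) == 3L
    alt[alt3] <- AA3TO1[alt[alt3]]
    keep <- !is.na(pos) & ref %in% AA1 & alt %in% AA1 & ref != alt
    if (is.null(hgvs)) hgvs <- paste0("p.", ref, pos, alt)
  }
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("parse_variant_rows: dropped ", dropped, " non-missense row(s)")

  df <- data.frame(position = pos[keep], ref_aa = ref[keep],
                   alt_aa = alt[keep],
                   hgvs_p = as.character(if (is.null(hgvs)) NA else hgvs)[keep],
                   stringsAsFactors = FALSE)
  af <- getcol("allele_frequency"); ac <- getcol("allele_count")
  sig <- getcol("significance"); phen <- getcol("phenotype")
  if (source == "gnomad") {
    df$allele_frequency <- if (is.null(af)) NA_real_ else as.numeric(af)[keep]
    df$allele_count <- if (is.null(ac)) NA_integer_ else as.integer(ac)[keep]
    df$significance <- "unannotated"
    df$phenotype <- "none"
    df$in_clinvar <- FALSE; df$in_gnomad <- TRUE
  } else {
    df$allele_frequency <- if (is.null(af)) NA_real_ else as.numeric(af)[keep]
    df$allele_count <- if (is.null(ac)) NA_integer_ else as.integer(ac)[keep]
    df$significance <- if (is.null(sig)) "unannotated" else normalize_significance(sig[keep])
    df$phenotype <- if (is.null(phen)) "none" else normalize_phenotype(phen[keep])
    df$in_clinvar <- TRUE; df$in_gnomad <- FALSE
  }

  key <- paste0(df$position, df$alt_aa)
  if (anyDuplicated(key)) {
    bad <- character()
    for (k in unique(key[duplicated(key)])) {
      sigs <- unique(df$significance[key == k])
      if (length(sigs) > 1L) bad <- c(bad, k)
    }
    if (length(bad) > 0L)
      stop("conflicting significance within one source for key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  variant_set(df, provenance = source)
}

#' Merge ClinVar-like and gnomAD-like variant sets
#'
#' Key-wise union of two [variant_set()]s. Presence flags are OR-ed.
#' For variants present in both, allele frequency and count come from the
#' gnomAD-flagged record and significance/phenotype from the
#' ClinVar-flagged record.
#'
#' @param a,b `variant_set` objects.
#' @return The merged `variant_set`.
#' @export
merge_sources <- function(a, b) {
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  df <- rbind(as.data.frame(a), as.data.frame(b))
  ## conflicting reference residues at a shared position are a keying error
  for (p in unique(df$position)) {
    if (length(unique(df$ref_aa[df$position == p])) > 1L)
      stop("conflicting ref_aa at position ", p, call. = FALSE)
  }
  key <- paste0(df$position, df$alt_aa)
  out <- df[!duplicated(key), , drop = FALSE]
  okey <- paste0(out$position, out$alt_aa)
  for (k in unique(key[duplicated(key)])) {
    rows <- df[key == k, , drop = FALSE]
    i <- match(k, okey)
    out$in_clinvar[i] <- any(rows$in_clinvar)
    out$in_gnomad[i] <- any(rows$in_gnomad)
    g <- rows[rows$in_gnomad, , drop = FALSE]
    if (nrow(g) > 0L) {
      out$allele_frequency[i] <- g$allele_frequency[1]
      out$allele_count[i] <- g$allele_count[1]
    }
    cv <- rows[rows$in_clinvar, , drop = FALSE]
    if (nrow(cv) > 0L) {
      out$significance[i] <- cv$significance[1]
      out$phenotype[i] <- cv$phenotype[1]
    }
  }
  variant_set(out, provenance = unique(c(attr(a, "provenance"),
                                         attr(b, "provenance"))))
}

#' Restrict a variant set to the modeled residue range
#'
#' Removes variants at positions outside `[first_modeled_residue,
#' last_modeled_residue]` (bounds inclusive). The removed keys are
#' attached as attribute `"removed"` and reported with a message.
#'
#' @param vs a [variant_set()].
#' @param first_modeled_residue,last_modeled_residue integer bounds.
#' @return The filtered `variant_set` with attribute `removed`.
#' @export
restrict_to_model <- function(vs, first_modeled_residue,
                              last_modeled_residue) {
  stopifnot(first_modeled_residue <= last_modeled_residue)
  drop <- vs$position < first_modeled_residue |
    vs$position > last_modeled_residue
  removed <- vs$hgvs_p[drop]
  if (length(removed) > 0L)
    message("restrict_to_model: removed ", length(removed),
            " variant(s) outside [", first_modeled_residue, ", ",
            last_modeled_residue, "]: ", paste(removed, collapse = ", "))
  out <- variant_set(as.data.frame(vs)[!drop, , drop = FALSE],
                     provenance = attr(vs, "provenance"))
  attr(out, "removed") <- removed
  out
}

#' Partition a variant set by clinical significance class
#'
#' Buckets: `pathogenic_or_lp` (pathogenic + likely pathogenic),
#' `vus_like` (VUS + unannotated, which are pooled for analysis),
#' `conflicting`, and `benign_or_lb`.
#'
#' @param vs a [variant_set()].
#' @return Named list of four `variant_set`s; sizes sum to `nrow(vs)`.
#' @export
partition_by_class <- function(vs) {
  df <- as.data.frame(vs)
  pick <- function(classes) {
    variant_set(df[df$significance %in% classes, , drop = FALSE],
                provenance = attr(vs, "provenance"))
  }
  list(
    pathogenic_or_lp = pick(c("pathogenic", "likely_pathogenic")),
    vus_like = pick(c("vus", "unannotated")),
    conflicting = pick("conflicting"),
    benign_or_lb = pick(c("benign", "likely_benign"))
  )
}

#' Write a variant set as canonical TSV
#' @param vs a [variant_set()].
#' @param path output file path.
#' @export
write_variant_tsv <- function(vs, path) {
  utils::write.table(as.data.frame(vs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a canonical variant TSV written by [write_variant_tsv()]
#' @param path file path.
#' @return A [variant_set()].
#' @export
read_variant_tsv <- function(path) {
  variant_set(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}
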