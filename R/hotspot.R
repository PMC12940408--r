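#' Spatial variant burden per residue
#'
#' For each residue, sums the weights of all variants whose position lies
#' within the residue's contact neighborhood (10 Angstrom by default in
#' the map). Weights are gnomAD allele counts (`allele_count`) or 1 per
#' distinct variant (`variant_count`). Variants lacking an allele count
#' are skipped with a warning under allele-count weighting.
#'
#' @param map a [build_contact_map()] result.
#' @param variants a [variant_set()]; positions must be modeled residues.
#' @param weighting `"allele_count"` or `"variant_count"`.
#' @return A `burden_profile` data.frame (residue, burden, p = NA) with
#'   attributes `state_id`, `weighting`.
#' @export
residue_burden <- function(map, variants,
                           weighting = c("allele_count", "variant_count")) {
  weighting <- match.arg(weighting)
  if (!all(variants$position %in% map$residues))
    stop("variant positions outside the modeled residue set: ",
         paste(setdiff(variants$position, map$residues), collapse = ", "),
         call. = FALSE)
  w <- variant_weights(variants, weighting)
  wv <- numeric(length(map$residues))
  idx <- match(w$position, map$residues)
  for (k in seq_along(idx)) wv[idx[k]] <- wv[idx[k]] + w$weight[k]
  burden <- as.numeric(map$adj %*% wv)
  out <- data.frame(residue = map$residues, burden = burden, p = NA_real_)
  structure(out, class = c("burden_profile", "data.frame"),
            state_id = map$state_id, weighting = weighting,
            n_permutations = 0L, seed = NA_integer_)
}

variant_weights <- function(variants, weighting) {
  if (weighting == "variant_count") {
    return(data.frame(position = variants$position,
                      weight = rep(1, nrow(variants))))
  }
  have <- !is.na(variants$allele_count)
  if (any(!have))
    warning(sum(!have), " variant(s) lack allele_count; skipped in ",
            "allele-count weighting")
  data.frame(position = variants$position[have],
             weight = as.numeric(variants$allele_count[have]))
}

#' Permutation-derived empirical p-values for spatial burden
#'
#' The null keeps the observed variants (and their weights) and reassigns
#' their positions uniformly at random without replacement over all
#' modeled residues, preserving the total variant count and total weight
#' exactly. For each residue, p = (number of permutations whose null
#' burden is >= the observed burden) / n_permutations; p can be exactly 0.
#'
#' @inheritParams residue_burden
#' @param n_permutations number of permutations (default 10000).
#' @param seed integer RNG seed; identical seeds give identical p-values.
#' @return A `burden_profile` with the `p` column filled.
#' @export
permutation_pvalues <- function(map, variants,
                                weighting = c("allele_count", "variant_count"),
                                n_permutations = 10000, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(n_permutations >= 1)
  prof <- residue_burden(map, variants, weighting)
  w <- suppressWarnings(variant_weights(variants, weighting))
  n_res <- length(map$residues)
  if (nrow(w) > n_res)
    stop("more weighted variants (", nrow(w), ") than modeled residues (",
         n_res, "); permutation without replacement impossible",
         call. = FALSE)
  obs <- prof$burden
  exceed <- integer(n_res)
  if (nrow(w) == 0L) {
    ## no variant mass: every null burden ties the all-zero observation
    prof$p <- rep(1, n_res)
  } else {
    set.seed(seed)
    block <- 1000L
    done <- 0L
    while (done < n_permutations) {
      b <- min(block, n_permutations - done)
      W <- matrix(0, n_res, b)
      for (j in seq_len(b)) {
        pos <- sample.int(n_res, nrow(w))
        W[cbind(pos, j)] <- w$weight
      }
      nullb <- as.matrix(map$adj %*% W)
      exceed <- exceed + rowSums(nullb >= obs)
      done <- done + b
    }
    prof$p <- exceed / n_permutations
  }
  attr(prof, "n_permutations") <- as.integer(n_permutations)
  attr(prof, "seed") <- as.integer(seed)
  prof
}

#' @export
print.burden_profile <- function(x, ...) {
  cat("burden_profile: state", attr(x, "state_id"), ", weighting",
      attr(x, "weighting"), ",", nrow(x), "residues, total burden",
      sum(x$burden))
  if (attr(x, "n_permutations") > 0L)
    cat(",", attr(x, "n_permutations"), "permutations (seed",
        attr(x, "seed"), ")")
  cat("\n")
  invisible(x)
}

#' Call hotspot residues from a burden profile
#'
#' When `min_burden` is not given it is derived from the permutation
#' p-values: the smallest observed burden value B such that every residue
#' with burden >= B has p < `alpha`. Hotspot members are exactly the
#' residues with burden >= the threshold. If no positive burden value
#' satisfies the criterion the hotspot set is empty.
#'
#' @param profile a [permutation_pvalues()] result (p-values required
#'   unless `min_burden` is supplied).
#' @param alpha empirical p-value threshold (default 1e-4).
#' @param min_burden optional explicit burden threshold; when given,
#'   calling is simple thresholding and p-values are not consulted.
#' @return A `hotspot_set` with fields `members`, `min_burden`,
#'   `state_id`, `weighting`, `alpha`.
#' @export
call_hotspots <- function(profile, alpha = 0.0001, min_burden = NULL) {
  if (is.null(min_burden)) {
    if (all(is.na(profile$p)))
      stop("p-values not computed; supply min_burden or run permutation_pvalues",
           call. = FALSE)
    levels <- sort(unique(profile$burden[profile$burden > 0]),
                   decreasing = TRUE)
    min_burden <- Inf
    for (B in levels) {
      if (all(profile$p[profile$burden >= B] < alpha)) min_burden <- B
      else break
    }
  }
  members <- profile$residue[profile$burden >= min_burden]
  structure(list(members = members, min_burden = min_burden,
                 state_id = attr(profile, "state_id"),
                 weighting = attr(profile, "weighting"), alpha = alpha),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("hotspot_set: state", x$state_id, ",", x$weighting, "weighting,",
      length(x$members), "residues at burden >=", x$min_burden, "\n")
  invisible(x)
}

#' Overlap report across hotspot analyses
#'
#' @param sets list of >= 2 [call_hotspots()] results.
#' @return List with `union_size`, `shared` (residues present in every
#'   set), `shared_count`, `shared_fraction` (of the union) and the
#'   pairwise `jaccard` matrix.
#' @export
hotspot_union_overlap <- function(sets) {
  stopifnot(length(sets) >= 2L)
  members <- lapply(sets, function(s) s$members)
  un <- Reduce(union, members)
  sh <- Reduce(intersect, members)
  k <- length(sets)
  jac <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    u <- length(union(members[[i]], members[[j]]))
    jac[i, j] <- jac[j, i] <-
      if (u == 0) 1 else length(intersect(members[[i]], members[[j]])) / u
  }
  list(union_size = length(un), shared = sort(sh),
       shared_count = length(sh),
       shared_fraction = if (length(un) == 0) NA_real_ else length(sh) / length(un),
       jaccard = jac)
}

#' Export hotspot membership as a per-residue table
#' @param profile a `burden_profile`.
#' @param hotspots a `hotspot_set` from the same profile.
#' @return data.frame(residue, state, weighting, burden, p, in_hotspot).
#' @export
hotspot_table <- function(profile, hotspots) {
  data.frame(residue = profile$residue,
             state = attr(profile, "state_id"),
             weighting = attr(profile, "weighting"),
             burden = profile$burden, p = profile$p,
             in_hotspot = profile$residue %in% hotspots$members)
}
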