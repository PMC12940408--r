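#' Generate a toy multi-state structure
#'
#' Builds an idealized multi-helix bundle of two pseudo-domains, with a
#' C-alpha and one pseudo side-chain atom per residue, in three
#' conformational states. States 2 and 3 apply increasing rigid-body
#' separations of the second pseudo-domain along x, emulating the
#' inward-facing / intermediate / outward-facing series: inter-domain
#' contacts decrease monotonically from state 1 to state 3.
#'
#' @param n_res total residues (>= 20), split between the two domains.
#' @param n_states number of states (fixed at 3).
#' @param inter_state_displacement total x-separation (Angstrom) of
#'   domain B in state 3 (state 2 gets half).
#' @param seed integer seed (controls residue identities and coordinate
#'   jitter); identical (parameters, seed) give identical structures.
#' @param first_residue numbering of the first modeled residue.
#' @return A [state_model_set()] with attribute `sequence` (named
#'   one-letter residue identities).
#' @export
make_structure <- function(n_res, n_states = 3, inter_state_displacement = 0,
                           seed = 1L, first_residue = 1L) {
  if (n_res < 20) stop("n_res must be at least 20", call. = FALSE)
  stopifnot(n_states == 3)
  set.seed(seed)
  res <- seq.int(first_residue, length.out = n_res)
  seq_aa <- sample(AA1, n_res, replace = TRUE)
  n_a <- floor(n_res / 2)
  domain <- rep(c("A", "B"), c(n_a, n_res - n_a))

  ## three helix axes per domain, triangular packing 8.5 A apart
  centers_a <- rbind(c(0, 0), c(8.5, 0), c(4.25, 7.4))
  centers_b <- centers_a
  centers_b[, 1] <- centers_b[, 1] + 15.5

  place_domain <- function(n, centers) {
    per <- ceiling(n / 3)
    xyz <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      h <- ((i - 1) %/% per) + 1
      k <- (i - 1) %% per
      ang <- k * 100 * pi / 180
      xyz[i, ] <- c(centers[h, 1] + 2.3 * cos(ang),
                    centers[h, 2] + 2.3 * sin(ang),
                    k * 1.5)
    }
    xyz
  }
  ca <- rbind(place_domain(n_a, centers_a),
              place_domain(n_res - n_a, centers_b))
  ca <- ca + matrix(stats::rnorm(3 * n_res, sd = 0.1), n_res, 3)
  ## pseudo side chain: radially outward from the local helix axis
  cb <- ca
  for (i in seq_len(n_res)) {
    ctr <- if (domain[i] == "A") colMeans(centers_a) else colMeans(centers_b)
    v <- ca[i, 1:2] - ctr
    v <- v / sqrt(sum(v * v))
    cb[i, 1:2] <- cb[i, 1:2] + 1.7 * v
  }

  models <- lapply(1:3, function(s) {
    shift <- c(0, inter_state_displacement / 2, inter_state_displacement)[s]
    mk <- function(xyz) {
      xyz2 <- xyz
      xyz2[domain == "B", 1] <- xyz2[domain == "B", 1] + shift
      xyz2
    }
    ca_s <- mk(ca); cb_s <- mk(cb)
    atoms <- data.frame(
      resno = rep(res, each = 2),
      elety = rep(c("CA", "CB"), n_res),
      resid = rep(unname(toupper(AA3[seq_aa])), each = 2),
      x = as.vector(rbind(ca_s[, 1], cb_s[, 1])),
      y = as.vector(rbind(ca_s[, 2], cb_s[, 2])),
      z = as.vector(rbind(ca_s[, 3], cb_s[, 3])),
      stringsAsFactors = FALSE)
    state_model(s, atoms)
  })
  out <- state_model_set(models)
  attr(out, "sequence") <- stats::setNames(seq_aa, res)
  attr(out, "domain_split") <- res[n_a]
  out
}

## Heavy-tailed allele counts: discrete Pareto, capped.
sample_allele_counts <- function(n, alpha = 1.3, cap = 60) {
  u <- stats::runif(n)
  pmin(floor(u^(-1 / alpha)), cap)
}

#' Generate a synthetic variant cohort
#'
#' Places `round(enrichment * n)` variants at positions drawn from the
#' 10-Angstrom contact neighborhoods of the given centers and the rest
#' uniformly over modeled residues. Allele counts follow a truncated
#' heavy-tailed integer distribution (optionally rescaled to an exact
#' total); allele frequencies are log-uniform over `af_log10_range`.
#'
#' @param n number of variants.
#' @param structures a [make_structure()] result.
#' @param hotspot_centers residues around which to enrich (may be empty).
#' @param enrichment fraction in \[0, 1\] of variants placed near centers.
#' @param af_log10_range log10 allele-frequency range, default c(-6, -2).
#' @param seed integer seed.
#' @param total_allele_count optional exact total for allele counts.
#' @param significance_probs named probabilities over significance
#'   labels; default mirrors a ClinVar-like mix.
#' @param map optional precomputed state-1 contact map (10 Angstrom).
#' @return List with `variants` (a [variant_set()]) and `truth`
#'   (planted residues = union of center neighborhoods, per-variant
#'   `enriched` flags, seed).
#' @export
make_variant_cohort <- function(n, structures, hotspot_centers = integer(),
                                enrichment = 0, af_log10_range = c(-6, -2),
                                seed = 1L, total_allele_count = NULL,
                                significance_probs = c(pathogenic = 0.09,
                                                       vus = 0.77,
                                                       unannotated = 0.07,
                                                       conflicting = 0.02,
                                                       benign = 0.05),
                                map = NULL) {
  stopifnot(enrichment >= 0, enrichment <= 1)
  res <- structures$residues
  if (length(hotspot_centers) > 0 && !all(hotspot_centers %in% res))
    stop("hotspot centers outside the modeled range: ",
         paste(setdiff(hotspot_centers, res), collapse = ", "),
         call. = FALSE)
  if (is.null(map) && length(hotspot_centers) > 0)
    map <- build_contact_map(structures$models[[1]], 10)
  planted <- if (length(hotspot_centers) > 0)
    sort(unique(unlist(lapply(hotspot_centers, contact_neighbors, map = map))))
  else integer()

  set.seed(seed)
  n_enr <- if (length(planted) > 0) round(enrichment * n) else 0L
  pos_enr <- if (n_enr > 0) sample(planted, n_enr, replace = TRUE) else integer()
  ## uniform background positions are distinct where possible, mirroring
  ## the permutation null's without-replacement placement
  pos_uni <- sample(res, n - n_enr, replace = (n - n_enr) > length(res))
  position <- c(pos_enr, pos_uni)
  enriched <- rep(c(TRUE, FALSE), c(n_enr, n - n_enr))

  seq_aa <- attr(structures, "sequence")
  ref <- unname(seq_aa[as.character(position)])
  alt <- vapply(ref, function(r) sample(setdiff(AA1, r), 1), character(1))
  ## enforce unique (position, alt) keys
  key <- paste0(position, alt)
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    for (i in d) alt[i] <- sample(setdiff(AA1, ref[i]), 1)
    key <- paste0(position, alt)
  }

  ac <- sample_allele_counts(n)
  if (!is.null(total_allele_count)) {
    stopifnot(total_allele_count >= n)
    diff <- total_allele_count - sum(ac)
    while (diff != 0) {
      i <- sample.int(n, 1)
      step <- sign(diff)
      if (ac[i] + step >= 1) {
        ac[i] <- ac[i] + step
        diff <- diff - step
      }
    }
  }
  af <- 10^stats::runif(n, af_log10_range[1], af_log10_range[2])
  sig <- sample(names(significance_probs), n, replace = TRUE,
                prob = significance_probs)
  phen <- sample(c("pxe", "gaci", "both", "none"), n, replace = TRUE,
                 prob = c(0.15, 0.01, 0.12, 0.72))
  in_cv <- sig != "unannotated"
  vs <- variant_set(data.frame(
    position = position, ref_aa = ref, alt_aa = alt,
    allele_frequency = af, allele_count = ac,
    significance = sig, phenotype = phen,
    in_clinvar = in_cv, in_gnomad = TRUE,
    stringsAsFactors = FALSE), provenance = "synthetic")
  list(variants = vs,
       truth = list(planted_residues = planted,
                    enriched = enriched[order(position, alt)],
                    centers = hotspot_centers, seed = seed))
}

#' Generate stability profiles for planted mechanism categories
#'
#' Builds a per-variant stability table whose ddG pattern, PAM30 score
#' and hydropathy delta fire (or avoid firing) the planted rule:
#' `functional_stability` variants get ddG near `effect` in all three
#' states; `conformational_dynamics` in exactly one state;
#' `atp_binding`/`ligand_binding`/`regulation` get neutral ddG with a
#' strongly negative PAM30; `membrane_interactions` neutral ddG with a
#' large hydropathy drop; `none` is neutral everywhere. Gaussian noise
#' of sd `noise_sd` is added to all ddG entries.
#'
#' @param variants a [variant_set()].
#' @param truth character vector of planted categories along the sorted
#'   variant rows (values from the six categories or "none").
#' @param effect planted |ddG|, kcal/mol (>= 0).
#' @param noise_sd ddG noise, kcal/mol (>= 0).
#' @param seed integer seed.
#' @return A `stability_table` consumable by [classify_cohort()].
#' @export
make_stability_profiles <- function(variants, truth, effect = 5,
                                    noise_sd = 0.3, seed = 1L) {
  stopifnot(effect >= 0, noise_sd >= 0, length(truth) == nrow(variants))
  set.seed(seed)
  n <- nrow(variants)
  ddg <- matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  pam <- integer(n); dhyd <- numeric(n)
  for (i in seq_len(n)) {
    switch(truth[i],
      functional_stability = { ddg[i, ] <- ddg[i, ] + effect
                               pam[i] <- 2; dhyd[i] <- 0 },
      conformational_dynamics = { s <- sample.int(3, 1)
                                  ddg[i, s] <- ddg[i, s] + effect
                                  pam[i] <- 2; dhyd[i] <- 0 },
      atp_binding = { pam[i] <- -5; dhyd[i] <- 0 },
      ligand_binding = { pam[i] <- -5; dhyd[i] <- 0 },
      regulation = { pam[i] <- -5; dhyd[i] <- 0 },
      membrane_interactions = { pam[i] <- 1; dhyd[i] <- -4 },
      { pam[i] <- 2; dhyd[i] <- 0 })
  }
  out <- data.frame(position = variants$position, ref_aa = variants$ref_aa,
                    alt_aa = variants$alt_aa,
                    ddg_state1 = ddg[, 1], ddg_state2 = ddg[, 2],
                    ddg_state3 = ddg[, 3],
                    frustration_state1 = NA_real_,
                    frustration_state2 = NA_real_,
                    frustration_state3 = NA_real_,
                    pam30 = pam, delta_hydrophobicity = dhyd,
                    stringsAsFactors = FALSE)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Draws a toy three-state structure, plants one mechanism category (or
#' "none") per variant at distinct positions, emits the matching
#' annotation configuration (pocket sites, PTM sites, membrane slab) and
#' the stability table. The resulting cohort round-trips through
#' [build_residue_context()] and [classify_cohort()] with recoverable
#' labels.
#'
#' @param n_res residues in the toy structure.
#' @param n number of variants (<= `n_res`).
#' @param seed integer seed.
#' @param effect,noise_sd passed to [make_stability_profiles()].
#' @param categories candidate planted categories.
#' @return List: `structures`, `variants`, `profiles`, `truth` (named
#'   category per variant key), `config`, `seed`.
#' @export
synthetic_cohort <- function(n_res = 120, n = 48, seed = 1L, effect = 5,
                             noise_sd = 0.3,
                             categories = c("atp_binding", "ligand_binding",
                                            "membrane_interactions",
                                            "regulation",
                                            "conformational_dynamics",
                                            "functional_stability", "none")) {
  stopifnot(n <= n_res)
  structures <- make_structure(n_res, inter_state_displacement = 6,
                               seed = seed)
  set.seed(seed + 1L)
  res <- structures$residues
  seq_aa <- attr(structures, "sequence")
  rel_asa <- residue_rel_asa(structures$models[[1]])
  exposed <- res[rel_asa > 0.5]

  position <- sample(res, n)
  cat_pool <- rep(categories, length.out = n)
  truth <- sample(cat_pool)
  ## membrane planting needs a lipid-exposed residue; swap positions in
  ## from the exposed pool where necessary
  for (i in which(truth == "membrane_interactions")) {
    if (!(position[i] %in% exposed)) {
      free <- setdiff(exposed, position)
      if (length(free) == 0) { truth[i] <- "none"; next }
      position[i] <- sample(free, 1)
    }
  }
  ref <- unname(seq_aa[as.character(position)])
  ## charge-matched replacements keep the membrane charge rule quiet for
  ## non-membrane plants
  charge_group <- function(a) {
    if (a %in% c("R", "K")) "pos" else if (a %in% c("D", "E")) "neg" else "unc"
  }
  alt <- vapply(seq_len(n), function(i) {
    pool <- setdiff(AA1, ref[i])
    same <- pool[vapply(pool, charge_group, "") == charge_group(ref[i])]
    sample(if (length(same) > 0) same else pool, 1)
  }, character(1))

  vs <- variant_set(data.frame(
    position = position, ref_aa = ref, alt_aa = alt,
    allele_frequency = 10^stats::runif(n, -6, -3),
    allele_count = sample_allele_counts(n),
    significance = "vus", phenotype = "none",
    in_clinvar = TRUE, in_gnomad = TRUE, stringsAsFactors = FALSE),
    provenance = "synthetic")
  ord <- order(position, alt)
  truth <- truth[ord]
  names(truth) <- variant_key(vs)

  split <- attr(structures, "domain_split")
  config <- annotation_config(
    domains = data.frame(name = c("TMD1", "NBD1"),
                         start = c(min(res), split + 1),
                         end = c(split, max(res))),
    ptm_sites = vs$position[truth == "regulation"],
    membrane_slab = if (any(truth == "membrane_interactions"))
      range(structures$models[[1]]$atoms$z) + c(-1, 1) else NULL,
    atp_sites = vs$position[truth == "atp_binding"],
    ligand_sites = vs$position[truth == "ligand_binding"])

  profiles <- make_stability_profiles(vs, unname(truth), effect = effect,
                                      noise_sd = noise_sd, seed = seed + 2L)
  list(structures = structures, variants = vs, profiles = profiles,
       truth = truth, config = config, seed = seed)
}
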