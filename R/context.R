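#' Residue annotation configuration
#'
#' Holds every residue-level annotation input that is data, not code:
#' domain boundaries, nucleotide-binding motif intervals, PTM sites,
#' regulatory intervals, interfacial helix intervals, the membrane slab
#' (z bounds in the model frame), reference coordinates for bound ATP and
#' substrate, conserved binding-site residue lists, and the ABCC-family
#' divergent (degenerate NBD1) region.
#'
#' @param domains data.frame(name, start, end); names from
#'   \{TMD0, L0, TMD1, NBD1, L1, TMD2, NBD2\}.
#' @param motifs data.frame(name, start, end); names from
#'   \{walker_a, walker_b, signature, h_loop, q_loop\}.
#' @param ptm_sites integer vector of PTM positions.
#' @param regulatory_intervals data.frame(start, end).
#' @param interfacial_helices data.frame(start, end); defaults are the
#'   three membrane-surface positively charged helices 204-208, 217-228
#'   and 931-943.
#' @param membrane_slab numeric c(zmin, zmax) or NULL.
#' @param atp_coords,ligand_coords numeric n x 3 matrices of reference
#'   heavy-atom coordinates (model frame, states 2/3), or NULL.
#' @param atp_sites,ligand_sites integer vectors of conserved
#'   binding-site residues.
#' @param abcc_divergent data.frame(start, end) or NULL.
#' @param pocket_cutoff distance (Angstrom) defining pocket membership
#'   around reference coordinates; default 5.
#' @param ptm_window sequence window around a PTM considered regulatory;
#'   default 3 residues.
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(domains = NULL, motifs = NULL,
                              ptm_sites = integer(),
                              regulatory_intervals = NULL,
                              interfacial_helices = data.frame(
                                start = c(204, 217, 931),
                                end = c(208, 228, 943)),
                              membrane_slab = NULL,
                              atp_coords = NULL, ligand_coords = NULL,
                              atp_sites = integer(),
                              ligand_sites = integer(),
                              abcc_divergent = NULL,
                              pocket_cutoff = 5, ptm_window = 3) {
  structure(list(domains = domains, motifs = motifs,
                 ptm_sites = as.integer(ptm_sites),
                 regulatory_intervals = regulatory_intervals,
                 interfacial_helices = interfacial_helices,
                 membrane_slab = membrane_slab,
                 atp_coords = atp_coords, ligand_coords = ligand_coords,
                 atp_sites = as.integer(atp_sites),
                 ligand_sites = as.integer(ligand_sites),
                 abcc_divergent = abcc_divergent,
                 pocket_cutoff = pocket_cutoff,
                 ptm_window = ptm_window),
            class = "annotation_config")
}

#' Read an annotation configuration from YAML
#' @param path YAML file with keys matching [annotation_config()]
#'   arguments; interval tables as lists of \{name, start, end\}.
#' @return An `annotation_config`.
#' @export
read_annotation_config <- function(path) {
  y <- yaml::read_yaml(path)
  iv <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    do.call(rbind, lapply(x, function(e) {
      data.frame(name = e$name %||% NA_character_,
                 start = as.integer(e$start), end = as.integer(e$end),
                 stringsAsFactors = FALSE)
    }))
  }
  cm <- function(x) if (is.null(x)) NULL else matrix(unlist(x), ncol = 3, byrow = TRUE)
  annotation_config(
    domains = iv(y$domains), motifs = iv(y$motifs),
    ptm_sites = unlist(y$ptm_sites) %||% integer(),
    regulatory_intervals = iv(y$regulatory_intervals),
    interfacial_helices = iv(y$interfacial_helices) %||%
      data.frame(start = c(204, 217, 931), end = c(208, 228, 943)),
    membrane_slab = unlist(y$membrane_slab),
    atp_coords = cm(y$atp_coords), ligand_coords = cm(y$ligand_coords),
    atp_sites = unlist(y$atp_sites) %||% integer(),
    ligand_sites = unlist(y$ligand_sites) %||% integer(),
    abcc_divergent = iv(y$abcc_divergent),
    pocket_cutoff = y$pocket_cutoff %||% 5,
    ptm_window = y$ptm_window %||% 3)
}

#' Default ABCC6 annotation configuration
#'
#' Approximate defaults for human ABCC6 (NP_001162.5) assembled from
#' UniProt-style domain/motif annotation. These intervals are packaged
#' defaults, not measured quantities; supply a curated configuration for
#' production analyses.
#' @return An `annotation_config`.
#' @export
default_abcc6_config <- function() {
  read_annotation_config(system.file("extdata", "abcc6_annotation.yaml",
                                     package = "mechvar"))
}

## Map positions onto named intervals; unmatched -> `none`.
interval_label <- function(pos, intervals, none = "none") {
  out <- rep(none, length(pos))
  if (is.null(intervals) || NROW(intervals) == 0L) return(out)
  for (i in seq_len(nrow(intervals))) {
    hit <- pos >= intervals$start[i] & pos <= intervals$end[i]
    out[hit] <- intervals$name[i]
  }
  out
}

## Any residue heavy atom strictly within `cutoff` of any reference atom.
near_coords <- function(model, coords, cutoff) {
  res <- model$residues
  out <- stats::setNames(rep(FALSE, length(res)), res)
  if (is.null(coords) || nrow(coords) == 0L) return(out)
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2min <- rep(Inf, nrow(xyz))
  for (k in seq_len(nrow(coords))) {
    dx <- xyz[, 1] - coords[k, 1]; dy <- xyz[, 2] - coords[k, 2]
    dz <- xyz[, 3] - coords[k, 3]
    d2min <- pmin(d2min, dx * dx + dy * dy + dz * dz)
  }
  hit <- tapply(d2min, match(a$resno, res), min) < cutoff^2
  out[] <- as.logical(hit)
  out
}

#' Annotate ATP and ligand binding pockets
#'
#' A residue is in the ATP pocket when it lies in an ATP-binding sequence
#' motif (Walker A/B, signature, H-loop, Q-loop), is a conserved
#' nucleotide-binding site, or has any heavy atom strictly within
#' `pocket_cutoff` (default 5 Angstrom) of a reference ATP atom in any
#' state. The ligand pocket is defined analogously from the substrate
#' reference atoms and conserved ligand sites.
#'
#' @param models a [state_model_set()].
#' @param config an [annotation_config()].
#' @return data.frame(residue, atp_pocket, ligand_pocket).
#' @export
annotate_pockets <- function(models, config) {
  res <- models$residues
  if (is.null(config$atp_coords) && is.null(config$ligand_coords) &&
      length(config$atp_sites) == 0L && length(config$ligand_sites) == 0L &&
      NROW(config$motifs) == 0L)
    warning("no pocket reference coordinates, sites or motif ranges configured; all pocket flags FALSE")
  atp <- in_intervals(res, config$motifs) | res %in% config$atp_sites
  lig <- res %in% config$ligand_sites
  for (m in models$models) {
    atp <- atp | near_coords(m, config$atp_coords, config$pocket_cutoff)
    lig <- lig | near_coords(m, config$ligand_coords, config$pocket_cutoff)
  }
  data.frame(residue = res, atp_pocket = unname(atp),
             ligand_pocket = unname(lig))
}

#' Annotate membrane exposure and interfacial helices
#'
#' A residue is lipid-exposed when its side-chain centroid lies within
#' the membrane slab (z bounds in the model frame, membrane normal along
#' z) and its relative accessible surface area exceeds 0.50. Interfacial
#' helix membership is purely positional.
#'
#' @param model the [state_model()] oriented in the membrane frame
#'   (state 1 conventionally).
#' @param membrane_slab numeric c(zmin, zmax).
#' @param helix_intervals data.frame(start, end).
#' @param rel_asa optional precomputed [residue_rel_asa()] vector.
#' @return data.frame(residue, membrane_exposed, interfacial_helix).
#' @export
annotate_membrane <- function(model, membrane_slab,
                              helix_intervals = NULL, rel_asa = NULL) {
  res <- model$residues
  helix <- in_intervals(res, helix_intervals)
  if (is.null(membrane_slab)) {
    return(data.frame(residue = res, membrane_exposed = FALSE,
                      interfacial_helix = helix))
  }
  if (membrane_slab[1] >= membrane_slab[2])
    stop("membrane slab zmin must be below zmax", call. = FALSE)
  if (is.null(rel_asa)) rel_asa <- residue_rel_asa(model)
  a <- model$atoms
  sidechain <- !(a$elety %in% c("N", "CA", "C", "O"))
  cz <- vapply(res, function(r) {
    sel <- a$resno == r & sidechain
    if (!any(sel)) sel <- a$resno == r & a$elety == "CA"
    if (!any(sel)) sel <- a$resno == r
    mean(a$z[sel])
  }, numeric(1))
  in_slab <- cz >= membrane_slab[1] & cz <= membrane_slab[2]
  data.frame(residue = res,
             membrane_exposed = in_slab & rel_asa[as.character(res)] > 0.50,
             interfacial_helix = helix)
}

#' Annotate regulatory importance
#'
#' A residue is regulatory when it lies within `window` residues of a PTM
#' site or inside a configured regulatory interval.
#'
#' @param residues integer vector of modeled residues.
#' @param ptm_sites integer vector of PTM positions.
#' @param regulatory_intervals data.frame(start, end) or NULL.
#' @param window sequence distance from a PTM (default 3).
#' @return Logical vector along `residues`.
#' @export
annotate_regulatory <- function(residues, ptm_sites,
                                regulatory_intervals = NULL, window = 3) {
  near_ptm <- rep(FALSE, length(residues))
  for (p in ptm_sites) near_ptm <- near_ptm | abs(residues - p) <= window
  near_ptm | in_intervals(residues, regulatory_intervals)
}

#' Inter-domain contact flag
#'
#' TRUE for residues contacting at least one residue assigned to a
#' different domain; linker loops (L0, L1) are excluded as contact
#' partners, so a contact into a loop does not make a residue
#' interfacial.
#'
#' @param map a [build_contact_map()] result.
#' @param domains character vector of domain labels along `map$residues`.
#' @return Logical vector along `map$residues`.
#' @export
interface_contacts <- function(map, domains) {
  stopifnot(length(domains) == length(map$residues))
  adj <- as.matrix(map$adj)
  partner_ok <- !(domains %in% c("L0", "L1"))
  vapply(seq_along(map$residues), function(i) {
    nb <- which(adj[i, ])
    any(domains[nb] != domains[i] & partner_ok[nb])
  }, logical(1))
}

#' Assemble the full per-residue structural context
#'
#' Runs every residue-level annotation (domain, motif, pockets, membrane
#' exposure, interfacial helix, regulatory proximity, ABCC-divergent
#' region, inter-domain contacts) over a three-state model set and one
#' configuration. Hotspot membership is initialized FALSE; the pipeline
#' writes it back after the hotspot scan.
#'
#' @param models a [state_model_set()].
#' @param config an [annotation_config()].
#' @param contact_map optional precomputed state-1 [build_contact_map()];
#'   built at 10 Angstrom if missing.
#' @return A `residue_context` data.frame, one row per modeled residue.
#' @export
build_residue_context <- function(models, config, contact_map = NULL) {
  res <- models$residues
  domain <- interval_label(res, config$domains)
  motif <- interval_label(res, config$motifs)
  pockets <- annotate_pockets(models, config)
  memb <- annotate_membrane(models$models[[1]], config$membrane_slab,
                            config$interfacial_helices)
  if (is.null(contact_map))
    contact_map <- build_contact_map(models$models[[1]], 10)
  ctx <- data.frame(
    residue = res,
    domain = domain,
    motif = motif,
    atp_pocket = pockets$atp_pocket,
    ligand_pocket = pockets$ligand_pocket,
    membrane_exposed = memb$membrane_exposed,
    interfacial_helix = memb$interfacial_helix,
    regulatory = annotate_regulatory(res, config$ptm_sites,
                                     config$regulatory_intervals,
                                     config$ptm_window),
    abcc_divergent = in_intervals(res, config$abcc_divergent),
    interface = interface_contacts(contact_map, domain),
    hotspot = FALSE,
    stringsAsFactors = FALSE)
  class(ctx) <- c("residue_context", "data.frame")
  ctx
}
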