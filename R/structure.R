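#' Load three conformational-state models
#'
#' Reads three single-chain PDB files (one per conformational state:
#' inward-facing, intermediate, outward-facing), keeps heavy atoms, and
#' checks that all states model exactly the same residue set.
#'
#' @param paths character vector of three PDB file paths, in state order.
#' @return A `state_model_set`: list of three `state_model`s plus the
#'   shared residue vector and modeled range.
#' @export
load_state_models <- function(paths) {
  stopifnot(length(paths) == 3L)
  models <- lapply(seq_along(paths), function(i) {
    pdb <- bio3d::read.pdb(paths[i], verbose = FALSE)
    at <- pdb$atom
    at <- at[at$type %in% c("ATOM", "HETATM") & at$elety != "H" &
               !grepl("^[0-9]*H", at$elety), , drop = FALSE]
    at <- at[at$type == "ATOM", , drop = FALSE]
    if (length(unique(at$chain[!is.na(at$chain)])) > 1L)
      stop("multi-chain file: ", paths[i], call. = FALSE)
    state_model(state_id = i,
                atoms = data.frame(resno = at$resno, elety = at$elety,
                                   resid = at$resid, x = at$x, y = at$y,
                                   z = at$z, stringsAsFactors = FALSE))
  })
  state_model_set(models)
}

#' Construct a single-state model from an atom table
#'
#' @param state_id integer state identifier (1, 2 or 3).
#' @param atoms data.frame with columns `resno`, `elety`, `resid`,
#'   `x`, `y`, `z` (heavy atoms only, coordinates in Angstrom).
#' @return A `state_model`.
#' @export
state_model <- function(state_id, atoms) {
  stopifnot(all(c("resno", "elety", "resid", "x", "y", "z") %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(state_id = as.integer(state_id), atoms = atoms,
                 residues = sort(unique(atoms$resno))),
            class = "state_model")
}

#' Bundle three state models sharing one residue range
#' @param models list of three [state_model()]s.
#' @return A `state_model_set` with elements `models`, `residues`,
#'   `range`.
#' @export
state_model_set <- function(models) {
  stopifnot(length(models) == 3L)
  res_sets <- lapply(models, function(m) m$residues)
  ref <- res_sets[[1]]
  for (i in 2:3) {
    diffs <- c(setdiff(ref, res_sets[[i]]), setdiff(res_sets[[i]], ref))
    if (length(diffs) > 0L)
      stop("residue sets differ between state 1 and state ", i,
           " at residue(s): ", paste(sort(unique(diffs)), collapse = ", "),
           call. = FALSE)
  }
  structure(list(models = models, residues = ref,
                 range = range(ref)),
            class = "state_model_set")
}

#' @export
print.state_model_set <- function(x, ...) {
  cat("state_model_set: 3 states,", length(x$residues),
      "residues, range [", x$range[1], ",", x$range[2], "]\n")
  invisible(x)
}

#' Write a state model to a PDB file
#' @param model a [state_model()].
#' @param path output path.
#' @export
write_state_model <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = rep("A", nrow(a)))
  invisible(path)
}

## Minimum heavy-atom distance between every residue pair, as a dense
## matrix. Computed residue-by-residue against all atoms; adequate for
## the structure sizes this package targets.
residue_min_dist <- function(model) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res <- model$residues
  n <- length(res)
  idx <- match(a$resno, res)
  out <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    ai <- xyz[idx == i, , drop = FALSE]
    ## min over atoms of residue i of squared distance to every atom
    d2 <- rep(Inf, nrow(xyz))
    for (k in seq_len(nrow(ai))) {
      dx <- xyz[, 1] - ai[k, 1]; dy <- xyz[, 2] - ai[k, 2]
      dz <- xyz[, 3] - ai[k, 3]
      d2 <- pmin(d2, dx * dx + dy * dy + dz * dz)
    }
    out[i, ] <- sqrt(tapply(d2, idx, min))
  }
  dimnames(out) <- list(res, res)
  out
}

#' Residue contact map at a distance cutoff
#'
#' Two residues are in contact when their minimum heavy-atom distance is
#' strictly below `cutoff` (default 10 Angstrom). Every residue is its
#' own neighbor; the map is symmetric.
#'
#' @param model a [state_model()].
#' @param cutoff contact distance in Angstrom; must be positive.
#' @return A `contact_map` with fields `state_id`, `cutoff`, `residues`
#'   and the logical adjacency matrix `adj` (sparse).
#' @export
build_contact_map <- function(model, cutoff = 10) {
  stopifnot(cutoff > 0)
  d <- residue_min_dist(model)
  adj <- d < cutoff
  diag(adj) <- TRUE
  structure(list(state_id = model$state_id, cutoff = cutoff,
                 residues = model$residues,
                 adj = Matrix::Matrix(adj, sparse = TRUE)),
            class = "contact_map")
}

#' Neighbors of a residue in a contact map
#' @param map a [build_contact_map()] result.
#' @param residue residue number.
#' @return Integer vector of neighbor residues (self included).
#' @export
contact_neighbors <- function(map, residue) {
  i <- match(residue, map$residues)
  if (is.na(i)) stop("residue ", residue, " not in map", call. = FALSE)
  map$residues[as.logical(map$adj[i, ])]
}

#' @export
print.contact_map <- function(x, ...) {
  nn <- Matrix::rowSums(x$adj) - 1
  cat("contact_map: state", x$state_id, ",", length(x$residues),
      "residues, cutoff", x$cutoff, "A, mean neighbors",
      round(mean(nn), 1), "\n")
  invisible(x)
}
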