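# Fixtures built in code: tiny structures with exact geometry, and small
# variant tables.

# A state_model whose residues sit on a line at given CA x-spacings,
# with a CB 1 A above each CA. Controls inter-residue distances exactly.
line_model <- function(x, state_id = 1L) {
  n <- length(x)
  state_model(state_id, data.frame(
    resno = rep(seq_len(n), each = 2),
    elety = rep(c("CA", "CB"), n),
    resid = rep("ALA", 2 * n),
    x = rep(x, each = 2),
    y = 0,
    z = rep(c(0, 1), n),
    stringsAsFactors = FALSE))
}

# Minimal variant_set from position/ref/alt triples.
vs_from <- function(position, ref, alt, ...) {
  variant_set(data.frame(position = position, ref_aa = ref, alt_aa = alt,
                         in_gnomad = TRUE, ...,
                         stringsAsFactors = FALSE))
}

# Brute-force residue min-distance contact oracle.
brute_contacts <- function(model, cutoff = 10) {
  a <- model$atoms
  res <- model$residues
  n <- length(res)
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ai <- a[a$resno == res[i], c("x", "y", "z")]
    aj <- a[a$resno == res[j], c("x", "y", "z")]
    dmin <- min(as.matrix(stats::dist(rbind(ai, aj)))[seq_len(nrow(ai)),
                                                      nrow(ai) + seq_len(nrow(aj))])
    out[i, j] <- i == j || dmin < cutoff
  }
  out
}

# The cohort stability fixture shipped with the package.
cohort_fixture <- function() {
  utils::read.table(system.file("extdata", "abcc6_cohort_stability.tsv",
                                package = "mechvar"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Residue context rows that are all-FALSE except what the caller sets.
blank_context <- function(residues) {
  data.frame(residue = residues, domain = "TMD1", motif = "none",
             atp_pocket = FALSE, ligand_pocket = FALSE,
             membrane_exposed = FALSE, interfacial_helix = FALSE,
             regulatory = FALSE, abcc_divergent = FALSE,
             interface = FALSE, hotspot = FALSE, stringsAsFactors = FALSE)
}
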