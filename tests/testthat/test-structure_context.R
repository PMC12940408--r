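test_that("three-state PDB loading enforces a shared residue range", {
  s <- make_structure(20, seed = 1)
  paths <- vapply(1:3, function(i) {
    p <- tempfile(fileext = ".pdb")
    write_state_model(s$models[[i]], p)
    p
  }, character(1))
  on.exit(unlink(paths))
  loaded <- load_state_models(paths)
  expect_equal(loaded$range, c(1, 20))
  expect_equal(loaded$residues, 1:20)

  s26 <- make_structure(20, seed = 1, first_residue = 26)
  for (i in 1:3) write_state_model(s26$models[[i]], paths[i])
  expect_equal(load_state_models(paths)$range[1], 26)

  ## drop residue 50-equivalent (here 30) from state 2
  m2 <- s26$models[[2]]
  m2$atoms <- m2$atoms[m2$atoms$resno != 30, ]
  write_state_model(state_model(2, m2$atoms), paths[2])
  expect_error(load_state_models(paths), "state 2.*30")
})

test_that("contacts use strict minimum heavy-atom distance", {
  ## CB atoms are 1 A above CA, so CA spacing 9.9 gives min distance 9.9
  m <- line_model(c(0, 9.9, 19.9))
  map <- build_contact_map(m, 10)
  expect_true(2 %in% contact_neighbors(map, 1))
  expect_true(1 %in% contact_neighbors(map, 2))
  m10 <- line_model(c(0, 10.0))
  expect_false(2 %in% contact_neighbors(build_contact_map(m10, 10), 1))
})

test_that("contact maps equal the all-pairs brute-force oracle", {
  s <- make_structure(24, inter_state_displacement = 5, seed = 3)
  for (st in 1:3) {
    model <- s$models[[st]]
    map <- build_contact_map(model, 10)
    expect_equal(unname(as.matrix(map$adj)), brute_contacts(model, 10))
  }
})

test_that("contact maps are symmetric, reflexive and cutoff-monotone", {
  s <- make_structure(40, inter_state_displacement = 7, seed = 9)
  m <- s$models[[2]]
  a8 <- as.matrix(build_contact_map(m, 8)$adj)
  a12 <- as.matrix(build_contact_map(m, 12)$adj)
  for (a in list(a8, a12)) {
    expect_true(all(a == t(a)))
    expect_true(all(diag(a)))
  }
  expect_true(all(a12[a8]))  # growing the cutoff never removes a contact
})

test_that("pocket flags combine reference-atom distance, motifs and sites", {
  s <- make_structure(30, seed = 2)
  ca1 <- s$models[[1]]$atoms
  ref_atom <- as.numeric(ca1[ca1$resno == 5 & ca1$elety == "CA",
                             c("x", "y", "z")]) + c(3.8, 0, 0)
  cfg <- annotation_config(
    motifs = data.frame(name = "walker_a", start = 20, end = 22),
    atp_coords = matrix(ref_atom, 1, 3))
  pk <- annotate_pockets(s, cfg)
  expect_true(pk$atp_pocket[pk$residue == 5])     # atom 3.8 A from ATP
  expect_true(all(pk$atp_pocket[pk$residue %in% 20:22]))  # motif interval
  far <- setdiff(which(!pk$atp_pocket), c(5, 20:22))
  expect_true(length(far) > 0)
  expect_false(any(pk$ligand_pocket))

  ## distance-threshold monotonicity; at 0 only range/site flags remain
  cfg5 <- cfg; cfg5$pocket_cutoff <- 5
  cfg9 <- cfg; cfg9$pocket_cutoff <- 9
  cfg0 <- cfg; cfg0$pocket_cutoff <- 1e-9
  p5 <- annotate_pockets(s, cfg5)$atp_pocket
  p9 <- annotate_pockets(s, cfg9)$atp_pocket
  p0 <- annotate_pockets(s, cfg0)$atp_pocket
  expect_true(all(p9[p5]))
  expect_equal(which(p0), which(pk$residue %in% 20:22))
})

test_that("empty pocket configuration warns and returns all-FALSE", {
  s <- make_structure(20, seed = 2)
  expect_warning(pk <- annotate_pockets(s, annotation_config()),
                 "all pocket flags FALSE")
  expect_false(any(pk$atp_pocket) || any(pk$ligand_pocket))
})

test_that("membrane exposure needs both the slab and >50% relative ASA", {
  s <- make_structure(30, seed = 4)
  m <- s$models[[1]]
  rel <- residue_rel_asa(m)
  zr <- range(m$atoms$z) + c(-1, 1)
  memb <- annotate_membrane(m, zr, data.frame(start = 8, end = 12),
                            rel_asa = rel)
  exposed <- memb$residue[memb$membrane_exposed]
  buried <- memb$residue[!memb$membrane_exposed]
  expect_true(all(rel[as.character(exposed)] > 0.5))
  expect_true(all(rel[as.character(buried)] <= 0.5))
  expect_true(length(exposed) > 0 && length(buried) > 0)
  expect_true(all(memb$interfacial_helix[memb$residue %in% 8:12]))
  expect_false(any(memb$interfacial_helix[!memb$residue %in% 8:12]))
  ## a slab excluding every centroid exposes nothing
  none <- annotate_membrane(m, c(1e5, 1e5 + 1), rel_asa = rel)
  expect_false(any(none$membrane_exposed))
  expect_error(annotate_membrane(m, c(5, 5)), "zmin")
})

test_that("regulatory proximity uses a +/-3 window around PTMs", {
  res <- c(500, 899, 902, 905, 906, 920)
  reg <- annotate_regulatory(res, ptm_sites = c(244, 902),
                             regulatory_intervals = data.frame(start = 911,
                                                               end = 931))
  expect_equal(reg, c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("inter-domain contact flags match a brute-force scan", {
  s <- make_structure(30, seed = 6)
  map <- build_contact_map(s$models[[1]], 10)
  doms <- rep(c("TMD1", "NBD1"), c(15, 15))
  flag <- interface_contacts(map, doms)
  adj <- as.matrix(map$adj)
  oracle <- vapply(seq_len(30), function(i)
    any(adj[i, ] & doms != doms[i]), logical(1))
  expect_equal(flag, oracle)
  expect_true(any(flag) && !all(flag))

  ## linker partners never confer interface status
  doms_l <- rep(c("TMD1", "L1"), c(15, 15))
  expect_false(any(interface_contacts(map, doms_l)[1:15]))
})

test_that("context annotation is a pure function of structure and config", {
  s <- make_structure(25, seed = 8)
  cfg <- annotation_config(
    domains = data.frame(name = c("TMD1", "NBD1"), start = c(1, 13),
                         end = c(12, 25)),
    motifs = data.frame(name = "walker_a", start = 14, end = 16),
    ptm_sites = 20, membrane_slab = range(s$models[[1]]$atoms$z))
  c1 <- suppressWarnings(build_residue_context(s, cfg))
  c2 <- suppressWarnings(build_residue_context(s, cfg))
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 25L)
  expect_true(all(c1$domain %in% c("TMD1", "NBD1")))
  expect_equal(c1$motif[c1$residue %in% 14:16], rep("walker_a", 3))
})

test_that("annotation config round-trips through YAML", {
  cfg <- annotation_config(
    domains = data.frame(name = "TMD1", start = 1, end = 50),
    ptm_sites = c(10, 20), membrane_slab = c(-15, 15))
  y <- tempfile(fileext = ".yaml")
  on.exit(unlink(y))
  yaml::write_yaml(list(
    domains = list(list(name = "TMD1", start = 1, end = 50)),
    ptm_sites = c(10, 20), membrane_slab = c(-15, 15)), y)
  got <- read_annotation_config(y)
  expect_equal(got$domains$start, 1L)
  expect_equal(got$ptm_sites, c(10L, 20L))
  expect_equal(got$membrane_slab, c(-15, 15))
  expect_equal(got$ptm_window, 3)
  ## the packaged ABCC6 defaults parse and cover the modeled range
  abcc6 <- default_abcc6_config()
  expect_equal(abcc6$domains$start[1], 26L)
  expect_true("walker_a" %in% abcc6$motifs$name)
})
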