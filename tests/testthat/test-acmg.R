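# Independent enumeration of the 2015 combining rules, coded separately
# from the package's combiner, over the five lines this study populates.
oracle_class <- function(pm1, pm2, pm5, pp3, pp4) {
  pm <- sum(pm1, pm2, pm5)
  pp <- sum(pp3, pp4)
  if (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4))
    "likely_pathogenic" else "vus"
}

five_line_vectors <- function() {
  g <- expand.grid(PM1 = c(FALSE, TRUE), PM2 = c(FALSE, TRUE),
                   PM5 = c(FALSE, TRUE), PP3 = c(FALSE, TRUE),
                   PP4 = c(FALSE, TRUE))
  lapply(seq_len(nrow(g)), function(i)
    evidence_vector(PM1 = g$PM1[i], PM2 = g$PM2[i], PM5 = g$PM5[i],
                    PP3 = g$PP3[i], PP4 = g$PP4[i]))
}

test_that("the combiner matches an exhaustive five-line enumeration", {
  for (ev in five_line_vectors()) {
    call <- combine_acmg(ev)
    expect_equal(call$combined_class,
                 oracle_class(ev[["PM1"]], ev[["PM2"]], ev[["PM5"]],
                              ev[["PP3"]], ev[["PP4"]]))
  }
})

test_that("combining handles the canonical patterns", {
  lp <- combine_acmg(evidence_vector("PM1", "PM2", "PM5"))
  expect_equal(lp$combined_class, "likely_pathogenic")
  expect_equal(lp$satisfied_rule, "lp_3pm")
  expect_equal(lp$lines_to_lp, 0)

  expect_equal(combine_acmg(evidence_vector())$combined_class, "vus")

  path <- combine_acmg(evidence_vector("PVS1", "PS1"))
  expect_equal(path$combined_class, "pathogenic")

  ben <- combine_acmg(evidence_vector("BS1", "BS2"))
  expect_equal(ben$combined_class, "benign")
  lb <- combine_acmg(evidence_vector("BP1", "BP2"))
  expect_equal(lb$combined_class, "likely_benign")

  conflict <- combine_acmg(evidence_vector("PM1", "PM2", "PM5", "BA1"))
  expect_equal(conflict$combined_class, "vus")
  expect_equal(conflict$satisfied_rule, "conflicting_evidence")

  expect_error(evidence_vector("PM9"), "undefined ACMG")
})

test_that("evidence gap equals brute-force minimal-addition search", {
  brute_gap <- function(ev) {
    cnt <- mechvar:::evidence_counts(ev)
    best <- Inf
    for (a in 0:6) for (b in 0:6) {
      cls <- mechvar:::combine_from_counts(cnt$pvs, cnt$ps, cnt$pm + a,
                                           cnt$pp + b, cnt$ba, cnt$bs,
                                           cnt$bp)$class
      if (cls %in% c("pathogenic", "likely_pathogenic"))
        best <- min(best, a + b)
    }
    best
  }
  expect_equal(evidence_gap(evidence_vector("PM1", "PM2")), 1)
  expect_equal(evidence_gap(evidence_vector("PM1", "PM2", "PM5")), 0)
  expect_equal(evidence_gap(evidence_vector()), 3)
  for (ev in five_line_vectors()) {
    expect_equal(evidence_gap(ev), brute_gap(ev))
    ## zero gap exactly on the likely-pathogenic-or-stronger side
    expect_equal(evidence_gap(ev) == 0,
                 combine_acmg(ev)$combined_class %in%
                   c("pathogenic", "likely_pathogenic"))
  }
})

test_that("adding evidence never weakens the call or widens the gap", {
  rank <- c(benign = 1, likely_benign = 2, vus = 3,
            likely_pathogenic = 4, pathogenic = 5)
  addable <- c("PVS1", "PS1", "PM3", "PP1")
  for (ev in five_line_vectors()) {
    base <- combine_acmg(ev)
    for (line in addable) {
      ev2 <- ev
      ev2[line] <- TRUE
      more <- combine_acmg(ev2)
      expect_gte(rank[more$combined_class], rank[base$combined_class])
      expect_lte(more$lines_to_lp, base$lines_to_lp)
    }
  }
})

test_that("evidence assignment implements the five line definitions", {
  ctx <- blank_context(487)
  v <- list(position = 487, ref_aa = "R", alt_aa = "G",
            allele_frequency = 6.57e-6, in_clinvar = TRUE, in_gnomad = TRUE,
            phenotype = "none")
  ev <- assign_evidence(v, ctx[1, ], hotspot_members = 480:495,
                        call = "functional_stability",
                        pathogenic_positions = list(`487` = "W"))
  expect_true(ev[["PM1"]])  # hotspot residue
  expect_true(ev[["PM2"]])  # AF below 0.33% past residue 250
  expect_true(ev[["PM5"]])  # different pathogenic change at 487
  expect_true(ev[["PP3"]])  # categorized
  expect_false(ev[["PP4"]]) # no phenotype
  expect_equal(combine_acmg(ev)$combined_class, "likely_pathogenic")

  ## early positions never earn frequency-based PM2
  early <- assign_evidence(list(position = 200, ref_aa = "G", alt_aa = "R",
                                allele_frequency = 1e-6, in_clinvar = FALSE,
                                in_gnomad = TRUE, phenotype = "none"),
                           blank_context(200)[1, ], integer(),
                           "uncategorized")
  expect_false(early[["PM2"]])

  ## ClinVar-only presence earns PM2 regardless of position
  cv_only <- assign_evidence(list(position = 200, ref_aa = "G", alt_aa = "R",
                                  allele_frequency = NA, in_clinvar = TRUE,
                                  in_gnomad = FALSE, phenotype = "both"),
                             blank_context(200)[1, ], integer(),
                             "uncategorized")
  expect_true(cv_only[["PM2"]])
  expect_true(cv_only[["PP4"]])

  ## motif residues earn PM1 without hotspot membership
  motif_ctx <- blank_context(695); motif_ctx$motif <- "walker_a"
  in_motif <- assign_evidence(list(position = 695, ref_aa = "G", alt_aa = "R",
                                   allele_frequency = NA, in_clinvar = TRUE,
                                   in_gnomad = FALSE, phenotype = "none"),
                              motif_ctx[1, ], integer(), "uncategorized")
  expect_true(in_motif[["PM1"]])
  ## the same change as the known pathogenic one is not PM5
  same <- assign_evidence(v, ctx[1, ], integer(), "uncategorized",
                          pathogenic_positions = list(`487` = "G"))
  expect_false(same[["PM5"]])
})

test_that("reclassification reports count reachers and near-misses", {
  zero <- reclassification_report(
    evidence = list(a = evidence_vector("PM1")), existing_plp_count = 84)
  expect_equal(zero$n_reclassified, 0)
  expect_equal(zero$percent_increase, 0)

  set.seed(9)
  evs <- lapply(1:40, function(i) {
    ev <- evidence_vector()
    for (l in sample(c("PM1", "PM2", "PM5", "PP3", "PP4"), sample(0:4, 1)))
      ev[l] <- TRUE
    ev
  })
  names(evs) <- paste0("v", 1:40)
  rep <- reclassification_report(evidence = evs, existing_plp_count = 84)
  oracle_n <- sum(vapply(evs, function(e)
    combine_acmg(e)$combined_class == "likely_pathogenic", logical(1)))
  oracle_one <- sum(vapply(evs, function(e) evidence_gap(e) == 1, logical(1)))
  expect_equal(rep$n_reclassified, oracle_n)
  expect_equal(rep$n_one_away, oracle_one)
  expect_equal(rep$percent_increase, round(100 * oracle_n / 84))
})
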