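test_that("single-variant calls follow the order-of-specificity tree", {
  ctx <- blank_context(1)

  atp <- ctx; atp$atp_pocket <- TRUE
  call <- classify_variant(list(position = 1302, ref_aa = "G", alt_aa = "R"),
                           atp[1, ], NULL)
  expect_equal(call$category, "atp_binding")
  expect_true("atp_nonconservative" %in% call$triggered_rules)

  prof <- data.frame(ddg_state1 = -0.1, ddg_state2 = 0, ddg_state3 = 8,
                     pam30 = -2, delta_hydrophobicity = -0.4)
  conf <- classify_variant(list(position = 1042, ref_aa = "G", alt_aa = "S"),
                           ctx[1, ], prof)
  expect_equal(conf$category, "conformational_dynamics")

  prof2 <- data.frame(ddg_state1 = 0, ddg_state2 = 0.1, ddg_state3 = -1.4,
                      pam30 = -3, delta_hydrophobicity = -3.7)
  un <- classify_variant(list(position = 317, ref_aa = "S", alt_aa = "R"),
                         ctx[1, ], prof2)
  expect_equal(un$category, "uncategorized")
  expect_length(un$triggered_rules, 0)

  iface <- ctx; iface$interface <- TRUE
  prof3 <- data.frame(ddg_state1 = 1.2, ddg_state2 = 0.5, ddg_state3 = 0.4,
                      pam30 = -2, delta_hydrophobicity = -0.1)
  stab <- classify_variant(list(position = 1138, ref_aa = "R", alt_aa = "Q"),
                           iface[1, ], prof3)
  expect_equal(stab$category, "functional_stability")
  expect_equal(stab$triggered_rules, "interface_charge_loss")
})

test_that("pocket rules outrank the global stability rules", {
  ctx <- blank_context(1); ctx$atp_pocket <- TRUE
  prof <- data.frame(ddg_state1 = 5, ddg_state2 = 5, ddg_state3 = 5,
                     pam30 = 3, delta_hydrophobicity = 0)
  call <- classify_variant(list(position = 1, ref_aa = "A", alt_aa = "V"),
                           ctx[1, ], prof)
  expect_equal(call$category, "atp_binding")
  expect_equal(call$triggered_rules, "atp_destabilizing")
})

test_that("membrane rule fires on hydropathy loss or charge change", {
  ctx <- blank_context(1); ctx$membrane_exposed <- TRUE
  hyd <- data.frame(ddg_state1 = 0, ddg_state2 = 0, ddg_state3 = 0,
                    pam30 = 1, delta_hydrophobicity = -2.6)
  expect_equal(classify_variant(list(position = 1, ref_aa = "I", alt_aa = "T"),
                                ctx[1, ], hyd)$category,
               "membrane_interactions")
  chg <- data.frame(ddg_state1 = 0, ddg_state2 = 0, ddg_state3 = 0,
                    pam30 = 1, delta_hydrophobicity = 0.3)
  expect_equal(classify_variant(list(position = 1, ref_aa = "L", alt_aa = "K"),
                                ctx[1, ], chg)$category,
               "membrane_interactions")
})

test_that("missing stability data degrades to annotation-only, flagged", {
  ctx <- blank_context(1)
  call <- classify_variant(list(position = 9, ref_aa = "A", alt_aa = "V"),
                           ctx[1, ], NULL)
  expect_equal(call$category, "uncategorized")
  expect_match(call$note, "no-data")
})

test_that("extremizing ddG never drops a categorized variant", {
  ctx <- blank_context(1)
  set.seed(4)
  for (i in 1:40) {
    ddg <- round(stats::rnorm(3, 0, 2.5), 2)
    prof <- data.frame(ddg_state1 = ddg[1], ddg_state2 = ddg[2],
                       ddg_state3 = ddg[3], pam30 = 2,
                       delta_hydrophobicity = 0)
    v <- list(position = 1, ref_aa = "A", alt_aa = "V")
    before <- classify_variant(v, ctx[1, ], prof)$category
    prof2 <- prof
    prof2[1, 1:3] <- 2 * ddg
    after <- classify_variant(v, ctx[1, ], prof2)$category
    if (before != "uncategorized") expect_false(after == "uncategorized")
  }
})

test_that("planted categories round-trip through the classifier", {
  hits <- 0; total <- 0
  for (seed in 1:20) {
    co <- synthetic_cohort(n_res = 120, n = 48, seed = seed,
                           effect = 5, noise_sd = 0.3)
    ctx <- build_residue_context(co$structures, co$config)
    calls <- classify_cohort(co$variants, ctx, co$profiles)
    planted <- unname(co$truth)
    got <- calls$category
    recovered <- ifelse(planted == "none", got == "uncategorized",
                        got == planted)
    hits <- hits + sum(recovered); total <- total + length(recovered)
  }
  expect_gte(hits / total, 0.95)
})

test_that("every category is reachable from a constructed exemplar", {
  co <- synthetic_cohort(n_res = 140, n = 56, seed = 5, noise_sd = 0)
  ctx <- build_residue_context(co$structures, co$config)
  calls <- classify_cohort(co$variants, ctx, co$profiles)
  for (cat in setdiff(mechvar:::MECHANISM_CATEGORIES, "uncategorized")) {
    idx <- which(unname(co$truth) == cat)
    expect_true(any(calls$category[idx] == cat),
                info = paste("category", cat))
  }
  ## determinism
  calls2 <- classify_cohort(co$variants, ctx, co$profiles)
  expect_identical(calls, calls2)
})

test_that("concordance metrics reduce to the expected arithmetic", {
  mk_calls <- function(categories) {
    structure(data.frame(category = categories, stringsAsFactors = FALSE),
              class = c("mechanism_calls", "data.frame"))
  }
  perfect <- concordance_metrics(
    mk_calls(c("atp_binding", "uncategorized")), c(TRUE, FALSE))
  expect_equal(perfect$mechanism$accuracy, 1)

  none <- concordance_metrics(mk_calls(rep("uncategorized", 5)), rep(TRUE, 5))
  expect_equal(none$mechanism$recall, 0)

  ## confusion counts (tp=40, fn=10, fp=5, tn=45) -> accuracy 0.85
  cats <- c(rep("atp_binding", 45), rep("uncategorized", 55))
  labs <- c(rep(TRUE, 40), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 45))
  got <- concordance_metrics(mk_calls(cats), labs)
  expect_equal(got$mechanism$accuracy, 0.85)
  expect_equal(got$mechanism$precision, 40 / 45)
  expect_equal(got$mechanism$recall, 0.8)

  ext <- concordance_metrics(
    mk_calls(cats), labs,
    external = data.frame(cadd = ifelse(labs, 25, 10),
                          sift = ifelse(labs, 0.01, 0.5)))
  expect_equal(ext$cadd$accuracy, 1)
  expect_equal(ext$sift$accuracy, 1)

  expect_error(concordance_metrics(mk_calls("atp_binding"), NA), "no overlap")
})
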