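mk_profile <- function(values, mode = 1L) {
  structure(list(value = values, mode_index = mode), class = "dsas_profile")
}

test_that("the |dSAS| window flags exactly the in-range residues", {
  v <- c(res1 = 10, res2 = 25, res3 = 39, res4 = 41)
  fl <- flag_exposed_residues(list(mk_profile(v)), exposite_config())
  expect_setequal(unique(fl$residue), c("res2", "res3"))
  expect_true(all(fl$dsas >= 20 & fl$dsas <= 40))
})

test_that("an empty window raises a distinct no-signal condition", {
  v <- c(res1 = 1, res2 = 5, res3 = 12)
  expect_error(flag_exposed_residues(list(mk_profile(v)), exposite_config()),
               class = "exposite_no_signal")
})

test_that("flagging is a union over modes; the max switch changes the rule", {
  quiet <- c(r1 = 5, r2 = 5, r3 = 5)
  m7 <- c(r1 = 5, r2 = 30, r3 = 5)
  profs <- c(lapply(1:6, function(k) mk_profile(quiet, k)),
             list(mk_profile(m7, 7L)),
             lapply(8:10, function(k) mk_profile(quiet, k)))
  fl <- flag_exposed_residues(profs, exposite_config())
  expect_equal(unique(fl$residue), "r2")
  expect_equal(fl$mode, 7L)
  # max-over-modes: a residue whose max lies above the window is excluded
  # even though one mode falls inside it
  p2 <- list(mk_profile(c(r1 = 30, r2 = 25), 1L),
             mk_profile(c(r1 = 80, r2 = 10), 2L))
  fl_union <- flag_exposed_residues(p2, exposite_config())
  expect_setequal(unique(fl_union$residue), c("r1", "r2"))
  fl_max <- flag_exposed_residues(p2, exposite_config(aggregate = "max"))
  expect_equal(unique(fl_max$residue), "r2")
  # optional ceiling drops pathological exposure changes before windowing
  p3 <- list(mk_profile(c(r1 = 30, r2 = 90), 1L))
  fl_ceil <- flag_exposed_residues(p3, exposite_config(dsas_ceiling = 75))
  expect_equal(unique(fl_ceil$residue), "r1")
})

test_that("the centroid criterion is strict at its 12 A cutoff", {
  s <- ca_structure(rbind(c(0, 0, 11.9), c(0, 0, 12), c(0, 0, 12.1)))
  pred <- list(site = c(0, 0, 0))
  ids <- residue_ids(s)
  expect_true(evaluate_centroid(pred, ids[1], s)$success)
  expect_false(evaluate_centroid(pred, ids[2], s)$success)
  expect_false(evaluate_centroid(pred, ids[3], s)$success)
  expect_equal(evaluate_centroid(pred, ids[2], s)$distance, 12)
  expect_error(evaluate_centroid(pred, character(), s), "empty")
})

test_that("the ligand criterion is inclusive at its 4 A cutoff", {
  pred <- list(site = c(0, 0, 0))
  lig <- function(d) data.frame(x = d, y = 0, z = 0)
  expect_true(evaluate_ligand(pred, lig(3.9))$success)
  expect_true(evaluate_ligand(pred, lig(4.0))$success)
  expect_false(evaluate_ligand(pred, lig(5.0))$success)
  # the minimum over atoms decides
  many <- data.frame(x = c(30, 3.5, 20), y = 0, z = 0)
  ev <- evaluate_ligand(pred, many)
  expect_equal(ev$distance, 3.5)
  expect_true(ev$success)
  expect_error(evaluate_ligand(pred, many[0, ]), "ligand")
})

test_that("the EnSite baseline picks the pocket nearest the molecular centroid", {
  s <- ca_structure(rbind(c(-2, 0, 0), c(2, 0, 0), c(0, 2, 0)))  # centroid origin
  mkp <- function(ctr) structure(list(center = ctr, volume = 10, n_cells = 10),
                                 class = "pocket")
  pk <- lapply(list(c(8, 0, 0), c(0, 3, 0), c(0, 0, 15)), mkp)
  expect_equal(unname(baseline_ensite(s, pk)), c(0, 3, 0))
  expect_equal(unname(baseline_ensite(s, pk[1])), c(8, 0, 0))
  expect_error(baseline_ensite(s, list()), "no pockets")
})

test_that("prediction on the hinge fixture lands near the known cleft", {
  fx <- make_hinge(seed = 1)
  pred <- predict_active_site(fx$structure)
  expect_lt(sqrt(sum((pred$site - fx$cleft_center)^2)), 12)
  expect_gt(nrow(pred$flagged), 0)
  d <- sapply(pred$ranked_pockets, `[[`, "dist_to_site")
  expect_true(all(diff(d) >= 0))
  ev <- evaluate_centroid(pred, fx$cleft_lining_residues, fx$structure)
  expect_true(ev$success)
})

test_that("a rigid helix gives no exposure signal rather than a crash", {
  h <- make_helix(20)
  expect_error(predict_active_site(h), class = "exposite_no_signal")
})

test_that("the pipeline is deterministic and equivariant under rigid motion", {
  fx <- make_hinge(seed = 3)
  p1 <- predict_active_site(fx$structure)
  p2 <- predict_active_site(fx$structure)
  expect_identical(prediction_report(p1), prediction_report(p2))
  R <- random_rotation(21); tv <- c(10, -6, 3)
  st <- transform_structure(fx$structure, R, tv)
  pt <- predict_active_site(st)
  expect_equal(unname(pt$site), unname(as.numeric(R %*% p1$site + tv)),
               tolerance = 0.5)   # pocket/SASA grids re-discretise
  expect_setequal(unique(pt$flagged$residue), unique(p1$flagged$residue))
  # success against the transformed truth is preserved
  ctr_t <- as.numeric(R %*% fx$cleft_center + tv)
  expect_lt(sqrt(sum((pt$site - ctr_t)^2)), 12)
})

test_that("threshold sweep reports rates and favours the trained window", {
  fxs <- lapply(1:6, function(sd) make_hinge(seed = sd))
  structures <- lapply(fxs, `[[`, "structure")
  truths <- lapply(fxs, `[[`, "cleft_center")
  tab <- sweep_thresholds(structures, truths,
                          dsas_grid = list(c(20, 40), c(60, 80)),
                          modes_grid = 10)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$success_rate >= 0 & tab$success_rate <= 1))
  r2040 <- tab$success_rate[tab$dsas_min == 20]
  r6080 <- tab$success_rate[tab$dsas_min == 60]
  expect_gte(r2040, r6080)
  # single-cell sweep returns a single rate
  tab1 <- sweep_thresholds(structures[1], truths[1],
                           dsas_grid = list(c(20, 40)), modes_grid = 5)
  expect_equal(nrow(tab1), 1)
})

test_that("prediction reports serialise to JSON with site and pockets", {
  fx <- make_hinge(seed = 2)
  pred <- predict_active_site(fx$structure)
  js <- jsonlite::fromJSON(prediction_report(pred), simplifyVector = FALSE)
  expect_equal(unlist(js$site), unname(round(pred$site, 3)))
  expect_length(js$ranked_pockets, length(pred$ranked_pockets))
})
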