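# reference monoisotopic masses computed independently (pyteomics), frozen
REFERENCE_MASSES <- c(
  H2O = 18.010565, C11H13NO3 = 207.089543, C26H43NO6 = 465.309038,
  C26H43NO5 = 449.314123, C13H14N2O3 = 246.100442, C9H11NO2 = 165.078979,
  C9H11NO3 = 181.073893, C5H10N2O3 = 146.069142, C4H7NO4 = 133.037508,
  C24H40O5 = 408.287574, C6H12O6 = 180.063388, C5H9NO4 = 147.053158,
  C10H16N2O3S = 244.088163, C3H7NO2S = 121.019749,
  C63H88CoN14O14P = NA,  # cobalt not supported; parser must refuse it
  C19H28O2 = 288.20893, C27H46O = 386.354866, C8H10NO6P = 247.024574,
  C21H27N7O14P2 = 663.109122, C10H13N5O4 = 267.096754
)

test_that("formula parser agrees with the reference mass table to 1e-4 Da", {
  for (f in names(REFERENCE_MASSES)) {
    ref <- REFERENCE_MASSES[[f]]
    if (is.na(ref)) {
      expect_error(monoisotopic_mass(f), "unknown element")
    } else {
      expect_equal(monoisotopic_mass(f), ref, tolerance = 1e-4 / ref)
    }
  }
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5)
})

test_that("formula parser rejects malformed input by name", {
  expect_error(monoisotopic_mass("C6h12O6"), "malformed|unknown")
  expect_error(monoisotopic_mass("Xx2"), "unknown element")
  expect_error(monoisotopic_mass(""), "non-empty")
  expect_error(monoisotopic_mass("C0H2"), "malformed")
})

test_that("adduct arithmetic reproduces the cluster-2 bile acid ions", {
  gca <- monoisotopic_mass("C26H43NO6")
  expect_equal(adduct_mz(gca, "M+H-H2O"), 448.305749, tolerance = 1e-6)
  gdca <- monoisotopic_mass("C26H43NO5")
  expect_equal(adduct_mz(gdca, "M+Na"), 472.303341, tolerance = 1e-6)
  expect_equal(adduct_mz(1e-9, "M+H"), 1.007276, tolerance = 1e-6)
  expect_error(adduct_mz(-1, "M+H"), "positive")
  expect_error(adduct_mz(100, "M+2H"), "unknown adduct")
  # preset contents
  expect_equal(nrow(adduct_table()), 5)
  expect_equal(setdiff(adduct_table()$name,
                       adduct_table("metlin-batch")$name), "M+K")
})

test_that("published features match their published identities within 10 ppm", {
  db <- small_db()
  # glycocholic acid via the water-loss protonated form
  h1 <- annotate_feature(448.303, db)
  expect_true(any(h1$record_id == "gca" & h1$adduct == "M+H-H2O"))
  expect_equal(abs(h1$ppm_error[h1$record_id == "gca" & h1$adduct == "M+H-H2O"]),
               6.132, tolerance = 1e-3)
  # glycodeoxycholic / glycoursodeoxycholic acid, protonated and sodiated
  h2 <- annotate_feature(450.318, db)
  expect_true(all(c("gdca", "gudca") %in%
                  h2$record_id[h2$adduct == "M+H"]))
  h3 <- annotate_feature(472.300, db)
  expect_true(all(c("gdca", "gudca") %in%
                  h3$record_id[h3$adduct == "M+Na"]))
  # acetylphenylalanine, protonated
  h4 <- annotate_feature(208.096, db)
  expect_true(any(h4$record_id == "acphe" & h4$adduct == "M+H"))
  expect_lt(abs(h4$ppm_error[h4$record_id == "acphe" & h4$adduct == "M+H"]),
            4.0)
  # hits sorted by |ppm|, empty db gives empty result
  expect_true(!is.unsorted(abs(h2$ppm_error)))
  expect_equal(nrow(annotate_feature(448.303, db[0, ])), 0)
})

test_that("every hit satisfies the ppm window when recomputed independently", {
  db <- small_db()
  set.seed(20)
  tab <- adduct_table()
  n_hits <- 0
  for (mz in c(448.303, 450.318, 472.300, 208.096,
               (db$mass + 1.007276) * (1 + runif(nrow(db), -2e-6, 2e-6)),
               runif(50, 85, 850))) {
    hits <- annotate_feature(mz, db)
    if (nrow(hits) == 0) next
    for (i in seq_len(nrow(hits))) {
      M <- db$mass[db$id == hits$record_id[i]][1]
      theo <- M + tab$mass_shift[tab$name == hits$adduct[i]]
      expect_lt(abs(1e6 * (mz - theo) / theo), 10 + 1e-9)
      n_hits <- n_hits + 1
    }
  }
  expect_gt(n_hits, nrow(db))
})

test_that("cluster batch annotation recovers the generating record", {
  cfg <- simulation_config(n_chemicals = 30, sigma_adduct = 0.01,
                           dropout_rate = 0, lod_quantile = 0,
                           differential_fraction = 0, seed = 21)
  db <- synthetic_metabolite_db(60, seed = 99)
  sim <- simulate_dataset(cfg, db)
  # take one chemical's three features as a cluster
  feats <- sim$truth$features
  one <- feats[feats$chemical_id == feats$chemical_id[1], ]
  cl <- list(seed_mz = sim$table$features$mz[
               match(one$feature_id, sim$table$features$feature_id)],
             satellite_mz = numeric(0))
  ann <- annotate_cluster(cl, db)
  expect_equal(length(ann$unmatched_mz), 0)
  top <- sapply(split(ann$hits, ann$hits$mz),
                function(h) h$record_id[which.min(abs(h$ppm_error))])
  expect_true(all(top == one$record_id[1]))
  # a cluster far from any record is all unmatched
  far <- list(seed_mz = c(840.0, 845.5), satellite_mz = numeric(0))
  db_small <- db[db$mass < 300, ]
  ann2 <- annotate_cluster(far, db_small)
  expect_equal(sort(ann2$unmatched_mz), c(840.0, 845.5))
  expect_equal(nrow(ann2$hits), 0)
})

test_that("tightening tolerance below the m/z noise lowers the hit rate", {
  cfg <- simulation_config(n_chemicals = 80, mz_error_ppm_sd = 3,
                           dropout_rate = 0, lod_quantile = 0, seed = 22)
  db <- synthetic_metabolite_db(160, seed = 23)
  sim <- simulate_dataset(cfg, db)
  mzs <- sim$table$features$mz
  rate <- function(tol) {
    cfg_a <- annotation_config(ppm_tolerance = tol)
    mean(vapply(mzs, function(m) nrow(annotate_feature(m, db, cfg_a)) > 0,
                logical(1)))
  }
  expect_gt(rate(10), rate(1))
  expect_gt(rate(10), 0.9)
})

test_that("background match rate behaves like a window-measure", {
  db <- small_db()
  r10 <- background_match_rate(db, annotation_config(10), n_draws = 2000,
                               seed = 30)
  r1 <- background_match_rate(db, annotation_config(1), n_draws = 2000,
                              seed = 30)
  r0 <- background_match_rate(db, annotation_config(1e-6), n_draws = 2000,
                              seed = 30)
  expect_lte(r1, r10)
  expect_lte(r0, r1)
  expect_lt(r0, 0.001)
  # reproducible under seed
  expect_equal(r10, background_match_rate(db, annotation_config(10),
                                          n_draws = 2000, seed = 30))
  # growing the db (disjoint masses) never lowers the rate on fixed draws
  db2 <- rbind(db, synthetic_metabolite_db(50, mass_range = c(500, 700),
                                           seed = 31))
  db2 <- validate_metabolite_db(db2)
  r_big <- background_match_rate(db2, annotation_config(10), n_draws = 2000,
                                 seed = 30)
  expect_gte(r_big, r10)
  expect_error(background_match_rate(db, n_draws = 10), ">= 100")
})
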