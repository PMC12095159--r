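test_that("cohort structure matches the configuration exactly", {
  cfg <- sim_config(n_antigens = 50, n_elev_ad_only = 3, n_elev_dlb_only = 2,
                    n_elev_shared = 4, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$subjects), 35)
  expect_equal(as.integer(table(co$subjects$diagnosis)[c("AD", "DLB", "CNI")]),
               c(18L, 8L, 9L))
  # every array carries the configured spots
  per_subject <- table(co$fluorescence$subject_id, co$fluorescence$spot_type)
  expect_true(all(per_subject[, "antigen"] == 50))
  expect_true(all(per_subject[, "pos_control"] == cfg$n_pos_controls))
  expect_true(all(per_subject[, "neg_control"] == cfg$n_neg_controls))
  # planted set sizes and ledger arithmetic
  expect_equal(length(co$truth$elevated_ad), 3 + 4)
  expect_equal(length(co$truth$elevated_dlb), 2 + 4)
  expect_equal(length(union(co$truth$elevated_ad, co$truth$elevated_dlb)),
               3 + 2 + 4)
  expect_true(all(co$truth$elevated_ad %in% colnames(co$truth$latent_au)))
})

test_that("null configuration plants nothing", {
  co <- generate_cohort(sim_config(n_antigens = 30, n_elev_ad_only = 0,
                                   n_elev_dlb_only = 0, n_elev_shared = 0,
                                   seed = 4))
  expect_length(co$truth$elevated_ad, 0)
  expect_length(co$truth$elevated_dlb, 0)
})

test_that("seeding contract: same seed identical, different seed different", {
  cfg1 <- sim_config(n_antigens = 40, seed = 1)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg1)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_identical(a$subjects, b$subjects)
  c2 <- generate_cohort(sim_config(n_antigens = 40, seed = 2))
  expect_false(identical(a$fluorescence$intensity, c2$fluorescence$intensity))
})

test_that("invalid configurations are rejected with the violated bound", {
  expect_error(sim_config(n_antigens = 5, n_elev_ad_only = 10),
               "exceed panel size")
  expect_error(sim_config(effect_fold = 1), "effect_fold")
  expect_error(sim_config(female_frac_ad = 1.2), "female_frac_ad")
  expect_error(sim_config(pos_control_level = 10, neg_control_level = 50),
               "pos_control_level")
  expect_error(sim_config(n_ad = -1), "n_ad")
})

test_that("trait coupling has the configured sign", {
  co <- generate_cohort(sim_config(seed = 9))
  drv <- co$truth$trait_drivers$MMSE
  expect_lt(drv$coef, 0)
  r <- spearman(co$truth$latent_au[, drv$antigen], co$subjects$MMSE)
  expect_lt(r$rho, 0)
})

test_that("group sex fractions respond to the configured imbalance", {
  co <- generate_cohort(sim_config(n_ad = 200, n_dlb = 200, n_cni = 200,
                                   n_antigens = 5, n_elev_ad_only = 0,
                                   n_elev_dlb_only = 0, n_elev_shared = 0,
                                   seed = 12))
  frac <- tapply(co$subjects$sex == "female", co$subjects$diagnosis, mean)
  expect_equal(unname(frac["AD"]), 0.824, tolerance = 0.1)
  expect_equal(unname(frac["CNI"]), 0.333, tolerance = 0.1)
  expect_gt(frac["AD"], frac["CNI"])
})

test_that("sequence generation respects bounds, pairs and seeding", {
  ids <- paste0("AG", 1:5)
  s <- generate_sequences(ids, c(50, 60), seed = 2)
  expect_length(s, 5)
  expect_true(all(nchar(s) >= 50 & nchar(s) <= 60))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", s)))
  expect_identical(s, generate_sequences(ids, c(50, 60), seed = 2))

  dup <- generate_sequences(ids, c(50, 60), seed = 2,
                            near_duplicates = list(
                              list(a = "AG1", b = "AG2", identity = 100)))
  expect_identical(dup[["AG1"]], dup[["AG2"]])
  near <- generate_sequences(ids, c(60, 60), seed = 2,
                             near_duplicates = list(
                               list(a = "AG1", b = "AG2", identity = 80)))
  al <- needleman_wunsch(near[["AG1"]], near[["AG2"]])
  expect_gte(al$pct_identity, 75)
  expect_error(generate_sequences(character(0)), "empty")
})

test_that("cohort artifacts round-trip through their writers", {
  co <- generate_cohort(sim_config(n_antigens = 10, n_elev_ad_only = 1,
                                   n_elev_dlb_only = 1, n_elev_shared = 1,
                                   seed = 5))
  td <- withr::local_tempdir()
  f <- write_fluorescence_tsv(co$fluorescence, file.path(td, "f.tsv"))
  back <- read_fluorescence_tsv(f)
  expect_equal(back$intensity, co$fluorescence$intensity, tolerance = 1e-12)
  expect_equal(back$spot_type, co$fluorescence$spot_type)

  s <- write_subjects_csv(co$subjects, file.path(td, "s.csv"))
  subj <- read_subjects_csv(s)
  expect_equal(subj$diagnosis, co$subjects$diagnosis)

  seqs <- generate_sequences(paste0("AG", 1:3), seed = 1)
  fa <- write_fasta(seqs, file.path(td, "a.fasta"))
  expect_identical(read_fasta(fa), seqs)
})
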