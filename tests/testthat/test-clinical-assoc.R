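test_that("star assignment is exact at the thresholds", {
  expect_equal(p_stars(c(0.05, 0.049999, 0.01, 0.009, 0.001, 0.0009, NA)),
               c("", "*", "*", "**", "**", "***", ""))
})

test_that("trait correlations flag planted drivers with the right sign", {
  co <- generate_cohort(sim_config(seed = 21))
  aum <- build_au_matrix(co$fluorescence)
  drv <- co$truth$trait_drivers$MMSE
  assoc <- trait_correlations(aum$au[, c(drv$antigen, colnames(aum$au)[1:2]),
                                     drop = FALSE],
                              co$subjects, c("MMSE", "HDSR", "age"))
  cell_rho <- assoc$rho[drv$antigen, "MMSE"]
  expect_lt(cell_rho, 0)
  expect_true(assoc$stars[drv$antigen, "MMSE"] != "")
  # an antibody against itself as pseudo-trait correlates perfectly
  subj2 <- co$subjects
  subj2$self <- aum$au[, drv$antigen]
  self_assoc <- trait_correlations(aum$au[, drv$antigen, drop = FALSE],
                                   subj2, "self")
  expect_equal(unname(self_assoc$rho[1, 1]), 1)
})

test_that("missing and constant traits yield not-computable cells", {
  co <- generate_cohort(sim_config(n_antigens = 10, n_elev_ad_only = 1,
                                   n_elev_dlb_only = 1, n_elev_shared = 1,
                                   seed = 22))
  aum <- build_au_matrix(co$fluorescence)
  subj <- co$subjects
  subj$all_missing <- NA_real_
  subj$constant <- 5
  assoc <- trait_correlations(aum$au[, 1:3], subj,
                              c("all_missing", "constant", "MMSE"))
  expect_true(all(!assoc$computable[, "all_missing"]))
  expect_true(all(!assoc$computable[, "constant"]))
  expect_true(all(assoc$computable[, "MMSE"]))
  expect_true(all(assoc$stars[, "all_missing"] == ""))
  # pairwise-complete n equals the count of subjects with both values
  subj$half <- c(rep(NA, 10), subj$MMSE[11:35])
  a2 <- trait_correlations(aum$au[, 1:2], subj, "half")
  expect_equal(unname(a2$n[1, "half"]), 25)
})

test_that("subscale profile puts the driven subscale on top", {
  co <- generate_cohort(sim_config(seed = 23))
  aum <- build_au_matrix(co$fluorescence)
  drv <- co$truth$trait_drivers$MMSE_Recall
  prof <- subscale_profile(aum$au[, drv$antigen], co$subjects)
  expect_setequal(prof$subscale, grep("^MMSE_", names(co$subjects), value = TRUE))
  # the Recall subscale is coupled most strongly in the generator; among the
  # uncoupled subscales none should beat it at this effect size
  recall_rho <- abs(prof$rho[prof$subscale == "MMSE_Recall"])
  uncoupled <- prof$rho[!prof$subscale %in%
                          c("MMSE_Recall", "MMSE_Registration")]
  expect_gt(recall_rho, max(abs(uncoupled)))
  # constant subscale is not computable
  subj <- co$subjects
  subj$MMSE_Const <- 3
  prof2 <- subscale_profile(aum$au[, drv$antigen], subj,
                            subscales = "MMSE_Const")
  expect_true(is.na(prof2$rho))
})

test_that("adjusted regression recovers coefficients and exposes confounding", {
  set.seed(31)
  n <- 80
  subj <- data.frame(subject_id = seq_len(n),
                     sex = sample(c("male", "female"), n, replace = TRUE),
                     age = runif(n, 70, 90))
  ab <- rnorm(n, 50, 10)
  # trait driven purely by the antibody; sex irrelevant
  subj$trait <- 30 - 0.5 * ab + rnorm(n, 0, 1)
  fit <- adjusted_regression("trait", ab, subj)
  mv <- fit$multivariate
  expect_equal(mv$estimate[mv$term == "antibody"], -0.5, tolerance = 0.1)
  expect_lt(mv$p_value[mv$term == "antibody"], 0.001)
  expect_gt(mv$p_value[mv$term == "sex"], 0.05)

  # trait driven by sex; antibody correlated with sex but not causal
  sex01 <- as.integer(subj$sex == "female")
  ab2 <- 50 + 20 * sex01 + rnorm(n, 0, 1)
  subj$trait2 <- 10 + 5 * sex01 + rnorm(n, 0, 0.5)
  fit2 <- adjusted_regression("trait2", ab2, subj)
  uni_p <- fit2$univariate$p_value[fit2$univariate$term == "antibody"]
  mv_p <- fit2$multivariate$p_value[fit2$multivariate$term == "antibody"]
  expect_lt(uni_p, 0.05)       # naive association
  expect_gt(mv_p, 0.05)        # gone after sex adjustment

  expect_error(adjusted_regression("trait", ab[1:4], subj[1:4, ]),
               "complete cases")
})

test_that("coefficient bias vanishes as trait noise shrinks", {
  set.seed(37)
  n <- 60
  subj <- data.frame(subject_id = 1:n, sex = "male", age = runif(n, 70, 90))
  ab <- rnorm(n, 40, 8)
  bias_at <- function(noise_sd) {
    subj$y <- 5 + 2 * ab + rnorm(n, 0, noise_sd)
    # sex constant here, so adjust with age only via the univariate path
    fit <- ols_fit(subj$y, cbind(1, age = subj$age, antibody = ab))
    abs(fit$estimate[3] - 2)
  }
  expect_lt(bias_at(0.01), bias_at(10))
  expect_lt(bias_at(0.001), 1e-3)
})

test_that("box summaries follow the Tukey hinge convention", {
  v <- c(1, 2, 3, 4, 5, 100)
  g <- rep("AD", 6)
  s <- group_box_summary(v, g)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(s$q1, q[1])
  expect_equal(s$q3, q[2])
  # the outlier at 100 lies beyond the 1.5 IQR whisker
  expect_lt(s$whisker_high, 100)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$n, 6)
})
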