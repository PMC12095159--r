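# Synthetic PWAbS cohorts: lognormal autoantibody background with planted
# group-specific elevations, control-spot fluorescence back-computed from the
# latent AU scale, and clinical traits coupled to designated driver antigens.

#' Trait model specification
#'
#' One entry per clinical trait. `mu` gives the baseline mean per diagnosis
#' group, `sd` the within-group noise. An optional `driver` names an antigen
#' whose latent autoantibody level (z-scored across the cohort) is added with
#' coefficient `coef`, so traits can be made to track specific autoantibodies.
#' `range` clips the realized values; `binary = TRUE` thresholds the latent
#' value at its median into 0/1.
#'
#' @param name Trait name.
#' @param mu Named numeric: means for `AD`, `DLB`, `CNI`.
#' @param sd Residual standard deviation.
#' @param driver Antigen id (or index into the planted AD-elevated set when
#'   given as `"elevated_ad:<i>"`) coupled to the trait; `NULL` for none.
#' @param coef Trait units per standard deviation of driver latent AU.
#' @param range Optional length-2 clip range.
#' @param binary Dichotomize at the cohort median.
#' @return A list describing the trait.
#' @export
trait_spec <- function(name, mu, sd, driver = NULL, coef = 0,
                       range = NULL, binary = FALSE) {
  stopifnot(all(c("AD", "DLB", "CNI") %in% names(mu)), sd >= 0)
  list(name = name, mu = mu, sd = sd, driver = driver, coef = coef,
       range = range, binary = binary)
}

default_trait_model <- function() {
  list(
    # Cognitive scores: dementia groups depressed relative to controls, with
    # the MMSE family negatively coupled to the first planted AD antigen so
    # trait-association recovery is testable.
    trait_spec("MMSE", c(AD = 20.2, DLB = 21.1, CNI = 28.9), sd = 2.5,
               driver = "elevated_ad:1", coef = -2.0, range = c(0, 30)),
    trait_spec("MMSE_Registration", c(AD = 2.0, DLB = 2.2, CNI = 2.9), sd = 0.4,
               driver = "elevated_ad:1", coef = -0.5, range = c(0, 3)),
    trait_spec("MMSE_Recall", c(AD = 1.0, DLB = 1.4, CNI = 2.7), sd = 0.5,
               driver = "elevated_ad:1", coef = -0.8, range = c(0, 3)),
    trait_spec("MMSE_Orientation_Time", c(AD = 3.0, DLB = 3.3, CNI = 4.8),
               sd = 0.8, range = c(0, 5)),
    trait_spec("MMSE_Orientation_Space", c(AD = 3.5, DLB = 3.7, CNI = 4.9),
               sd = 0.8, range = c(0, 5)),
    trait_spec("MMSE_Attention", c(AD = 2.5, DLB = 2.6, CNI = 4.4), sd = 1.0,
               range = c(0, 5)),
    trait_spec("HDSR", c(AD = 19.9, DLB = 22.1, CNI = 27.9), sd = 3.0,
               range = c(0, 30)),
    trait_spec("CGA7", c(AD = 4.5, DLB = 4.8, CNI = 6.5), sd = 1.0,
               range = c(0, 7)),
    trait_spec("GDS15", c(AD = 5.0, DLB = 6.0, CNI = 3.0), sd = 2.0,
               range = c(0, 15)),
    trait_spec("Barthel", c(AD = 80, DLB = 70, CNI = 95), sd = 10,
               range = c(0, 100)),
    trait_spec("back_pain", c(AD = 0.4, DLB = 0.5, CNI = 0.2), sd = 0.5,
               driver = "elevated_ad:2", coef = 0.4, binary = TRUE)
  )
}

#' Simulation configuration
#'
#' Default values emulate the study conditions the pipeline is designed for:
#' 18 AD, 8 DLB and 9 cognitively normal subjects; a scaled-down panel of 300
#' antigens with 30 planted elevations (10 AD-only, 10 DLB-only, 10 shared);
#' a lognormal AU background; fourfold elevation in affected groups; 10%
#' multiplicative per-spot measurement noise; and the reported sex imbalance
#' (female fraction 0.824 / 0.625 / 0.333 in AD / DLB / CNI).
#'
#' @param n_ad,n_dlb,n_cni Subject counts per group.
#' @param n_antigens Panel size (the full wet-array scale of 13,455 clones is
#'   available by setting this; the default is desk-scale).
#' @param n_pos_controls,n_neg_controls Control spots per array.
#' @param background_log_mean,background_log_sd Lognormal parameters of the
#'   latent AU background.
#' @param pos_control_level,neg_control_level Expected fluorescence of the
#'   positive / negative control spots (arbitrary fluorescence units).
#' @param control_cv Lognormal coefficient of variation of control-spot
#'   intensities around their expected level.
#' @param n_elev_ad_only,n_elev_dlb_only,n_elev_shared Planted elevated
#'   antigen counts.
#' @param effect_fold Multiplicative AU elevation in the affected group(s);
#'   must exceed 1.
#' @param measurement_cv Per-spot multiplicative noise CV (0 disables noise).
#' @param female_frac_ad,female_frac_dlb,female_frac_cni Sex fractions.
#' @param age_range Shared age range (years) for all groups.
#' @param trait_model List of [trait_spec] entries.
#' @param seed Integer seed; identical config + seed reproduces identical
#'   outputs.
#' @return A validated `pwabs_sim_config` list.
#' @export
sim_config <- function(n_ad = 18L, n_dlb = 8L, n_cni = 9L,
                       n_antigens = 300L,
                       n_pos_controls = 8L, n_neg_controls = 8L,
                       background_log_mean = log(8), background_log_sd = 0.8,
                       pos_control_level = 10000, neg_control_level = 100,
                       control_cv = 0.05,
                       n_elev_ad_only = 10L, n_elev_dlb_only = 10L,
                       n_elev_shared = 10L,
                       effect_fold = 4,
                       measurement_cv = 0.1,
                       female_frac_ad = 0.824, female_frac_dlb = 0.625,
                       female_frac_cni = 0.333,
                       age_range = c(70, 90),
                       trait_model = default_trait_model(),
                       seed = 1L) {
  cfg <- list(n_ad = as.integer(n_ad), n_dlb = as.integer(n_dlb),
              n_cni = as.integer(n_cni), n_antigens = as.integer(n_antigens),
              n_pos_controls = as.integer(n_pos_controls),
              n_neg_controls = as.integer(n_neg_controls),
              background_log_mean = background_log_mean,
              background_log_sd = background_log_sd,
              pos_control_level = pos_control_level,
              neg_control_level = neg_control_level,
              control_cv = control_cv,
              n_elev_ad_only = as.integer(n_elev_ad_only),
              n_elev_dlb_only = as.integer(n_elev_dlb_only),
              n_elev_shared = as.integer(n_elev_shared),
              effect_fold = effect_fold,
              measurement_cv = measurement_cv,
              female_frac_ad = female_frac_ad,
              female_frac_dlb = female_frac_dlb,
              female_frac_cni = female_frac_cni,
              age_range = age_range,
              trait_model = trait_model,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "pwabs_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_ad", "n_dlb", "n_cni", "n_antigens", "n_pos_controls",
              "n_neg_controls", "n_elev_ad_only", "n_elev_dlb_only",
              "n_elev_shared")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("sim_config: ", nm, " must be a non-negative count")
  }
  n_planted <- cfg$n_elev_ad_only + cfg$n_elev_dlb_only + cfg$n_elev_shared
  if (n_planted > cfg$n_antigens)
    stop("sim_config: planted elevated antigens (", n_planted,
         ") exceed panel size (", cfg$n_antigens, ")")
  if (cfg$effect_fold <= 1)
    stop("sim_config: effect_fold must exceed 1 (got ", cfg$effect_fold, ")")
  if (cfg$neg_control_level < 0 ||
      cfg$pos_control_level <= cfg$neg_control_level)
    stop("sim_config: need pos_control_level > neg_control_level >= 0")
  for (nm in c("female_frac_ad", "female_frac_dlb", "female_frac_cni")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("sim_config: ", nm, " must lie in [0, 1]")
  }
  if (cfg$measurement_cv < 0) stop("sim_config: measurement_cv must be >= 0")
  if (cfg$n_pos_controls < 1L || cfg$n_neg_controls < 1L)
    stop("sim_config: each array needs at least one control spot per class")
  invisible(cfg)
}

cv_to_sdlog <- function(cv) if (cv <= 0) 0 else sqrt(log(1 + cv^2))

#' Generate a synthetic PWAbS cohort
#'
#' Draws a latent subjects x antigens AU matrix from the configured lognormal
#' background, multiplies planted antigens by `effect_fold` in the affected
#' group(s), back-computes per-spot fluorescence through each array's own
#' (jittered) control spots as
#' `F = F_neg + AU/100 * (F_pos - F_neg)` before multiplicative noise, and
#' draws clinical traits from group baselines plus driver-antigen coupling.
#' The returned truth ledger records the planted sets, trait drivers and the
#' noise-free latent AU for recovery testing.
#'
#' @param config A [sim_config] object.
#' @return A list with `fluorescence` (long data.frame: subject_id, spot_id,
#'   spot_type, antigen_id, intensity), `subjects` (one row per subject with
#'   diagnosis, sex, age and traits), and `truth` (ledger list).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n_sub <- config$n_ad + config$n_dlb + config$n_cni
  diagnosis <- rep(c("AD", "DLB", "CNI"),
                   times = c(config$n_ad, config$n_dlb, config$n_cni))
  subject_id <- sprintf("S%02d", seq_len(n_sub))
  antigen_id <- sprintf("AG%04d", seq_len(config$n_antigens))

  # planted sets drawn without replacement from the panel
  n_planted <- config$n_elev_ad_only + config$n_elev_dlb_only +
    config$n_elev_shared
  planted <- if (n_planted > 0L) sample(antigen_id, n_planted) else character(0)
  ad_only <- utils::head(planted, config$n_elev_ad_only)
  dlb_only <- planted[seq_len(config$n_elev_dlb_only) + config$n_elev_ad_only]
  shared <- utils::tail(planted, config$n_elev_shared)
  elevated_ad <- c(ad_only, shared)
  elevated_dlb <- c(dlb_only, shared)

  # latent AU: lognormal background times planted fold elevations
  latent <- matrix(
    stats::rlnorm(n_sub * config$n_antigens,
                  meanlog = config$background_log_mean,
                  sdlog = config$background_log_sd),
    nrow = n_sub, dimnames = list(subject_id, antigen_id))
  latent[diagnosis == "AD", elevated_ad] <-
    latent[diagnosis == "AD", elevated_ad] * config$effect_fold
  latent[diagnosis == "DLB", elevated_dlb] <-
    latent[diagnosis == "DLB", elevated_dlb] * config$effect_fold

  # demographics
  female_frac <- c(AD = config$female_frac_ad, DLB = config$female_frac_dlb,
                   CNI = config$female_frac_cni)
  sex <- ifelse(stats::runif(n_sub) < female_frac[diagnosis],
                "female", "male")
  age <- round(stats::runif(n_sub, config$age_range[1], config$age_range[2]), 1)

  # traits: group baseline + coefficient * z(driver latent AU) + noise
  resolve_driver <- function(driver) {
    if (is.null(driver)) return(NA_character_)
    if (grepl("^elevated_ad:", driver)) {
      i <- as.integer(sub("^elevated_ad:", "", driver))
      if (i > length(elevated_ad)) return(NA_character_)
      return(elevated_ad[i])
    }
    if (driver %in% antigen_id) driver else NA_character_
  }
  traits <- list()
  trait_drivers <- list()
  for (ts in config$trait_model) {
    base <- ts$mu[diagnosis] + stats::rnorm(n_sub, 0, ts$sd)
    drv <- resolve_driver(ts$driver)
    if (!is.na(drv) && ts$coef != 0) {
      z <- as.numeric(scale(latent[, drv]))
      base <- base + ts$coef * z
      trait_drivers[[ts$name]] <- list(antigen = drv, coef = ts$coef)
    }
    if (!is.null(ts$range))
      base <- pmin(ts$range[2], pmax(ts$range[1], base))
    if (isTRUE(ts$binary))
      base <- as.integer(base > stats::median(base))
    else
      base <- round(base, 2)
    traits[[ts$name]] <- base
  }

  subjects <- data.frame(subject_id = subject_id, diagnosis = diagnosis,
                         sex = sex, age = age, stringsAsFactors = FALSE)
  for (nm in names(traits)) subjects[[nm]] <- traits[[nm]]

  # per-array fluorescence: jittered control spots, antigen spots mapped from
  # latent AU through this array's own median controls, then spot noise
  ctrl_sdlog <- cv_to_sdlog(config$control_cv)
  noise_sdlog <- cv_to_sdlog(config$measurement_cv)
  recs <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    pos <- config$pos_control_level *
      stats::rlnorm(config$n_pos_controls, -ctrl_sdlog^2 / 2, ctrl_sdlog)
    neg <- config$neg_control_level *
      stats::rlnorm(config$n_neg_controls, -ctrl_sdlog^2 / 2, ctrl_sdlog)
    f_pos <- stats::median(pos); f_neg <- stats::median(neg)
    f_ag <- f_neg + latent[i, ] / 100 * (f_pos - f_neg)
    if (noise_sdlog > 0)
      f_ag <- f_ag * stats::rlnorm(config$n_antigens,
                                   -noise_sdlog^2 / 2, noise_sdlog)
    recs[[i]] <- data.frame(
      subject_id = subject_id[i],
      spot_id = c(sprintf("POS%02d", seq_len(config$n_pos_controls)),
                  sprintf("NEG%02d", seq_len(config$n_neg_controls)),
                  antigen_id),
      spot_type = c(rep("pos_control", config$n_pos_controls),
                    rep("neg_control", config$n_neg_controls),
                    rep("antigen", config$n_antigens)),
      antigen_id = c(rep(NA_character_,
                         config$n_pos_controls + config$n_neg_controls),
                     antigen_id),
      intensity = c(pos, neg, unname(f_ag)),
      stringsAsFactors = FALSE)
  }
  fluorescence <- do.call(rbind, recs)
  rownames(fluorescence) <- NULL

  truth <- list(elevated_ad = elevated_ad, elevated_dlb = elevated_dlb,
                elevated_ad_only = ad_only, elevated_dlb_only = dlb_only,
                elevated_shared = shared,
                trait_drivers = trait_drivers,
                latent_au = latent,
                effect_fold = config$effect_fold,
                seed = config$seed)
  list(fluorescence = fluorescence, subjects = subjects, truth = truth)
}

#' Generate random amino-acid sequences for an antigen panel
#'
#' One sequence per antigen id over the 20-letter amino-acid alphabet, with
#' lengths uniform in `length_range`. `near_duplicates` plants pairs with a
#' target percent identity: each listed pair (a, b, identity) copies a's
#' sequence into b and mutates the complementary fraction of positions.
#'
#' @param panel Character vector of antigen ids (non-empty).
#' @param length_range Length-2 integer range, both >= 1.
#' @param seed Integer seed.
#' @param near_duplicates Optional list of `list(a =, b =, identity =)` with
#'   identity in \[0, 100\].
#' @return Named character vector of sequences (names = antigen ids).
#' @export
generate_sequences <- function(panel, length_range = c(50L, 60L), seed = 1L,
                               near_duplicates = NULL) {
  if (length(panel) == 0L) stop("generate_sequences: empty antigen panel")
  if (length_range[1] < 1L) stop("generate_sequences: lengths must be >= 1")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  lens <- sample(seq(length_range[1], length_range[2]), length(panel),
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- panel
  for (nd in near_duplicates) {
    if (!all(c(nd$a, nd$b) %in% panel))
      stop("generate_sequences: near-duplicate ids must be in the panel")
    src <- strsplit(seqs[[nd$a]], "")[[1]]
    n_mut <- round(length(src) * (1 - nd$identity / 100))
    if (n_mut > 0L) {
      pos <- sample(length(src), n_mut)
      for (p in pos) {
        src[p] <- sample(setdiff(aa, src[p]), 1L)
      }
    }
    seqs[[nd$b]] <- paste(src, collapse = "")
  }
  seqs
}

# ---- writers (plain-text formats) ------------------------------------------

#' Write cohort artifacts to disk
#'
#' Fluorescence as TSV, subjects as CSV, truth ledger as JSON and sequences
#' as FASTA, using the column layouts the quantification reader expects.
#'
#' @param x Object to write.
#' @param path Output file path.
#' @return The path, invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_fluorescence_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_fluorescence_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("subject_id", "spot_id", "spot_type", "antigen_id", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fluorescence TSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname cohort_io
#' @export
write_subjects_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_subjects_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @export
write_truth_json <- function(x, path) {
  x$latent_au <- NULL  # matrix omitted from the JSON ledger; kept in memory
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_fasta <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x)) {
    writeLines(paste0(">", nm), con)
    writeLines(gsub("(.{60})", "\\1\n", x[[nm]]), con)
  }
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  idx <- grepl("^>", lines)
  if (!any(idx)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*", "", lines[idx])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(idx)
  seqs <- vapply(split(lines[!idx], grp[!idx]),
                 function(z) paste(z, collapse = ""), character(1))
  stats::setNames(toupper(seqs), ids)
}
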