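# Association of selected autoantibody levels with demographic and clinical
# traits: significance-starred Spearman correlation matrices, MMSE-subscale
# profiles, quartile summaries per diagnosis group, and age/sex-adjusted
# linear regression.

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise
#' (strict inequalities; p = 0.05 earns no star).
#'
#' @param p Numeric p-value(s); `NA` yields an empty star.
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

# Spearman over pairwise-complete observations; binary traits are rank-coded
# automatically (ranking a 0/1 vector gives the two mid-rank groups).
pairwise_spearman <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  n <- sum(keep)
  if (n < 3L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  spearman(x[keep], y[keep])
}

#' Autoantibody x trait correlation matrix
#'
#' Pairwise-complete Spearman correlation between each selected autoantibody
#' and each trait, with significance stars. Cells with fewer than 3 complete
#' pairs, or a constant vector, are marked not-computable (`NA` rho/p, empty
#' star, `computable = FALSE`).
#'
#' @param au_subset Subjects x antibodies AU matrix (columns = the selected
#'   autoantibodies), row names matching `subjects$subject_id` order is the
#'   caller's responsibility: rows must align with `subjects`.
#' @param subjects Subject data.frame carrying the trait columns.
#' @param traits Character vector of trait column names. Character traits
#'   (e.g. sex) are converted to factor codes before ranking.
#' @return A `pwabs_assoc` list of matrices `rho`, `p`, `stars`, `n`,
#'   `computable` (antibodies x traits) plus a tidy data.frame `table`.
#' @export
trait_correlations <- function(au_subset, subjects, traits) {
  m <- as.matrix(au_subset)
  if (nrow(m) != nrow(subjects))
    stop("trait_correlations: matrix rows must align with subjects")
  miss <- setdiff(traits, names(subjects))
  if (length(miss))
    stop("trait_correlations: unknown traits: ", paste(miss, collapse = ", "))
  abs_ids <- colnames(m)
  rho <- p <- nmat <- matrix(NA_real_, ncol(m), length(traits),
                             dimnames = list(abs_ids, traits))
  for (tr in traits) {
    tv <- subjects[[tr]]
    if (is.character(tv) || is.factor(tv)) tv <- as.numeric(factor(tv))
    if (is.logical(tv)) tv <- as.numeric(tv)
    for (ab in abs_ids) {
      r <- pairwise_spearman(m[, ab], tv)
      rho[ab, tr] <- r$rho; p[ab, tr] <- r$p_value; nmat[ab, tr] <- r$n
    }
  }
  stars <- matrix(p_stars(p), nrow(rho), ncol(rho), dimnames = dimnames(rho))
  computable <- !is.na(rho)
  tab <- expand.grid(antibody = abs_ids, trait = traits,
                     stringsAsFactors = FALSE)
  tab$rho <- rho[cbind(tab$antibody, tab$trait)]
  tab$p_value <- p[cbind(tab$antibody, tab$trait)]
  tab$star <- stars[cbind(tab$antibody, tab$trait)]
  tab$n <- nmat[cbind(tab$antibody, tab$trait)]
  structure(list(rho = rho, p = p, stars = stars, n = nmat,
                 computable = computable, table = tab),
            class = "pwabs_assoc")
}

#' MMSE-subscale correlation profile for one autoantibody
#'
#' One Spearman row restricted to the given subscales.
#'
#' @param ab Numeric AU vector for one autoantibody, aligned with `subjects`.
#' @param subjects Subject data.frame.
#' @param subscales Character vector of subscale column names (default: all
#'   columns starting with `MMSE_`).
#' @return Data.frame with `subscale`, `rho`, `p_value`, `star`, `n`.
#' @export
subscale_profile <- function(ab, subjects,
                             subscales = grep("^MMSE_", names(subjects),
                                              value = TRUE)) {
  if (length(subscales) == 0L) stop("subscale_profile: no subscales given")
  rows <- lapply(subscales, function(sc) {
    r <- pairwise_spearman(ab, subjects[[sc]])
    data.frame(subscale = sc, rho = r$rho, p_value = r$p_value,
               star = p_stars(r$p_value), n = r$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Univariate and age/sex-adjusted regression of a trait on one autoantibody
#'
#' Complete-case OLS. Univariate: `trait ~ antibody`. Multivariate:
#' `trait ~ age + sex + antibody`, with sex coded 0 = male, 1 = female.
#'
#' @param trait Trait column name in `subjects`.
#' @param ab Numeric AU vector aligned with `subjects` rows.
#' @param subjects Subject data.frame with `age` and `sex` columns.
#' @return List with coefficient tables `univariate` and `multivariate`
#'   (see [ols_fit]) and `n_complete`.
#' @export
adjusted_regression <- function(trait, ab, subjects) {
  y <- subjects[[trait]]
  if (is.null(y)) stop("adjusted_regression: unknown trait ", trait)
  sex01 <- ifelse(subjects$sex == "female", 1, 0)
  keep <- stats::complete.cases(y, ab, subjects$age, sex01)
  n <- sum(keep)
  if (n < 3L + 2L)
    stop("adjusted_regression: only ", n,
         " complete cases; need at least predictors + 2")
  Xu <- cbind("(Intercept)" = 1, antibody = ab[keep])
  Xm <- cbind("(Intercept)" = 1, age = subjects$age[keep], sex = sex01[keep],
              antibody = ab[keep])
  list(univariate = ols_fit(y[keep], Xu),
       multivariate = ols_fit(y[keep], Xm),
       n_complete = n, sex_coding = c(male = 0, female = 1))
}

#' Quartile (box-plot hinge) summary per diagnosis group
#'
#' Tukey convention: hinges are the first and third quartiles; whiskers
#' extend to the most extreme points within 1.5 interquartile ranges of the
#' hinges.
#'
#' @param values Numeric vector (e.g. one antibody's AU levels).
#' @param groups Grouping vector (e.g. diagnosis).
#' @return Data.frame per group: `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`.
#' @export
group_box_summary <- function(values, groups) {
  out <- lapply(split(as.numeric(values), groups), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_lim <- q[1] - 1.5 * iqr; hi_lim <- q[3] + 1.5 * iqr
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = min(v[v >= lo_lim]),
               whisker_high = max(v[v <= hi_lim]))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Write association matrices as CSV
#'
#' @param x A `pwabs_assoc` object.
#' @param rho_path,p_path,stars_path Output CSV paths (NULL skips).
#' @return `rho_path`, invisibly.
#' @export
write_assoc_csv <- function(x, rho_path = NULL, p_path = NULL,
                            stars_path = NULL) {
  wr <- function(m, path) {
    df <- data.frame(antibody = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  if (!is.null(rho_path)) wr(x$rho, rho_path)
  if (!is.null(p_path)) wr(x$p, p_path)
  if (!is.null(stars_path)) wr(x$stars, stars_path)
  invisible(rho_path)
}
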