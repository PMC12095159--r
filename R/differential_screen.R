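# Volcano-style differential elevation screen: Mann-Whitney U versus the
# cognitively normal group combined with a fold-change threshold, Venn set
# arithmetic over the AD / DLB panels, and PCA of subjects on the selected
# antigens.

#' Fold change of group means on zero-clipped AU
#'
#' AU values are clipped below at 0 before averaging (the normalization
#' formula permits negative AU, which would make a ratio ill-behaved). When
#' the control mean does not exceed `epsilon`, `epsilon` replaces it as the
#' denominator, so the ratio is always finite and non-negative.
#'
#' @param case_values,control_values Numeric AU vectors, both non-empty.
#' @param epsilon Denominator floor, default 1 AU.
#' @return Non-negative fold change (case over control).
#' @export
fold_change <- function(case_values, control_values, epsilon = 1.0) {
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop("fold_change: both groups must be non-empty")
  m_case <- mean(pmax(case_values, 0))
  m_ctrl <- mean(pmax(control_values, 0))
  denom <- if (m_ctrl > epsilon) m_ctrl else epsilon
  m_case / denom
}

#' Volcano selection of differentially elevated autoantibodies
#'
#' Per antigen and per contrast (AD vs CNI, DLB vs CNI): two-sided
#' Mann-Whitney p-value and fold change of group means. An antigen is flagged
#' elevated when `p < p_threshold` and `fold change >= fc_threshold`; the
#' fold-change condition makes selection one-directional (case above
#' control).
#'
#' @param matrix A `pwabs_au` object or subjects x antigens AU matrix.
#' @param diagnosis Character vector aligned with the matrix rows, values in
#'   `AD`, `DLB`, `CNI`.
#' @param p_threshold Significance cutoff (default 0.05).
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param epsilon Passed to [fold_change].
#' @return A `pwabs_differential` data.frame, one row per antigen:
#'   group means, `fc_ad`, `fc_dlb`, `p_ad`, `p_dlb`, `log2_fc_*`,
#'   `neg_log10_p_*`, `elevated_ad`, `elevated_dlb`, `in_union`.
#' @export
volcano_select <- function(matrix, diagnosis, p_threshold = 0.05,
                           fc_threshold = 2, epsilon = 1.0) {
  m <- if (inherits(matrix, "pwabs_au")) matrix$au else as.matrix(matrix)
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != nrow(m))
    stop("volcano_select: diagnosis length must match matrix rows")
  for (g in c("AD", "DLB", "CNI")) {
    if (sum(diagnosis == g) < 2L)
      stop("volcano_select: group ", g, " has fewer than 2 subjects")
  }
  ad <- m[diagnosis == "AD", , drop = FALSE]
  dlb <- m[diagnosis == "DLB", , drop = FALSE]
  cni <- m[diagnosis == "CNI", , drop = FALSE]

  per_antigen <- function(case_m, j) {
    x <- case_m[, j]; y <- cni[, j]
    c(p = mann_whitney_u(x, y)$p_value,
      fc = fold_change(x, y, epsilon = epsilon))
  }
  n_ag <- ncol(m)
  res_ad <- vapply(seq_len(n_ag), function(j) per_antigen(ad, j), numeric(2))
  res_dlb <- vapply(seq_len(n_ag), function(j) per_antigen(dlb, j), numeric(2))

  out <- data.frame(
    antigen_id = colnames(m),
    mean_ad = colMeans(ad), mean_dlb = colMeans(dlb), mean_cni = colMeans(cni),
    fc_ad = res_ad["fc", ], fc_dlb = res_dlb["fc", ],
    p_ad = res_ad["p", ], p_dlb = res_dlb["p", ],
    stringsAsFactors = FALSE)
  out$log2_fc_ad <- log2(pmax(out$fc_ad, .Machine$double.eps))
  out$log2_fc_dlb <- log2(pmax(out$fc_dlb, .Machine$double.eps))
  out$neg_log10_p_ad <- -log10(out$p_ad)
  out$neg_log10_p_dlb <- -log10(out$p_dlb)
  out$elevated_ad <- out$p_ad < p_threshold & out$fc_ad >= fc_threshold
  out$elevated_dlb <- out$p_dlb < p_threshold & out$fc_dlb >= fc_threshold
  out$in_union <- out$elevated_ad | out$elevated_dlb
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  attr(out, "fc_threshold") <- fc_threshold
  class(out) <- c("pwabs_differential", "data.frame")
  out
}

#' Venn counts for two antigen id sets
#'
#' @param set_ad,set_dlb Character vectors of antigen ids (duplicates
#'   removed).
#' @return Named list: `n_ad`, `n_dlb`, `n_shared`, `n_union`
#'   (inclusion-exclusion).
#' @export
venn_counts <- function(set_ad, set_dlb) {
  a <- unique(set_ad); b <- unique(set_dlb)
  n_shared <- length(intersect(a, b))
  list(n_ad = length(a), n_dlb = length(b), n_shared = n_shared,
       n_union = length(a) + length(b) - n_shared)
}

#' Venn union from printed panel counts
#'
#' Inclusion-exclusion on the reported set sizes alone, for when only the
#' counts (not the ids) are available.
#'
#' @param n_ad,n_dlb,n_shared Non-negative counts with
#'   `n_shared <= min(n_ad, n_dlb)`.
#' @return The union count `n_ad + n_dlb - n_shared`.
#' @export
venn_union <- function(n_ad, n_dlb, n_shared) {
  if (n_shared > min(n_ad, n_dlb) || any(c(n_ad, n_dlb, n_shared) < 0))
    stop("venn_union: need 0 <= n_shared <= min(n_ad, n_dlb)")
  n_ad + n_dlb - n_shared
}

#' PCA embedding of subjects on a selected antigen panel
#'
#' Columns are centered and scaled to unit variance (zero-variance columns
#' dropped with a warning), the embedding comes from the singular value
#' decomposition, and each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param matrix Subjects x antigens AU matrix (or `pwabs_au`), already
#'   restricted to the panel of interest.
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (subjects x components), `loadings`,
#'   `explained_variance_ratio`, and `dropped` (zero-variance column names).
#' @export
pca_embed <- function(matrix, n_components = 2L) {
  m <- if (inherits(matrix, "pwabs_au")) matrix$au else as.matrix(matrix)
  if (nrow(m) < 2L) stop("pca_embed: need at least 2 subjects")
  if (ncol(m) < 1L) stop("pca_embed: need at least 1 antigen")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("pca_embed: dropping zero-variance columns: ",
            paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("pca_embed: all columns have zero variance")
  z <- scale(m)
  sv <- svd(z)
  k <- min(n_components, length(sv$d))
  # sign convention: largest-|loading| entry of each PC made positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", seq_len(k))
  evr <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, loadings = loadings,
       explained_variance_ratio = evr[seq_len(k)], dropped = dropped)
}

#' Write differential-screen artifacts
#'
#' @param x A `pwabs_differential` table.
#' @param table_path CSV for the full per-antigen table.
#' @param volcano_path Optional CSV of volcano coordinates.
#' @param selected_path Optional plain-text file of selected antigen ids (the
#'   union panel), one per line.
#' @return `table_path`, invisibly.
#' @export
write_differential_csv <- function(x, table_path, volcano_path = NULL,
                                   selected_path = NULL) {
  utils::write.csv(as.data.frame(x), table_path, row.names = FALSE)
  if (!is.null(volcano_path)) {
    utils::write.csv(
      data.frame(antigen_id = x$antigen_id,
                 log2_fc_ad = x$log2_fc_ad, neg_log10_p_ad = x$neg_log10_p_ad,
                 log2_fc_dlb = x$log2_fc_dlb,
                 neg_log10_p_dlb = x$neg_log10_p_dlb),
      volcano_path, row.names = FALSE)
  }
  if (!is.null(selected_path))
    writeLines(x$antigen_id[x$in_union], selected_path)
  invisible(table_path)
}
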