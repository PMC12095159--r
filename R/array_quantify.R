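# Control-spot normalization of per-spot fluorescence into autoantibody
# levels in arbitrary units (AU): 0 at the negative-control intensity, 100 at
# the positive-control intensity.

#' Autoantibody level in arbitrary units
#'
#' `AU = (F_antigen - F_neg) / (F_pos - F_neg) * 100`. Values below 0 or
#' above 100 are legitimate (antigen spots dimmer than the negative control
#' or brighter than the positive control) and are not clipped.
#'
#' @param f_antigen Fluorescence of the antigen spot(s); vectorized.
#' @param f_neg,f_pos Negative / positive control intensities (scalars or
#'   vectors recycled against `f_antigen`); requires `f_pos > f_neg`.
#' @param subject_id Optional id used in the degenerate-control error message.
#' @return Numeric AU value(s), linear in `f_antigen`.
#' @export
compute_au <- function(f_antigen, f_neg, f_pos, subject_id = NULL) {
  if (any(f_pos <= f_neg)) {
    who <- if (is.null(subject_id)) "" else paste0(" for subject ", subject_id)
    stop("degenerate controls", who,
         ": positive-control intensity must exceed negative-control intensity")
  }
  (f_antigen - f_neg) / (f_pos - f_neg) * 100
}

#' Assemble the subjects x antigens AU matrix
#'
#' Per subject, `f_neg` and `f_pos` are the medians of that subject's
#' negative / positive control-spot intensities; every antigen spot is mapped
#' through [compute_au] and duplicate spots of one antigen for one subject
#' are averaged (arithmetic mean).
#'
#' @param table Long fluorescence data.frame with columns `subject_id`,
#'   `spot_id`, `spot_type` (one of `antigen`, `pos_control`, `neg_control`),
#'   `antigen_id`, `intensity`.
#' @return A `pwabs_au` object: list with `au` (numeric matrix, subjects as
#'   rows), `sal` (named per-subject row sums), `controls` (per-subject median
#'   control intensities) and `provenance`.
#' @export
build_au_matrix <- function(table) {
  need <- c("subject_id", "spot_type", "antigen_id", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("build_au_matrix: missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$intensity)))
    stop("build_au_matrix: non-finite intensities present")
  bad_type <- setdiff(unique(table$spot_type),
                      c("antigen", "pos_control", "neg_control"))
  if (length(bad_type))
    stop("build_au_matrix: unknown spot_type: ", paste(bad_type, collapse = ", "))

  subjects <- unique(table$subject_id)
  ag_rows <- table$spot_type == "antigen"
  if (any(ag_rows & (is.na(table$antigen_id) | table$antigen_id == "")))
    stop("build_au_matrix: antigen spots must carry a non-empty antigen_id")
  antigens <- unique(table$antigen_id[ag_rows])

  ctrl <- lapply(subjects, function(s) {
    rows <- table$subject_id == s
    pos <- table$intensity[rows & table$spot_type == "pos_control"]
    neg <- table$intensity[rows & table$spot_type == "neg_control"]
    if (length(pos) == 0L || length(neg) == 0L)
      stop("build_au_matrix: subject ", s,
           " is missing a control class (needs >= 1 pos_control and >= 1 neg_control)")
    c(f_pos = stats::median(pos), f_neg = stats::median(neg))
  })
  ctrl <- do.call(rbind, ctrl)
  rownames(ctrl) <- subjects

  au <- matrix(NA_real_, nrow = length(subjects), ncol = length(antigens),
               dimnames = list(subjects, antigens))
  for (s in subjects) {
    rows <- ag_rows & table$subject_id == s
    vals <- compute_au(table$intensity[rows],
                       ctrl[s, "f_neg"], ctrl[s, "f_pos"], subject_id = s)
    # duplicate antigen spots averaged
    cell <- tapply(vals, table$antigen_id[rows], mean)
    au[s, names(cell)] <- cell
  }
  if (anyNA(au)) {
    holes <- which(is.na(au), arr.ind = TRUE)
    stop("build_au_matrix: missing antigen measurements, e.g. subject ",
         rownames(au)[holes[1, 1]], " / antigen ", colnames(au)[holes[1, 2]])
  }
  structure(
    list(au = au, sal = compute_sal(au), controls = ctrl,
         provenance = list(aggregation = "mean of duplicate spots",
                           control_rule = "median of control spots per subject")),
    class = "pwabs_au")
}

#' Sum of autoantibody levels (SAL)
#'
#' Per-subject total over all antigens, a gross-autoreactivity statistic.
#' Negative AU values are included (no clipping).
#'
#' @param matrix A `pwabs_au` object or a plain subjects x antigens matrix.
#' @return Named numeric vector of row sums.
#' @export
compute_sal <- function(matrix) {
  m <- if (inherits(matrix, "pwabs_au")) matrix$au else as.matrix(matrix)
  rowSums(m)
}

#' @export
print.pwabs_au <- function(x, ...) {
  cat(sprintf("pwabs AU matrix: %d subjects x %d antigens; SAL range [%.1f, %.1f]\n",
              nrow(x$au), ncol(x$au), min(x$sal), max(x$sal)))
  invisible(x)
}

#' Write AU matrix and SAL to CSV
#'
#' @param x A `pwabs_au` object.
#' @param au_path,sal_path Output CSV paths (antigens as header columns;
#'   subjects as the first column).
#' @return `au_path`, invisibly.
#' @export
write_au_csv <- function(x, au_path, sal_path = NULL) {
  df <- data.frame(subject_id = rownames(x$au), x$au, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, au_path, row.names = FALSE)
  if (!is.null(sal_path)) {
    utils::write.csv(data.frame(subject_id = names(x$sal), sal = unname(x$sal)),
                     sal_path, row.names = FALSE)
  }
  invisible(au_path)
}

#' Read an AU matrix CSV written by [write_au_csv]
#'
#' @param path CSV path.
#' @return Numeric matrix with subject row names.
#' @export
read_au_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
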