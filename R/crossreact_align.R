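# Cross-reactivity screening: autoantibodies whose serum levels correlate
# strongly across subjects may reflect one antibody binding several antigens;
# candidate pairs are checked for shared sequence by global alignment
# percent identity.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Spearman correlation matrix across selected autoantibodies
#'
#' @param au_subset Subjects x antibodies AU matrix (>= 3 subjects).
#' @return List with `rho` (symmetric, unit diagonal), `p`, and `flagged`
#'   (names of constant columns, whose rows/columns are `NA` off-diagonal).
#' @export
ab_correlation_matrix <- function(au_subset) {
  m <- as.matrix(au_subset)
  if (nrow(m) < 3L) stop("ab_correlation_matrix: need at least 3 subjects")
  ids <- colnames(m)
  k <- ncol(m)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(rho) <- 1
  flagged <- ids[apply(m, 2, function(v) length(unique(v)) < 2L)]
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      if (ids[i] %in% flagged || ids[j] %in% flagged) next
      r <- spearman(m[, i], m[, j])
      rho[i, j] <- rho[j, i] <- r$rho
      p[i, j] <- p[j, i] <- r$p_value
    }
  }
  list(rho = rho, p = p, flagged = flagged)
}

#' Needleman-Wunsch global alignment with identity scoring
#'
#' Dynamic-programming global alignment under match = 1, mismatch = 0,
#' linear gap = -1 by default, with deterministic tie-breaking in the
#' traceback (diagonal preferred over up over left). Percent identity is
#' identical aligned residues over the alignment length by default; the
#' shorter-sequence denominator is available because the reported identity
#' value depends on this convention.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (20-letter alphabet).
#' @param match,mismatch,gap Scoring parameters.
#' @param identity_denom `"alignment"` (default) or `"shorter"`.
#' @return An `AlignmentResult` list: `id_a`/`id_b` aligned strings,
#'   `alignment_length`, `identities`, `pct_identity`, `gaps` (gap columns),
#'   `score`.
#' @export
needleman_wunsch <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = -1,
                             identity_denom = c("alignment", "shorter")) {
  identity_denom <- match.arg(identity_denom)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) == 0L || length(b) == 0L)
    stop("needleman_wunsch: sequences must be non-empty")
  for (nm in list(list(a, "first"), list(b, "second"))) {
    bad <- which(!(nm[[1]] %in% AA_ALPHABET))
    if (length(bad))
      stop("needleman_wunsch: non-amino-acid character '",
           nm[[1]][bad[1]], "' at position ", bad[1], " of the ", nm[[2]],
           " sequence")
  }
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  # traceback: 1 = diagonal, 2 = up (gap in b), 3 = left (gap in a)
  TB <- matrix(0L, n + 1L, m + 1L)
  TB[, 1] <- 2L; TB[1, ] <- 3L; TB[1, 1] <- 0L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      diag_s <- S[i, j] + sub[j]
      up_s <- S[i, j + 1L] + gap
      left_s <- S[i + 1L, j] + gap
      best <- max(diag_s, up_s, left_s)
      S[i + 1L, j + 1L] <- best
      TB[i + 1L, j + 1L] <- if (diag_s == best) 1L
        else if (up_s == best) 2L else 3L
    }
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  al_a <- character(0); al_b <- character(0)
  while (i > 1L || j > 1L) {
    move <- TB[i, j]
    if (move == 1L) {
      al_a <- c(a[i - 1L], al_a); al_b <- c(b[j - 1L], al_b)
      i <- i - 1L; j <- j - 1L
    } else if (move == 2L) {
      al_a <- c(a[i - 1L], al_a); al_b <- c("-", al_b)
      i <- i - 1L
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j - 1L], al_b)
      j <- j - 1L
    }
  }
  aln_len <- length(al_a)
  idents <- sum(al_a == al_b & al_a != "-")
  gaps <- sum(al_a == "-" | al_b == "-")
  denom <- if (identity_denom == "alignment") aln_len else min(n, m)
  structure(list(aligned_a = paste(al_a, collapse = ""),
                 aligned_b = paste(al_b, collapse = ""),
                 alignment_length = aln_len, identities = idents,
                 pct_identity = idents / denom * 100, gaps = gaps,
                 score = S[n + 1L, m + 1L],
                 identity_denom = identity_denom),
            class = "pwabs_alignment")
}

#' @export
print.pwabs_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g, identity %.1f%% (%d/%d), %d gap column(s)\n",
              x$score, x$pct_identity, x$identities, x$alignment_length,
              x$gaps))
  invisible(x)
}

#' Cross-reactivity screen
#'
#' Computes the Spearman correlation matrix over the selected autoantibodies
#' and globally aligns the antigen sequences of every pair with rho strictly
#' above `r_threshold`. Pairs whose sequence is unavailable are reported as
#' unresolved rather than failing the screen.
#'
#' @param selected Character vector of antigen ids to screen.
#' @param au Subjects x antigens AU matrix (or `pwabs_au`) containing the
#'   selected columns.
#' @param sequences Named character vector of antigen sequences (see
#'   [read_fasta]).
#' @param r_threshold Correlation threshold (exclusive; default 0.5).
#' @param identity_denom Passed to [needleman_wunsch].
#' @return A `pwabs_crossreact` list: `correlations` (from
#'   [ab_correlation_matrix]), `pairs` (data.frame id_a, id_b, rho,
#'   pct_identity, alignment_length, gaps, score, resolved), `r_threshold`.
#' @export
crossreact_screen <- function(selected, au, sequences, r_threshold = 0.5,
                              identity_denom = "alignment") {
  m <- if (inherits(au, "pwabs_au")) au$au else as.matrix(au)
  miss <- setdiff(selected, colnames(m))
  if (length(miss))
    stop("crossreact_screen: antigens absent from AU matrix: ",
         paste(miss, collapse = ", "))
  sub <- m[, selected, drop = FALSE]
  corr <- ab_correlation_matrix(sub)
  ids <- selected
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        rho <- corr$rho[ids[i], ids[j]]
        if (is.na(rho) || rho <= r_threshold) next
        has_seq <- ids[i] %in% names(sequences) && ids[j] %in% names(sequences)
        if (has_seq) {
          al <- needleman_wunsch(sequences[[ids[i]]], sequences[[ids[j]]],
                                 identity_denom = identity_denom)
          rows[[length(rows) + 1L]] <- data.frame(
            id_a = ids[i], id_b = ids[j], rho = rho,
            pct_identity = al$pct_identity,
            alignment_length = al$alignment_length, gaps = al$gaps,
            score = al$score, resolved = TRUE, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            id_a = ids[i], id_b = ids[j], rho = rho,
            pct_identity = NA_real_, alignment_length = NA_integer_,
            gaps = NA_integer_, score = NA_real_, resolved = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0), rho = numeric(0),
               pct_identity = numeric(0), alignment_length = integer(0),
               gaps = integer(0), score = numeric(0), resolved = logical(0))
  structure(list(correlations = corr, pairs = pairs,
                 r_threshold = r_threshold),
            class = "pwabs_crossreact")
}

#' Write cross-reactivity artifacts
#'
#' @param x A `pwabs_crossreact` object.
#' @param corr_path CSV for the correlation matrix (NULL skips).
#' @param report_path TSV for the aligned-pair report (NULL skips).
#' @return `report_path`, invisibly.
#' @export
write_crossreact <- function(x, corr_path = NULL, report_path = NULL) {
  if (!is.null(corr_path)) {
    df <- data.frame(antigen_id = rownames(x$correlations$rho),
                     x$correlations$rho, check.names = FALSE)
    utils::write.csv(df, corr_path, row.names = FALSE)
  }
  if (!is.null(report_path)) {
    utils::write.table(x$pairs, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report_path)
}
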