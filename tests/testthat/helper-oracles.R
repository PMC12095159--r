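# Independent brute-force oracles used to check the analytical
# implementations on small cases.

# Two-sided Mann-Whitney p by full enumeration of group-label assignments:
# counts pairs directly on the data, no rank formula shared with the
# implementation.
mwu_enum_oracle <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Optimal global-alignment score by exhaustive recursion over all
# alignments (practical for sequences of length <= 6).
align_enum_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Fluorescence table for hand-checkable quantification cases.
toy_fluorescence <- function() {
  data.frame(
    subject_id = rep(c("A", "B"), each = 5),
    spot_id = rep(c("P1", "N1", "G1", "G2", "G3"), 2),
    spot_type = rep(c("pos_control", "neg_control", rep("antigen", 3)), 2),
    antigen_id = rep(c(NA, NA, "ag1", "ag2", "ag3"), 2),
    intensity = c(1050, 50, 550, 1050, 50,
                  2050, 50, 1050, 2050, 550),
    stringsAsFactors = FALSE)
}

# Three well-separated Gaussian clusters in feature space for the
# three-class network.
separable_three_class <- function(n_per = 30L, p = 10L, sep = 6, seed = 11L) {
  set.seed(seed)
  centers <- matrix(0, 3, p)
  centers[1, 1] <- sep; centers[2, 2] <- sep; centers[3, 3] <- sep
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(n_per * p), n_per, p) +
      matrix(centers[k, ], n_per, p, byrow = TRUE)))
  colnames(X) <- paste0("f", seq_len(p))
  y <- rep(c("CNI", "AD", "DLB"), each = n_per)
  list(X = X, y = y)
}
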