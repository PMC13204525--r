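# Internal numerical helpers shared across modules.

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) log(p / (1 - p))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Half-sample symmetric reflection of 1-based indices into [1, n]; for a
# normalized symmetric kernel this boundary makes smoothing doubly stochastic,
# so the grid mean is preserved exactly.
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  period <- 2L * n
  j <- ((j - 1L) %% period + period) %% period # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
gauss_smooth3 <- function(arr, sigma_vox) {
  dm <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    k <- gauss_kernel1d(s)
    r <- (length(k) - 1L) / 2L
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = dm[ax])
    acc <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k)) {
      idx <- reflect_index(seq_len(dm[ax]) + (t - 1L - r), dm[ax])
      acc <- acc + k[t] * m[idx, , drop = FALSE]
    }
    arr <- aperm(array(acc, dm[perm]), order(perm))
  }
  arr
}

# Stratified k-fold assignment; returns integer fold id per row.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Stratified train/test split with largest-remainder allocation so the test
# size is exactly round(frac * n) overall.
stratified_split <- function(labels, frac_test, seed) {
  set.seed(seed)
  n <- length(labels)
  n_test <- round(frac_test * n)
  strata <- split(seq_len(n), labels)
  quota <- vapply(strata, function(i) frac_test * length(i), 0)
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  test_idx <- unlist(mapply(function(i, m) if (m > 0) sample(i, m) else integer(0),
                            strata, base, SIMPLIFY = FALSE), use.names = FALSE)
  partition <- rep("train", n)
  partition[test_idx] <- "test1"
  partition
}

# Mean silhouette for a 1-D two-group assignment, O(n log n) via sorted
# prefix sums of absolute differences.
silhouette_1d <- function(x, grp) {
  mean_abs <- function(vals, pts) {
    # mean |pts - vals_j| over j, for each point in pts
    if (length(vals) == 0L) return(rep(NA_real_, length(pts)))
    s <- sort(vals)
    cs <- cumsum(s)
    tot <- cs[length(s)]
    k <- findInterval(pts, s)
    below <- ifelse(k > 0, cs[pmax(k, 1)] * (k > 0), 0)
    (pts * k - below + (tot - below) - pts * (length(s) - k)) / length(s)
  }
  g1 <- x[grp == 1L]; g2 <- x[grp == 2L]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  sil_for <- function(own, other) {
    n <- length(own)
    if (n == 1L) return(0) # singleton cluster: silhouette defined as 0
    a <- mean_abs(own, own) * n / (n - 1) # exclude self (distance 0)
    b <- mean_abs(other, own)
    (b - a) / pmax(a, b)
  }
  mean(c(sil_for(g1, g2), sil_for(g2, g1)))
}

# Pair-counting AUC of scores for binary labels (ties count 1/2).
auc_rank <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
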