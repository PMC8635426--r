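## Independent oracles used across tests. These deliberately re-derive each
## quantity by the most direct route available (exhaustive scans, closed
## forms, hand formulas) and never call the implementation they check.

## Exhaustive Otsu: scan all 255 cuts of the 256-bin histogram, computing the
## between-class variance directly from the per-class bin values.
otsu_brute_force <- function(channel) {
  bins <- as.integer(round(as.vector(channel) * 255))
  n <- length(bins)
  best <- -Inf
  best_cuts <- integer(0)
  for (t in 0:254) {
    lo <- bins[bins <= t]
    hi <- bins[bins > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_cuts <- t
    } else if (abs(bcv - best) <= 1e-12) {
      best_cuts <- c(best_cuts, t)
    }
  }
  (mean(best_cuts) + 0.5) / 255
}

## One-way ANOVA F from the definitional sums of squares.
anova_f_hand <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tabulate(groups)
  ms_between <- sum(sizes * (means - gm)^2) / (k - 1)
  ms_within <- sum((values - means[groups])^2) / (n - k)
  ms_between / ms_within
}

## Dense eigendecomposition of the correlation matrix, with the same sign
## convention as fiber_feature_pca (largest-magnitude loading positive).
pca_eigen_oracle <- function(x) {
  x <- as.matrix(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  v <- e$vectors
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  list(loadings = v,
       scores = scale(x) %*% v,
       explained_variance = e$values / sum(e$values))
}

## Mean resultant length of a von Mises law: the Bessel ratio I1/I0.
bessel_ratio <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

## Independent component recount via EBImage's 4-connected labeller.
recount_components_4 <- function(mask) {
  max(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
}
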