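#' @name stats1d
#' @title One-dimensional time-series inference and robust comparisons
#'
#' @description
#' Paired condition inference at the continuum level via a sign-flip
#' cluster-mass permutation test (a small-sample-exact alternative to
#' random-field inference that needs no smoothness estimation), and robust
#' trimmed-mean comparisons (Yuen's paired test on 20% trimmed means).
NULL

#' 20% trimmed mean
#'
#' Discards `floor(trim * n)` observations from each tail before averaging;
#' `trim = 0` reduces to the ordinary mean.
#'
#' @param x numeric vector.
#' @param trim fraction trimmed from each tail, in `[0, 0.5)`.
#' @return the trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.20) {
  stopifnot(is.numeric(x), trim >= 0, trim < 0.5)
  n <- length(x)
  if (n - 2 * floor(trim * n) < 1) {
    stop("over-trimming: no observations left after trimming", call. = FALSE)
  }
  mean(x, trim = trim)
}

# Winsorize at the g-th order statistics from each tail.
winsorize <- function(x, g) {
  xs <- sort(x)
  lo <- xs[g + 1]; hi <- xs[length(x) - g]
  pmin(pmax(x, lo), hi)
}

#' Yuen's paired test on trimmed means
#'
#' Compares two paired samples through their trimmed means, with the
#' standard error built from the winsorized variances and covariance;
#' degrees of freedom are `h - 1` with `h = n - 2 * floor(trim * n)`.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param trim fraction trimmed from each tail, default 0.20.
#' @return list with `t_stat`, `df`, `p_value`, `diff_trimmed`.
#' @export
yuen_paired <- function(x, y, trim = 0.20) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  g <- floor(trim * n)
  h <- n - 2 * g
  if (h < 2) stop("over-trimming: fewer than 2 observations left", call. = FALSE)
  tmx <- trimmed_mean(x, trim)
  tmy <- trimmed_mean(y, trim)
  wx <- winsorize(x, g); wy <- winsorize(y, g)
  q <- (n - 1) * (var(wx) + var(wy) - 2 * stats::cov(wx, wy)) / (h * (h - 1))
  dtm <- tmx - tmy
  t_stat <- if (q <= .Machine$double.eps^0.5 && abs(dtm) < .Machine$double.eps^0.5) {
    0
  } else {
    dtm / sqrt(q)
  }
  df <- h - 1
  list(t_stat = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df),
       diff_trimmed = dtm)
}

# Pointwise paired t statistics of a difference matrix (participants x time);
# zero-variance points give t = 0.
pointwise_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, 0)
  t
}

# Suprathreshold cluster runs of |t| and their masses.
find_clusters <- function(t_stat, threshold) {
  above <- abs(t_stat) > threshold
  if (!any(above)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      mass = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    start_idx = starts[keep], end_idx = ends[keep],
    mass = vapply(keep, function(i) sum(abs(t_stat[starts[i]:ends[i]])),
                  numeric(1))
  )
}

#' Paired cluster-mass permutation test for 1D traces
#'
#' Computes the pointwise paired t statistic between two within-participant
#' trace conditions, derives the cluster-forming threshold as the
#' `1 - alpha` quantile of the sign-flip permutation distribution of the
#' maximum absolute statistic (the analogue of a random-field critical
#' value), and assigns each suprathreshold cluster a p-value from the
#' permutation distribution of the maximum cluster mass (sum of
#' suprathreshold `|t|`; ties counted with `>=`). Deterministic given
#' `seed`.
#'
#' @param tsA,tsB numeric matrices, participants in rows, time in columns.
#' @param alpha cluster-forming level, default 0.05.
#' @param n_perm number of sign-flip permutations, at least 100.
#' @param seed integer seed for the permutation draws.
#' @return list of class `cluster_test`: `clusters` (tibble with
#'   `start_idx`, `end_idx`, `mass`, `p`), `threshold_stat`, `t`,
#'   `n_permutations`, `seed`, `alpha`.
#' @export
paired_cluster_test <- function(tsA, tsB, alpha = 0.05, n_perm = 1000,
                                seed = 1L) {
  tsA <- as.matrix(tsA); tsB <- as.matrix(tsB)
  if (!all(dim(tsA) == dim(tsB))) stop("tsA and tsB must match in shape",
                                       call. = FALSE)
  n <- nrow(tsA)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  D <- tsA - tsB
  t_obs <- pointwise_t(D)

  q <- colMeans(D^2)  # invariant under sign flips
  t_from_means <- function(m) {
    v <- (q - m^2) * n / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    ifelse(se > 0, m / se, 0)
  }
  flips <- with_seed(seed, {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  })
  M <- (flips %*% D) / n                       # n_perm x T permuted means
  Tperm <- t(apply(M, 1, t_from_means))
  if (ncol(D) == 1) Tperm <- matrix(Tperm, ncol = 1)
  max_abs <- apply(abs(Tperm), 1, max)
  threshold <- quantile(max_abs, 1 - alpha, type = 1, names = FALSE)

  cl <- find_clusters(t_obs, threshold)
  if (nrow(cl)) {
    perm_mass <- vapply(seq_len(n_perm), function(i) {
      ci <- find_clusters(Tperm[i, ], threshold)
      if (nrow(ci)) max(ci$mass) else 0
    }, numeric(1))
    cl$p <- vapply(cl$mass, function(m) {
      (1 + sum(perm_mass >= m)) / (1 + n_perm)
    }, numeric(1))
  } else {
    cl$p <- numeric(0)
  }
  structure(list(clusters = tibble::as_tibble(cl), threshold_stat = threshold,
                 t = t_obs, n_permutations = n_perm, seed = seed,
                 alpha = alpha),
            class = "cluster_test")
}

#' @export
#' @method print cluster_test
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "Sign-flip cluster test: threshold |t| = %.3f (%d permutations)\n",
    x$threshold_stat, x$n_permutations))
  if (nrow(x$clusters)) {
    print(x$clusters)
  } else {
    cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}

#' Serialize a cluster-test result as JSON
#'
#' @param x a `cluster_test` result.
#' @param path output file.
#' @export
write_cluster_result <- function(x, path) {
  stopifnot(inherits(x, "cluster_test"))
  jsonlite::write_json(
    list(threshold_stat = x$threshold_stat, alpha = x$alpha,
         n_permutations = x$n_permutations, seed = x$seed,
         clusters = x$clusters),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
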