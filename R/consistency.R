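#' Split-half temporal consistency of trial dynamics
#'
#' Quantifies whether a channel's band dynamics repeat across trials:
#' trials are randomly divided into two halves, each half is averaged over
#' trials, and the two mean time courses are Pearson-correlated. The mean
#' correlation over `n_splits` random partitions is returned. With an odd
#' trial count the larger half receives the extra trial, assigned randomly
#' per split. Splits in which either mean series is constant are skipped
#' (with a warning) but still counted.
#'
#' @param x `trial x time` matrix of warped series for one channel and
#'   condition (>= 4 trials).
#' @param n_splits number of random partitions (default 1000).
#' @param seed optional integer seed.
#' @param splits optional list of pre-fixed index vectors (each giving the
#'   trials of half A); overrides the random partitioning. Used to check the
#'   estimator against a direct two-group computation.
#' @return the mean split-half correlation (scalar in `[-1, 1]`).
#' @export
split_half_consistency <- function(x, n_splits = 1000L, seed = NULL,
                                   splits = NULL) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 trials", call. = FALSE)
  run <- function() {
    if (is.null(splits)) {
      half <- n %/% 2L
      splits <- lapply(seq_len(n_splits), function(i) sample.int(n, half))
    }
    S <- matrix(0, length(splits), n)
    for (i in seq_along(splits)) S[i, splits[[i]]] <- 1
    A <- (S %*% x) / rowSums(S)
    B <- ((1 - S) %*% x) / rowSums(1 - S)
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
    va <- rowSums(A^2)
    vb <- rowSums(B^2)
    bad <- va < 1e-20 | vb < 1e-20
    vals <- rowSums(A * B) / sqrt(pmax(va * vb, 1e-300))
    if (any(bad)) {
      warning(sum(bad), " split(s) with a constant mean series skipped")
      vals[bad] <- 0
    }
    mean(vals)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Multilevel block permutation test for a condition difference
#'
#' Tests whether per-channel statistics (typically split-half consistency
#' values) are larger in condition A than in condition B. The observed
#' statistic is the mean over channels of the paired difference; the null is
#' built by randomly exchanging the two condition labels of each channel,
#' with participants recorded as exchangeability blocks (channels stay
#' within their participant's block; block structure is also used by the
#' cluster bootstrap CI, which resamples participants).
#'
#' @param cons_a,cons_b numeric vectors: per-channel values in conditions A
#'   and B (same channels, same order).
#' @param participant integer/factor vector: participant of each channel.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param alternative `"greater"` (default; A > B), `"less"` or
#'   `"two.sided"`.
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @return An object of class `permutation_result`: list with `statistic`
#'   (mean difference, also the effect size reported alongside Cohen's d),
#'   `p`, `null` (permutation sample), `cohens_d`, `ci` (95% cluster
#'   bootstrap over participants), `n_perm`, `alternative`.
#' @export
condition_difference_test <- function(cons_a, cons_b, participant,
                                      n_perm = 1000L, seed = NULL,
                                      alternative = c("greater", "less",
                                                      "two.sided"),
                                      n_boot = 2000L) {
  alternative <- match.arg(alternative)
  stopifnot(length(cons_a) == length(cons_b),
            length(participant) == length(cons_a))
  if (length(unique(participant)) < 2L) {
    warning("single participant: falling back to within-participant ",
            "permutation")
  }
  d <- cons_a - cons_b
  nc <- length(d)
  obs <- mean(d)
  run <- function() {
    null <- vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), nc, replace = TRUE)
      mean(d * flips)
    }, numeric(1))
    p <- switch(alternative,
      greater = (1 + sum(null >= obs)) / (n_perm + 1),
      less = (1 + sum(null <= obs)) / (n_perm + 1),
      two.sided = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1))
    blocks <- split(seq_len(nc), participant)
    boot <- vapply(seq_len(n_boot), function(i) {
      bs <- sample(seq_along(blocks), replace = TRUE)
      mean(d[unlist(blocks[bs])])
    }, numeric(1))
    list(null = null, p = p,
         ci = unname(quantile(boot, c(0.025, 0.975))))
  }
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(statistic = obs, p = r$p, null = r$null,
                 cohens_d = obs / max(sd(d), 1e-12), ci = r$ci,
                 n_perm = n_perm, alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): statistic = %.4f, p = %.4g",
              x$alternative, x$statistic, x$p))
  if (!is.null(x$cohens_d)) cat(sprintf(", d = %.2f", x$cohens_d))
  if (!is.null(x$ci)) {
    cat(sprintf(", 95%% CI [%.3f, %.3f]", x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' Spatial correlation of consistency between conditions
#'
#' Correlates per-channel consistency values of two conditions across
#' channels, asking whether the same recording sites carry structured
#' dynamics in both. Inference permutes the channel pairings within each
#' participant's block, keeping the across-participant structure intact.
#'
#' @inheritParams condition_difference_test
#' @return A `permutation_result` with `statistic` = Pearson r (two-sided p).
#' @export
cross_condition_spatial_correlation <- function(cons_a, cons_b, participant,
                                                n_perm = 1000L, seed = NULL) {
  stopifnot(length(cons_a) == length(cons_b))
  if (length(cons_a) < 6L) stop("need at least 6 channels", call. = FALSE)
  blocks <- split(seq_along(cons_a), participant)
  small <- vapply(blocks, length, 0L) < 3L
  if (any(small)) {
    warning("participant block(s) with < 3 channels merged for permutation")
    merged <- unlist(blocks[small], use.names = FALSE)
    blocks <- c(blocks[!small], list(merged = merged))
  }
  obs <- cor(cons_a, cons_b)
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      bp <- cons_b
      for (blk in blocks) bp[blk] <- bp[sample(blk)]
      cor(cons_a, bp)
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  structure(list(statistic = obs, p = p, null = null, cohens_d = NULL,
                 ci = NULL, n_perm = n_perm, alternative = "two.sided"),
            class = "permutation_result")
}
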