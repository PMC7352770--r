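# Validation and inference statistics: Bland-Altman agreement, Pearson
# correlation matrices and a slice-clustered permutation test.

#' Bland-Altman agreement between two paired counters
#'
#' Differences are `a - b`; the bias is their mean, `sd_diff` the sample
#' standard deviation (n - 1 denominator) and the 95% limits of agreement
#' `bias -+ 1.96 sd_diff`.
#'
#' @param a,b Paired measurements of equal length, n >= 2.
#' @return Object of class `"bland_altman"`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `differences` and `means`
#'   (for plotting).
#' @examples
#' pc <- generate_paired_counts(rpois(100, 10), sd_a = 3, sd_b = 3, seed = 2)
#' bland_altman(pc$a, pc$b)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 n = length(a), differences = d, means = (a + b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  bias      %8.3f\n  sd(diff)  %8.3f\n", x$bias, x$sd_diff))
  cat(sprintf("  95%% limits of agreement [%.3f, %.3f]\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson R for every column pair with two-sided p-values from the
#' t-distribution with n - 2 degrees of freedom; rows with any missing value
#' are dropped (listwise deletion). Zero-variance columns give `NA`
#' correlations for their pairs, with a warning.
#'
#' @param table Data frame or matrix of numeric columns (e.g. a
#'   `"slice_morphology"` table restricted to its numeric measures);
#'   n >= 3 complete rows required.
#' @return Object of class `"correlation_matrix"`: list with `R`, `p`
#'   (matrices with unit/NA diagonal), `n` and `variables`.
#' @examples
#' prof <- generate_depth_profile(30, seed = 7)
#' cm <- pearson_matrix(prof[, c("depth", "necrotic_fraction",
#'                               "dapi_fraction")])
#' round(cm$R, 2)
#' @export
pearson_matrix <- function(table) {
  x <- as.matrix(as.data.frame(table))
  stopifnot(is.numeric(x))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 complete rows", call. = FALSE)
  k <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; their correlations are undefined (NA)")
  R <- suppressWarnings(stats::cor(x))
  R[, sds == 0] <- NA_real_
  R[sds == 0, ] <- NA_real_
  diag(R)[sds > 0] <- 1
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(R = R, p = p, n = n, variables = colnames(x)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (n = ", x$n, ")\n", sep = "")
  print(round(x$R, digits))
  invisible(x)
}

#' Slice-clustered permutation test for a treatment effect
#'
#' Per-nucleus (or per-cell) values are nested in slices, and slices carry
#' the treatment label, so nuclei are not exchangeable across groups while
#' slices are. The test statistic is the difference of group means of slice
#' means; slice-level group labels are permuted (respecting the group sizes)
#' and the two-sided p-value is `(1 + #{|T*| >= |T|}) / (n_perm + 1)` (the +1
#' correction avoids zero p-values).
#'
#' @param values Numeric per-nucleus values.
#' @param slice Slice identifier per value.
#' @param group Group label per value; exactly two groups, each with at
#'   least 2 slices.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return Object of class `"perm_test"`: list with `p`, `observed`
#'   (difference of group means of slice means, first group minus second),
#'   `slice_means`, `n_perm`, `groups`.
#' @examples
#' prof <- data.frame(v = rnorm(60), s = rep(1:6, each = 10),
#'                    g = rep(c("ctrl", "irr"), each = 30))
#' clustered_permutation_test(prof$v, prof$s, prof$g, n_perm = 199, seed = 1)
#' @export
clustered_permutation_test <- function(values, slice, group,
                                       n_perm = 10000L, seed = 1L) {
  stopifnot(length(values) == length(slice),
            length(values) == length(group))
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  sl <- interaction(slice, drop = TRUE)
  sm <- tapply(values, sl, mean)
  sg <- tapply(as.character(group), sl, function(g) {
    u <- unique(g)
    if (length(u) != 1L)
      stop("a slice maps to more than one group", call. = FALSE)
    u
  })
  groups <- sort(unique(sg))
  if (length(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  n_by <- table(factor(sg, levels = groups))
  if (any(n_by < 2L))
    stop("each group needs at least 2 slices (got ",
         paste(n_by, collapse = " and "), ")", call. = FALSE)

  is_a <- sg == groups[1]
  n1 <- sum(is_a); ns <- length(sm)
  stat <- function(sel_a) mean(sm[sel_a]) - mean(sm[!sel_a])
  observed <- stat(is_a)
  perms <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sel <- logical(ns)
      sel[sample.int(ns, n1)] <- TRUE
      stat(sel)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perms) >= abs(observed) - 1e-12)) / (n_perm + 1)
  structure(list(p = p, observed = observed, slice_means = sm,
                 n_perm = n_perm, groups = groups),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Slice-clustered permutation test (", x$n_perm, " permutations)\n",
      sep = "")
  cat(sprintf("  difference of group means of slice means (%s - %s): %.4f\n",
              x$groups[1], x$groups[2], x$observed))
  cat(sprintf("  two-sided p = %.4g\n", x$p))
  invisible(x)
}
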