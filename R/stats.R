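# Paired comparisons between the two electrode systems: paired t, Wilcoxon
# signed-rank, Pearson correlation, intraclass correlation with a
# permutation null, and the Monte-Carlo permutation test for
# time-frequency maps. Permutation p-values use the add-one convention
# p = (1 + #{null >= observed}) / (n_perm + 1), and every randomized test
# takes its own seed so statistics never share a stream with data
# generation.

#' Paired t-test
#'
#' Classic paired t on the within-subject differences, two-sided.
#'
#' @param a,b equal-length numeric vectors of per-subject values.
#' @return List of class `paired_test_result`: `statistic`, `df`,
#'   `p_value`, `test_name`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least two pairs")
  d <- a - b
  if (!all(is.finite(d))) stop("inputs must be finite")
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      # identical inputs: no evidence of a difference
      return(structure(
        list(statistic = 0, df = length(d) - 1L, p_value = 1, test_name = "paired_t"),
        class = "paired_test_result"
      ))
    }
    stop("differences have zero variance; paired t-test is degenerate")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  structure(
    list(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value, test_name = "paired_t"
    ),
    class = "paired_test_result"
  )
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original convention). The
#' statistic V is the sum of the ranks of the positive differences. The
#' p-value is exact (signed-rank distribution) for n <= 25 with untied
#' ranks, and a normal approximation with tie correction otherwise.
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List of class `paired_test_result` with `statistic` (V), `n`
#'   (pairs used after dropping zeros), `p_value`, `exact`, `test_name`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; signed-rank test is degenerate")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    p_ge <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(V, n)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      greater = p_ge,
      less = p_le
    )
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_sizes^3 - tie_sizes) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    exact <- FALSE
  }
  structure(
    list(statistic = V, n = n, p_value = p, exact = exact,
         test_name = "wilcoxon"),
    class = "paired_test_result"
  )
}

#' Pearson correlation with t-test for deviation from zero
#'
#' @param a,b equal-length numeric vectors (n >= 3, nonzero variance).
#' @return List of class `correlation_result`: `r`, `n`, `p_value`
#'   (two-sided, from t with n-2 df).
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least three pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance input")
  r <- stats::cor(a, b)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, n = n, p_value = p), class = "correlation_result")
}

#' Intraclass correlation between two aligned series
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC --
#' ICC(2,1) -- treating time points as targets and the two systems as
#' raters; a consistency variant, ICC(3,1), is available as a switch.
#' Symmetric in its two arguments.
#'
#' @param x,y equal-length numeric series (length >= 3).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @return The ICC value (scalar, <= 1).
#' @export
icc_single <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 3L) stop("series too short for an ICC (need >= 3 points)")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("both series are constant; ICC degenerate")
  k <- 2
  row_mean <- (x + y) / 2
  grand <- mean(row_mean)
  col_mean <- c(mean(x), mean(y))
  ss_rows <- k * sum((row_mean - grand)^2)
  ss_cols <- n * sum((col_mean - grand)^2)
  ss_tot <- sum((x - grand)^2) + sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Permutation test for the mean individual-level ICC
#'
#' The observed statistic is the mean over subjects of the ICC between the
#' two systems' series. The null reassigns the pooled series at random to
#' subject-by-system slots (free relabeling across all subjects and
#' systems), recomputes per-subject ICCs and averages; the p-value is the
#' add-one-corrected fraction of null means at or above the observed mean.
#'
#' @param pairs list over subjects of `list(a = series, b = series)`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param type ICC variant, see [icc_single()].
#' @return List of class `icc_result`: `mean_icc`, `per_subject_iccs`,
#'   `p_value`, `n_permutations`, `null_mean_iccs`.
#' @export
icc_permutation_test <- function(pairs, n_perm = 1000, seed = 1L,
                                 type = "agreement") {
  S <- length(pairs)
  if (S < 2L) stop("need at least two subjects")
  per_subject <- vapply(pairs, function(p) icc_single(p$a, p$b, type), numeric(1))
  true_mean <- mean(per_subject)
  pool <- c(lapply(pairs, `[[`, "a"), lapply(pairs, `[[`, "b"))
  null_means <- with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(2L * S)
      mean(vapply(seq_len(S), function(s) {
        icc_single(pool[[idx[s]]], pool[[idx[S + s]]], type)
      }, numeric(1)))
    }, numeric(1))
  })
  p <- (1 + sum(null_means >= true_mean)) / (n_perm + 1)
  structure(
    list(
      mean_icc = true_mean, per_subject_iccs = per_subject, p_value = p,
      n_permutations = n_perm, null_mean_iccs = null_means
    ),
    class = "icc_result"
  )
}

# Per-cell paired t-statistics for S x C matrices of cell values.
cellwise_paired_t <- function(d) {
  S <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - S * m^2) / (S - 1)
  v <- pmax(v, 0)
  tt <- ifelse(v > 0, m / sqrt(v / S), 0)
  tt
}

#' Point-wise permutation test for paired time-frequency maps
#'
#' Compares two systems' per-subject maps cell by cell with a paired
#' t-statistic, then builds each cell's null distribution by randomly
#' flipping the sign of each subject's difference map (equivalent to
#' swapping the two system labels within a subject, the
#' exchangeability-respecting operation for a paired design). Cells whose
#' differences are identically zero are assigned t = 0 and p = 1.
#'
#' @param maps_a,maps_b numeric arrays, subjects x (cell dims...); the
#'   shapes must match.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alpha significance threshold recorded with the result.
#' @return List of class `permutation_result`: `t_map`, `p_map` (same cell
#'   shape as one subject's map), `n_permutations`, `alpha`, `seed`.
#' @export
tf_permutation_test <- function(maps_a, maps_b, n_perm = 1000, seed = 1L,
                                alpha = 0.05) {
  if (!identical(dim(maps_a), dim(maps_b))) stop("map grids do not match")
  dims <- dim(maps_a)
  S <- dims[1]
  cell_dim <- dims[-1]
  d <- matrix(maps_a - maps_b, nrow = S)
  t_true <- cellwise_paired_t(d)
  count_ge <- numeric(length(t_true))
  with_seed(as.integer(seed), {
    for (i in seq_len(n_perm)) {
      signs <- sample(c(-1, 1), S, replace = TRUE)
      t_perm <- cellwise_paired_t(d * signs)
      count_ge <- count_ge + (abs(t_perm) >= abs(t_true))
    }
  })
  p <- (1 + count_ge) / (n_perm + 1)
  all_zero <- colSums(d != 0) == 0
  p[all_zero] <- 1
  t_map <- array(t_true, dim = cell_dim)
  p_map <- array(p, dim = cell_dim)
  structure(
    list(t_map = t_map, p_map = p_map, n_permutations = n_perm,
         alpha = alpha, seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject waveforms (vectors) or maps (matrices /
#' arrays) with identical shapes.
#'
#' @param xs list of equal-shaped numeric vectors/arrays.
#' @return The element-wise mean, same shape as each input.
#' @export
grand_average <- function(xs) {
  if (length(xs) == 0L) stop("empty input")
  ref <- dim(xs[[1]]) %||% length(xs[[1]])
  for (x in xs) {
    if (!identical(dim(x) %||% length(x), ref)) stop("inputs have mismatched shapes")
  }
  Reduce(`+`, xs) / length(xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
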