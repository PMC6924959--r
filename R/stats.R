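# Rank-based two-sample tests with exact small-sample null distributions,
# and descriptive group summaries (box-plot convention).
#
# Exact null distributions are computed by dynamic programming over
# mid-ranks (doubled so ties at .5 become integers): for the rank-sum test
# the number of size-n_x subsets of the pooled ranks attaining each rank
# total; for the signed-rank test the number of sign patterns attaining
# each positive-rank total. Two-tailed p = min(1, 2 * min(lower tail,
# upper tail)).

# counts[s + 1] = number of k-subsets of integer weights d summing to s
.subset_sum_counts <- function(d, k) {
  S <- sum(d)
  dp <- matrix(0, nrow = k + 1L, ncol = S + 1L)
  dp[1L, 1L] <- 1
  for (w in d) {
    for (j in k:1L) {                      # descending so each weight used once
      nz <- which(dp[j, ] > 0)
      if (length(nz))
        dp[j + 1L, nz + w] <- dp[j + 1L, nz + w] + dp[j, nz]
    }
  }
  dp[k + 1L, ]
}

# counts[s + 1] = number of subsets (any size) of weights d summing to s
.signflip_sum_counts <- function(d) {
  counts <- c(1, numeric(sum(d)))
  for (w in d) {
    nz <- which(counts > 0)
    counts[nz + w] <- counts[nz + w] + counts[nz]
  }
  counts
}

.two_tailed_from_counts <- function(counts, w_obs) {
  total <- sum(counts)
  lower <- sum(counts[seq_len(w_obs + 1L)]) / total
  upper <- sum(counts[(w_obs + 1L):length(counts)]) / total
  min(1, 2 * min(lower, upper))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-tailed test of identical distributions against a location shift.
#' In exact mode the null distribution of the rank sum is enumerated over
#' all assignments of the pooled mid-ranks (ties handled exactly); in
#' normal-approximation mode a tie-corrected variance and a continuity
#' correction of 1/2 are used. `mode = "auto"` uses the exact distribution
#' when `length(x) + length(y) <= 20`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic` (Mann-Whitney U of `x`), `p.value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])                 # rank sum of x (mid-ranks)
  u <- w - nx * (nx + 1) / 2
  if (mode == "auto") mode <- if (N <= 20L) "exact" else "normal"
  if (mode == "exact") {
    d <- as.integer(round(2 * r))
    counts <- .subset_sum_counts(d, nx)
    p <- .two_tailed_from_counts(counts, as.integer(round(2 * w)))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- nx * ny / 2
    v <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = u, p.value = p,
       method = paste("two-tailed Wilcoxon rank-sum test,", method))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed test on paired differences `after - before`. Zero differences
#' are dropped (Wilcoxon convention); if all differences are zero the test
#' is degenerate and returns p = 1 with a warning. In exact mode the null
#' distribution of the positive-rank sum is enumerated over all sign
#' patterns (mid-ranks for tied magnitudes); `mode = "auto"` uses the exact
#' distribution when the number of non-zero differences is <= 20, else a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param before,after Paired numeric samples of equal length (>= 2).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic` (positive-rank sum V), `p.value`, `method`.
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(before) != length(after))
    stop("paired samples must have equal length")
  if (length(before) < 2L) stop("need at least two pairs")
  d <- after - before
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1,
                method = "two-tailed Wilcoxon signed-rank test, degenerate"))
  }
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "normal"
  if (mode == "exact") {
    counts <- .signflip_sum_counts(as.integer(round(2 * r)))
    p <- .two_tailed_from_counts(counts, as.integer(round(2 * v)))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    varv <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(varv)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = v, p.value = p,
       method = paste("two-tailed Wilcoxon signed-rank test,", method))
}

#' Compare the reference layer against every other layer
#'
#' For one pathway and cell type, runs two-tailed rank-sum tests of the
#' reference layer (L4 for VPM, L5A for POm) against each other layer, for
#' EPSP amplitude and slope, both absolute and normalized. No
#' multiple-comparison adjustment is applied by default (set `adjust` to a
#' [stats::p.adjust()] method to change that). Only control-condition cells
#' enter the comparisons. Pairs with an empty group are marked untestable.
#'
#' @param normalized Output of [normalize_dataset()].
#' @param pathway `"VPM"` or `"POm"`.
#' @param cell_type Cell class to compare across layers (default `"EXC"`).
#' @param mode Test mode passed to [wilcoxon_rank_sum()].
#' @param adjust Multiple-testing adjustment method (default `"none"`).
#' @return data.frame with one row per (layer, feature, scale): `n_ref`,
#'   `n`, `p_value`, `testable`.
#' @export
compare_reference_layer <- function(normalized, pathway,
                                    cell_type = "EXC",
                                    mode = c("auto", "exact", "normal"),
                                    adjust = "none") {
  mode <- match.arg(mode)
  pathway <- match.arg(pathway, PATHWAYS)
  ref <- reference_layer(pathway)
  df <- normalized[normalized$pathway == pathway &
                     normalized$cell_type == cell_type &
                     normalized$condition == "control", , drop = FALSE]
  if ("analyzed" %in% names(df)) df <- df[df$analyzed, , drop = FALSE]
  feats <- data.frame(
    feature = c("amplitude", "amplitude", "slope", "slope"),
    scale = c("absolute", "normalized", "absolute", "normalized"),
    column = c("peak_amp_mV", "norm_amp", "slope_mV_per_ms", "norm_slope"))
  layers <- setdiff(LAYERS, ref)
  out <- do.call(rbind, lapply(layers, function(ly) {
    do.call(rbind, lapply(seq_len(nrow(feats)), function(k) {
      xv <- df[[feats$column[k]]][df$layer == ref]
      yv <- df[[feats$column[k]]][df$layer == ly]
      xv <- xv[!is.na(xv)]; yv <- yv[!is.na(yv)]
      testable <- length(xv) >= 1L && length(yv) >= 1L
      data.frame(pathway = pathway, cell_type = cell_type,
                 ref_layer = ref, layer = ly,
                 feature = feats$feature[k], scale = feats$scale[k],
                 n_ref = length(xv), n = length(yv),
                 p_value = if (testable)
                   wilcoxon_rank_sum(xv, yv, mode)$p.value else NA_real_,
                 testable = testable)
    }))
  }))
  if (adjust != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  out
}

#' Descriptive summary of a group (box-plot convention)
#'
#' Mean, SD (n-1 denominator), SEM, median, linear-interpolation (type 7)
#' quartiles, and whiskers extending to the smallest/largest data points
#' within 1.5 x IQR of the first/third quartile.
#'
#' @param values Numeric vector, `NA`s dropped; at least one value.
#' @return One-row data.frame: `n, mean, sd, sem, median, q1, q3,
#'   whisker_lo, whisker_hi`. SD and SEM are `NA` for a single value.
#' @export
summarize_group <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("cannot summarize an empty group")
  n <- length(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  s <- if (n > 1L) stats::sd(v) else NA_real_
  data.frame(n = n, mean = mean(v), sd = s, sem = s / sqrt(n),
             median = q[2L], q1 = q[1L], q3 = q[3L],
             whisker_lo = min(v[v >= q[1L] - 1.5 * iqr]),
             whisker_hi = max(v[v <= q[3L] + 1.5 * iqr]))
}
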