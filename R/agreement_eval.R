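#' Synchronize measured and reference stride series
#'
#' Protocols start the reference capture with a known foot (the subject
#' steps into the walkway with the right foot), so the initial contact of
#' the very first reference stride can be identified in both systems.
#' The returned offset is `reference first IC - measured first IC of the
#' matching foot`; adding it to measured times aligns the two series.
#'
#' @param measured stride table (data.frame with `ic_time`, `foot`).
#' @param reference reference stride table.
#' @return time offset, s.
#' @export
synchronize_by_first_stride <- function(measured, reference) {
  if (!nrow(measured) || !nrow(reference))
    stop("cannot synchronize empty stride series")
  ref_foot <- reference$foot[1]
  m <- measured[measured$foot == ref_foot, , drop = FALSE]
  if (!nrow(m)) m <- measured
  reference$ic_time[1] - m$ic_time[1]
}

#' Match measured strides to reference strides by initial-contact time
#'
#' Greedy one-to-one nearest matching: candidate pairs within `tol` of one
#' another (after applying `offset` to the measured times and restricting
#' to the same foot) are accepted in order of increasing time difference,
#' each stride used at most once.
#'
#' @param measured,reference stride tables with `ic_time`, `foot`, and the
#'   metric columns.
#' @param offset time offset added to measured IC times, s.
#' @param tol matching tolerance, s.
#' @param metric which parameter to pair: `"stride_length"` or
#'   `"stride_time"`.
#' @return list of class `matched_stride_pairs`: data.frame `pairs` with
#'   `measured`, `reference`, `ic_time`, `foot`; `metric`;
#'   `n_unmatched_measured`; `n_unmatched_reference`.
#' @export
match_strides <- function(measured, reference, offset = 0, tol = 0.25,
                          metric = c("stride_length", "stride_time")) {
  metric <- match.arg(metric)
  mt <- measured$ic_time + offset
  rt <- reference$ic_time
  cand <- expand.grid(i = seq_along(mt), j = seq_along(rt))
  cand$d <- abs(mt[cand$i] - rt[cand$j])
  same_foot <- measured$foot[cand$i] == reference$foot[cand$j]
  cand <- cand[cand$d <= tol & same_foot, , drop = FALSE]
  cand <- cand[order(cand$d), , drop = FALSE]
  used_i <- logical(length(mt))
  used_j <- logical(length(rt))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(rt[cand$j]), , drop = FALSE]
  pairs <- data.frame(
    measured = measured[[metric]][cand$i],
    reference = reference[[metric]][cand$j],
    ic_time = rt[cand$j],
    foot = reference$foot[cand$j],
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, metric = metric,
                 n_unmatched_measured = sum(!used_i),
                 n_unmatched_reference = sum(!used_j)),
            class = "matched_stride_pairs")
}

#' @export
print.matched_stride_pairs <- function(x, ...) {
  cat(sprintf("<matched_stride_pairs> %d pairs of %s (%d/%d unmatched measured/reference)\n",
              nrow(x$pairs), x$metric, x$n_unmatched_measured,
              x$n_unmatched_reference))
  invisible(x)
}

pair_values <- function(pairs) {
  if (inherits(pairs, "matched_stride_pairs")) pairs$pairs else pairs
}

#' Correlation / regression agreement analysis
#'
#' Pearson correlation, ordinary-least-squares regression of measured on
#' reference, and the root-mean-square error about the identity line
#' (`sqrt(mean((measured - reference)^2))`) -- RMSE quantifies deviation
#' from the gold standard, not scatter about the fitted line, so a slope
#' away from 1 and a small RMSE can coexist.
#'
#' @param pairs a [match_strides()] result (or data.frame with `measured`
#'   and `reference` columns).
#' @return list of class `agreement_report`: `r`, `slope`, `intercept`,
#'   `rmse`, `n`.
#' @export
correlation_analysis <- function(pairs) {
  d <- pair_values(pairs)
  if (nrow(d) < 3) stop("need at least 3 pairs for correlation analysis")
  if (stats::var(d$reference) == 0)
    stop("reference values have zero variance; correlation undefined")
  slope <- stats::cov(d$measured, d$reference) / stats::var(d$reference)
  intercept <- mean(d$measured) - slope * mean(d$reference)
  structure(list(
    r = stats::cor(d$measured, d$reference),
    slope = slope, intercept = intercept,
    rmse = sqrt(mean((d$measured - d$reference)^2)),
    n = nrow(d)), class = "agreement_report")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = measured - reference`; `bias = mean(d)` and limits of
#' agreement `bias +/- 1.96 sd(d)` with the n-1 denominator.  The
#' per-pair means `(measured + reference)/2` are returned for plotting.
#'
#' @param pairs a [match_strides()] result (or data.frame with `measured`
#'   and `reference` columns).
#' @return list of class `bland_altman_report`: `bias`, `loa_half_width`,
#'   `loa_lower`, `loa_upper`, `n`, plus `differences` and `means`.
#' @export
bland_altman <- function(pairs) {
  d <- pair_values(pairs)
  if (nrow(d) < 2) stop("need at least 2 pairs for Bland-Altman analysis")
  diffs <- d$measured - d$reference
  bias <- mean(diffs)
  half <- 1.96 * stats::sd(diffs)
  structure(list(bias = bias, loa_half_width = half,
                 loa_lower = bias - half, loa_upper = bias + half,
                 n = nrow(d),
                 differences = diffs, means = (d$measured + d$reference) / 2),
            class = "bland_altman_report")
}

# mean silhouette coefficient for 1-d points under Euclidean distance
mean_silhouette <- function(x, labels) {
  n <- length(x)
  D <- abs(outer(x, x, `-`))
  s <- numeric(n)
  lev <- unique(labels)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(lev[lev != labels[i]],
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' K-means screen on stride differences
#'
#' Clusters the per-stride differences (measured - reference) into `k`
#' groups and reports the mean silhouette coefficient, a cluster-separation
#' measure in [-1, 1] (1 = clusters far apart).  Cross-tabulating the
#' labels against the foot of each stride exposes left/right-inconsistent
#' device pairs: two well-separated clusters that coincide with the feet
#' indicate one miscalibrated unit, a pattern invisible in pooled summary
#' statistics.
#'
#' @param pairs a [match_strides()] result (or data.frame with `measured`,
#'   `reference` and optionally `foot` columns).
#' @param k number of clusters.
#' @param seed RNG seed for the k-means initialization (deterministic).
#' @return list of class `cluster_report`: `labels`, `mean_sc`,
#'   `cluster_means` (per-cluster mean difference), `foot_table`
#'   (labels x foot contingency table, when feet are known).
#' @export
cluster_differences <- function(pairs, k = 2, seed = 0) {
  d <- pair_values(pairs)
  diffs <- d$measured - d$reference
  if (length(diffs) < k) stop("need at least k pairs")
  if (stats::sd(diffs) == 0)
    stop("all differences identical; clustering degenerate")
  if (length(diffs) == k) {
    labels <- order(order(diffs)) - 1L  # k = n: every point its own cluster
  } else {
    km <- with_local_seed(seed,
      stats::kmeans(matrix(diffs, ncol = 1), centers = k, nstart = 10))
    labels <- km$cluster - 1L
  }
  ft <- if (!is.null(d$foot)) table(cluster = labels, foot = d$foot) else NULL
  structure(list(labels = labels,
                 mean_sc = mean_silhouette(diffs, labels),
                 cluster_means = tapply(diffs, labels, mean),
                 foot_table = ft, k = k),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d, mean silhouette %.3f\n", x$k, x$mean_sc))
  if (!is.null(x$foot_table)) print(x$foot_table)
  invisible(x)
}

#' Full agreement evaluation of one metric
#'
#' Convenience wrapper: synchronize, match, then run correlation,
#' Bland-Altman and the k-means screen.
#'
#' @param measured,reference stride tables.
#' @param metric `"stride_length"` or `"stride_time"`.
#' @param tol matching tolerance, s.
#' @param cluster_seed seed for [cluster_differences()].
#' @return list with `matched`, `correlation`, `bland_altman`, `clusters`.
#' @export
evaluate_agreement <- function(measured, reference,
                               metric = "stride_length", tol = 0.25,
                               cluster_seed = 0) {
  offset <- synchronize_by_first_stride(measured, reference)
  matched <- match_strides(measured, reference, offset, tol, metric)
  list(matched = matched,
       correlation = correlation_analysis(matched),
       bland_altman = bland_altman(matched),
       clusters = if (nrow(matched$pairs) >= 2 &&
                      stats::sd(matched$pairs$measured -
                                matched$pairs$reference) > 0)
         cluster_differences(matched, seed = cluster_seed) else NULL,
       offset = offset)
}
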