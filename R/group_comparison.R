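#' Difference in group medians
#'
#' `median(a) - median(b)`; the even-length median is the mean of the two
#' central order statistics (the base R convention).
#'
#' @param a,b Nonempty numeric vectors.
#' @return Numeric scalar.
#' @export
median_difference <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0, is.numeric(a), is.numeric(b))
  median(a) - median(b)
}

#' Percentile bootstrap CI for the difference in medians
#'
#' Each replicate resamples `a` and `b` independently with replacement at
#' their original sizes and records the median difference; the confidence
#' interval is the (alpha/2, 1 - alpha/2) percentile pair of the replicate
#' distribution (linear interpolation between order statistics). The
#' difference is significant when the interval does not cover zero. Results
#' are bit-identical under a fixed seed.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param n_replicates Number of bootstrap replicates (default 10,000).
#' @param alpha Two-sided significance level.
#' @param seed Integer seed (recorded in the result).
#' @param group_a,group_b Labels for the output row.
#' @return One-row `data.frame` of class `bis_bootstrap`: `group_a`,
#'   `group_b`, `n_a`, `n_b`, `estimate`, `ci_low`, `ci_high`,
#'   `n_replicates`, `alpha`, `significant`, `seed`.
#' @export
bootstrap_median_ci <- function(a, b, n_replicates = 10000, alpha = 0.05,
                                seed = NULL, group_a = "a", group_b = "b") {
  stopifnot(length(a) >= 2, length(b) >= 2, alpha > 0, alpha < 1)
  if (n_replicates < 2) stop("n_replicates must be at least 2")
  if (n_replicates < 100) {
    warning("fewer than 100 bootstrap replicates; interval will be coarse")
  }
  na <- length(a)
  nb <- length(b)
  diffs <- with_seed(seed, {
    ma <- matrix(a[sample.int(na, na * n_replicates, replace = TRUE)], na)
    mb <- matrix(b[sample.int(nb, nb * n_replicates, replace = TRUE)], nb)
    apply(ma, 2, median) - apply(mb, 2, median)
  })
  ci <- quantile(diffs, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  out <- data.frame(
    group_a = group_a, group_b = group_b, n_a = na, n_b = nb,
    estimate = median_difference(a, b),
    ci_low = ci[1], ci_high = ci[2],
    n_replicates = n_replicates, alpha = alpha,
    significant = ci[1] > 0 || ci[2] < 0,
    seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bis_bootstrap", "data.frame")
  out
}

#' Asymptotic Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties, continuity-corrected normal
#' approximation with tie-corrected variance, two-sided p-value. When every
#' value in both groups is identical the test is degenerate and p = 1 is
#' returned with a warning.
#'
#' @param a,b Nonempty numeric vectors.
#' @return List: `statistic` (rank sum of `a`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a)
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(na)])
  if (length(unique(c(a, b))) == 1) {
    warning("all values identical across both groups; p set to 1")
    return(list(statistic = w, p_value = 1))
  }
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(statistic = w, p_value = ht$p.value)
}

#' Compare health groups by bootstrap and Wilcoxon
#'
#' Runs the percentile bootstrap (and Wilcoxon validation) for the group
#' pairs healthy vs IBD, healthy vs prediabetes, prediabetes vs IBD, and
#' Crohn's disease vs ulcerative colitis, where IBD pools the `ibd_cd` and
#' `ibd_uc` donors. The difference is first-listed group minus second. Pairs
#' where either group has fewer than 2 donors are skipped with a message.
#'
#' @param donor_profiles A [aggregate_by_donor()] result, or its `donors`
#'   `data.frame`.
#' @param metric `"presence_count"` or `"bacteroidetes_abundance"`.
#' @param n_replicates,alpha Bootstrap parameters.
#' @param seed Base seed; pair i uses `seed + i`.
#' @return `data.frame` with one row per comparable pair: the
#'   [bootstrap_median_ci()] columns plus `metric`, `wilcoxon_statistic`,
#'   `wilcoxon_p`.
#' @export
compare_all_groups <- function(donor_profiles,
                               metric = c("presence_count",
                                          "bacteroidetes_abundance"),
                               n_replicates = 10000, alpha = 0.05,
                               seed = 1L) {
  metric <- match.arg(metric)
  donors <- if (inherits(donor_profiles, "bis_donor_profiles")) {
    donor_profiles$donors
  } else {
    donor_profiles
  }
  col <- if (metric == "presence_count") "presence_count" else "bacteroidetes"
  if (!col %in% names(donors)) stop("donor table lacks column ", col)
  values <- function(grp) {
    g <- if (grp == "ibd") c("ibd_cd", "ibd_uc") else grp
    donors[[col]][donors$group %in% g]
  }
  pairs <- list(c("healthy", "ibd"), c("healthy", "prediabetes"),
                c("prediabetes", "ibd"), c("ibd_cd", "ibd_uc"))
  rows <- list()
  for (i in seq_along(pairs)) {
    a <- values(pairs[[i]][1])
    b <- values(pairs[[i]][2])
    if (length(a) < 2 || length(b) < 2) {
      message("skipping ", pairs[[i]][1], " vs ", pairs[[i]][2],
              ": fewer than 2 donors in a group")
      next
    }
    res <- bootstrap_median_ci(a, b, n_replicates = n_replicates,
                               alpha = alpha, seed = seed + i,
                               group_a = pairs[[i]][1],
                               group_b = pairs[[i]][2])
    wt <- wilcoxon_rank_sum(a, b)
    res$metric <- metric
    res$wilcoxon_statistic <- wt$statistic
    res$wilcoxon_p <- wt$p_value
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out
}
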