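# Statistical analyses: Fisher's exact association test (aggregate location
# x TOM20 status) and pairwise Wilcoxon rank-sum comparisons of per-group
# aggregate areas with Benjamini-Hochberg correction.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Row 1 is one location class (e.g. extracellular marker-positive /
#' marker-negative), row 2 the other. The two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table; the reported odds
#' ratio is the sample cross-product `(a*d)/(b*c)` (`Inf` when `b*c = 0` and
#' `a*d > 0`), with the conditional maximum-likelihood estimate retained in
#' `odds_ratio_cmle`. The 95% CI is from the conditional exact (noncentral
#' hypergeometric inversion) method. A table with a zero margin carries no
#' information about association: p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise: a, b / c, d),
#'   or a 2x2 matrix as `a`.
#' @return An object of class `fisher_result` with `odds_ratio`,
#'   `odds_ratio_cmle`, `p_two_sided`, `ci_95`, `method_note`, `table` and
#'   `proportions` (row-wise marker-positive percentages).
#' @examples
#' fisher_exact_2x2(28, 18, 33, 3)   # location x TOM20 status
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  # `c` is a cell count here; be explicit about base::c throughout
  if (is.matrix(a)) {
    if (!all(dim(a) == base::c(2L, 2L))) stop("invalid table: need a 2x2 matrix")
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- base::c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("invalid table: counts must be non-negative integers")
  if (sum(cells) < 1) stop("invalid table: total must be at least 1")
  tab <- matrix(as.numeric(cells), 2L, 2L, byrow = TRUE)
  or_sample <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  margins_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  if (margins_ok) {
    ft <- stats::fisher.test(tab, conf.level = 0.95)
    p <- ft$p.value
    ci <- as.numeric(ft$conf.int)
    or_cmle <- unname(ft$estimate)
  } else {
    p <- 1
    ci <- base::c(NA_real_, NA_real_)
    or_cmle <- NA_real_
  }
  structure(list(
    table = tab,
    odds_ratio = or_sample,
    odds_ratio_cmle = or_cmle,
    p_two_sided = p,
    ci_95 = ci,
    proportions = base::c(row1_pos_pct = 100 * a / max(a + b, 1),
                          row2_pos_pct = 100 * c / max(c + d, 1)),
    method_note = paste("two-sided conditional exact p; sample (cross-product)",
                        "odds ratio; CI by conditional exact inversion")
  ), class = "fisher_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' The reported statistic is the rank sum of the first sample on midranks.
#' The p-value is from the exact rank-sum distribution when
#' `min(n_x, n_y) <= 10` and there are no ties, and otherwise from the normal
#' approximation with tie-corrected variance and continuity correction
#' (the asymptotic regime of the area experiment, where group sizes are
#' ~94--107).
#'
#' @param x,y non-empty numeric samples.
#' @return A list with `statistic` (rank sum of `x`), `p_raw`, and `exact`
#'   (whether the exact distribution was used).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  pooled <- c(x, y)
  ranks <- rank(pooled)
  statistic <- sum(ranks[seq_along(x)])
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- min(length(x), length(y)) <= 10L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = statistic, p_raw = min(1, wt$p.value), exact = use_exact)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, sets `adjusted_i = min over j >= i of
#' (m * p_j / j)` capped at 1, and returns the adjusted values in the input
#' order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("invalid p-value: all values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise Wilcoxon rank-sum comparisons with BH correction
#'
#' Runs [wilcoxon_rank_sum()] on every requested pair of groups (default: all
#' unordered pairs, e.g. the 6 pairs of the 4 culture conditions) and applies
#' Benjamini-Hochberg correction across exactly that family of tests.
#'
#' @param table data frame with columns `group` and `area_nm2` (all areas
#'   positive).
#' @param pairs optional list of `c(group1, group2)` label pairs.
#' @return A data frame sorted by pair label with columns `group1`, `group2`,
#'   `statistic`, `p_raw`, `p_adjusted`.
#' @export
compare_groups <- function(table, pairs = NULL) {
  if (!all(c("group", "area_nm2") %in% names(table)))
    stop("table must have columns 'group' and 'area_nm2'")
  if (any(table$area_nm2 <= 0)) stop("every area must be positive")
  groups <- sort(unique(as.character(table$group)))
  if (is.null(pairs)) {
    if (length(groups) < 2L) stop("need at least two groups")
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
  }
  for (p in pairs) {
    if (!all(p %in% groups))
      stop("missing group: ", paste(setdiff(p, groups), collapse = ", "))
  }
  res <- lapply(pairs, function(p) {
    x <- table$area_nm2[table$group == p[1]]
    y <- table$area_nm2[table$group == p[2]]
    wr <- wilcoxon_rank_sum(x, y)
    data.frame(group1 = p[1], group2 = p[2],
               statistic = wr$statistic, p_raw = wr$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$group1, out$group2), , drop = FALSE]
  out$p_adjusted <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}
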