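#' Friedman rank test for repeated measures
#'
#' Nonparametric test of whether k repeated measurements (timepoints) differ
#' across n subjects, computed from mid-ranks within each subject:
#' `Q = 12 / (n k (k + 1)) * sum(Rj^2) - 3 n (k + 1)` with `Rj` the column
#' rank sums, referred to a chi-squared distribution with k - 1 degrees of
#' freedom.
#'
#' @param x numeric matrix, subjects in rows, timepoints in columns; or a
#'   long data frame with the columns named in `subject`, `timepoint`,
#'   `value`.
#' @param subject,timepoint,value column names used when `x` is a data
#'   frame.
#' @return tibble: `statistic`, `df`, `p.value`, `n`, `k`.
#' @examples
#' m <- rbind(c(1.1, 2.3, 3.0), c(0.9, 2.1, 3.3))
#' friedman_test(m)  # both rows rank 1,2,3: Q = 4
#' @export
friedman_test <- function(x, subject = "eye_id", timepoint = "timepoint",
                          value = "value") {
  if (is.data.frame(x)) {
    x <- long_to_wide(x, subject, timepoint, value)
  }
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells; restrict to complete cases first")
  n <- nrow(x); k <- ncol(x)
  if (k < 3) stop("need at least 3 timepoints")
  if (n < 2) stop("need at least 2 subjects")
  R <- t(apply(x, 1, rank))  # mid-ranks on ties
  Rj <- colSums(R)
  Q <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  tibble::tibble(statistic = Q, df = k - 1,
                 p.value = pchisq(Q, k - 1, lower.tail = FALSE),
                 n = n, k = k)
}

long_to_wide <- function(df, subject, timepoint, value) {
  stopifnot(all(c(subject, timepoint, value) %in% names(df)))
  tp <- df[[timepoint]]
  lev <- if (is.factor(tp)) levels(tp) else unique(tp)
  sub <- unique(df[[subject]])
  m <- matrix(NA_real_, length(sub), length(lev),
              dimnames = list(sub, lev))
  m[cbind(match(df[[subject]], sub), match(tp, lev))] <- df[[value]]
  m
}

#' Baseline-contrast paired tests with Bonferroni adjustment
#'
#' Compares every follow-up timepoint against baseline with a paired test on
#' the subjects observed at both visits (complete-case per contrast, which
#' accommodates dropout), then applies the Bonferroni correction
#' `p_adj = min(1, m p)` over the m contrasts. Contrasts whose paired
#' differences have zero variance are assigned p = 1 and flagged degenerate.
#'
#' @param table long data frame with subject, timepoint and value columns.
#' @param baseline label of the reference timepoint.
#' @param method `"wilcoxon"` (signed rank, normal approximation) or `"t"`
#'   (paired Student t).
#' @param subject,timepoint,value column names in `table`.
#' @return tibble per contrast: `timepoint`, `n`, `statistic`, `p_raw`,
#'   `p_adj`, `degenerate`.
#' @export
paired_tests_bonferroni <- function(table, baseline = "baseline",
                                    method = c("wilcoxon", "t"),
                                    subject = "eye_id",
                                    timepoint = "timepoint",
                                    value = "value") {
  method <- match.arg(method)
  w <- long_to_wide(table, subject, timepoint, value)
  if (!baseline %in% colnames(w)) stop("baseline label not found")
  follow <- setdiff(colnames(w), baseline)
  m <- length(follow)
  rows <- lapply(follow, function(tp) {
    keep <- complete.cases(w[, c(baseline, tp)])
    a <- w[keep, baseline]; b <- w[keep, tp]
    n <- sum(keep)
    if (n < 2) stop("fewer than 2 paired observations for ", tp)
    dif <- b - a
    if (all(dif == 0) || sd(dif) == 0) {
      return(tibble::tibble(timepoint = tp, n = n, statistic = NA_real_,
                            p_raw = 1, degenerate = TRUE))
    }
    ht <- if (method == "t") t.test(b, a, paired = TRUE)
          else suppressWarnings(wilcox.test(b, a, paired = TRUE,
                                            exact = FALSE, correct = TRUE))
    tibble::tibble(timepoint = tp, n = n,
                   statistic = unname(ht$statistic),
                   p_raw = ht$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p_raw)
  out
}

#' Pearson correlation with r-squared
#'
#' Product-moment correlation between paired change rates, reporting r, r^2
#' and the two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))`.
#' Zero variance in either variable leaves the coefficient undefined
#' (`NA`, flagged).
#'
#' @param x,y numeric vectors of equal length (n >= 3), e.g. thickness and
#'   entropy change rates per eye/sector.
#' @return tibble: `r`, `r_squared`, `p.value`, `n`, `degenerate`.
#' @export
pearson_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) {
    return(tibble::tibble(r = NA_real_, r_squared = NA_real_,
                          p.value = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), n - 2)
  }
  tibble::tibble(r = r, r_squared = r^2, p.value = p, n = n,
                 degenerate = FALSE)
}

#' Relative change from baseline
#'
#' `(followup - baseline) / baseline`; the scale used for both edema
#' reduction and entropy change rates.
#'
#' @param baseline,followup numeric vectors (baseline must be positive).
#' @return numeric vector of change rates.
#' @examples
#' change_rate(400, 320)  # -0.2
#' @export
change_rate <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be positive")
  (followup - baseline) / baseline
}

#' Two-group comparison
#'
#' Cross-sectional comparisons: Student's t-test (equal variances),
#' Mann-Whitney (Wilcoxon rank sum with normal approximation and tie
#' correction), or chi-squared on a 2x2 contingency table without
#' continuity correction.
#'
#' @param a,b numeric vectors (for `"chi_square"`, two length-2 count
#'   vectors forming the 2x2 table rows).
#' @param kind `"t"`, `"mann_whitney"` or `"chi_square"`.
#' @return tibble: `statistic`, `p.value`, `kind`.
#' @export
group_compare <- function(a, b, kind = c("t", "mann_whitney", "chi_square")) {
  kind <- match.arg(kind)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  ht <- switch(kind,
    t = t.test(a, b, var.equal = TRUE),
    mann_whitney = suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)),
    chi_square = {
      stopifnot(length(a) == 2, length(b) == 2)
      suppressWarnings(chisq.test(rbind(a, b), correct = FALSE))
    })
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 kind = kind)
}

#' Longitudinal statistics over a cohort sector table
#'
#' For every (layer, sector/scope) combination in a combined multi-eye
#' sector table, runs the Friedman rank test over the complete-case
#' subjects-by-timepoints block and the Bonferroni-adjusted baseline
#' contrasts ([paired_tests_bonferroni()]).
#'
#' @param table long data frame with columns `eye_id`, `timepoint`, `layer`,
#'   `sector`, and a value column named `mean` (as produced by binding
#'   [run_pipeline()] sector tables across eyes).
#' @param baseline baseline timepoint label.
#' @param method paired-test method, `"wilcoxon"` or `"t"`.
#' @param scopes sectors/scopes to analyze; default all present.
#' @return list of two tibbles: `friedman` (layer, sector, statistic, df,
#'   p.value, n, k) and `contrasts` (layer, sector, timepoint, n, statistic,
#'   p_raw, p_adj, degenerate).
#' @export
longitudinal_stats <- function(table, baseline = "baseline",
                               method = c("wilcoxon", "t"), scopes = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("eye_id", "timepoint", "layer", "sector", "mean") %in%
                  names(table)))
  if (is.null(scopes)) scopes <- unique(table$sector)
  fr <- list(); ct <- list()
  for (l in unique(table$layer)) {
    for (sc in scopes) {
      sub <- table[table$layer == l & table$sector == sc, ]
      if (nrow(sub) == 0 || length(unique(sub$eye_id)) < 2) next
      w <- long_to_wide(sub, "eye_id", "timepoint", "mean")
      cc <- w[complete.cases(w), , drop = FALSE]
      key <- paste(l, sc, sep = ".")
      if (nrow(cc) >= 2 && ncol(cc) >= 3) {
        f <- friedman_test(cc)
        f$layer <- l; f$sector <- sc
        fr[[key]] <- f
      }
      cnt <- paired_tests_bonferroni(sub, baseline = baseline,
                                     method = method, value = "mean")
      cnt$layer <- l; cnt$sector <- sc
      ct[[key]] <- cnt
    }
  }
  list(friedman = do.call(rbind, unname(fr)),
       contrasts = do.call(rbind, unname(ct)))
}
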