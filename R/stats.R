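# Statistical layer: bimodality decision (Gaussian versus sum of two
# Gaussians on histogram counts), nonparametric group comparisons, and the
# individual-versus-collective chirality correlation.

gauss1 <- function(x, A, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2))

#' Bimodality decision by Gaussian versus sum-of-two-Gaussians fit
#'
#' The sample is histogrammed (bin width `bin_deg`, 0 at a bin edge) and both
#' a single Gaussian and a sum of two Gaussians are least-squares fitted to
#' the bin counts (unweighted).  The nested models are compared by the
#' extra-sum-of-squares F test,
#' `F = ((SS1 - SS2) / (df1 - df2)) / (SS2 / df2)`, preferring the double
#' model when `p < alpha`.  The distribution is called bimodal when the
#' double model is preferred and its ordered component means straddle zero
#' (one negative, one positive): the signature of a population split between
#' mirror-image chiral states.
#'
#' @param values Angle sample in degrees (>= 50 values recommended; smaller
#'   samples are fitted with a message).
#' @param bin_deg Histogram bin width (degrees).
#' @param alpha Significance level of the F test.
#' @return A `BimodalFit`: list with `histogram`, `single` (A, mu, sigma,
#'   ss, df), `double` (A1, mu1, sigma1, A2, mu2, sigma2, ss, df),
#'   `F`, `p_value`, `preferred`, `bimodal`, `converged`.
#' @export
fit_bimodal <- function(values, bin_deg = 5, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 50)
    message("fit_bimodal: only ", length(values),
            " values; the fit may be unstable below 50")
  hg <- hist_zero_anchored(values, bin_deg)
  x <- hg$mids; y <- hg$counts
  if (length(x) < 7)
    stop("histogram has too few bins for the nested-model comparison")
  # single-Gaussian fit, moment-based start
  mu0 <- mean(values); s0 <- max(stats::sd(values), bin_deg / 2)
  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ gauss1(x, A, mu, sigma),
                      start = list(A = max(y), mu = mu0, sigma = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit1)) stop("single-Gaussian fit failed to converge")
  c1 <- stats::coef(fit1)
  ss1 <- sum(stats::resid(fit1)^2)
  df1 <- length(y) - 3
  # double-Gaussian starts: deterministic k-means split, plus the single fit
  # embedded (guarantees SS2 <= SS1 up to optimiser tolerance)
  km <- stats::kmeans(values, centers = sort(stats::quantile(values, c(.25, .75))))
  ord <- order(km$centers)
  m1 <- km$centers[ord[1]]; m2 <- km$centers[ord[2]]
  sd1 <- max(c(stats::sd(values[km$cluster == ord[1]]), bin_deg / 2), na.rm = TRUE)
  sd2 <- max(c(stats::sd(values[km$cluster == ord[2]]), bin_deg / 2), na.rm = TRUE)
  starts <- list(
    list(A1 = max(y) * 0.7, mu1 = m1, s1 = sd1,
         A2 = max(y) * 0.7, mu2 = m2, s2 = sd2),
    list(A1 = unname(c1["A"]), mu1 = unname(c1["mu"]), s1 = unname(c1["sigma"]),
         A2 = unname(c1["A"]) * 0.05, mu2 = unname(c1["mu"]) + s0,
         s2 = unname(c1["sigma"])))
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ gauss1(x, A1, mu1, s1) + gauss1(x, A2, mu2, s2),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || sum(stats::resid(f)^2) <
                          sum(stats::resid(best)^2)))
      best <- f
  }
  converged <- !is.null(best)
  if (converged) {
    c2 <- stats::coef(best)
    if (c2["mu1"] > c2["mu2"])  # ordering convention mu1 < mu2
      c2 <- c(A1 = unname(c2["A2"]), mu1 = unname(c2["mu2"]), s1 = unname(c2["s2"]),
              A2 = unname(c2["A1"]), mu2 = unname(c2["mu1"]), s2 = unname(c2["s1"]))
    ss2 <- sum(stats::resid(best)^2)
  } else {
    c2 <- c(A1 = NA, mu1 = NA, s1 = NA, A2 = NA, mu2 = NA, s2 = NA)
    ss2 <- NA_real_
  }
  df2 <- length(y) - 6
  if (converged && ss2 <= ss1 && df2 > 0) {
    Fstat <- max(((ss1 - ss2) / (df1 - df2)) / (ss2 / df2), 0)
    p <- stats::pf(Fstat, df1 - df2, df2, lower.tail = FALSE)
  } else {
    Fstat <- 0; p <- 1
  }
  preferred <- if (converged && p < alpha) "double" else "single"
  bimodal <- preferred == "double" &&
    is.finite(c2["mu1"]) && is.finite(c2["mu2"]) &&
    c2[["mu1"]] < 0 && c2[["mu2"]] > 0
  structure(list(
    histogram = hg,
    single = list(A = c1[["A"]], mu = c1[["mu"]], sigma = abs(c1[["sigma"]]),
                  ss = ss1, df = df1),
    double = list(A1 = c2[["A1"]], mu1 = c2[["mu1"]], sigma1 = abs(c2[["s1"]]),
                  A2 = c2[["A2"]], mu2 = c2[["mu2"]], sigma2 = abs(c2[["s2"]]),
                  ss = ss2, df = df2),
    F = Fstat, p_value = p, preferred = preferred, bimodal = bimodal,
    converged = converged), class = "BimodalFit")
}

#' Nonparametric group comparisons
#'
#' The three tests of the analysis: two-tailed Mann-Whitney U between two
#' groups, Kruskal-Wallis across several groups with Dunn's post-hoc test
#' (multiplicity-adjusted p values), and the one-sample Wilcoxon signed-rank
#' test against zero.  Inputs must be per-cell or per-culture summary values,
#' never per-segment measurements pooled across cells.
#'
#' @param a Numeric vector: first group (or the only sample for
#'   `"wilcoxon-zero"`).
#' @param b Numeric vector: second group (for `"mann-whitney"`).
#' @param groups Named list of numeric vectors (for `"kruskal-dunn"`).
#' @param kind `"mann-whitney"`, `"kruskal-dunn"` or `"wilcoxon-zero"`.
#' @return For the two-sample and one-sample kinds, the `htest` object; for
#'   `"kruskal-dunn"`, a list with `kruskal` (htest) and `dunn` (data frame
#'   of pairwise z, p, p_adjusted).
#' @export
compare_groups <- function(a = NULL, b = NULL, groups = NULL,
                           kind = c("mann-whitney", "kruskal-dunn", "wilcoxon-zero")) {
  kind <- match.arg(kind)
  if (kind == "mann-whitney") {
    if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
    return(stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                              correct = TRUE))
  }
  if (kind == "wilcoxon-zero") {
    if (length(a) < 3) stop("sample needs n >= 3")
    return(stats::wilcox.test(a, mu = 0, alternative = "two.sided",
                              exact = FALSE, correct = TRUE))
  }
  if (is.null(groups) || length(groups) < 2)
    stop("kruskal-dunn needs a list of >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("each group needs n >= 3")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups), vapply(groups, length, integer(1))),
               levels = names(groups))
  kw <- stats::kruskal.test(values, gf)
  list(kruskal = kw, dunn = dunn_posthoc(values, gf))
}

# Dunn's post-hoc test: pairwise z statistics on mean ranks with tie
# correction; Bonferroni multiplicity adjustment.
dunn_posthoc <- function(values, groups) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  mean_rank <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[g1]] + 1 / n[[g2]]))
    out$z[i] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    out$p[i] <- 2 * stats::pnorm(-abs(out$z[i]))
  }
  out$p_adjusted <- pmin(out$p * m, 1)
  out
}

#' Individual-versus-collective chirality correlation
#'
#' Pearson and Spearman correlations between the per-condition mean
#' radial-fibre tilt and the per-condition mean nematic director angle.
#' Conditions lacking either readout are excluded with a message.
#'
#' @param table Data frame with columns `rf_tilt_mean` and `director_mean`
#'   (one row per condition); extra columns are ignored.
#' @return List with `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`,
#'   `n`.
#' @export
chirality_correlation <- function(table) {
  stopifnot(all(c("rf_tilt_mean", "director_mean") %in% names(table)))
  ok <- is.finite(table$rf_tilt_mean) & is.finite(table$director_mean)
  if (any(!ok))
    message(sum(!ok), " condition(s) excluded for missing readouts")
  x <- table$rf_tilt_mean[ok]; y <- table$director_mean[ok]
  if (length(x) < 3) stop("need at least 3 conditions with both readouts")
  pe <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}
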