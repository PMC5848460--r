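#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, implemented directly from the formulas
#' (the suite cross-checks it against [stats::t.test()]). Significance is
#' reported at the study's alpha = 1%.
#'
#' @param a,b Numeric samples, each of length >= 2; at least one must have
#'   positive variance.
#' @param labels Length-2 character vector of group labels.
#' @param alpha Significance level (default 0.01).
#' @return Object of class `group_comparison`: list with `labels`, `n`,
#'   `means`, `sds`, `t_statistic`, `df`, `p_value`, `significant`.
#' @export
welch_t_test <- function(a, b, labels = c("a", "b"), alpha = 0.01) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(
    list(labels = labels, n = c(na, nb), means = c(mean(a), mean(b)),
         sds = c(sqrt(va), sqrt(vb)), t_statistic = t, df = df,
         p_value = p, significant = p < alpha, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Welch t-test %s vs %s: t = %.4f, df = %.2f, p = %.4g (%ssignificant at alpha = %g)\n",
    x$labels[1], x$labels[2], x$t_statistic, x$df, x$p_value,
    if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Direct-formula sample correlation (the suite cross-checks it against
#' [stats::cor()]).
#'
#' @param x,y Equal-length numeric samples (n >= 3) with positive variance.
#' @param label Subset description, e.g. `"1+ and 2+ pooled"`.
#' @return Object of class `correlation_result`: list with `n`, `pearson_r`,
#'   `label`.
#' @export
pearson_r <- function(x, y, label = "") {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length samples with n >= 3")
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("constant input: correlation undefined")
  structure(list(n = length(x), pearson_r = sum(dx * dy) / (sx * sy),
                 label = label),
            class = "correlation_result")
}

#' Per-category summary, histogram bins and pairwise tests
#'
#' The cohort-level summary: per-score mean +/- SD of width and intensity
#' over cells and over specimens, histogram counts of per-cell widths
#' (default 0.1 um bins), and all pairwise Welch comparisons of per-specimen
#' mean widths between categories.
#'
#' @param cells Per-cell table with `score_preset` (or `score`),
#'   `mean_width_um`, `mean_intensity_pct`.
#' @param specimens Per-specimen table with the same score column plus
#'   `mean_width_um`, `mean_intensity_pct`.
#' @param bin_width Histogram bin width in um.
#' @param alpha Significance level for the pairwise tests.
#' @return List with `summary` (per-score data.frame), `cell_hist`
#'   (data.frame `bin_left_um`, `score`, `count`), and `pairwise`
#'   (data.frame of Welch comparisons on per-specimen mean widths).
#' @export
category_summary <- function(cells, specimens, bin_width = 0.1,
                             alpha = 0.01) {
  score_col <- function(d) {
    cn <- intersect(c("score_preset", "score", "assigned_score"), names(d))
    if (length(cn) == 0) stop("no score column in table")
    as.character(d[[cn[1]]])
  }
  cs <- score_col(cells); ss <- score_col(specimens)
  bad <- setdiff(unique(c(cs, ss)), score_levels())
  if (length(bad)) stop("unknown score label(s): ", paste(bad, collapse = ", "))
  cats <- intersect(score_levels(), unique(cs))
  summ <- do.call(rbind, lapply(cats, function(sc) {
    cw <- cells$mean_width_um[cs == sc]
    ci <- cells$mean_intensity_pct[cs == sc]
    sw <- specimens$mean_width_um[ss == sc]
    data.frame(
      score = sc, n_cells = sum(cs == sc), n_specimens = sum(ss == sc),
      cell_width_mean = mean(cw, na.rm = TRUE),
      cell_width_sd = if (sum(!is.na(cw)) > 1) stats::sd(cw, na.rm = TRUE)
                      else NA_real_,
      cell_intensity_mean = mean(ci, na.rm = TRUE),
      specimen_width_mean = mean(sw, na.rm = TRUE),
      specimen_width_sd = if (sum(!is.na(sw)) > 1) stats::sd(sw, na.rm = TRUE)
                          else NA_real_
    )
  }))
  breaks <- seq(0, max(cells$mean_width_um, na.rm = TRUE) + bin_width,
                by = bin_width)
  hist_df <- do.call(rbind, lapply(cats, function(sc) {
    h <- hist(cells$mean_width_um[cs == sc & !is.na(cells$mean_width_um)],
              breaks = breaks, plot = FALSE)
    data.frame(bin_left_um = h$breaks[-length(h$breaks)], score = sc,
               count = h$counts)
  }))
  pairs <- if (length(cats) >= 2) utils::combn(cats, 2, simplify = FALSE)
           else list()
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    wa <- specimens$mean_width_um[ss == pr[1]]
    wb <- specimens$mean_width_um[ss == pr[2]]
    if (sum(!is.na(wa)) < 2 || sum(!is.na(wb)) < 2) {
      return(data.frame(group_a = pr[1], group_b = pr[2],
                        t_statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, significant = NA))
    }
    ct <- welch_t_test(wa, wb, labels = pr, alpha = alpha)
    data.frame(group_a = pr[1], group_b = pr[2],
               t_statistic = ct$t_statistic, df = ct$df,
               p_value = ct$p_value, significant = ct$significant)
  }))
  list(summary = summ, cell_hist = hist_df, pairwise = pw)
}

#' ISH subgroup comparison within the 2+ category
#'
#' Welch comparisons of per-specimen mean width and mean intensity between
#' ISH-positive and ISH-negative equivocal (2+) specimens. On synthetic
#' cohorts both labels come from the same generative model, so this is a
#' negative control: neither parameter should separate the groups.
#'
#' @param specimens Per-specimen table with `ish_label`, `mean_width_um`,
#'   `mean_intensity_pct`; pre-filter it to the 2+ category.
#' @param alpha Significance level.
#' @return List with `width` and `intensity`, each a [welch_t_test()]
#'   `group_comparison`.
#' @export
ish_subgroup_comparison <- function(specimens, alpha = 0.01) {
  pos <- specimens$ish_label == "positive"
  neg <- specimens$ish_label == "negative"
  if (!any(pos) || !any(neg)) stop("both ISH labels must be present")
  list(
    width = welch_t_test(specimens$mean_width_um[pos],
                         specimens$mean_width_um[neg],
                         labels = c("ISH+", "ISH-"), alpha = alpha),
    intensity = welch_t_test(specimens$mean_intensity_pct[pos],
                             specimens$mean_intensity_pct[neg],
                             labels = c("ISH+", "ISH-"), alpha = alpha)
  )
}
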