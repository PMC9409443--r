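#' Per-site methylation frequency
#'
#' The methylation frequency at a site is the methylated-call read count
#' divided by the total coverage at that position. Sites with zero coverage
#' carry no information and must be excluded upstream; passing one is an
#' error rather than a silent NaN.
#'
#' @param k Methylated-call read count(s).
#' @param n Total coverage(s); must be > 0.
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
#' @examples
#' site_frequency(5, 10)
site_frequency <- function(k, n) {
  if (any(n <= 0)) {
    abort("site has no coverage (n = 0); filter such sites out first",
          class = "methexpr_no_coverage")
  }
  stopifnot(all(k >= 0), all(k <= n))
  k / n
}

#' Likelihood-ratio (Wilks) confidence interval for a binomial proportion
#'
#' The interval is the set of proportions p whose likelihood-ratio statistic
#' 2\[l(k/n) - l(p)\] stays below the chi-squared(1) critical value for the
#' requested level, where l is the binomial log-likelihood. Bounds are found
#' by bisection on each side of the MLE to 1e-8; at k = 0 the lower bound is
#' exactly 0 and at k = n the upper bound is exactly 1. Vectorised and
#' memoised over repeated (k, n) pairs.
#'
#' @param k Methylated counts (vector).
#' @param n Coverages (vector, >= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `lo` and `hi`.
#' @export
#' @examples
#' wilks_ci(5, 10)
wilks_ci <- function(k, n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1)",
          class = "methexpr_parameter_error")
  }
  stopifnot(length(k) == length(n), all(n >= 1), all(k >= 0), all(k <= n))
  crit <- qchisq(level, df = 1)
  key <- paste(k, n)
  uniq <- !duplicated(key)
  bounds <- vapply(which(uniq), function(i) wilks_ci_one(k[i], n[i], crit),
                   numeric(2))
  colnames(bounds) <- key[uniq]
  tibble(lo = unname(bounds[1, key]), hi = unname(bounds[2, key]))
}

wilks_ci_one <- function(k, n, crit) {
  fhat <- k / n
  ll <- function(p) {
    (if (k > 0) k * log(p) else 0) + (if (k < n) (n - k) * log1p(-p) else 0)
  }
  lhat <- ll(fhat)
  # 2*(lhat - ll(p)) - crit is negative at fhat and grows towards each edge
  g <- function(p) 2 * (lhat - ll(p)) - crit
  bisect <- function(lo, hi, increasing) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      pos <- g(mid) > 0
      if (pos == increasing) hi <- mid else lo <- mid
      if (hi - lo < 1e-8) break
    }
    (lo + hi) / 2
  }
  lo <- if (k == 0) 0 else bisect(0, fhat, increasing = FALSE)
  hi <- if (k == n) 1 else bisect(fhat, 1, increasing = TRUE)
  c(lo, hi)
}

#' Logistic transform of a methylation frequency
#'
#' Maps a frequency to v = ln((1 + f) / (1 - f)), a quasi-normalising,
#' strictly increasing transform with v(0) = 0. Because v diverges at
#' f = 1, frequencies (and CI margins) are clamped to
#' \[0, 1 - 1/(2 n)\] using the site's own coverage before evaluation, which
#' keeps the statistic finite and monotone in the methylated count.
#'
#' @param f Frequencies in \[0, 1\].
#' @param n Coverage(s) used for the clamp; `NULL` disables clamping (then
#'   f = 1 yields `Inf`).
#' @return Transformed values.
#' @export
#' @examples
#' meth_transform(0.5) # log(3)
meth_transform <- function(f, n = NULL) {
  stopifnot(all(f >= -1), all(f <= 1))
  if (!is.null(n)) f <- pmin(f, 1 - 1 / (2 * n))
  log((1 + f) / (1 - f))
}

#' Standard deviation of the transformed frequency via the CI/6 rule
#'
#' The standard deviation of v is taken as one sixth of the confidence
#' interval length after transforming its margins:
#' (v(hi) - v(lo)) / 6. It is 0 for a degenerate interval and never
#' negative, and it never decreases when the interval widens.
#'
#' @param lo,hi CI margins on the frequency scale, `lo <= hi`.
#' @param n Coverage(s) for the transform clamp (see [meth_transform()]).
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' transform_sd(0, 0.5) # log(3)/6
transform_sd <- function(lo, hi, n = NULL) {
  stopifnot(all(lo <= hi))
  (meth_transform(hi, n) - meth_transform(lo, n)) / 6
}

#' Two-sample regression-slope contrast at one site
#'
#' Fits Y = b0 + b1 * group by least squares with the design matrix
#' X = \[\[1, -1\], \[1, +1\]\] (intercept column and a -1/+1 group column,
#' control coded -1 and case +1). With exactly two observations the fit is
#' exact: b0 = (v_ctrl + v_as)/2 and b1 = (v_as - v_ctrl)/2, half the group
#' difference of the transformed frequencies. Assuming independence of the
#' two observations, SD(b1) = sqrt(sd_ctrl^2 + sd_as^2)/2, and the
#' significance of the slope is its z-score z = b1/SD(b1). A positive slope
#' means hyper-methylation in the case group, a negative slope
#' hypo-methylation. If SD(b1) = 0 and b1 = 0 then z = 0; if SD(b1) = 0 and
#' b1 != 0 the site is degenerate-infinite: z = +/-Inf, significant with
#' the sign of b1.
#'
#' @param v_ctrl,v_as Transformed frequencies of the control and case
#'   sample (vectors).
#' @param sd_ctrl,sd_as Their standard deviations.
#' @return Tibble with `b0`, `b1`, `sd_b1`, `z`, `direction` (hyper, hypo
#'   or NA_character_ when b1 = 0).
#' @export
#' @examples
#' pair_contrast(0, 0.2, log(3), 0.2)
pair_contrast <- function(v_ctrl, sd_ctrl, v_as, sd_as) {
  stopifnot(all(sd_ctrl >= 0), all(sd_as >= 0))
  b0 <- (v_ctrl + v_as) / 2
  b1 <- (v_as - v_ctrl) / 2
  sd_b1 <- sqrt(sd_ctrl^2 + sd_as^2) / 2
  z <- ifelse(sd_b1 > 0, b1 / sd_b1,
              ifelse(b1 == 0, 0, Inf * sign(b1)))
  tibble(b0 = b0, b1 = b1, sd_b1 = sd_b1, z = z,
         direction = case_when(b1 > 0 ~ "hyper", b1 < 0 ~ "hypo",
                               TRUE ~ NA_character_))
}

#' Per-site contrasts for both sample pairs
#'
#' The main per-site operation: filters sites to those with coverage of at
#' least `min_coverage` in all four samples, computes each sample's
#' frequency, Wilks confidence interval, transformed value and CI/6
#' standard deviation, and contrasts control against case within each
#' sex-matched pair via [pair_contrast()].
#'
#' @param pileups Long pileup tibble with columns `sample`, `pair`, `group`,
#'   `chrom`, `pos`, `strand`, `meth`, `cov` (see [simulate_methylation()]
#'   or [read_cytosine_report()]).
#' @param min_coverage Minimum per-sample coverage for a site to enter the
#'   analysis (applied across all samples jointly); default 5.
#' @param level Confidence level of the Wilks interval; default 0.95.
#' @return Tibble with one row per retained site and pair: `chrom`, `pos`,
#'   `strand`, `pair`, `f_ctrl`, `f_as`, `v_ctrl`, `v_as`, `b0`, `b1`,
#'   `sd_b1`, `z`, sorted by (pair, chrom, pos).
#' @export
site_contrasts <- function(pileups, min_coverage = 5, level = 0.95) {
  needed <- c("sample", "pair", "group", "chrom", "pos", "strand", "meth", "cov")
  stopifnot(all(needed %in% names(pileups)))
  n_samples <- dplyr::n_distinct(pileups$sample)

  kept <- pileups %>%
    group_by(.data$chrom, .data$pos) %>%
    filter(dplyr::n() == n_samples, all(.data$cov >= min_coverage)) %>%
    ungroup()
  if (nrow(kept) == 0) {
    return(tibble(chrom = character(), pos = numeric(), strand = character(),
                  pair = character(), f_ctrl = numeric(), f_as = numeric(),
                  v_ctrl = numeric(), v_as = numeric(), b0 = numeric(),
                  b1 = numeric(), sd_b1 = numeric(), z = numeric()))
  }

  ci <- wilks_ci(kept$meth, kept$cov, level = level)
  kept <- kept %>% mutate(
    f = site_frequency(.data$meth, .data$cov),
    v = meth_transform(.data$f, .data$cov),
    sd_v = transform_sd(ci$lo, ci$hi, .data$cov)
  )

  wide <- kept %>%
    select("pair", "group", "chrom", "pos", "strand", "f", "v", "sd_v") %>%
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("f", "v", "sd_v"))
  fit <- pair_contrast(wide$v_ctrl, wide$sd_v_ctrl, wide$v_as, wide$sd_v_as)
  wide %>%
    transmute_contrast(fit) %>%
    arrange(.data$pair, .data$chrom, .data$pos)
}

transmute_contrast <- function(wide, fit) {
  tibble(chrom = wide$chrom, pos = wide$pos, strand = wide$strand,
         pair = wide$pair, f_ctrl = wide$f_ctrl, f_as = wide$f_as,
         v_ctrl = wide$v_ctrl, v_as = wide$v_as,
         b0 = fit$b0, b1 = fit$b1, sd_b1 = fit$sd_b1, z = fit$z)
}

#' Plot per-site contrast z-scores along the genome
#'
#' @param contrasts Output of [site_contrasts()].
#' @param alpha Significance level whose z threshold is drawn as guides.
#' @return A ggplot object: z against position, faceted by chromosome and
#'   pair.
#' @export
plot_contrasts <- function(contrasts, alpha = 0.05) {
  zc <- qnorm(1 - alpha / 2)
  ggplot2::ggplot(contrasts, ggplot2::aes(x = .data$pos, y = .data$z)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(-zc, zc), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(ggplot2::vars(.data$pair), ggplot2::vars(.data$chrom),
                        scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "slope z-score")
}
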