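#' Spearman rank correlation
#'
#' Non-parametric, two-tailed Spearman test: the rank correlation with
#' midranks for ties and the two-sided p-value of the t approximation.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return A list of class `correlation_result`: `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE, alternative = "two.sided"))
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r %.4f, p %s, n = %d\n", x$r,
              format.pval(x$p, digits = 3), x$n))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U counts the pairs `(a_i, b_j)` with `a_i > b_j`, ties counting one
#' half.  The two-tailed p-value uses exact enumeration of all group
#' assignments (valid with ties) when both samples have fewer than 8
#' observations, and the tie-corrected normal approximation otherwise.
#'
#' @param a,b non-empty numeric samples.
#' @return A list of class `mann_whitney_result`: `U`, `p`, `n1`, `n2`,
#'   `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) < 8L) {
    mu <- n1 * n2 / 2
    rr <- rank(c(a, b))
    picks <- utils::combn(n1 + n2, n1)
    us <- apply(picks, 2L, function(ix) sum(rr[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                       correct = TRUE))
    p <- wt$p.value
    if (is.na(p)) p <- 1 # all observations identical
    method <- "normal approximation with tie correction"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, p %s (n = %d, %d; %s)\n", x$U,
              format.pval(x$p, digits = 3), x$n1, x$n2, x$method))
  invisible(x)
}

#' Fixed-width binned averaging
#'
#' Pools points into contiguous bins `[k*width, (k+1)*width)` of the
#' independent variable and averages x and y inside each bin.  Bins
#' containing a single data point are excluded from the series and logged.
#' The default width of 5.0e6 nm^3 matches the spine-volume binning used
#' throughout the downstream two-regime analysis.
#'
#' @param x non-negative independent variable (nm^3).
#' @param y dependent variable, same length.
#' @param width bin width (> 0).
#' @return An object of class `binned_series`: `width`, `bins` (data.frame
#'   `bin`, `x_lo`, `x_hi`, `x_mean`, `y_mean`, `n`), `excluded`
#'   (data.frame of dropped bins), `n_points`.
#' @export
bin_average <- function(x, y, width = 5.0e6) {
  if (!length(x)) stop("empty input")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (width <= 0) stop("bin width must be positive")
  if (any(x < 0)) stop("x must be non-negative")
  k <- floor(x / width)
  groups <- split(seq_along(x), k)
  rows <- lapply(groups, function(ix) {
    kk <- k[ix[1L]]
    data.frame(bin = kk, x_lo = kk * width, x_hi = (kk + 1) * width,
               x_mean = mean(x[ix]), y_mean = mean(y[ix]),
               n = length(ix))
  })
  all_bins <- do.call(rbind, rows)
  all_bins <- all_bins[order(all_bins$bin), , drop = FALSE]
  keep <- all_bins$n >= 2L
  excluded <- all_bins[!keep, c("bin", "x_lo", "x_hi", "n"), drop = FALSE]
  excluded$reason <- if (nrow(excluded)) "single_point" else character(0)
  rownames(all_bins) <- rownames(excluded) <- NULL
  structure(list(width = width, bins = all_bins[keep, , drop = FALSE],
                 excluded = excluded, n_points = length(x)),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf(
    "<binned_series> width %.3g: %d retained bins (%d points), %d excluded\n",
    x$width, nrow(x$bins), sum(x$bins$n), nrow(x$excluded)))
  invisible(x)
}

# slope/intercept/R2/p with guards for exactly constant y
ols_summary <- function(xb, yb, conf_level = 0.95) {
  fit <- lm(yb ~ xb)
  sm <- suppressWarnings(summary(fit)) # exact fits are handled below
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0
  cf <- coef(sm)
  sl <- unname(coef(fit)[2L])
  p_slope <- if (nrow(cf) >= 2L && is.finite(cf[2L, 4L])) cf[2L, 4L]
             else if (is.na(sl) || abs(sl) < 1e-12) 1 else 0
  band <- cbind(x = xb,
                suppressWarnings(predict(fit, interval = "confidence",
                                         level = conf_level)))
  list(fit = fit, slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]), r2 = r2, p_slope = p_slope,
       band = as.data.frame(band))
}

#' Two-regime threshold regression on a binned series
#'
#' Describes the piecewise behaviour in which the dependent variable grows
#' linearly with the binned independent variable up to a volume threshold
#' and stays roughly constant above it.  Candidate thresholds are the bin
#' boundaries leaving at least `min_bins` retained bins on each side; for
#' every candidate an ordinary least-squares line is fitted to the bins
#' below, and the threshold maximizing the goodness of fit (R^2) of that
#' lower-range regression is selected (ties resolve to the smallest
#' candidate).  The upper range is summarized by its own fit and mean.
#' 95\% confidence bands (t distribution) and slope-versus-zero p-values
#' are reported for both regimes.
#'
#' Candidates whose R^2 falls within `tie_tol` of the maximum are treated
#' as equivalent (R^2 differences below that resolution are sampling
#' noise, and a short lower range can win such a comparison by chance);
#' among equivalent candidates the largest threshold is selected, so the
#' linear regime extends as far as the fit quality supports.  If every
#' candidate is equivalent there is no detectable upper regime: the
#' smallest candidate is returned and the fit is flagged
#' `degenerate_linear`.
#'
#' @param series a [bin_average()] result with at least `2 * min_bins`
#'   retained bins.
#' @param min_bins minimal number of bins per regime.
#' @param conf_level confidence level of the lower-fit band.
#' @param tie_tol R^2 resolution below which candidates count as tied.
#' @return An object of class `two_regime_fit`: `threshold`, `lower` and
#'   `upper` fit summaries, `n_bins`, `n_lower`, `candidates`, `flags`.
#' @export
fit_two_regime <- function(series, min_bins = 3L, conf_level = 0.95,
                           tie_tol = 1e-3) {
  stopifnot(inherits(series, "binned_series"))
  bins <- series$bins
  n <- nrow(bins)
  if (n < 2L * min_bins)
    stop(sprintf("need at least %d retained bins, have %d", 2L * min_bins,
                 n))
  cand_i <- seq.int(min_bins + 1L, n - min_bins + 1L)
  cand <- data.frame(threshold = bins$bin[cand_i] * series$width,
                     r2 = NA_real_, n_lower = cand_i - 1L)
  for (j in seq_along(cand_i)) {
    lower <- bins[seq_len(cand_i[j] - 1L), ]
    cand$r2[j] <- ols_summary(lower$x_mean, lower$y_mean)$r2
  }
  qual <- cand$r2 >= max(cand$r2) - tie_tol
  best_j <- if (all(qual)) 1L else max(which(qual))
  thr <- cand$threshold[best_j]
  lower_bins <- bins[bins$x_hi <= thr, , drop = FALSE]
  upper_bins <- bins[bins$x_hi > thr, , drop = FALSE]
  lo <- ols_summary(lower_bins$x_mean, lower_bins$y_mean, conf_level)
  up <- ols_summary(upper_bins$x_mean, upper_bins$y_mean, conf_level)
  up$mean_y <- mean(upper_bins$y_mean)

  flags <- character(0)
  r2_all <- ols_summary(bins$x_mean, bins$y_mean)$r2
  if (r2_all >= max(cand$r2) - 1e-9) flags <- c(flags, "degenerate_linear")
  if (lo$p_slope >= 0.05) flags <- c(flags, "no_trend")

  structure(list(threshold = thr,
                 lower = lo[c("slope", "intercept", "r2", "p_slope",
                              "band")],
                 upper = up[c("slope", "intercept", "r2", "p_slope",
                              "mean_y")],
                 n_bins = n, n_lower = nrow(lower_bins),
                 candidates = cand, flags = flags,
                 width = series$width),
            class = "two_regime_fit")
}

#' @export
print.two_regime_fit <- function(x, ...) {
  cat(sprintf(
    "<two_regime_fit> threshold %.4g (n' = %d of %d bins)\n", x$threshold,
    x$n_lower, x$n_bins))
  cat(sprintf("  lower: slope %.4g, R2 %.4f, slope-vs-0 p %s\n",
              x$lower$slope, x$lower$r2,
              format.pval(x$lower$p_slope, digits = 3)))
  cat(sprintf("  upper: slope %.4g, mean %.4g, slope-vs-0 p %s\n",
              x$upper$slope, x$upper$mean_y,
              format.pval(x$upper$p_slope, digits = 3)))
  if (length(x$flags)) cat("  flags:", toString(x$flags), "\n")
  invisible(x)
}

#' Compare two cohorts variable by variable
#'
#' Mean, SEM and n per cohort plus the Mann-Whitney U and two-tailed p for
#' each requested variable, with significance stars at 0.05 / 0.01 /
#' 0.001.  No multiple-testing correction is applied.
#'
#' @param a,b data.frames holding the two cohorts.
#' @param variables column names to compare.
#' @return A data.frame with one row per variable.
#' @export
cohort_compare <- function(a, b, variables) {
  if (!nrow(a) || !nrow(b)) stop("both cohorts must be non-empty")
  missing <- setdiff(variables, intersect(names(a), names(b)))
  if (length(missing))
    stop("unknown variable(s): ", toString(missing))
  rows <- lapply(variables, function(v) {
    va <- a[[v]]; vb <- b[[v]]
    mw <- mann_whitney(va, vb)
    data.frame(variable = v,
               mean_a = mean(va), sem_a = sd(va) / sqrt(length(va)),
               n_a = length(va),
               mean_b = mean(vb), sem_b = sd(vb) / sqrt(length(vb)),
               n_b = length(vb),
               U = mw$U, p = mw$p, signif = sig_stars(mw$p))
  })
  do.call(rbind, rows)
}
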