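#' Linear fit tested against a flat line
#'
#' Ordinary least squares `y = a + b x`, evaluated against the null model of
#' a flat (constant-y) line with an F-test: `F = (SS_flat - SS_fit) /
#' (SS_fit / (n - 2))` with (1, n-2) degrees of freedom. This is the
#' standard test of whether a signal (e.g. QDF per mass) depends on a shape
#' proxy (mass per area) at all. Pearson's correlation is reported
#' alongside; for simple linear regression `r_squared = pearson_r^2`.
#'
#' @param data A data frame; `x` and `y` are evaluated inside it
#'   (tidyverse-style), or pass vectors directly via `x`, `y` with
#'   `data = NULL`.
#' @param x,y Column names (unquoted) or numeric vectors.
#' @return A `qdf_fit` object: list with `slope`, `intercept`, `r_squared`,
#'   `pearson_r`, `f_statistic`, `p_value`, `n`, and the underlying `lm`
#'   fit. Has [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' fit_vs_flat(d, x, y)
#' @export
fit_vs_flat <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  } else {
    xv <- x; yv <- y
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("need at least 3 points for the F-test", call. = FALSE)
  if (stats::var(xv) == 0) stop("x is constant; slope undefined",
                                call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  ss_fit <- sum(stats::residuals(fit)^2)
  ss_flat <- sum((yv - mean(yv))^2)
  if (ss_flat == 0) {
    # y constant: the flat line is already a perfect fit
    return(structure(list(slope = 0, intercept = mean(yv), r_squared = 0,
                          pearson_r = 0, f_statistic = 0, p_value = 1,
                          n = n, fit = fit), class = "qdf_fit"))
  }
  if (ss_fit == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_flat - ss_fit) / (ss_fit / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  r <- if (stats::var(yv) == 0) 0 else stats::cor(xv, yv)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_flat == 0) 0 else 1 - ss_fit / ss_flat,
    pearson_r = r,
    f_statistic = f,
    p_value = p,
    n = n,
    fit = fit
  ), class = "qdf_fit")
}

#' @export
print.qdf_fit <- function(x, ...) {
  cat(sprintf("<qdf_fit> y = %.4g + %.4g x  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R = %.3g, R^2 = %.3g, F = %.4g, p = %.3g (vs flat line)\n",
              x$pearson_r, x$r_squared, x$f_statistic, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for a `qdf_fit`
#'
#' `tidy()` returns the coefficient table; `glance()` the one-row model
#' summary with the flat-line F-test.
#'
#' @param x A `qdf_fit` from [fit_vs_flat()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy qdf_fit
tidy.qdf_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.qdf_fit
#' @export
#' @method glance qdf_fit
glance.qdf_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, pearson.r = x$pearson_r,
    statistic = x$f_statistic, p.value = x$p_value, nobs = x$n
  )
}

#' Binned means and standard deviations
#'
#' Partitions `x` into half-open bins `[k w, (k+1) w)` of width `w` and
#' summarizes `y` within each; empty bins are omitted. This is the binned
#' overlay used on signal-vs-shape scatter plots (bins of 0.1 pg/um^2 in the
#' standard display). The standard deviation of a single-point bin is 0.
#'
#' @param data A data frame, or `NULL` to pass vectors.
#' @param x,y Column names (unquoted) or numeric vectors.
#' @param bin_width Bin width, > 0.
#' @return Tibble with `bin_left`, `bin_mid`, `n`, `mean`, `sd`.
#' @export
binned_fit <- function(data, x, y, bin_width = 0.1) {
  stopifnot(bin_width > 0)
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  } else {
    xv <- x; yv <- y
  }
  ok <- is.finite(xv) & is.finite(yv)
  tibble::tibble(bin = floor(xv[ok] / bin_width), y = yv[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$y),
      sd = if (dplyr::n() > 1) stats::sd(.data$y) else 0,
      .groups = "drop"
    ) |>
    dplyr::transmute(bin_left = .data$bin * bin_width,
                     bin_mid = (.data$bin + 0.5) * bin_width,
                     n = .data$n, mean = .data$mean, sd = .data$sd) |>
    dplyr::arrange(.data$bin_left)
}

#' Kullback-Leibler divergence between two sample sets
#'
#' Histograms both sample sets on shared bin edges spanning the pooled
#' 1st-99th percentile range (values beyond the range are clamped into the
#' end bins), normalizes to frequencies, mixes in a small uniform weight
#' (`smooth`) so empty bins in Q never produce infinities, and computes
#' `D_KL(P || Q) = sum p_i log(p_i / q_i)`. Smoothing acts on frequencies,
#' not raw counts, so two sample sets with identical binned distributions
#' give exactly zero divergence regardless of their sizes. D_KL is
#' asymmetric and always >= 0; larger means more separated distributions.
#' Reported in bits (base 2) by default.
#'
#' @param p_samples,q_samples Numeric sample vectors (nonempty).
#' @param n_bins Number of shared histogram bins (default 32).
#' @param base Logarithm base: 2 for bits (default), `exp(1)` for nats.
#' @param smooth Uniform mixture weight in \[0, 1) (default 1e-3; 0
#'   disables smoothing).
#' @return A `kl_divergence` object: list with `dkl`, `base`, `unit`,
#'   `bin_edges`, `p_probs`, `q_probs`, `n_p`, `n_q`.
#' @examples
#' set.seed(1)
#' kl_divergence(rnorm(500), rnorm(500, 2))$dkl
#' @export
kl_divergence <- function(p_samples, q_samples, n_bins = 32, base = 2,
                          smooth = 1e-3) {
  stopifnot(length(p_samples) > 0, length(q_samples) > 0, n_bins >= 2,
            smooth >= 0, smooth < 1)
  pooled <- c(p_samples, q_samples)
  rng <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(xs) {
    pmin(pmax(findInterval(xs, edges, rightmost.closed = TRUE), 1L), n_bins)
  }
  p <- tabulate(bin_of(p_samples), n_bins) / length(p_samples)
  q <- tabulate(bin_of(q_samples), n_bins) / length(q_samples)
  p <- (1 - smooth) * p + smooth / n_bins
  q <- (1 - smooth) * q + smooth / n_bins
  pos <- p > 0
  dkl <- sum(p[pos] * log(p[pos] / q[pos])) / log(base)
  structure(list(dkl = dkl, base = base,
                 unit = if (base == 2) "bits" else "nats",
                 bin_edges = edges, p_probs = p, q_probs = q,
                 n_p = length(p_samples), n_q = length(q_samples)),
            class = "kl_divergence")
}

#' @export
print.kl_divergence <- function(x, ...) {
  cat(sprintf("D_KL(P||Q) = %.4g %s over %d bins (n = %d, %d)\n",
              x$dkl, x$unit, length(x$p_probs), x$n_p, x$n_q))
  invisible(x)
}

#' KL divergence from explicit probabilities
#'
#' @param p,q Probability vectors over the same bins (each sums to 1).
#' @param base Logarithm base.
#' @return The divergence (number).
#' @export
kl_from_probs <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q),
            abs(sum(p) - 1) < 1e-9, abs(sum(q) - 1) < 1e-9)
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos])) / log(base)
}

#' Two-sample t-test
#'
#' Pooled-variance two-sample t-test (the classical default), with the
#' Welch variant by flag. Degenerate inputs are resolved explicitly rather
#' than erroring: zero pooled variance with equal means gives `t = 0,
#' p = 1`; zero pooled variance with unequal means gives `p = 0` with a
#' warning.
#'
#' @param a_samples,b_samples Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) statistic?
#' @return Tibble with `t`, `p`, `df`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
two_sample_t <- function(a_samples, b_samples, welch = FALSE) {
  stopifnot(length(a_samples) >= 2, length(b_samples) >= 2)
  va <- stats::var(a_samples); vb <- stats::var(b_samples)
  out <- tibble::tibble(
    t = NA_real_, p = NA_real_, df = NA_real_,
    mean_a = mean(a_samples), mean_b = mean(b_samples),
    n_a = length(a_samples), n_b = length(b_samples)
  )
  if (va == 0 && vb == 0) {
    if (out$mean_a == out$mean_b) {
      out$t <- 0; out$p <- 1
    } else {
      warning("zero variance in both samples with unequal means; p = 0",
              call. = FALSE)
      out$t <- Inf; out$p <- 0
    }
    out$df <- out$n_a + out$n_b - 2
    return(out)
  }
  tt <- stats::t.test(a_samples, b_samples, var.equal = !welch)
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}
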