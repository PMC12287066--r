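#' Area under an onset-aligned trace over a time window
#'
#' Trapezoidal integral of a Z-score trace over a closed window of
#' relative time, in z·s. Window endpoints falling between samples are
#' handled by linear interpolation of the trace at the exact endpoints,
#' so the integral is grid-resolution robust, exact for piecewise-linear
#' traces, and additive over adjacent windows.
#'
#' @param z Trace values on `rel_time`.
#' @param rel_time Relative time grid (seconds, 0 at event onset).
#' @param window Numeric `c(t0, t1)` inside the span of `rel_time`.
#' @return Area in z·s.
#' @export
#' @examples
#' rel <- seq(-1, 1, by = 0.01)
#' auc(rep(1, length(rel)), rel, c(0, 0.3)) # 0.3
auc <- function(z, rel_time, window) {
  if (length(window) != 2L || window[1] >= window[2]) {
    abort_parameter("window must be c(t0, t1) with t0 < t1")
  }
  if (window[1] < min(rel_time) || window[2] > max(rel_time)) {
    abort_parameter(sprintf(
      "window [%g, %g] outside the trace span [%g, %g]",
      window[1], window[2], min(rel_time), max(rel_time)
    ))
  }
  inner <- rel_time > window[1] & rel_time < window[2]
  t_pts <- c(window[1], rel_time[inner], window[2])
  z_pts <- approx(rel_time, z, xout = t_pts, ties = "ordered")$y
  pracma::trapz(t_pts, z_pts)
}

#' Before/during AUC windows
#'
#' The two analysis windows around event onset: `before` defaults to
#' \eqn{[-0.6, -0.3]} s and `during` to \eqn{[0, +0.3]} s. The 300 ms
#' window length corresponds to the duration of one sniff.
#'
#' @param before,during Numeric `c(t0, t1)` windows relative to onset;
#'   `before` must end at or before 0 and `during` start at or after 0.
#' @return An `auc_windows` list.
#' @export
auc_windows <- function(before = c(-0.6, -0.3), during = c(0, 0.3)) {
  if (!(before[1] < before[2] && before[2] <= 0 &&
        0 <= during[1] && during[1] < during[2])) {
    abort_parameter("windows must satisfy t_a < t_b <= 0 <= t_c < t_d")
  }
  structure(list(before = before, during = during), class = "auc_windows")
}

#' Per-unit before/during AUC table
#'
#' Computes the AUC in the `before` and `during` windows for each analysis
#' unit, on the same trace. Units are either the event rows of a single
#' ensemble (`x` a `ph_ensemble`) or the per-animal mean traces of a list
#' of ensembles (one per animal). Units whose trace does not cover both
#' windows are excluded and counted in the `n_excluded` attribute.
#'
#' @param x A `ph_ensemble` (unit = event) or a list of ensembles
#'   (unit = animal, each contributing its mean trace).
#' @param windows An [auc_windows()].
#' @return Tibble with columns `unit`, `auc_before`, `auc_during`.
#' @export
before_during <- function(x, windows = auc_windows()) {
  if (inherits(x, "ph_ensemble")) {
    traces <- lapply(seq_len(nrow(x$matrix)), function(i) {
      list(unit = paste0(x$event_ids$session[i], ":", x$event_ids$index[i]),
           rel_time = x$rel_time, z = x$matrix[i, ])
    })
  } else {
    traces <- lapply(seq_along(x), function(i) {
      list(unit = as.character(x[[i]]$event_ids$session[1] %||% i),
           rel_time = x[[i]]$rel_time, z = x[[i]]$mean)
    })
  }
  rows <- list()
  excluded <- 0L
  for (tr in traces) {
    covers <- min(tr$rel_time) <= windows$before[1] &&
      max(tr$rel_time) >= windows$during[2]
    if (!covers) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      unit = tr$unit,
      auc_before = auc(tr$z, tr$rel_time, windows$before),
      auc_during = auc(tr$z, tr$rel_time, windows$during)
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(unit = character(), auc_before = numeric(), auc_during = numeric())
  }
  attr(out, "n_excluded") <- excluded
  out
}

#' Normality-gated paired comparison
#'
#' Compares paired values (e.g. before vs during AUC per animal) with the
#' test chosen by a Shapiro-Wilk gate on the paired differences: a paired
#' t-test when normality is not rejected (`normality_p >= alpha_normality`),
#' a paired Wilcoxon signed-rank test otherwise. Sidedness is always
#' caller-specified; `alternative = "greater"` tests during > before.
#'
#' Degenerate differences are flagged rather than erroring: all-zero
#' differences give p = 1; constant non-zero differences have zero
#' variance, so the t statistic is infinite and p is 0 in the direction of
#' the shift (1 against it).
#'
#' @param pairs Tibble with `auc_before` and `auc_during` columns (or any
#'   two paired columns named via `before_col`/`during_col`).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (for
#'   during - before).
#' @param alpha_normality Gate level for the Shapiro-Wilk test.
#' @param before_col,during_col Column names of the paired values.
#' @return A `ph_paired` object; see [glance()] for the one-row summary.
#' @export
paired_test <- function(pairs, alternative = c("two.sided", "greater", "less"),
                        alpha_normality = 0.05,
                        before_col = "auc_before", during_col = "auc_during") {
  alternative <- match.arg(alternative)
  before <- pairs[[before_col]]
  during <- pairs[[during_col]]
  n <- length(before)
  if (n < 3L) abort_parameter("paired test needs at least 3 pairs")
  d <- during - before

  degenerate <- NULL
  if (all(d == 0)) {
    res <- list(normality_p = NA_real_, test_used = "degenerate",
                statistic = 0, p_value = 1)
    degenerate <- "all_zero"
    warn("all paired differences are zero; p reported as 1")
  } else if (sd(d) == 0) {
    stat <- sign(d[1]) * Inf
    p <- switch(alternative,
      two.sided = 0,
      greater = if (d[1] > 0) 0 else 1,
      less = if (d[1] < 0) 0 else 1
    )
    res <- list(normality_p = NA_real_, test_used = "paired t",
                statistic = stat, p_value = p)
    degenerate <- "constant_shift"
  } else {
    normality_p <- shapiro.test(d)$p.value
    if (normality_p >= alpha_normality) {
      ht <- t.test(during, before, paired = TRUE, alternative = alternative)
      res <- list(normality_p = normality_p, test_used = "paired t",
                  statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      ht <- suppressWarnings(
        wilcox.test(during, before, paired = TRUE, alternative = alternative)
      )
      res <- list(normality_p = normality_p, test_used = "paired Wilcoxon",
                  statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  }
  structure(
    c(res, list(
      alternative = alternative, alpha_normality = alpha_normality,
      n = n, degenerate = degenerate, pairs = pairs
    )),
    class = "ph_paired"
  )
}

#' @export
print.ph_paired <- function(x, ...) {
  cat(sprintf(
    "<ph_paired> %s (%s), n = %d: statistic = %.4g, p = %.4g (normality p = %.3g)%s\n",
    x$test_used, x$alternative, x$n, x$statistic, x$p_value, x$normality_p,
    if (!is.null(x$degenerate)) paste0(" [", x$degenerate, "]") else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ph_paired <- function(x, ...) {
  tibble::as_tibble(x$pairs)
}

#' @exportS3Method generics::glance
glance.ph_paired <- function(x, ...) {
  tibble(
    test_used = x$test_used,
    alternative = x$alternative,
    statistic = x$statistic,
    p_value = x$p_value,
    normality_p = x$normality_p,
    n = x$n,
    degenerate = x$degenerate %||% NA_character_
  )
}
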