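#' Partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' control variables from both (OLS residuals on an intercept plus the
#' controls).  With a single control this equals the first-order recursive
#' formula `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`; with no
#' controls it is the plain Pearson correlation.  The two-sided p-value uses
#' `t = r sqrt((n - 2 - k) / (1 - r^2))` with `k` controls.  Incomplete rows
#' are dropped listwise.
#'
#' @param data a data frame.
#' @param x,y names of the two variables.
#' @param controls character vector of control variable names (possibly
#'   empty).
#' @return A one-row tibble: `x`, `y`, `r`, `p`, `n`, `df`, `controls`,
#'   `band` (`"significant"` if p < 0.05, `"marginal"` if 0.05 <= p < 0.10,
#'   else `"ns"`).
#' @examples
#' d <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
#' partial_correlation(d, "a", "b", "c")
#' @export
partial_correlation <- function(data, x, y, controls = character()) {
  stopifnot(all(c(x, y, controls) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(x, y, controls), drop = FALSE]),
            c(x, y, controls), drop = FALSE]
  n <- nrow(d)
  k <- length(controls)
  if (n <= k + 3L) stop("need n > number of controls + 3 complete cases", call. = FALSE)
  if (k == 0L) {
    r <- stats::cor(d[[x]], d[[y]])
  } else {
    C <- as.matrix(d[, controls, drop = FALSE])
    rx <- residualize(matrix(d[[x]], ncol = 1L), C)
    ry <- residualize(matrix(d[[y]], ncol = 1L), C)
    tol <- 1e-10
    if (stats::sd(rx) <= tol * max(stats::sd(d[[x]]), 1) ||
        stats::sd(ry) <= tol * max(stats::sd(d[[y]]), 1)) {
      stop("zero residual variance after controlling; partial correlation undefined",
           call. = FALSE)
    }
    r <- stats::cor(as.numeric(rx), as.numeric(ry))
  }
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(x = x, y = y, r = r, p = p, n = n, df = df,
                 controls = paste(controls, collapse = ","),
                 band = significance_band(p))
}

significance_band <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.10, "marginal", "ns"))
}

#' First-order partial correlation from marginal correlations
#'
#' The closed-form route used as the analytic cross-check of the
#' residualization route.
#'
#' @param r_xy,r_xz,r_yz marginal Pearson correlations.
#' @return The partial correlation of x and y given z.
#' @examples
#' partial_correlation_formula(-0.46, -0.31, 0.10)  # -0.4535
#' @export
partial_correlation_formula <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Significance-based mediation test
#'
#' The decision rule: if an initially significant correlation
#' (p < 0.05, after controlling the covariates of no interest) between `x`
#' and `y` is no longer significant after additionally controlling the
#' candidate mediator, the association is declared mediated; if it stays
#' significant it is independent of the mediator; if it was never
#' significant the verdict is `no_initial_association`.  No effect
#' decomposition is performed (the rule is purely significance-based).
#'
#' @param data a data frame.
#' @param x,y variable names.
#' @param mediator name of the candidate mediator.
#' @param covariates character vector of covariates of no interest.
#' @param alpha significance level of the rule (default 0.05).
#' @return A one-row tibble: `x`, `y`, `mediator`, `r_before`, `p_before`,
#'   `r_after`, `p_after`, `verdict`.
#' @export
mediation_test <- function(data, x, y, mediator, covariates = character(),
                           alpha = 0.05) {
  med <- data[[mediator]]
  if (stats::sd(med, na.rm = TRUE) == 0) {
    stop("mediator '", mediator, "' is constant", call. = FALSE)
  }
  before <- partial_correlation(data, x, y, covariates)
  after <- partial_correlation(data, x, y, c(covariates, mediator))
  verdict <- if (before$p >= alpha) "no_initial_association"
             else if (after$p >= alpha) "mediated" else "independent"
  tibble::tibble(x = x, y = y, mediator = mediator,
                 r_before = before$r, p_before = before$p,
                 r_after = after$r, p_after = after$p, verdict = verdict)
}

#' Steiger's z-test for two dependent overlapping correlations
#'
#' Compares `cor(x, y1)` with `cor(x, y2)` measured on the same `n` subjects
#' (the correlations share the variable `x` and are therefore dependent).
#' Both correlations are Fisher z-transformed; their covariance uses the
#' Dunn-Clark term evaluated at the mean correlation (Steiger's
#' modification), giving an asymptotically standard normal
#' `Z = (z1 - z2) sqrt((n - 3) / (2 - 2 s))` with `s` the null covariance
#' of the transformed correlations.  Two-sided p-value.
#'
#' @param r_xy1 correlation of x with y1.
#' @param r_xy2 correlation of x with y2.
#' @param r_y1y2 correlation between y1 and y2 (the overlap).
#' @param n sample size (> 3).
#' @return A one-row tibble: `z`, `p`, `n`.
#' @examples
#' steiger_z(-0.46, -0.31, 0.3, 75)
#' @export
steiger_z <- function(r_xy1, r_xy2, r_y1y2, n) {
  rs <- c(r_xy1, r_xy2, r_y1y2)
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  z1 <- atanh(r_xy1)
  z2 <- atanh(r_xy2)
  rbar <- (r_xy1 + r_xy2) / 2
  # Dunn-Clark covariance of the Fisher-transformed correlations at rbar
  s <- (r_y1y2 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_y1y2^2)) /
    (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)), n = as.integer(n))
}

#' Shared variance of a correlation
#'
#' @param r Pearson correlation.
#' @param percent return a percentage (default TRUE).
#' @param digits rounding (default 0 for the percent form).
#' @return `r^2`, optionally as a rounded percentage (0.56 -> 31).
#' @export
shared_variance <- function(r, percent = TRUE, digits = 0) {
  v <- r^2
  if (percent) round(100 * v, digits) else v
}

#' Family of cross-modal partial correlations
#'
#' Runs [partial_correlation()] for every requested pair under a common
#' control set and returns the stacked tibble.  P-values are uncorrected by
#' default; the flag applies a Holm correction across the family.
#'
#' @param data a data frame.
#' @param pairs two-column character matrix or data frame of variable pairs.
#' @param controls character vector of shared control variables.
#' @param holm apply Holm correction across the family (default FALSE).
#' @return A tibble, one row per pair.
#' @export
crossmodal_correlations <- function(data, pairs, controls = character(),
                                    holm = FALSE) {
  pairs <- as.matrix(pairs)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i)
    partial_correlation(data, pairs[i, 1L], pairs[i, 2L], controls)))
  if (holm) {
    out$p_holm <- stats::p.adjust(out$p, method = "holm")
    out$band <- significance_band(out$p_holm)
  }
  out
}
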