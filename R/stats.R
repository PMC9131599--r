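#' Shapiro-Wilk normality screen
#'
#' Validated wrapper around [stats::shapiro.test()] used to screen COI samples
#' before the repeated-measures ANOVA.
#'
#' @param x Numeric sample, `3 <= n <= 5000`, not all values identical.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got n = ", n, ")")
  }
  if (stats::sd(x) == 0) stop("constant sample: W is undefined")
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p_value = res$p.value)
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' For a complete balanced participants x conditions table, the within-subject
#' sum-of-squares decomposition is
#' `SS_total = SS_subjects + SS_conditions + SS_error`, with
#' `F = (SS_cond / df_cond) / (SS_err / df_err)`, `df_cond = k - 1`,
#' `df_err = (n - 1)(k - 1)`. The effect size is partial eta squared,
#' `SS_cond / (SS_cond + SS_err)`. The sphericity-assumed p-value is primary;
#' the Greenhouse-Geisser epsilon and corrected p-value are always reported
#' alongside.
#'
#' @param table Numeric matrix or data frame, rows = participants, columns =
#'   conditions; no missing cells.
#' @return Object of class `rm_anova`: `f_value`, `df_effect`, `df_error`,
#'   `p_value`, `partial_eta_sq`, `gg_epsilon`, `p_value_gg`, and the SS
#'   components (`ss_conditions`, `ss_subjects`, `ss_error`, `ss_total`).
#' @examples
#' rm_anova(rbind(c(1, 2), c(2, 3), c(3, 5)))
#' @export
rm_anova <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("table must be numeric")
  if (anyNA(m)) stop("missing cells: repeated-measures ANOVA needs a complete table")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 participants and 2 conditions")
  grand <- mean(m)
  subj_means <- rowMeans(m)
  cond_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df_cond <- k - 1
  df_err <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df_cond
  ms_err <- ss_err / df_err
  f <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- stats::pf(f, df_cond, df_err, lower.tail = FALSE)
  eps <- gg_epsilon(m)
  p_gg <- stats::pf(f, eps * df_cond, eps * df_err, lower.tail = FALSE)
  structure(
    list(f_value = f, df_effect = df_cond, df_error = df_err, p_value = p,
         partial_eta_sq = if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0,
         gg_epsilon = eps, p_value_gg = p_gg,
         ss_conditions = ss_cond, ss_subjects = ss_subj, ss_error = ss_err,
         ss_total = ss_total, n = n, k = k),
    class = "rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the double-centered condition covariance
gg_epsilon <- function(m) {
  k <- ncol(m)
  S <- stats::cov(m)
  rowm <- rowMeans(S)
  D <- S - outer(rowm, rep(1, k)) - outer(rep(1, k), rowm) + mean(S)
  tr <- sum(diag(D))
  denom <- (k - 1) * sum(D^2)
  if (denom <= 0) return(1)
  min(1, max(1 / (k - 1), tr^2 / denom))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4f\n",
              x$df_effect, x$df_error, x$f_value, x$p_value))
  cat(sprintf("partial eta^2 = %.3f; GG epsilon = %.3f (corrected p = %.4f)\n",
              x$partial_eta_sq, x$gg_epsilon, x$p_value_gg))
  invisible(x)
}
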