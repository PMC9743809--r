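#' Shapiro--Wilk normality gate
#'
#' Runs the Shapiro--Wilk test and records the analysis-path decision: when
#' `p < alpha` the data are treated as non-normal and downstream comparisons
#' take the nonparametric (rank) path. Constant input is flagged as
#' degenerate instead of erroring deep in the pipeline.
#'
#' @param x Numeric vector, 3 <= n <= 5000.
#' @param alpha Gate level (default 0.05).
#' @return Object of class `normality_gate`: list with `statistic`, `p`,
#'   `n`, `nonparametric` (logical) and `degenerate` flag.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop_cogload("unsupported-size", "Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (length(unique(x)) == 1L) {
    return(structure(list(statistic = NA_real_, p = NA_real_, n = n,
                          nonparametric = NA, degenerate = TRUE),
                     class = "normality_gate"))
  }
  sw <- stats::shapiro.test(x)
  structure(list(statistic = unname(sw$statistic), p = sw$p.value, n = n,
                 nonparametric = sw$p.value < alpha, degenerate = FALSE),
            class = "normality_gate")
}

#' @export
print.normality_gate <- function(x, ...) {
  if (x$degenerate) {
    cat("Shapiro-Wilk gate: degenerate input (all values identical)\n")
  } else {
    cat(sprintf("Shapiro-Wilk: W = %.4f, p = %.3g (n = %d) -> %s path\n",
                x$statistic, x$p, x$n,
                if (x$nonparametric) "nonparametric" else "parametric"))
  }
  invisible(x)
}

# Exact two-sided rank-sum p-value (no ties): W is the rank sum of the first
# sample; U = W - n1(n1+1)/2 follows the Mann-Whitney null distribution.
ranksum_exact_p <- function(W, n1, n2) {
  U <- W - n1 * (n1 + 1) / 2
  lo <- stats::pwilcox(U, n1, n2)
  hi <- 1 - stats::pwilcox(U - 1, n1, n2)
  min(1, 2 * min(lo, hi))
}

#' Mann--Whitney--Wilcoxon rank-sum comparison
#'
#' Two-sided two-sample rank test using the table convention
#' `W = sum of the pooled-sample ranks of the first sample` (so
#' `W >= n1(n1+1)/2` always). Ties receive midranks. The p-value is exact
#' (null enumeration) when `n1 + n2 <= 16` and the pooled sample is
#' tie-free; otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used. Group descriptives (mean, SD, median)
#' are carried in the result, mirroring the reporting schema.
#'
#' @param x,y Numeric vectors (first and second sample).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path; default
#'   `NULL` decides by size and ties as above.
#' @param continuity Apply the 0.5 continuity correction on the normal path.
#' @return Object of class `rank_test` with elements `method`, `n1`, `n2`,
#'   `mean1`, `sd1`, `median1`, `mean2`, `sd2`, `median2`, `W`, `U`, `p`,
#'   `exact`, and significance flags `sig_05`, `sig_01`, `sig_001`.
#' @export
mann_whitney <- function(x, y, exact = NULL, continuity = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop_cogload("invalid-input", "both samples must be nonempty")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_cogload("invalid-input", "samples must contain finite values only")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- if (is.null(exact)) (N <= 16L && !ties) else (exact && !ties)
  if (use_exact) {
    p <- ranksum_exact_p(W, n1, n2)
  } else {
    tt <- table(r)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- W - n1 * (N + 1) / 2
      cc <- if (continuity) sign(d) * 0.5 else 0
      z <- (d - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(
    list(method = "mann_whitney", n1 = n1, n2 = n2,
         mean1 = mean(x), sd1 = stats::sd(x), median1 = stats::median(x),
         mean2 = mean(y), sd2 = stats::sd(y), median2 = stats::median(y),
         W = W, U = W - n1 * (n1 + 1) / 2, p = p, exact = use_exact,
         sig_05 = p < 0.05, sig_01 = p < 0.01, sig_001 = p < 0.001),
    class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney-Wilcoxon (%s p): W = %g, p = %.4g%s\n",
              if (x$exact) "exact" else "normal approx.", x$W, x$p,
              if (x$sig_001) " ***" else if (x$sig_01) " **"
              else if (x$sig_05) " *" else ""))
  print(data.frame(group = c(1, 2), N = c(x$n1, x$n2),
                   Mean = c(x$mean1, x$mean2), SD = c(x$sd1, x$sd2),
                   Median = c(x$median1, x$median2)))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); n <= 8 in practice.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation
#'
#' Spearman's rho: the Pearson correlation of midranks. The two-sided
#' p-value is by exact permutation enumeration for `n <= 8` and by the
#' t-approximation with `n - 2` degrees of freedom otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @param exact Force/forbid the permutation path; default decides by n.
#' @return Object of class `correlation_result`: list with `rho`, `p`, `n`,
#'   `exact`.
#' @export
spearman_cor <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_cogload("invalid-input", "x and y must have equal length")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_cogload("invalid-input", "need n >= 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_cogload("undefined-correlation",
                 "correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 8L else exact
  if (use_exact) {
    perms <- permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  structure(list(rho = rho, p = p, n = n, exact = use_exact),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n,
              if (x$exact) "exact permutation" else "t approximation"))
  invisible(x)
}

#' Condition-comparison table in the Measure/N/Mean/SD/Median/W/p schema
#'
#' Assembles, for each measure, a two-row block (one row per condition) of
#' descriptives plus the Mann--Whitney--Wilcoxon W and two-sided p-value
#' comparing the two conditions. Per-measure Ns may differ because upstream
#' exclusions propagate. No multiple-testing adjustment is applied by
#' default; Holm and Benjamini--Hochberg adjusted p columns are available.
#'
#' Observations pooled across participants are treated as independent by
#' the rank test; the output carries a metadata note flagging that pooling.
#'
#' @param data Long data frame with columns `measure`, `condition` (two
#'   levels; the lower sorted level is "sample 1"), `value`.
#' @param measures Measures to tabulate (default: all present, in order of
#'   appearance).
#' @param adjust `"none"`, `"holm"` or `"BH"`.
#' @return Data frame of class `comparison_table` with columns `Measure`,
#'   `N_back`, `N`, `Mean`, `SD`, `Median`, `W`, `p_value` (+ `p_adj`), and
#'   `signif` flags. Attributes: `adjust`, `note`.
#' @export
comparison_table <- function(data, measures = NULL,
                             adjust = c("none", "holm", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("measure", "condition", "value") %in% names(data)))
  measures <- measures %||% unique(data$measure)
  levs <- sort(unique(as.character(data$condition)))
  if (length(levs) != 2L) {
    stop_cogload("invalid-input", "condition must have exactly two levels")
  }
  rows <- list(); ps <- rep(NA_real_, length(measures))
  for (j in seq_along(measures)) {
    mm <- measures[j]
    d <- data[data$measure == mm & is.finite(data$value), ]
    x <- d$value[d$condition == levs[1]]
    y <- d$value[d$condition == levs[2]]
    if (length(x) == 0L || length(y) == 0L) {
      rows[[j]] <- data.frame(
        Measure = mm, N_back = levs, N = c(length(x), length(y)),
        Mean = NA_real_, SD = NA_real_, Median = NA_real_,
        W = NA_real_, p_value = NA_real_, signif = "")
      next
    }
    rt <- mann_whitney(x, y)
    ps[j] <- rt$p
    flag <- if (rt$sig_001) "***" else if (rt$sig_01) "**" else
      if (rt$sig_05) "*" else ""
    rows[[j]] <- data.frame(
      Measure = mm, N_back = levs, N = c(rt$n1, rt$n2),
      Mean = c(rt$mean1, rt$mean2), SD = c(rt$sd1, rt$sd2),
      Median = c(rt$median1, rt$median2),
      W = c(rt$W, NA_real_), p_value = c(rt$p, NA_real_),
      signif = c(flag, ""))
  }
  out <- do.call(rbind, rows)
  if (adjust != "none") {
    padj <- stats::p.adjust(ps, method = adjust)
    out$p_adj <- NA_real_
    out$p_adj[!is.na(out$p_value)] <- padj[!is.na(ps)]
  }
  rownames(out) <- NULL
  attr(out, "adjust") <- adjust
  attr(out, "note") <- paste(
    "W = sum of pooled ranks of sample 1 (condition", levs[1], ").",
    "Trial-level observations pooled across participants are treated as",
    "independent by the rank test.")
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, digits = 4, ...) {
  d <- as.data.frame(x)
  for (cl in c("Mean", "SD", "Median", "p_value", "p_adj")) {
    if (cl %in% names(d)) d[[cl]] <- signif(d[[cl]], digits)
  }
  print.data.frame(d, row.names = FALSE, na.print = "")
  cat("Signif.: *** p<0.001, ** p<0.01, * p<0.05",
      if (attr(x, "adjust") != "none")
        sprintf("(adjusted: %s)", attr(x, "adjust")) else "", "\n")
  invisible(x)
}
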