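#' Normality test with size-dependent method choice
#'
#' Shapiro-Wilk for samples smaller than 5000, otherwise a
#' Kolmogorov-Smirnov test against a normal with sample-estimated mean and
#' SD (a Lilliefors-style use: the estimated parameters make the nominal KS
#' p-value conservative, which is accepted and documented). A sample of
#' exactly 5000 goes to the KS branch. The sample is called normal when
#' p >= 0.05. A constant sample is flagged degenerate and not normal.
#'
#' @param values numeric vector, length >= 3.
#' @return list: `test` (`"shapiro_wilk"` or `"kolmogorov_smirnov"`),
#'   `p_value`, `normal`, `degenerate`, `n`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 finite values", call. = FALSE)
  if (sd(values) == 0)
    return(list(test = if (n < 5000) "shapiro_wilk" else "kolmogorov_smirnov",
                p_value = 0, normal = FALSE, degenerate = TRUE, n = n))
  if (n < 5000) {
    p <- shapiro.test(values)$p.value
    test <- "shapiro_wilk"
  } else {
    p <- suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))$p.value)
    test <- "kolmogorov_smirnov"
  }
  list(test = test, p_value = p, normal = p >= 0.05, degenerate = FALSE,
       n = n)
}

#' Correlation with normality-gated method selection
#'
#' Pearson when both variables pass the normality test, Spearman otherwise
#' (the standard pairing: product-moment correlation for Gaussian data, rank
#' correlation for non-Gaussian). Two-sided test of the null of no
#' correlation; significant when p < 0.05. Zero variance in either variable
#' yields a not-computable report.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list of class `correlation_report`: `method`, `rho`, `p_value`,
#'   `n`, `significant`, `computable`.
#' @export
correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(method = NA_character_, rho = NA_real_,
                          p_value = NA_real_, n = n, significant = FALSE,
                          computable = FALSE),
                     class = "correlation_report"))
  nx <- normality_test(x); ny <- normality_test(y)
  method <- if (nx$normal && ny$normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, rho = unname(ct$estimate),
                 p_value = ct$p.value, n = n,
                 significant = ct$p.value < 0.05, computable = TRUE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  if (!x$computable) {
    cat("correlation not computable (degenerate variable), n =", x$n, "\n")
  } else {
    cat(sprintf("%s correlation: rho = %.4f, p = %.4g, n = %d%s\n",
                x$method, x$rho, x$p_value, x$n,
                if (x$significant) " (significant at 0.05)" else ""))
  }
  invisible(x)
}

#' Normality-gated descriptive summary
#'
#' Mean and standard deviation for samples that pass the normality test,
#' median and interquartile range otherwise. Quartiles use linear
#' interpolation (R's default type-7 rule). Samples too small to test
#' (n < 3) take the non-normal path.
#'
#' @param values numeric vector.
#' @param normal optional logical overriding the normality decision.
#' @return list: `normal`, `center`, `spread`, `center_type`
#'   (`"mean"`/`"median"`), `spread_type` (`"sd"`/`"iqr"`), `n`.
#' @export
describe_values <- function(values, normal = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 1)
  if (is.null(normal))
    normal <- if (n >= 3) normality_test(values)$normal else FALSE
  if (n == 1)
    return(list(normal = normal, center = values, spread = 0,
                center_type = if (normal) "mean" else "median",
                spread_type = if (normal) "sd" else "iqr", n = 1L))
  if (normal) {
    list(normal = TRUE, center = mean(values), spread = sd(values),
         center_type = "mean", spread_type = "sd", n = n)
  } else {
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    list(normal = FALSE, center = q[2], spread = q[3] - q[1],
         center_type = "median", spread_type = "iqr", n = n)
  }
}
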