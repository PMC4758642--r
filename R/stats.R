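#' Mean and standard error of the mean
#'
#' @param values numeric vector with at least 2 finite values
#' @return named vector c(mean, sem); sem uses the n-1 sample sd
#' @examples
#' meanSem(c(1, 2, 3))   # mean 2, sem 1/sqrt(3)
#' @export
meanSem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("insufficient data: need at least 2 values")
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

#' Chi-square test of association for a 2x2 table
#'
#' Uncorrected chi-square statistic
#' \code{n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with its p value from the
#' chi-square distribution with 1 degree of freedom, the test used for
#' comparing mobile-particle proportions between genotypes.
#'
#' @param table 2x2 matrix of non-negative counts
#' @return list with \code{chi2}, \code{p}, \code{df = 1}
#' @examples
#' chiSquare2x2(matrix(c(30, 10, 10, 30), 2))$chi2   # 20
#' @export
chiSquare2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("'table' must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  n <- sum(table)
  if (n == 0) stop("degenerate table: no observations")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("degenerate table: a marginal total is zero")
  chi2 <- n * (a * d - b * c)^2 / prod(marg)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Two-sample t test
#'
#' Student (pooled-variance) or Welch two-sided t test. The pooled form is
#' the default, matching the "Student's t test" used for the transport
#' comparisons. Degenerate zero-variance inputs are resolved explicitly:
#' equal means give t = 0, unequal means an infinite statistic with p = 0.
#'
#' @param a,b numeric vectors, each with at least 2 values
#' @param welch use the Welch unequal-variance form (default FALSE)
#' @return list with \code{t}, \code{df}, \code{p}
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient data: each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Fits a one-way ANOVA across the groups and follows it with pooled-variance
#' pairwise t tests whose p values are Bonferroni-adjusted (multiplied by the
#' number of comparisons, capped at 1). With \code{reference} set, only
#' comparisons against that group are made — a conservative alternative to
#' Dunnett's many-to-one procedure.
#'
#' @param groups named list of numeric vectors, each with at least 2 values
#' @param reference optional name of the reference group
#' @return list with \code{F}, \code{df}, \code{p} and \code{pairwise}, a
#'   data.frame (groupA, groupB, t, pRaw, pAdjusted)
#' @examples
#' g <- list(wt = c(20, 22, 19, 21), mut = c(14, 15, 13, 16))
#' anovaBonferroni(g)$F
#' @export
anovaBonferroni <- function(groups, reference = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("insufficient data: every group needs at least 2 values")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  Fval <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  dfs <- an[["Df"]]

  pairs <- if (is.null(reference)) utils::combn(names(groups), 2)
           else rbind(reference,
                      setdiff(names(groups), reference))
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    tt <- twoSampleT(groups[[pairs[1, i]]], groups[[pairs[2, i]]])
    data.frame(groupA = pairs[1, i], groupB = pairs[2, i],
               t = tt$t, pRaw = tt$p)
  })
  pw <- do.call(rbind, rows)
  pw$pAdjusted <- pmin(pw$pRaw * m, 1)
  list(F = Fval, df = dfs, p = pval, pairwise = pw)
}
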