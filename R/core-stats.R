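#' Ordinary least-squares fit of expression on a biomarker
#'
#' Fits the simple linear model `y = w0 + w1 * x + e` by exact least squares
#' and records the quantities the Chow test consumes: the coefficient vector,
#' the residual sum of squares `S`, and the sample count `N`.
#'
#' @param x Numeric predictor vector (imaging biomarker values).
#' @param y Numeric response vector (expression values), same length as `x`.
#' @return An object of class `regression_fit`: a list with elements
#'   `coefficients` (intercept, slope), `rss`, `n_samples` and `n_params`.
#' @examples
#' fit <- ols_fit(c(0, 1, 2), c(1, 3, 5))
#' coef(fit)   # exact line: intercept 1, slope 2
#' fit$rss     # 0
#' @export
ols_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_fedchow("x and y must have equal length", "fedchow_invalid")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- 2L
  if (n < k + 1L)
    stop_fedchow(sprintf("need at least %d complete observations, got %d", k + 1L, n),
                 "fedchow_unfittable")
  if (stats::sd(x) == 0)
    stop_fedchow("predictor is constant; slope is not identifiable",
                 "fedchow_unfittable")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x = x), y)
  regression_fit(coefficients = unname(fit$coefficients),
                 rss = sum(fit$residuals^2),
                 n_samples = n)
}

#' Construct a regression_fit object
#'
#' Low-level constructor used by both the centralized and federated solvers.
#'
#' @param coefficients Numeric vector, intercept first.
#' @param rss Residual sum of squares (>= 0).
#' @param n_samples Number of observations the fit used.
#' @param converged Logical; `FALSE` flags a federated solve that hit the
#'   iteration cap before the gradient-norm tolerance.
#' @param grad_norm Final global mean-loss gradient norm (federated solves).
#' @param n_iter Iterations used (federated solves).
#' @return A `regression_fit` object.
#' @export
regression_fit <- function(coefficients, rss, n_samples,
                           converged = TRUE, grad_norm = NA_real_,
                           n_iter = NA_integer_) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            is.numeric(rss), rss >= -1e-8, n_samples >= 0)
  structure(list(coefficients = as.numeric(coefficients),
                 rss = max(0, as.numeric(rss)),
                 n_samples = as.integer(n_samples),
                 n_params = length(coefficients),
                 converged = isTRUE(converged),
                 grad_norm = grad_norm,
                 n_iter = n_iter),
            class = "regression_fit")
}

#' @export
coef.regression_fit <- function(object, ...) {
  stats::setNames(object$coefficients,
                  c("(Intercept)", paste0("x", seq_len(object$n_params - 1L))))
}

#' @exportS3Method base::print
print.regression_fit <- function(x, ...) {
  cat("Linear fit (", x$n_samples, " obs): intercept = ",
      format(x$coefficients[1], digits = 6), ", slope = ",
      format(x$coefficients[2], digits = 6), ", RSS = ",
      format(x$rss, digits = 6), "\n", sep = "")
  if (!x$converged)
    cat("  [solver did not converge; gradient norm ",
        format(x$grad_norm, digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Generalized Chow structural-break test
#'
#' Tests whether the regression coefficients differ across G subgroups
#' (2 <= G <= 3) by comparing the pooled residual sum of squares `S_C`
#' with the per-group sums `S_g`:
#' \deqn{F = \frac{(S_C - \sum_g S_g) / ((G-1) k)}{\sum_g S_g / (\sum_g N_g - G k)}}
#' which under the null of equal coefficients follows an F distribution with
#' `(G-1)k` and `sum(N_g) - G k` degrees of freedom. For G = 3 and k = 2
#' the degrees of freedom are 2k = 4 and `N1 + N2 + N3 - 3k`. A numerator
#' made negative by floating-point (or federated-solver) residue is clamped
#' to zero, giving F = 0 and p = 1.
#'
#' @param group_fits List of [regression_fit] objects, one per subgroup.
#' @param combined_fit [regression_fit] for the pooled samples of those
#'   subgroups.
#' @return An object of class `chow_result` with elements `f_value`, `df_num`,
#'   `df_den`, `p_value`, `group_fits`, `combined_fit`, `n_groups`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); g <- rep(1:3, each = 10)
#' y <- x + rnorm(30, sd = 0.5)
#' fits <- lapply(split(seq_along(x), g), function(i) ols_fit(x[i], y[i]))
#' chow_test(fits, ols_fit(x, y))
#' @export
chow_test <- function(group_fits, combined_fit) {
  G <- length(group_fits)
  if (G < 2L)
    stop_fedchow("Chow test needs at least 2 subgroups", "fedchow_degenerate")
  if (G > 3L)
    stop_fedchow("at most 3 subgroups are supported", "fedchow_invalid")
  k <- combined_fit$n_params
  if (!all(vapply(group_fits, function(f) f$n_params, 0L) == k))
    stop_fedchow("all fits must share the same number of parameters k",
                 "fedchow_invalid")
  S_g <- sum(vapply(group_fits, function(f) f$rss, 0))
  N <- sum(vapply(group_fits, function(f) f$n_samples, 0L))
  if (N != combined_fit$n_samples)
    stop_fedchow("group sample counts do not sum to the combined fit's count",
                 "fedchow_invalid")
  df_num <- (G - 1L) * k
  df_den <- N - G * k
  if (df_den <= 0L)
    stop_fedchow("too few samples for the Chow test (df_den <= 0)",
                 "fedchow_insufficient")
  num <- (combined_fit$rss - S_g) / df_num
  den <- S_g / df_den
  f_value <- if (den <= 0) {
    # all groups fit exactly: any pooled excess is an infinite break signal
    if (num <= 0) 0 else Inf
  } else max(0, num / den)
  p_value <- stats::pf(f_value, df_num, df_den, lower.tail = FALSE)
  structure(list(f_value = f_value, df_num = df_num, df_den = df_den,
                 p_value = p_value, group_fits = group_fits,
                 combined_fit = combined_fit, n_groups = G),
            class = "chow_result")
}

#' @exportS3Method base::print
print.chow_result <- function(x, ...) {
  cat("Generalized Chow test (", x$n_groups, " subgroups)\n", sep = "")
  if (is.na(x$f_value)) {
    cat("  not testable:", attr(x, "reason") %||% "insufficient data", "\n")
    return(invisible(x))
  }
  ns <- vapply(x$group_fits, function(f) f$n_samples, 0L)
  cat("  group sizes: ", paste(ns, collapse = ", "),
      "  (pooled N = ", x$combined_fit$n_samples, ")\n", sep = "")
  cat("  F = ", format(x$f_value, digits = 6),
      " on (", x$df_num, ", ", x$df_den, ") df,  p = ",
      format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.chow_result <- function(object, ...) {
  print(object)
  if (!is.na(object$f_value)) {
    for (i in seq_along(object$group_fits)) {
      cat("  group ", i, ": ", sep = "")
      print(object$group_fits[[i]])
    }
    cat("  pooled : ")
    print(object$combined_fit)
  }
  invisible(object)
}

#' Hypergeometric enrichment of a gene selection against a reference list
#'
#' Probability model: draw `draw_size` genes without replacement from a
#' universe of `universe_size` genes containing `reference_size` reference
#' genes; `overlap` is the observed number of reference genes drawn.
#'
#' Three conventions for the reported p-value are available, because
#' published enrichment tables differ in which they print:
#' `"greater"` (default) is the strict upper tail P(X > overlap);
#' `"geq"` is the inclusive tail P(X >= overlap); `"pmf"` is the point
#' probability P(X = overlap), the value some enrichment reports print.
#' The four counts are always carried in the result so any convention can be
#' audited.
#'
#' @param universe_size Total genes M.
#' @param reference_size Reference-list genes n (n <= M).
#' @param draw_size Selected genes N (N <= M).
#' @param overlap Observed overlap k.
#' @param convention Tail convention, see Details.
#' @return An `enrichment_result` object.
#' @examples
#' hypergeom_enrichment(20211, 632, 1625, 73)
#' @export
hypergeom_enrichment <- function(universe_size, reference_size, draw_size,
                                 overlap,
                                 convention = c("greater", "geq", "pmf")) {
  convention <- match.arg(convention)
  M <- as.integer(universe_size); n <- as.integer(reference_size)
  N <- as.integer(draw_size); k <- as.integer(overlap)
  if (any(is.na(c(M, n, N, k))) || M < 1L)
    stop_fedchow("counts must be non-missing and the universe non-empty",
                 "fedchow_invalid")
  if (n > M || N > M)
    stop_fedchow("reference and draw sizes cannot exceed the universe size",
                 "fedchow_invalid")
  if (k < 0L || k > min(n, N))
    stop_fedchow("overlap must lie in [0, min(reference_size, draw_size)]",
                 "fedchow_invalid")
  if (k < max(0L, N - (M - n)))
    stop_fedchow("overlap below the hypergeometric support minimum", "fedchow_invalid")
  p <- switch(convention,
              greater = stats::phyper(k, n, M - n, N, lower.tail = FALSE),
              geq     = stats::phyper(k - 1L, n, M - n, N, lower.tail = FALSE),
              pmf     = stats::dhyper(k, n, M - n, N))
  structure(list(universe_size = M, reference_size = n, draw_size = N,
                 overlap = k, p_value = p, convention = convention),
            class = "enrichment_result")
}

#' @exportS3Method base::print
print.enrichment_result <- function(x, ...) {
  cat("Hypergeometric enrichment: overlap ", x$overlap, " of ", x$draw_size,
      " drawn (reference ", x$reference_size, " / universe ", x$universe_size,
      ")\n  p = ", format(x$p_value, digits = 4),
      "  [", x$convention, "]\n", sep = "")
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the usual t-based two-sided test,
#' reported per subgroup alongside each scanned trio.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop_fedchow("need at least 3 complete pairs", "fedchow_unfittable")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_fedchow("correlation undefined for a constant vector",
                 "fedchow_unfittable")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. Missing values are preserved and do not count
#' toward the number of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_fedchow("p-values must lie in [0, 1]", "fedchow_invalid")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the summed probability of all heterozygote counts no more probable than
#' the observed one under the HWE conditional distribution. `midp = TRUE`
#' gives the mid-p variant (half weight on outcomes exactly as probable as
#' the observed one), which is closer to uniform under the null at the cost
#' of not being strictly conservative.
#'
#' @param n_hom_ref Count of reference-homozygote genotypes.
#' @param n_het Count of heterozygote genotypes.
#' @param n_hom_alt Count of alternate-homozygote genotypes.
#' @param midp Use the mid-p correction? Default `FALSE`.
#' @return Exact p-value in \[0, 1\]. Monomorphic samples return 1.
#' @examples
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt, midp = FALSE) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(cnt)) || any(cnt < 0))
    stop_fedchow("genotype counts must be non-negative", "fedchow_invalid")
  cnt <- as.integer(round(cnt))
  n <- sum(cnt)
  if (n < 1L)
    stop_fedchow("all genotype counts are zero", "fedchow_invalid")
  n_a <- 2L * cnt[1L] + cnt[2L]   # reference alleles
  n_b <- 2L * cnt[3L] + cnt[2L]   # alternate alleles
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)       # monomorphic: single possible configuration
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log conditional probability of each heterozygote count given allele counts
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_comm <- n - h - hom_rare
    lfactorial(n) - lfactorial(h) - lfactorial(hom_rare) -
      lfactorial(hom_comm) + h * log(2) +
      lfactorial(n_a) + lfactorial(n_b) - lfactorial(2L * n)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(cnt[2L], hets)]
  eq <- abs(pr - obs) <= obs * 1e-12
  if (midp) {
    min(1, sum(pr[pr < obs & !eq]) + 0.5 * sum(pr[eq]))
  } else {
    min(1, sum(pr[pr <= obs | eq]))
  }
}

# internal: classed conditions so callers can distinguish unfittable data
# from genuine misuse
stop_fedchow <- function(msg, class) {
  stop(structure(class = c(class, "fedchow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
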