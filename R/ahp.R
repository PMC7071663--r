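#' Saaty random-index table
#'
#' Mean consistency index of random reciprocal matrices, used as the
#' denominator of the consistency ratio CR = CI / RI.
#'
#' @param n matrix dimension(s), 1 to 10.
#' @return numeric vector of random-index values.
#' @export
saaty_random_index <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (any(n < 1L))
    stop("matrix dimension must be positive", call. = FALSE)
  if (any(n > 10L))
    stop("no packaged random index for n > 10; supply ri explicitly",
         call. = FALSE)
  ri[n]
}

#' Default criterion labels and weights of the five-criterion MCDA tree
#'
#' The five prioritization criteria and their expert-derived weights:
#' number of people potentially affected (0.133), cost-effectiveness
#' (0.293), attributable burden in DALY per 100,000 (0.337),
#' hospitalization preventable under the 4x4 model (0.160), and
#' prevalence difference between income levels (0.077).
#'
#' @return named numeric vector of length 5 summing to 1.
#' @export
ncd_criteria_weights <- function() {
  c(people_affected = 0.133,
    cost_effectiveness = 0.293,
    attributable_burden = 0.337,
    hospitalization = 0.160,
    income_inequity = 0.077)
}

check_pairwise <- function(a, tol = 1e-9) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("pairwise comparison matrix must be square", call. = FALSE)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("pairwise comparison matrix must be strictly positive",
         call. = FALSE)
  if (any(abs(diag(a) - 1) > tol))
    stop("pairwise comparison matrix must have unit diagonal",
         call. = FALSE)
  rel <- abs(a * t(a) - 1)
  if (any(rel > tol * pmax(1, a * t(a))))
    stop("matrix is not reciprocal: a[j,i] must equal 1/a[i,j]",
         call. = FALSE)
  invisible(a)
}

#' Build a perfectly consistent comparison matrix from weights
#'
#' Returns the ratio matrix \code{a[i,j] = w[i] / w[j]}, which is exactly
#' reciprocal and consistent (CR = 0); the principal eigenvector of such
#' a matrix recovers \code{w} up to scale.
#'
#' @param weights positive numeric vector (any scale; only ratios enter).
#' @return square matrix with the names of \code{weights} on both
#'   dimensions.
#' @export
build_consistent_matrix <- function(weights) {
  w <- as.numeric(weights)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  a <- outer(w, w, "/")
  if (!is.null(names(weights)))
    dimnames(a) <- list(names(weights), names(weights))
  a
}

#' Derive criterion weights from a pairwise comparison matrix
#'
#' The default method computes the normalized principal right
#' eigenvector by power iteration (the eigenvector method used by
#' standard AHP software); \code{"geometric_mean"} returns normalized
#' row geometric means. The two agree exactly on consistent matrices.
#'
#' @param a a positive reciprocal square matrix.
#' @param method \code{"eigenvector"} or \code{"geometric_mean"}.
#' @param tol power-iteration convergence tolerance (max absolute
#'   difference between successive normalized iterates).
#' @param max_iter iteration cap.
#' @return list with \code{weights} (sums to 1, named from the matrix
#'   dimnames), \code{lambda_max} (principal eigenvalue estimate), and
#'   \code{iterations}.
#' @export
derive_weights <- function(a, method = c("eigenvector", "geometric_mean"),
                           tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  check_pairwise(a)
  n <- nrow(a)
  labels <- rownames(a)
  if (method == "geometric_mean") {
    gm <- apply(a, 1, function(r) exp(mean(log(r))))
    w <- gm / sum(gm)
    ## lambda_max from the Rayleigh-style estimate mean((A w)_i / w_i)
    lambda <- mean((a %*% w) / w)
    return(list(weights = stats::setNames(w, labels), lambda_max = lambda,
                iterations = 0L))
  }
  w <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    v <- as.numeric(a %*% w)
    w_new <- v / sum(v)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
    if (iter >= max_iter)
      stop("power iteration failed to converge after ", iter,
           " iterations", call. = FALSE)
  }
  lambda <- mean((a %*% w) / w)
  list(weights = stats::setNames(w, labels), lambda_max = lambda,
       iterations = iter)
}

#' Consistency ratio of a pairwise comparison matrix
#'
#' Computes the consistency index CI = (lambda_max - n) / (n - 1) and
#' the consistency ratio CR = CI / RI against the Saaty random index
#' for the matrix dimension. Judgments with CR < 0.1 are conventionally
#' acceptable. For n <= 2 a reciprocal matrix is always consistent and
#' CR is defined as 0.
#'
#' @param a a positive reciprocal square matrix.
#' @param threshold acceptability cutoff (default 0.1).
#' @param ri optional random index overriding the packaged table
#'   (required for n > 10).
#' @return list of class \code{"consistency_report"} with
#'   \code{lambda_max, ci, ri, cr, pass, n, threshold}.
#' @export
consistency_ratio <- function(a, threshold = 0.1, ri = NULL) {
  check_pairwise(a)
  n <- nrow(a)
  if (n < 2L)
    stop("need at least a 2 x 2 matrix", call. = FALSE)
  d <- derive_weights(a, method = "eigenvector")
  lambda <- d$lambda_max
  if (n <= 2L) {
    ci <- 0
    cr <- 0
    ri_val <- if (is.null(ri)) saaty_random_index(n) else ri
  } else {
    ci <- (lambda - n) / (n - 1)
    ri_val <- if (is.null(ri)) saaty_random_index(n) else ri
    cr <- ci / ri_val
  }
  ## lambda_max >= n for reciprocal positive matrices; clamp the
  ## vanishing negative residue of finite-precision arithmetic
  if (cr < 0 && cr > -1e-9) cr <- 0
  out <- list(lambda_max = lambda, ci = ci, ri = ri_val, cr = cr,
              pass = cr < threshold, n = n, threshold = threshold)
  class(out) <- "consistency_report"
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency: lambda_max = %.6f (n = %d), CI = %.6f, RI = %.2f\n",
    x$lambda_max, x$n, x$ci, x$ri))
  cat(sprintf("CR = %.6f -> %s (threshold %.2f)\n", x$cr,
              if (x$pass) "acceptable" else "NOT acceptable", x$threshold))
  invisible(x)
}

#' Aggregate expert judgment matrices
#'
#' Combines individual pairwise matrices by the element-wise geometric
#' mean (aggregation of individual judgments), the standard group-AHP
#' rule: it is the only symmetric aggregation that preserves
#' reciprocity, since the geometric means of \code{a[i,j]} and
#' \code{a[j,i] = 1/a[i,j]} are exact reciprocals.
#'
#' @param matrices a non-empty list of positive reciprocal matrices of
#'   identical dimension (and dimnames, when present).
#' @return the aggregated reciprocal matrix.
#' @export
aggregate_expert_matrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("need a non-empty list of matrices", call. = FALSE)
  for (m in matrices) check_pairwise(m)
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("all matrices must have the same dimension", call. = FALSE)
  labs <- lapply(matrices, rownames)
  labs <- unique(Filter(Negate(is.null), labs))
  if (length(labs) > 1L)
    stop("criterion labels differ between matrices", call. = FALSE)
  logsum <- Reduce(`+`, lapply(matrices, log))
  agg <- exp(logsum / length(matrices))
  diag(agg) <- 1
  if (length(labs)) dimnames(agg) <- list(labs[[1]], labs[[1]])
  agg
}

#' Fit criterion weights by the analytic hierarchy process
#'
#' Takes one pairwise comparison matrix or a list of per-expert
#' matrices, aggregates multiple experts by the element-wise geometric
#' mean, derives the weight vector, and checks consistency against the
#' CR < 0.1 rule.
#'
#' @param x a positive reciprocal matrix, or a list of them (one per
#'   expert).
#' @param method weight-derivation method passed to [derive_weights()].
#' @param threshold consistency-ratio cutoff (default 0.1).
#' @return an object of class \code{"ahp"}: a list with
#'   \code{weights}, \code{lambda_max}, \code{consistency} (a
#'   \code{"consistency_report"}), \code{matrix} (the aggregated
#'   matrix), \code{n_experts}, and \code{method}.
#' @export
#' @examples
#' a <- build_consistent_matrix(c(burden = 3, cost = 2, equity = 1))
#' fit <- ahp(a)
#' coef(fit)
ahp <- function(x, method = c("eigenvector", "geometric_mean"),
                threshold = 0.1) {
  method <- match.arg(method)
  if (is.matrix(x)) x <- list(x)
  agg <- aggregate_expert_matrices(x)
  d <- derive_weights(agg, method = method)
  cons <- consistency_ratio(agg, threshold = threshold)
  out <- list(weights = d$weights, lambda_max = d$lambda_max,
              consistency = cons, matrix = agg,
              n_experts = length(x), method = method)
  class(out) <- "ahp"
  out
}

#' @export
print.ahp <- function(x, digits = 4, ...) {
  cat(sprintf("AHP criterion weights (%s method, %d expert matri%s)\n",
              x$method, x$n_experts, if (x$n_experts == 1) "x" else "ces"))
  w <- round(x$weights, digits)
  nm <- if (is.null(names(w))) paste0("C", seq_along(w)) else names(w)
  for (i in seq_along(w)) cat(sprintf("  %-22s %.*f\n", nm[i], digits, w[i]))
  cat(sprintf("CR = %.4f (%s)\n", x$consistency$cr,
              if (x$consistency$pass) "consistent" else "inconsistent"))
  invisible(x)
}

#' @export
summary.ahp <- function(object, ...) {
  print(object, ...)
  cat("\n")
  print(object$consistency)
  invisible(object)
}

#' @export
coef.ahp <- function(object, ...) object$weights

#' @export
plot.ahp <- function(x, ...) {
  w <- sort(x$weights, decreasing = TRUE)
  nm <- if (is.null(names(w))) paste0("C", seq_along(w)) else names(w)
  graphics::barplot(rev(w), names.arg = rev(nm), horiz = TRUE, las = 1,
                    xlab = "weight", main = "AHP criterion weights", ...)
  invisible(x)
}
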