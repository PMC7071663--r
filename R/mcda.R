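check_criteria_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!is.numeric(m))
    stop("criteria matrix must be numeric", call. = FALSE)
  if (any(!is.finite(m)))
    stop("criteria matrix contains non-finite values", call. = FALSE)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative criterion value at row '%s', column '%s'",
                 if (is.null(rownames(m))) neg[1, 1] else
                   rownames(m)[neg[1, 1]],
                 if (is.null(colnames(m))) neg[1, 2] else
                   colnames(m)[neg[1, 2]]), call. = FALSE)
  m
}

#' Distributive-mode column normalization
#'
#' Divides every entry by its column sum, turning each criterion column
#' into shares that sum to 1. This is the distributive synthesis mode:
#' rankings become invariant to the units of each criterion. An all-zero
#' column is left at zero with a warning.
#'
#' @param m nonnegative numeric matrix, interventions in rows, criteria
#'   in columns.
#' @return matrix of the same shape with unit column sums.
#' @export
normalize_distributive <- function(m) {
  m <- check_criteria_matrix(m)
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero criterion column(s): ",
            paste(if (is.null(colnames(m))) which(zero) else
              colnames(m)[zero], collapse = ", "),
            " left unnormalized", call. = FALSE)
    cs[zero] <- 1
  }
  sweep(m, 2, cs, "/")
}

#' Weighted-sum composite scores
#'
#' Combines a column-normalized criteria matrix with criterion weights:
#' \code{score_i = sum_c w_c * norm[i, c]}. With unit column sums and
#' weights summing to 1, the composite scores also sum to 1 and read as
#' priority shares.
#'
#' @param norm normalized criteria matrix (see
#'   [normalize_distributive()]).
#' @param weights named weight vector; names must match the matrix
#'   columns (order-insensitive) when both are named.
#' @return named numeric vector of composite scores (one per row).
#' @export
aggregate_scores <- function(norm, weights) {
  norm <- as.matrix(norm)
  w <- as.numeric(weights)
  if (length(w) != ncol(norm))
    stop("weight length does not match the number of criteria",
         call. = FALSE)
  if (!is.null(names(weights)) && !is.null(colnames(norm))) {
    if (!setequal(names(weights), colnames(norm)))
      stop("weight labels do not match criteria columns: ",
           paste(setdiff(names(weights), colnames(norm)), collapse = ", "),
           call. = FALSE)
    w <- as.numeric(weights[colnames(norm)])
  }
  stats::setNames(as.numeric(norm %*% w), rownames(norm))
}

#' Rank interventions by composite score
#'
#' Orders interventions by descending composite score. Exact ties are
#' broken by the higher raw value on the tiebreak criterion (default:
#' the first column of \code{tiebreak}), then by code. Ranks are dense
#' and 1-based.
#'
#' @param scores named numeric vector of composite scores.
#' @param tiebreak optional named numeric vector (or single-column
#'   matrix) of tiebreak values per code; larger wins.
#' @return data frame \code{(rank, code, score)} in rank order.
#' @export
rank_interventions <- function(scores, tiebreak = NULL) {
  if (any(is.na(scores)) || any(!is.finite(scores)))
    stop("scores must be finite and non-missing", call. = FALSE)
  codes <- names(scores)
  if (is.null(codes)) codes <- as.character(seq_along(scores))
  tb <- rep(0, length(scores))
  if (!is.null(tiebreak)) {
    tiebreak <- drop(as.matrix(tiebreak))
    tb <- as.numeric(tiebreak[codes])
    tb[is.na(tb)] <- 0
  }
  ord <- order(-as.numeric(scores), -tb, codes, method = "radix")
  data.frame(rank = seq_along(scores), code = codes[ord],
             score = as.numeric(scores)[ord], stringsAsFactors = FALSE)
}

#' Fit a weighted-sum multi-criteria ranking
#'
#' The full distributive-mode MCDA: column-normalizes the criteria
#' matrix, combines it with the criterion weights into composite
#' scores, and ranks the interventions with deterministic tie-breaking
#' (highest tiebreak-criterion value, then code).
#'
#' @param criteria nonnegative matrix or data frame, one row per
#'   intervention code (rownames or a \code{code} column), one column
#'   per criterion.
#' @param weights named criterion weight vector, e.g. from
#'   [ncd_criteria_weights()] or \code{coef(ahp(...))}; normalized to
#'   sum to 1.
#' @param tiebreak name of the criterion used to break exact score ties
#'   (default: the largest-weight criterion).
#' @return an object of class \code{"mcda"}: list with \code{ranking}
#'   (data frame rank/code/score), \code{scores}, \code{contributions}
#'   (per-criterion share of each composite score),
#'   \code{criterion_ranks}, \code{normalized}, \code{criteria},
#'   \code{weights}, \code{tiebreak}.
#' @export
#' @examples
#' m <- matrix(c(4, 1, 2, 1, 3, 5), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("burden", "cost")))
#' fit <- mcda(m, c(burden = 0.7, cost = 0.3))
#' fit$ranking
mcda <- function(criteria, weights, tiebreak = NULL) {
  if (is.data.frame(criteria) && "code" %in% names(criteria)) {
    rn <- as.character(criteria$code)
    criteria <- as.matrix(criteria[setdiff(names(criteria), "code")])
    rownames(criteria) <- rn
  }
  m <- check_criteria_matrix(as.matrix(criteria))
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  w <- weights / sum(weights)
  if (!is.null(names(w)) && !is.null(colnames(m)))
    w <- w[colnames(m)]
  if (anyNA(w))
    stop("weights do not cover every criterion column", call. = FALSE)
  if (is.null(tiebreak))
    tiebreak <- if (!is.null(colnames(m))) colnames(m)[which.max(w)] else
      which.max(w)
  norm <- normalize_distributive(m)
  scores <- aggregate_scores(norm, w)
  contributions <- sweep(norm, 2, as.numeric(w), "*")
  criterion_ranks <- apply(-m, 2, rank, ties.method = "min")
  if (is.null(dim(criterion_ranks)))
    criterion_ranks <- matrix(criterion_ranks, nrow = nrow(m),
                              dimnames = dimnames(m))
  ranking <- rank_interventions(scores, tiebreak = m[, tiebreak])
  out <- list(ranking = ranking, scores = scores,
              contributions = contributions,
              criterion_ranks = criterion_ranks,
              normalized = norm, criteria = m, weights = w,
              tiebreak = tiebreak)
  class(out) <- "mcda"
  out
}

#' @export
print.mcda <- function(x, n = 10, digits = 4, ...) {
  cat(sprintf("Weighted-sum MCDA ranking: %d interventions, %d criteria\n",
              nrow(x$criteria), ncol(x$criteria)))
  top <- utils::head(x$ranking, n)
  top$score <- round(top$score, digits)
  print(top, row.names = FALSE)
  if (nrow(x$ranking) > n)
    cat("...", nrow(x$ranking) - n, "more\n")
  invisible(x)
}

#' @export
summary.mcda <- function(object, ...) {
  print(object, n = nrow(object$ranking), ...)
  cat("\nweights:\n")
  print(round(object$weights, 4))
  cat("\nper-criterion contribution to the top score:\n")
  top <- object$ranking$code[1]
  print(round(object$contributions[top, ], 4))
  invisible(object)
}

#' @export
coef.mcda <- function(object, ...) object$scores

#' @export
plot.mcda <- function(x, n = 15, ...) {
  top <- utils::head(x$ranking, n)
  contrib <- t(x$contributions[top$code, , drop = FALSE])
  graphics::barplot(contrib[, rev(seq_len(ncol(contrib))), drop = FALSE],
                    horiz = TRUE, las = 1, xlab = "composite score share",
                    legend.text = rownames(contrib),
                    main = "MCDA priorities", ...)
  invisible(x)
}

#' Rank stability under weight perturbation
#'
#' Repeatedly multiplies each criterion weight by an independent
#' Uniform(1 - p, 1 + p) factor, renormalizes, re-ranks, and summarizes
#' how stable the ranking is: the min/max rank attained by each
#' intervention and the fraction of replicates in which the top item is
#' unchanged.
#'
#' @param criteria nonnegative criteria matrix (as for [mcda()]).
#' @param weights criterion weight vector.
#' @param perturbation relative perturbation p, in (0, 1).
#' @param reps number of replicates (>= 1).
#' @param seed integer seed for reproducibility.
#' @return list with \code{rank_range} (data frame code/min/max of rank
#'   over replicates), \code{top1_stability} (fraction of replicates
#'   keeping the baseline top item), and \code{baseline} (the
#'   unperturbed \code{"mcda"} fit).
#' @export
weight_sensitivity <- function(criteria, weights, perturbation = 0.2,
                               reps = 500, seed = 1) {
  if (perturbation <= 0 || perturbation >= 1)
    stop("perturbation must lie strictly between 0 and 1", call. = FALSE)
  if (reps < 1)
    stop("reps must be at least 1", call. = FALSE)
  base <- mcda(criteria, weights)
  codes <- rownames(base$criteria)
  k <- length(base$weights)
  rank_min <- stats::setNames(rep(Inf, length(codes)), codes)
  rank_max <- stats::setNames(rep(-Inf, length(codes)), codes)
  top_hits <- 0L
  top_base <- base$ranking$code[1]
  old <- .Random.seed_guard(seed)
  on.exit(old())
  for (r in seq_len(reps)) {
    w <- base$weights * stats::runif(k, 1 - perturbation, 1 + perturbation)
    fit <- mcda(base$criteria, w / sum(w), tiebreak = base$tiebreak)
    rk <- stats::setNames(fit$ranking$rank, fit$ranking$code)[codes]
    rank_min <- pmin(rank_min, rk)
    rank_max <- pmax(rank_max, rk)
    if (fit$ranking$code[1] == top_base) top_hits <- top_hits + 1L
  }
  list(rank_range = data.frame(code = codes, min_rank = as.integer(rank_min),
                               max_rank = as.integer(rank_max),
                               stringsAsFactors = FALSE),
       top1_stability = top_hits / reps,
       baseline = base)
}

## Seed scoping: set the RNG deterministically and return a restorer,
## so package functions never clobber the caller's RNG stream.
.Random.seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}
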