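# Environmental-versus-spatial inference: collinearity reduction,
# permutation forward selection, PCNM spatial eigenvectors, RDA adjusted
# R-squared, Venn variance partitioning, and hierarchical partitioning.

#' Reduce collinear predictors
#'
#' Iteratively removes predictors until no pair has Pearson |r| above the
#' threshold: at each step, among all pairs exceeding the threshold, the
#' member with the largest mean |r| against all remaining predictors is
#' removed (ties broken by input order: the earlier-listed column is kept).
#' Constant predictors are dropped with a warning before the analysis.
#'
#' @param env Data frame or matrix of numeric predictors.
#' @param r_threshold Pearson |r| cutoff (default 0.80).
#' @return Character vector of kept predictor names, in input order.
#' @export
reduce_collinear <- function(env, r_threshold = 0.80) {
  env <- as.data.frame(env)
  v <- vapply(env, stats::var, numeric(1))
  if (any(v == 0 | is.na(v))) {
    warning("dropping constant predictor(s): ",
            paste(names(env)[v == 0 | is.na(v)], collapse = ", "),
            call. = FALSE)
    env <- env[, v > 0 & !is.na(v), drop = FALSE]
  }
  keep <- names(env)
  if (length(keep) < 2L) return(keep)
  repeat {
    r <- abs(stats::cor(env[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= r_threshold) break
    involved <- which(apply(r > r_threshold, 1, any))
    mean_r <- rowSums(r[involved, , drop = FALSE]) / (length(keep) - 1)
    # largest mean |r| removed; exact ties keep the earlier-listed column
    worst <- involved[which.max(mean_r + (seq_along(mean_r)) * 1e-12)]
    keep <- keep[-worst]
    if (length(keep) < 2L) break
  }
  keep
}

#' Redundancy-analysis R-squared and adjusted R-squared
#'
#' Y and X are column-centred; R2 is the trace of the covariance of fitted
#' values from multivariate least squares over the trace of the covariance
#' of Y; the Ezekiel adjustment uses the number of predictor columns.
#' Negative adjusted values are legal and reported raw.
#'
#' @param Y Numeric matrix (or data frame) of responses, rows = sites.
#' @param X Numeric matrix of predictors, full column rank after centring.
#' @return List with `r2`, `adj_r2`, `n`, `p`.
#' @export
rda_adj_r2 <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient predictor matrix; aliased columns: ",
         paste(if (length(bad)) bad else "(unnamed)", collapse = ", "),
         call. = FALSE)
  }
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 for the adjustment", call. = FALSE)
  fitted <- qr.fitted(qx, Y)
  r2 <- sum(fitted^2) / sum(Y^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2 = r2, adj_r2 = adj, n = n, p = p)
}

#' Permutation forward selection of predictors for a multivariate response
#'
#' Stepwise procedure on the RDA pseudo-F: at each forward step the
#' candidate with the largest partial pseudo-F (given the already selected
#' predictors) is added if its permutation p-value is at most `alpha`;
#' after each addition, any included predictor whose marginal permutation
#' p-value (given the others) exceeds `alpha` is dropped. Stops when no
#' change occurs. Permutations follow the reduced model (residuals of Y on
#' the conditioning set are permuted and the fitted part added back).
#'
#' @param Y Numeric matrix of responses.
#' @param X Data frame / matrix of candidate predictors (columns).
#' @param alpha Inclusion/retention threshold on the permutation p-value.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return Character vector of selected predictor names (input order).
#' @export
forward_select <- function(Y, X, alpha = 0.10, n_perm = 199, seed = 1) {
  stopifnot(n_perm >= 99)
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  stopifnot(nrow(Y) == nrow(X))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  vars <- names(X)
  selected <- character(0)
  repeat {
    changed <- FALSE
    candidates <- setdiff(vars, selected)
    if (length(candidates)) {
      f_obs <- vapply(candidates, function(v)
        .partial_pseudo_f(Y, X, v, selected), numeric(1))
      best <- candidates[which.max(f_obs)]
      # entry test on the maximum pseudo-F over candidates, so picking the
      # best of many does not inflate the entry rate
      p <- .perm_p_max(Y, X, candidates, selected, n_perm)
      if (p <= alpha) {
        selected <- vars[vars %in% c(selected, best)]
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      repeat {
        p_marg <- vapply(selected, function(v)
          .perm_p(Y, X, v, setdiff(selected, v), n_perm), numeric(1))
        if (max(p_marg) > alpha) {
          selected <- setdiff(selected, selected[which.max(p_marg)])
          changed <- TRUE
        } else break
        if (length(selected) <= 1L) break
      }
    }
    if (!changed) break
  }
  selected
}

# Partial pseudo-F of adding `term` given `cond` (names into X).
.partial_pseudo_f <- function(Y, X, term, cond) {
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  X1 <- cbind(1, as.matrix(X[, cond, drop = FALSE]))
  Xf <- cbind(X1, as.matrix(X[, term, drop = FALSE]))
  rss0 <- sum(stats::lm.fit(X1, Yc)$residuals^2)
  fitf <- stats::lm.fit(Xf, Yc)
  rss1 <- sum(fitf$residuals^2)
  dff <- n - fitf$rank
  ((rss0 - rss1) / 1) / (rss1 / dff)
}

# Adjusted R2 tolerant of aliased columns: effective p is the rank, fitted
# values come from the pivoted QR, so duplicated predictor matrices in a
# union contribute nothing extra (used by the partitioning routines).
.adj_r2_rank <- function(Y, X) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  qx <- qr(X)
  p <- qx$rank
  if (n <= p + 1) stop("need n > p + 1 for the adjustment", call. = FALSE)
  r2 <- sum(qr.fitted(qx, Y)^2) / sum(Y^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

.perm_p <- function(Y, X, term, cond, n_perm) {
  .perm_p_max(Y, X, term, cond, n_perm)
}

# Permutation p-value of the maximum partial pseudo-F over a candidate set,
# under the reduced model (residuals of Y on the conditioning set permuted,
# fitted part added back).
.perm_p_max <- function(Y, X, candidates, cond, n_perm) {
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  X1 <- cbind(1, as.matrix(X[, cond, drop = FALSE]))
  fit0 <- stats::lm.fit(X1, Yc)
  fit0_hat <- as.matrix(fit0$fitted.values)
  fit0_res <- as.matrix(fit0$residuals)
  maxf <- function(Yx) max(vapply(candidates, function(v)
    .partial_pseudo_f(Yx, X, v, cond), numeric(1)))
  f_obs <- maxf(Y)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    Yb <- fit0_hat + fit0_res[sample.int(n), , drop = FALSE]
    if (maxf(Yb) >= f_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Spatial eigenvector basis from sample coordinates: pairwise distances
#' beyond the truncation distance are replaced by four times the truncation
#' ("auto" = the longest minimum-spanning-tree edge, keeping the network
#' connected), the truncated distance matrix is Gower-centred and
#' eigen-decomposed, and eigenvectors with eigenvalue above 1e-10 are
#' returned under a deterministic sign convention (first nonzero loading
#' positive). Computation is delegated to `vegan::pcnm`.
#'
#' @param coords Numeric matrix/data frame of coordinates (rows = samples),
#'   or a `dist` object.
#' @param truncation Truncation distance, or "auto".
#' @return List with `vectors` (matrix, columns PCNM1..k), `values`
#'   (eigenvalues) and `truncation`.
#' @export
pcnm <- function(coords, truncation = "auto") {
  d <- if (inherits(coords, "dist")) coords else stats::dist(as.matrix(coords))
  if (max(d) == 0) stop("all points are identical", call. = FALSE)
  res <- if (identical(truncation, "auto")) vegan::pcnm(d)
         else vegan::pcnm(d, threshold = truncation)
  vec <- as.matrix(res$vectors)
  keep <- res$values[seq_len(ncol(vec))] > 1e-10
  vec <- vec[, keep, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    nz <- which(abs(vec[, j]) > 1e-12)[1]
    if (!is.na(nz) && vec[nz, j] < 0) vec[, j] <- -vec[, j]
  }
  list(vectors = vec, values = res$values[seq_len(ncol(vec))],
       truncation = res$threshold)
}

# Solve the Venn-region system: for each nonempty predictor-set subset S,
# adjR2(union of S) equals the sum of the regions it touches. Exact
# inclusion-exclusion, so raw fractions sum to the full-model adjusted R2.
.venn_solve <- function(adj_by_subset, k) {
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  A <- matrix(0, length(subsets), length(subsets))
  for (i in seq_along(subsets)) {      # measurement: union of subsets[[i]]
    for (j in seq_along(subsets)) {    # region: exactly subsets[[j]]
      if (length(intersect(subsets[[i]], subsets[[j]])) > 0) A[i, j] <- 1
    }
  }
  b <- vapply(subsets, function(s) adj_by_subset[[paste(s, collapse = "")]],
              numeric(1))
  frac <- solve(A, b)
  names(frac) <- vapply(subsets, paste, character(1), collapse = "")
  frac
}

#' Variance partitioning across 2-3 predictor matrices
#'
#' Computes the RDA adjusted R-squared of every non-empty union of the
#' predictor matrices and solves the Venn inclusion-exclusion system for
#' unique and shared fractions. Raw fractions sum exactly to the full-model
#' adjusted R-squared; a truncated view clamps negative fractions to zero
#' for display.
#'
#' @param Y Response matrix.
#' @param ... Two or three predictor matrices (named arguments name the
#'   fractions).
#' @return A `varpart_result`: list with `fractions` (data frame: component,
#'   raw, truncated), `total_adj_r2`, `labels`.
#' @export
variance_partition <- function(Y, ...) {
  Xs <- list(...)
  k <- length(Xs)
  stopifnot(k %in% c(2L, 3L))
  labels <- names(Xs)
  if (is.null(labels) || any(labels == "")) labels <- paste0("X", seq_len(k))
  adj <- list()
  for (m in seq_len(2^k - 1)) {
    s <- which(bitwAnd(m, 2^(0:(k - 1))) > 0)
    Xu <- do.call(cbind, lapply(Xs[s], as.matrix))
    adj[[paste(s, collapse = "")]] <- .adj_r2_rank(Y, Xu)
  }
  frac <- .venn_solve(adj, k)
  comp <- vapply(strsplit(names(frac), ""), function(ix)
    paste(labels[as.integer(ix)], collapse = "&"), character(1))
  fractions <- data.frame(component = comp, raw = unname(frac),
                          truncated = pmax(unname(frac), 0),
                          stringsAsFactors = FALSE)
  structure(list(fractions = fractions,
                 total_adj_r2 = adj[[paste(seq_len(k), collapse = "")]],
                 adj_by_subset = adj, labels = labels),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("variance partition (total adjusted R2 =",
      format(x$total_adj_r2, digits = 4), ")\n")
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

#' Hierarchical partitioning of predictor importance
#'
#' Scores each predictor by its average incremental adjusted R-squared over
#' all subsets of the remaining predictors, averaged hierarchically (within
#' each subset size, then across sizes). The contributions sum exactly to
#' the full-model adjusted R-squared. Exact enumeration over 2^p subsets,
#' limited to p <= `max_p`; group predictors into matrices beyond that.
#'
#' @param Y Response matrix.
#' @param predictors Named list of predictor matrices (a data frame is
#'   treated as one single-column matrix per column).
#' @param max_p Maximum number of predictors for exact enumeration.
#' @return Data frame: predictor, contribution; attribute `total_adj_r2`.
#' @export
hierarchical_partition <- function(Y, predictors, max_p = 15) {
  if (is.data.frame(predictors) || is.matrix(predictors)) {
    predictors <- as.data.frame(predictors)
    predictors <- stats::setNames(
      lapply(names(predictors), function(v) as.matrix(predictors[, v, drop = FALSE])),
      names(predictors))
  }
  p <- length(predictors)
  if (p > max_p) {
    stop("hierarchical partitioning enumerates 2^p subsets; group the ",
         p, " predictors into <= ", max_p, " matrices", call. = FALSE)
  }
  nm <- names(predictors)
  adj <- numeric(2^p)           # adj[mask + 1]; empty model = 0
  for (m in seq_len(2^p - 1)) {
    s <- which(bitwAnd(m, 2^(0:(p - 1))) > 0)
    Xu <- do.call(cbind, lapply(predictors[s], as.matrix))
    adj[m + 1] <- .adj_r2_rank(Y, Xu)
  }
  contrib <- numeric(p)
  for (i in seq_len(p)) {
    bit <- 2^(i - 1)
    inc_by_size <- vector("list", p)   # increments grouped by |S|
    for (m in 0:(2^p - 1)) {
      if (bitwAnd(m, bit) > 0) next
      sz <- sum(bitwAnd(m, 2^(0:(p - 1))) > 0)
      inc_by_size[[sz + 1]] <- c(inc_by_size[[sz + 1]],
                                 adj[m + bit + 1] - adj[m + 1])
    }
    level_means <- vapply(inc_by_size[!vapply(inc_by_size, is.null, logical(1))],
                          mean, numeric(1))
    contrib[i] <- mean(level_means)
  }
  out <- data.frame(predictor = nm, contribution = contrib,
                    stringsAsFactors = FALSE)
  attr(out, "total_adj_r2") <- adj[2^p]
  out
}
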