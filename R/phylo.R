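#' Read a time-calibrated tree from newick
#'
#' @param path Newick file; branch lengths are mandatory.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a time-calibrated tree is required")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  tree
}

#' Prune a tree to a set of tips
#'
#' Induced subtree on the kept species: dropped lineages are removed,
#' degree-2 nodes are suppressed with their edge lengths summed, so
#' root-to-tip distances of kept tips are unchanged.
#'
#' @param tree An `ape::phylo` tree.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned `phylo` tree.
#' @export
prune_to_tips <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least two tips after pruning")
  ape::keep.tip(tree, keep)
}

# Match the names of a tip-value vector to a tree's tip labels, tolerating
# space/underscore and case differences; reports substitutions.
match_tip_names <- function(values, tree) {
  norm <- function(s) tolower(gsub(" +", "_", trimws(s)))
  vn <- names(values)
  if (is.null(vn)) stop("tip values must be named by species")
  idx <- match(norm(tree$tip.label), norm(vn))
  if (anyNA(idx)) {
    stop("no value for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  subs <- vn[idx] != tree$tip.label
  if (any(subs)) {
    message("matched ", sum(subs), " species name(s) after normalizing ",
            "spaces/underscores and case")
  }
  stats::setNames(as.numeric(values[idx]), tree$tip.label)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML estimation of a continuous character at every internal node
#' of a rooted tree, assuming Brownian evolution: the node states
#' minimize the inverse-branch-length-weighted sum of squared changes
#' \eqn{\sum_e (\Delta_e)^2 / t_e}, the stationarity conditions of the
#' joint Gaussian likelihood. Solved as a (dense) linear system over the
#' internal nodes; the rate is \eqn{\hat\sigma^2 = SS_{min}/E} with E the
#' edge count, and the joint log-likelihood is reported. Every estimated
#' state lies within the range of the tip values.
#'
#' @param tree An `ape::phylo` tree with strictly positive edge lengths.
#' @param tip_values Named numeric vector covering every tip.
#' The minimized sum of squares depends only on the tip data (it equals
#' the root-centred quadratic form in the tips' Brownian covariance) and
#' is distributed as \eqn{\sigma^2 \chi^2_{n-1}}. The joint-ML rate
#' \eqn{SS/E} therefore carries the well-known downward bias of joint
#' estimation (its expectation is \eqn{\sigma^2 (n-1)/E}, about half the
#' truth on a binary tree); `sigma2_unbiased` rescales the same sum of
#' squares by \eqn{n-1} and is exactly unbiased. The ancestral states
#' themselves are identical under either normalization.
#'
#' @return A `bm_ancestral` list: `node_states` (named by ape node
#'   number), `sigma2` (joint ML, SS/E), `sigma2_unbiased` (SS/(n-1)),
#'   `log_likelihood`, `states` (tip + node states in ape order), and
#'   the `tree`.
#' @export
bm_ancestral_ml <- function(tree, tip_values) {
  if (any(tree$edge.length <= 0)) {
    stop("zero-length edge: collapse zero branches before estimation")
  }
  vals <- match_tip_names(tip_values, tree)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  w <- 1 / tree$edge.length

  # Laplacian system over internal nodes (numbered n+1 .. n+m in ape)
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (e in seq_along(parent)) {
    p <- parent[e] - n            # parents are always internal
    A[p, p] <- A[p, p] + w[e]
    if (child[e] > n) {
      q <- child[e] - n
      A[q, q] <- A[q, q] + w[e]
      A[p, q] <- A[p, q] - w[e]
      A[q, p] <- A[q, p] - w[e]
    } else {
      b[p] <- b[p] + w[e] * vals[child[e]]
    }
  }
  node_states <- solve(A, b)

  states <- c(vals, node_states)           # ape order: tips then nodes
  ss <- sum(w * (states[parent] - states[child])^2)
  E <- length(parent)
  sigma2 <- ss / E
  log_lik <- if (sigma2 > 0) {
    -0.5 * (E * log(2 * pi * sigma2) + sum(log(tree$edge.length)) + E)
  } else Inf

  structure(list(node_states = stats::setNames(node_states, n + seq_len(m)),
                 sigma2 = sigma2, sigma2_unbiased = ss / (n - 1),
                 log_likelihood = log_lik,
                 states = states, tree = tree),
            class = "bm_ancestral")
}

#' @export
print.bm_ancestral <- function(x, ...) {
  cat(sprintf("Brownian-motion ancestral states: %d nodes, sigma2 = %.4g\n",
              length(x$node_states), x$sigma2))
  cat(sprintf("  root state = %.4f, log-likelihood = %.4f\n",
              x$node_states[1], x$log_likelihood))
  invisible(x)
}

#' Sample a continuous character along branches
#'
#' Linear interpolation of the estimated character between each edge's
#' parent and child states, at positions spaced by `step` time units
#' (the child endpoint is always included) -- the numeric substrate of a
#' continuous character map.
#'
#' @param tree An `ape::phylo` tree.
#' @param estimates A `bm_ancestral` fit for this tree.
#' @param step Positive sampling increment in the tree's time units.
#' @return Data frame with columns `edge`, `parent`, `child`, `position`
#'   (distance from the parent end), `value`.
#' @export
map_to_branches <- function(tree, estimates, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("step must be a positive number")
  }
  states <- estimates$states
  if (length(states) != length(tree$tip.label) + tree$Nnode) {
    stop("estimates do not cover all nodes of the tree")
  }
  out <- lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    pos <- unique(c(seq(0, t_e, by = step), t_e))
    data.frame(edge = e, parent = p, child = ch, position = pos,
               value = states[p] + (states[ch] - states[p]) * pos / t_e)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `response ~ predictor` across species with error covariance
#' proportional to shared phylogenetic history, \eqn{C_{ij} =} root-to-
#' most-recent-common-ancestor path length. Coefficients are
#' \eqn{\hat\beta = (X'C^{-1}X)^{-1} X'C^{-1} y}; the residual Brownian
#' rate is estimated by restricted maximum likelihood (default) or ML.
#'
#' @param response,predictor Named numeric vectors covering every tip.
#' @param tree An `ape::phylo` tree (>= 3 tips).
#' @param method `"REML"` (default) or `"ML"`. REML log-likelihoods (and
#'   hence AICs) are comparable only between models with identical fixed
#'   effects.
#' @return A `pgls_bm` list: `coefficients` (intercept, slope), `sigma2`,
#'   `log_likelihood`, `aic`, `slope_se`, `slope_t`, `slope_p`, `df_residual`,
#'   `method`, `n`.
#' @export
pgls_brownian <- function(response, predictor, tree, method = c("REML", "ML")) {
  method <- match.arg(method)
  n <- length(tree$tip.label)
  if (n < 3L) stop("need at least three tips")
  y <- match_tip_names(response, tree)
  xv <- match_tip_names(predictor, tree)
  X <- cbind(`(Intercept)` = 1, slope = xv)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design: predictor is constant")

  C <- ape::vcv(tree)
  L <- chol(C)                               # C = L'L
  Xs <- backsolve(L, X, transpose = TRUE)    # L'^{-1} X
  ys <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)                # r' C^{-1} r
  logdetC <- 2 * sum(log(diag(L)))
  XtCiX <- crossprod(Xs)

  if (method == "REML") {
    sigma2 <- rss / (n - p)
    log_lik <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdetC +
                         determinant(XtCiX, logarithm = TRUE)$modulus[1] +
                         (n - p))
  } else {
    sigma2 <- rss / n
    log_lik <- -0.5 * (n * log(2 * pi * sigma2) + logdetC + n)
  }
  k <- p + 1L                                # coefficients + sigma2
  aic <- 2 * k - 2 * log_lik

  se <- sqrt(rss / (n - p) * solve(XtCiX)[2, 2])  # t-test always on n-p df
  t_stat <- beta[2] / se
  slope_p <- 2 * stats::pt(-abs(t_stat), df = n - p)

  structure(list(coefficients = beta, sigma2 = sigma2,
                 log_likelihood = as.numeric(log_lik), aic = as.numeric(aic),
                 slope_se = se, slope_t = as.numeric(t_stat),
                 slope_p = as.numeric(slope_p), df_residual = n - p,
                 method = method, n = n),
            class = "pgls_bm")
}

#' @export
print.pgls_bm <- function(x, ...) {
  cat(sprintf("PGLS (Brownian covariance, %s), n = %d\n", x$method, x$n))
  cat(sprintf("  intercept = %.4f, slope = %.4f (SE %.4f, t = %.3f, p = %.4g)\n",
              x$coefficients[1], x$coefficients[2], x$slope_se, x$slope_t,
              x$slope_p))
  cat(sprintf("  sigma2 = %.4g, logLik = %.4f, AIC = %.4f\n",
              x$sigma2, x$log_likelihood, x$aic))
  invisible(x)
}
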