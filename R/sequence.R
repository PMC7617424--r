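#' Rank items by closure score
#'
#' Builds a fusion sequence: the item (suture or region) with the highest
#' closure score -- the earliest to fuse -- receives rank 1, the lowest
#' rank n. Ties receive the average of the ranks they span.
#'
#' @param scores A `closure_table` or a named numeric vector of closure
#'   percentages.
#' @return A `fusion_sequence` data frame with columns `item`,
#'   `closure_pct`, `rank`, sorted by rank.
#' @export
rank_closure <- function(scores) {
  if (inherits(scores, "closure_table")) {
    key <- intersect(c("suture", "specimen", "region_name", "region", "species"),
                     names(scores))[1]
    items <- as.character(scores[[key]])
    vals <- scores$closure_pct
  } else {
    items <- names(scores)
    vals <- as.numeric(scores)
    if (is.null(items)) stop("scores must be named or a closure_table")
  }
  if (length(vals) < 2L) stop("need at least two items to rank")
  r <- rank(-vals, ties.method = "average")
  out <- data.frame(item = items, closure_pct = vals, rank = r,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$item), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fusion_sequence", "data.frame")
  out
}

# Exact null distribution of the number of discordant pairs (inversions)
# of a random permutation of 1..n: coefficients of prod_i (1+q+...+q^(i-1)).
inversion_counts <- function(n) {
  cnt <- 1
  for (i in 2:n) {
    new <- numeric(length(cnt) + i - 1L)
    for (k in 0:(i - 1L)) {
      new[seq_along(cnt) + k] <- new[seq_along(cnt) + k] + cnt
    }
    cnt <- new
  }
  cnt  # cnt[d+1] = number of permutations with d inversions
}

#' Kendall tau-b rank concordance
#'
#' Measures conservation of a sequence between two rankings (or score
#' vectors) over the same items:
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - t_x)(n_0 - t_y)}}
#' where C and D count concordant and discordant pairs, \eqn{n_0 =
#' n(n-1)/2}, and \eqn{t_x}, \eqn{t_y} count pairs tied within each
#' ranking. The two-sided p-value uses the exact permutation null when
#' n <= 8 and neither ranking has ties, and the normal approximation with
#' tie-corrected variance otherwise.
#'
#' @param x,y Numeric vectors over the same items. If both are named, `y`
#'   is aligned to `x` by name.
#' @return A `rank_comparison` list: `tau`, `p_raw`, `p_adjusted` (`NA`
#'   until a multiple-testing pass sets it), `n_items`, `concordant`,
#'   `discordant`, `tied_x`, `tied_y`, `tied_both`, `p_method`.
#' @export
kendall_tau_b <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) {
      stop("x and y must cover the same item set")
    }
    y <- y[names(x)]
  }
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least two items")
  if (anyNA(x) || anyNA(y)) stop("missing values in rankings")

  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- sign(x[pair[, 2]] - x[pair[, 1]])
  dy <- sign(y[pair[, 2]] - y[pair[, 1]])
  C <- sum(dx * dy > 0)
  D <- sum(dx * dy < 0)
  tx <- sum(dx == 0)
  ty <- sum(dy == 0)
  txy <- sum(dx == 0 & dy == 0)
  n0 <- n * (n - 1) / 2
  if (tx == n0 || ty == n0) {
    stop("tau undefined: zero variance (all values tied) in a ranking")
  }
  tau <- (C - D) / sqrt((n0 - tx) * (n0 - ty))

  if (n <= 8L && tx == 0L && ty == 0L) {
    cnt <- inversion_counts(n)
    taus <- (n0 - 2 * (seq_along(cnt) - 1)) / n0
    p <- sum(cnt[abs(taus) >= abs(tau) - 1e-12]) / sum(cnt)
    p_method <- "exact permutation"
  } else {
    tcx <- table(x); tcy <- table(y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tcx * (tcx - 1) * (2 * tcx + 5))
    vu <- sum(tcy * (tcy - 1) * (2 * tcy + 5))
    v1 <- sum(tcx * (tcx - 1)) * sum(tcy * (tcy - 1)) / (2 * n * (n - 1))
    v2 <- sum(tcx * (tcx - 1) * (tcx - 2)) * sum(tcy * (tcy - 1) * (tcy - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- (C - D) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    p_method <- "normal approximation, tie-corrected"
  }

  structure(list(tau = tau, p_raw = p, p_adjusted = NA_real_,
                 n_items = n, concordant = C, discordant = D,
                 tied_x = tx, tied_y = ty, tied_both = txy,
                 p_method = p_method),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f (n = %d; C = %d, D = %d; p = %.4g%s)\n",
              x$tau, x$n_items, x$concordant, x$discordant, x$p_raw,
              if (!is.na(x$p_adjusted))
                sprintf(", Bonferroni p = %.4g", x$p_adjusted) else ""))
  invisible(x)
}

#' Pairwise fusion-sequence comparisons between species
#'
#' Kendall tau-b between every unordered pair of species' per-suture
#' closure scores, with Bonferroni correction over the number of pairs.
#'
#' @param per_species_scores Named list (one element per species) of
#'   `closure_table`s at suture level, or of named score vectors; all
#'   species must cover the same suture set.
#' @return A `pairwise_comparisons` data frame with columns `species_a`,
#'   `species_b`, `tau`, `p_raw`, `p_adjusted`, `n_items`; attribute `m`
#'   holds the Bonferroni multiplier (the number of pairs).
#' @export
pairwise_species_comparison <- function(per_species_scores) {
  as_vec <- function(s) {
    if (inherits(s, "closure_table")) stats::setNames(s$closure_pct, s$suture)
    else s
  }
  vecs <- lapply(per_species_scores, as_vec)
  sp <- names(vecs)
  if (is.null(sp) || length(sp) < 2L) stop("need >=2 named species")
  base_items <- names(vecs[[1]])
  for (v in vecs) {
    if (!setequal(names(v), base_items)) {
      stop("every species must cover the same suture set")
    }
  }
  pairs <- utils::combn(sp, 2)
  m <- ncol(pairs)
  rows <- apply(pairs, 2, function(p) {
    cmp <- kendall_tau_b(vecs[[p[1]]], vecs[[p[2]]][names(vecs[[p[1]]])])
    data.frame(species_a = p[1], species_b = p[2], tau = cmp$tau,
               p_raw = cmp$p_raw, p_adjusted = min(1, cmp$p_raw * m),
               n_items = cmp$n_items, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Concordance with the Krogman fusion order
#'
#' Ranks the six Krogman regions by their average closure score and
#' compares that ranking (Kendall tau-b) against the classical reference
#' order: vault (1), cranial base (2), circum-meatal (3), palate (4),
#' facial (5), cranio-facial (6).
#'
#' @param region_scores A `closure_table` from [region_averages()] (or a
#'   data frame with `region` ordinals 1-6 and `closure_pct`).
#' @return A `rank_comparison`.
#' @export
compare_to_krogman <- function(region_scores) {
  if (!identical(as.integer(sort(region_scores$region)), 1:6)) {
    stop("need closure scores for exactly the six Krogman regions")
  }
  ord <- order(region_scores$region)
  observed_rank <- rank(-region_scores$closure_pct[ord],
                        ties.method = "average")
  reference_rank <- 1:6
  kendall_tau_b(observed_rank, reference_rank)
}

#' Count significant pairwise comparisons
#'
#' @param comparisons A `pairwise_comparisons` table with Bonferroni
#'   adjusted p-values.
#' @param alpha Significance level (default 0.05).
#' @return Number of comparisons with `p_adjusted < alpha`.
#' @export
count_significant <- function(comparisons, alpha = 0.05) {
  if (anyNA(comparisons$p_adjusted)) {
    stop("adjusted p-values missing; run pairwise_species_comparison first")
  }
  sum(comparisons$p_adjusted < alpha)
}
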