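write_tree_file <- function(text, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".nwk", .local_envir = env)
  writeLines(text, path)
  path
}

test_that("newick trees read, require branch lengths, and round-trip", {
  tr <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)

  expect_error(read_newick(write_tree_file("((A,B),C);")),
               "no branch lengths")
  expect_error(read_newick("/nonexistent/tree.nwk"), "not found")

  out <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, out)
  tr2 <- read_newick(out)
  expect_equal(ape::write.tree(tr2), ape::write.tree(tr))
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
})

test_that("pruning preserves root-to-tip distances of kept tips", {
  tr <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  expect_equal(ape::write.tree(prune_to_tips(tr, c("A", "C"))),
               "(A:2,C:2);")
  # keep all tips -> same tree
  same <- prune_to_tips(tr, c("A", "B", "C"))
  expect_equal(sort(same$tip.label), sort(tr$tip.label))
  expect_equal(max(ape::node.depth.edgelength(same)),
               max(ape::node.depth.edgelength(tr)))
  expect_error(prune_to_tips(tr, c("A", "Z")), "Z")
  expect_error(prune_to_tips(tr, "A"), "at least two")

  # property: depths of kept tips unchanged on a random tree
  set.seed(5)
  big <- simulate_tree(12, seed = 9)
  keep <- sample(big$tip.label, 6)
  pruned <- prune_to_tips(big, keep)
  d0 <- ape::node.depth.edgelength(big)[match(keep, big$tip.label)]
  d1 <- ape::node.depth.edgelength(pruned)[match(keep, pruned$tip.label)]
  expect_equal(d1, d0)
})

test_that("BM ancestral states match closed-form small-tree solutions", {
  # symmetric cherry: root is the midpoint
  tr <- read_newick(write_tree_file("(A:1,B:1);"))
  a <- bm_ancestral_ml(tr, c(A = 0, B = 10))
  expect_equal(unname(a$node_states[1]), 5)

  # asymmetric cherry: inverse-branch-length weighting
  tr2 <- read_newick(write_tree_file("(A:1,B:3);"))
  a2 <- bm_ancestral_ml(tr2, c(A = 0, B = 8))
  expect_equal(unname(a2$node_states[1]), 2, tolerance = 1e-10)

  # 3-tip caterpillar: two-step weighted average, solved by hand.
  # Root r and inner node v on ((A:1,B:1):1,C:2) satisfy
  #   v = (r + A + B)/3 (unit branches), r = (v/1 + C/2)/(1 + 1/2)
  tr3 <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  vals <- c(A = 2, B = 6, C = 12)
  a3 <- bm_ancestral_ml(tr3, vals)
  r <- unname(a3$node_states[1]); v <- unname(a3$node_states[2])
  expect_equal(v, (r + 2 + 6) / 3, tolerance = 1e-10)
  expect_equal(r, (v + 12 / 2) / 1.5, tolerance = 1e-10)

  # constant character: all states equal, rate zero
  ac <- bm_ancestral_ml(tr3, c(A = 7, B = 7, C = 7))
  expect_true(all(abs(ac$node_states - 7) < 1e-12))
  expect_equal(ac$sigma2, 0)

  expect_error(bm_ancestral_ml(
    read_newick(write_tree_file("(A:0,B:1);")), c(A = 0, B = 1)),
    "zero-length")
})

test_that("BM ancestral estimates agree with a numeric likelihood search", {
  # 4-tip tree: minimize the weighted sum of squared changes numerically
  tr <- read_newick(write_tree_file("((A:1,B:2):1,(C:1.5,D:0.5):2);"))
  vals <- c(A = 10, B = 4, C = 7, D = 1)
  a <- bm_ancestral_ml(tr, vals)

  obj <- function(s) {
    # s = states at nodes 5,6,7 (root, AB ancestor, CD ancestor)
    states <- c(vals, s)
    parent <- tr$edge[, 1]; child <- tr$edge[, 2]
    sum((states[parent] - states[child])^2 / tr$edge.length)
  }
  opt <- stats::optim(c(5, 5, 5), obj, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(unname(a$node_states), opt$par, tolerance = 1e-6)
  expect_equal(a$sigma2, opt$value / nrow(tr$edge), tolerance = 1e-6)
})

test_that("BM ancestral estimation matches the reference implementation", {
  set.seed(41)
  tr <- simulate_tree(10, seed = 13)
  sim <- simulate_bm_tips(tr, sigma2 = 30, root_value = 60, seed = 14)
  vals <- stats::setNames(as.numeric(sim), names(sim))
  a <- bm_ancestral_ml(tr, vals)
  ref <- suppressWarnings(phytools::anc.ML(tr, vals, model = "BM"))
  expect_equal(unname(a$node_states), unname(ref$ace), tolerance = 1e-6)
  expect_equal(a$sigma2, unname(ref$sig2), tolerance = 1e-4)
})

test_that("BM ancestral states are shift- and scale-equivariant and bounded", {
  set.seed(43)
  tr <- simulate_tree(8, seed = 21)
  vals <- stats::setNames(runif(8, 20, 80), tr$tip.label)
  a <- bm_ancestral_ml(tr, vals)
  shifted <- bm_ancestral_ml(tr, vals + 13)
  scaled <- bm_ancestral_ml(tr, vals * 2.5)
  expect_equal(shifted$node_states, a$node_states + 13, tolerance = 1e-9)
  expect_equal(scaled$node_states, a$node_states * 2.5, tolerance = 1e-9)
  expect_equal(scaled$sigma2, a$sigma2 * 2.5^2, tolerance = 1e-9)
  expect_true(all(a$node_states >= min(vals) - 1e-9 &
                    a$node_states <= max(vals) + 1e-9))
})

test_that("branch mapping interpolates linearly between node states", {
  tr <- read_newick(write_tree_file("(A:2,B:2);"))
  a <- bm_ancestral_ml(tr, c(A = 8, B = 0))    # root = 4
  mp <- map_to_branches(tr, a, step = 1)
  edgeA <- mp[mp$child == 1, ]                 # tip A is node 1
  expect_equal(edgeA$value, c(4, 6, 8))        # 4 -> 8 over length 2

  # step larger than the edge: endpoints only
  mp2 <- map_to_branches(tr, a, step = 10)
  expect_equal(nrow(mp2[mp2$child == 1, ]), 2L)
  expect_error(map_to_branches(tr, a, step = 0), "positive")

  # constant character maps to a constant everywhere
  ac <- bm_ancestral_ml(tr, c(A = 3, B = 3))
  expect_true(all(map_to_branches(tr, ac, 0.5)$value == 3))
})

test_that("PGLS equals OLS on a star phylogeny", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(47)
  x <- stats::setNames(rnorm(6), star$tip.label)
  y <- 1.5 + 2 * x + stats::setNames(rnorm(6, 0, 0.4), star$tip.label)
  fit <- pgls_brownian(y, x, star)
  ols <- stats::lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  # perfect linear response: exact slope and zero residual rate
  fit0 <- pgls_brownian(2 + 3 * x, x, star)
  expect_equal(unname(fit0$coefficients[2]), 3, tolerance = 1e-8)
  expect_lt(fit0$sigma2, 1e-16)
})

test_that("PGLS matches a dense generalized-least-squares oracle", {
  tr <- read_newick(write_tree_file("((A:1,B:1):2,(C:2,D:2):1);"))
  x <- c(A = 1, B = 2, C = 3, D = 5)
  y <- c(A = 2.2, B = 2.9, C = 4.8, D = 7.5)
  fit <- pgls_brownian(y, x, tr)
  C <- ape::vcv(tr)
  X <- cbind(1, x[rownames(C)])
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y[rownames(C)])
  expect_equal(unname(fit$coefficients), as.numeric(beta),
               tolerance = 1e-10)

  expect_error(pgls_brownian(y, c(A = 1, B = 1, C = 1, D = 1), tr),
               "singular")
})

test_that("PGLS reproduces the standard GLS fit under BM correlation", {
  skip_if_not_installed("nlme")
  set.seed(53)
  tr <- simulate_tree(12, seed = 31)
  x <- stats::setNames(rnorm(12), tr$tip.label)
  y <- 3 + 0.7 * x +
    stats::setNames(as.vector(t(chol(ape::vcv(tr))) %*% rnorm(12, 0, 0.5)),
                    tr$tip.label)
  d <- data.frame(y = y, x = x, sp = tr$tip.label)
  for (meth in c("REML", "ML")) {
    fit <- pgls_brownian(y, x, tr, meth)
    ref <- nlme::gls(y ~ x, data = d,
                     correlation = ape::corBrownian(1, tr, form = ~sp),
                     method = meth)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-8)
    expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-8)
    expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-8)
    expect_equal(fit$slope_p, summary(ref)$tTable[2, 4], tolerance = 1e-8)
  }
})

test_that("species names are matched across space/underscore variants", {
  tr <- read_newick(write_tree_file("(Mus_musculus:1,Rattus_rattus:1);"))
  expect_message(
    a <- bm_ancestral_ml(tr, c("Mus musculus" = 0, "Rattus rattus" = 10)),
    "normalizing")
  expect_equal(unname(a$node_states[1]), 5)
})
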