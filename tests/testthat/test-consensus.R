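test_that("F-score matches the worked example and the direct formula", {
  X <- cbind(f1 = c(1, 2, 3, 4, 5, 6))
  labels <- c("p", "p", "p", "n", "n", "n")
  fr <- f_scores(X, labels)
  expect_equal(fr$f_score, 2.25)        # ((2-3.5)^2 + (5-3.5)^2) / (1 + 1)

  set.seed(31)
  Xr <- matrix(rnorm(20 * 15), 20)
  colnames(Xr) <- paste0("f", 1:15)
  lab <- rep(c("NC", "AD"), each = 10)
  fr <- f_scores(Xr, lab)
  oracle <- apply(Xr, 2, function(v) {
    a <- v[lab == "NC"]; b <- v[lab == "AD"]; m <- mean(v)
    ((mean(a) - m)^2 + (mean(b) - m)^2) /
      (sum((a - mean(a))^2) / (length(a) - 1) +
         sum((b - mean(b))^2) / (length(b) - 1))
  })
  expect_equal(fr$f_score, unname(oracle), tolerance = 1e-12)
})

test_that("equal class means give F = 0; zero within-variance gives Inf first", {
  X <- cbind(flat = c(1, 2, 3, 1, 2, 3), sep = c(0, 0, 0, 1, 1, 1))
  labels <- rep(c("NC", "AD"), each = 3)
  expect_warning(fr <- f_scores(X, labels), "zero within-class variance")
  expect_equal(fr$f_score[1], 0)
  expect_true(is.infinite(fr$f_score[2]))
  expect_equal(fr$rank, c(2L, 1L))
})

test_that("ranking ties break stably by feature position", {
  X <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = c(1, 1, 0, 0))
  X <- X + matrix(c(.01, -.01, .01, -.01), 4, 3)   # identical F by symmetry
  fr <- f_scores(X, c("NC", "NC", "AD", "AD"))
  expect_equal(fr$rank, rank(-fr$f_score, ties.method = "first"))
})

## small helper: simulated two-group GC feature matrix
make_features <- function(n_per = 5, T = 80, seed = 1) {
  part <- tiny_partition()
  coh <- simulate_cohort(part, n_per, n_per, T = T, seed = seed)
  ecms <- lapply(coh, pairwise_gc)
  list(X = gc_feature_matrix(ecms),
       labels = vapply(coh, function(s) s$group, character(1)),
       part = part)
}

test_that("a perfectly separating top feature yields accuracy 1 at k = 1", {
  set.seed(33)
  X <- cbind(sep = c(rnorm(6, -5, .1), rnorm(6, 5, .1)),
             noise = rnorm(12))
  labels <- rep(c("NC", "AD"), each = 6)
  out <- accuracy_vs_k(X, labels, k_grid = c(1, 2))
  expect_equal(out$accuracy[1], 1)
  expect_equal(out$best_k, 1L)
})

test_that("null features give chance-level accuracy across k", {
  set.seed(34)
  accs <- replicate(20, {
    X <- matrix(rnorm(20 * 100), 20)
    colnames(X) <- paste0("f", 1:100)
    labels <- rep(c("NC", "AD"), 10)
    out <- accuracy_vs_k(X, labels, k_grid = c(5, 25, 100))
    out$accuracy
  })
  expect_true(all(colMeans(t(accs)) > 0.2 & colMeans(t(accs)) < 0.8))
})

test_that("the accuracy curve is deterministic and rejects oversized k", {
  f <- make_features(seed = 40)
  a <- accuracy_vs_k(f$X, f$labels, k_grid = c(10, 50))
  b <- accuracy_vs_k(f$X, f$labels, k_grid = c(10, 50))
  expect_identical(a, b)
  expect_error(accuracy_vs_k(f$X, f$labels, k_grid = ncol(f$X) + 1),
               class = "gcflow_bad_k")
})

test_that("fold-wise identical rankings give exactly chosen_k consensus entries", {
  f <- make_features(seed = 41)
  ## widen class separation on 20 chosen features so every fold ranks
  ## them first regardless of the held-out subject
  strong <- sample(ncol(f$X), 20)
  f$X[f$labels == "AD", strong] <- f$X[f$labels == "AD", strong] + 50
  mask <- consensus_mask(f$X, f$labels, chosen_k = 20)
  expect_equal(mask$n_consensus, 20)
  expect_equal(sum(mask$mask), 20)
  expect_equal(unname(diag(mask$mask)), rep(0L, 12))
})

test_that("disjoint fold rankings yield an empty consensus with a warning", {
  ## sample 1 is an outlier that ruins f1's within-class variance: the
  ## fold holding sample 1 out ranks f1 first (near-perfect separation),
  ## every other fold ranks f2 first, so the top-1 intersection is empty
  X <- cbind(f1 = c(50, 1, -1, 1.0005, -1.001, 0.9995),
             f2 = c(0, 0.5, -0.4, 0.6, -0.5, 0.45))
  labels <- rep(c("NC", "AD"), 3)
  attr(X, "pairs") <- data.frame(source = c("a", "b"), target = c("b", "a"),
                                 row = c(1L, 2L), col = c(2L, 1L))
  attr(X, "roi_labels") <- c("a", "b")
  colnames(X) <- c("a->b", "b->a")
  ## confirm the fold rankings really disagree before asserting emptiness
  expect_equal(f_scores(X[-1, ], labels[-1])$rank[1], 1L)
  expect_equal(f_scores(X[-2, ], labels[-2])$rank[2], 1L)
  expect_warning(m <- consensus_mask(X, labels, chosen_k = 1),
                 "consensus set is empty")
  expect_equal(m$n_consensus, 0)
  expect_true(all(m$mask == 0))
})

test_that("consensus masks are nested in k when rankings agree across folds", {
  f <- make_features(seed = 42)
  strong <- order(-colMeans(abs(f$X)))[1:40]
  f$X[f$labels == "AD", strong] <-
    f$X[f$labels == "AD", strong] + outer(rep(50, sum(f$labels == "AD")),
                                          40:1)
  m1 <- consensus_mask(f$X, f$labels, chosen_k = 10)
  m2 <- consensus_mask(f$X, f$labels, chosen_k = 25)
  expect_true(all(m2$mask[m1$mask == 1] == 1))
})

test_that("per-fold ranking never sees the held-out subject", {
  f <- make_features(seed = 43)
  mask <- consensus_mask(f$X, f$labels, chosen_k = 30)
  ## perturbing one subject's features can only affect folds that train on
  ## it; the fold holding it out contributes the same top-k set, so a
  ## perturbation confined to the held-out subject leaves that fold's
  ## ranking unchanged — verified by recomputing fold 1's ranking directly
  tr <- 2:nrow(f$X)
  r_before <- f_scores(f$X[tr, ], f$labels[tr])
  X2 <- f$X
  X2[1, ] <- X2[1, ] + 1000
  r_after <- f_scores(X2[tr, ], f$labels[tr])
  expect_identical(r_before$rank, r_after$rank)
})

test_that("apply_mask zeroes exactly the complement of the mask support", {
  part <- tiny_partition()
  ecm <- rand_ecm(part, seed = 44)
  R <- 12
  set.seed(45)
  m <- matrix(rbinom(R * R, 1, 0.3), R, dimnames = list(part$roi, part$roi))
  diag(m) <- 0
  mask <- structure(list(mask = m, chosen_k = 10L, n_consensus = sum(m)),
                    class = "consensus_mask")
  out <- apply_mask(ecm, mask)
  expect_true(out$masked)
  expect_true(all(out$values[m == 0] == 0))
  expect_identical(out$values[m == 1], ecm$values[m == 1])
  full <- mask; full$mask <- 1 - diag(R); dimnames(full$mask) <- dimnames(m)
  expect_equal(apply_mask(ecm, full)$values, ecm$values)
  empty <- mask; empty$mask <- matrix(0L, R, R, dimnames = dimnames(m))
  expect_true(all(apply_mask(ecm, empty)$values == 0))
  bad <- mask; bad$mask <- m[1:6, 1:6]
  expect_error(apply_mask(ecm, bad), class = "gcflow_shape_mismatch")
})

test_that("planted group-contrast edges are enriched among consensus features", {
  part <- default_partition()
  ps <- vapply(1:8, function(s) {
    coh <- simulate_cohort(part, 8, 8, T = 190, seed = s,
                           params = list(ad_attenuation = 0.3))
    gt <- attr(coh, "ground_truth")
    ecms <- lapply(coh, pairwise_gc)
    X <- gc_feature_matrix(ecms)
    labels <- vapply(coh, function(x) x$group, character(1))
    mask <- consensus_mask(X, labels, chosen_k = 300)
    pl <- gt$coupling_nc$planted
    pl <- pl[pl$dn_incident, ]
    planted <- matrix(FALSE, 52, 52, dimnames = dimnames(mask$mask))
    planted[cbind(pl$source, pl$target)] <- TRUE
    off <- !diag(52)
    k_hit <- sum(mask$mask[off] == 1 & planted[off])
    phyper(k_hit - 1, sum(planted[off]), sum(!planted[off]),
           sum(mask$mask[off]), lower.tail = FALSE)
  }, numeric(1))
  expect_lt(median(ps), 0.01)
})
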