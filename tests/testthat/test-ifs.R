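test_that("a zero matrix yields all-zero indicators and inter-system sums", {
  part <- toy_partition()
  z <- eff_conn(matrix(0, 4, 4, dimnames = list(part$roi, part$roi)), "z")
  reg <- regional_ifs(z, part)
  expect_true(all(reg[, 4:11] == 0))
  inter <- intersystem_ifs(z, part)
  expect_equal(nrow(inter), 30)
  expect_true(all(inter$ifs == 0))
})

test_that("the 4-ROI toy matches the hand-enumerated edge sums", {
  ## a, b in MTL; c, d in DM; edges a->b = 2, c->a = 1, b->d = 3
  part <- toy_partition()
  m <- matrix(0, 4, 4, dimnames = list(part$roi, part$roi))
  m["a", "b"] <- 2; m["c", "a"] <- 1; m["b", "d"] <- 3
  reg <- regional_ifs(eff_conn(m, "toy"), part)
  row <- function(r) reg[reg$roi == r, ]
  expect_equal(row("b")$intra_in, 2)
  expect_equal(row("a")$intra_out, 2)
  expect_equal(row("a")$inter_in, 1)
  expect_equal(row("b")$inter_out, 3)
  expect_equal(row("b")$inter_in_out, 3)
  expect_equal(row("b")$intra_in_out, 2)
  expect_equal(row("a")$intra_inter_in, 1)   # intra_in 0 + inter_in 1

  inter <- intersystem_ifs(eff_conn(m, "toy"), part)
  get <- function(s, t) inter$ifs[inter$source_network == s &
                                    inter$target_network == t]
  expect_equal(get("MTL", "DM"), 3)
  expect_equal(get("DM", "MTL"), 1)
  expect_true(all(inter$ifs[!(inter$source_network %in% c("MTL", "DM") &
                                inter$target_network %in% c("MTL", "DM"))] == 0))
})

test_that("pairwise-sum identities hold exactly for every ROI", {
  part <- tiny_partition()
  reg <- regional_ifs(rand_ecm(part, seed = 3), part)
  expect_identical(reg$intra_in_out, reg$intra_in + reg$intra_out)
  expect_identical(reg$inter_in_out, reg$inter_in + reg$inter_out)
  expect_identical(reg$intra_inter_in, reg$intra_in + reg$inter_in)
  expect_identical(reg$intra_inter_out, reg$intra_out + reg$inter_out)
})

test_that("conservation: within-network in equals out; global flows balance", {
  for (s in 1:100) {
    part <- if (s %% 2) tiny_partition() else default_partition()
    ecm <- rand_ecm(part, seed = s)
    reg <- regional_ifs(ecm, part)
    for (nn in network_names()) {
      sub <- reg[reg$network == nn, ]
      expect_equal(sum(sub$intra_in), sum(sub$intra_out), tolerance = 1e-12)
    }
    inter <- intersystem_ifs(ecm, part)
    expect_equal(sum(reg$inter_in), sum(reg$inter_out), tolerance = 1e-12)
    expect_equal(sum(inter$ifs), sum(reg$inter_out), tolerance = 1e-12)
  }
})

test_that("pooled t matches an independent formula and handles degeneracy", {
  set.seed(11)
  nc <- rnorm(27, 1); ad <- rnorm(24, 0)
  gs <- group_compare(nc, ad)
  n1 <- 24; n0 <- 27
  sp <- sqrt(((n1 - 1) * var(ad) + (n0 - 1) * var(nc)) / (n1 + n0 - 2))
  t_oracle <- (mean(ad) - mean(nc)) / (sp * sqrt(1 / n1 + 1 / n0))
  expect_equal(gs$t, t_oracle, tolerance = 1e-10)
  expect_equal(gs$df, 49)
  expect_equal(gs$p, 2 * pt(-abs(t_oracle), 49), tolerance = 1e-10)
  expect_identical(gs$direction, "AD<NC")

  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- group_compare(c(1, 1), c(2, 2))
  expect_true(degen$infinite)
  expect_true(is.infinite(degen$t))
})

test_that("BH step-up matches the hand evaluation and edge cases", {
  out <- bh_fdr(c(0.001, 0.013, 0.04, 0.5, 0.9), q = 0.05)
  expect_identical(out$significant, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$cutoff, 0.013)
  expect_equal(out$p_adjusted, p.adjust(c(0.001, 0.013, 0.04, 0.5, 0.9), "BH"))

  all0 <- bh_fdr(rep(0, 4), 0.05)
  expect_true(all(all0$significant))
  expect_error(bh_fdr(numeric(0)), class = "gcflow_too_few")
  ## BH mask always equals thresholding at the returned cutoff
  set.seed(12)
  for (r in 1:20) {
    p <- runif(30)^2
    o <- bh_fdr(p, 0.05)
    expect_identical(o$significant, p <= o$cutoff & o$cutoff > 0)
    expect_identical(o$significant, o$p_adjusted <= 0.05)
  }
})

test_that("BH controls the false-discovery rate under a simulated null", {
  set.seed(13)
  fdp <- replicate(1000, {
    p <- runif(30)
    o <- bh_fdr(p, 0.05)
    if (any(o$significant)) 1 else 0   # full null: any rejection is FDP 1
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("correlations match the covariance formula, with exact affine r = 1", {
  x <- c(1, 2, 4, 8, 9.5)
  y <- 3 * x - 2
  cr <- correlate(x, y)
  expect_equal(cr$r, 1, tolerance = 1e-12)

  set.seed(14)
  a <- rnorm(24); b <- rnorm(24)
  cr2 <- correlate(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cr2$r, r_oracle, tolerance = 1e-12)
  expect_equal(cr2$fisher_z, atanh(r_oracle), tolerance = 1e-12)
})

test_that("independent indicators rarely show strong intra/inter correlation", {
  set.seed(15)
  hits <- replicate(100, abs(cor(rnorm(24), rnorm(24))) < 0.5)
  expect_gte(mean(hits), 0.9)
})

test_that("intra_inter_correlation extracts per-ROI correlations by group", {
  part <- toy_partition()
  set.seed(16)
  tabs <- lapply(1:10, function(i) {
    ecm <- rand_ecm(part, seed = 100 + i, subject_id = sprintf("s%02d", i))
    tab <- regional_ifs(ecm, part)
    tab$group <- if (i <= 5) "NC" else "AD"
    tab
  })
  tab <- do.call(rbind, tabs)
  out <- intra_inter_correlation(tab, c("a", "c"), group = "AD")
  expect_equal(nrow(out), 2)
  sub <- tab[tab$group == "AD" & tab$roi == "a", ]
  expect_equal(out$r[1], cor(sub$intra_in_out, sub$inter_in_out),
               tolerance = 1e-12)
  expect_equal(out$n[1], 5)
})

test_that("the correlation Z test matches the closed form and its null is normal", {
  expect_equal(compare_correlations(0.95, 27, 0.5, 24)$z,
               (atanh(0.95) - atanh(0.5)) / sqrt(1 / 24 + 1 / 21),
               tolerance = 1e-12)
  expect_equal(compare_correlations(0.95, 27, 0.5, 24)$z, 4.29,
               tolerance = 0.01)
  expect_equal(compare_correlations(0.4, 20, 0.4, 30)$z, 0)
  expect_equal(compare_correlations(0.4, 20, 0.4, 30)$p, 1)
  expect_error(compare_correlations(1, 20, 0.5, 20), class = "gcflow_bad_r")

  set.seed(17)
  rho <- 0.5
  zs <- replicate(500, {
    mk <- function(n) {
      x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      cor(x, y)
    }
    compare_correlations(mk(27), 27, mk(24), 24)$z
  })
  expect_gt(ks.test(zs, "pnorm")$p.value, 0.01)
})
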