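test_that("null coupling has no off-diagonal entries", {
  part <- tiny_partition()
  coup <- build_coupling(part, "null", seed = 1)
  A <- coup$A
  diag(A) <- 0
  expect_true(all(A == 0))
  expect_equal(nrow(coup$planted), 0)
})

test_that("degenerate attenuation (1.0) reproduces the control matrix", {
  part <- default_partition()
  ctrl <- build_coupling(part, "control", seed = 4)
  ad1 <- build_coupling(part, "ad", params = list(ad_attenuation = 1.0),
                        seed = 4)
  expect_identical(ad1$A, ctrl$A)
})

test_that("attenuation 0.5 exactly halves DN-incident couplings, leaves others", {
  part <- default_partition()
  ctrl <- build_coupling(part, "control", seed = 4)
  ad <- build_coupling(part, "ad", params = list(ad_attenuation = 0.5),
                       seed = 4)
  dn <- part$network %in% c("MTL", "DM", "Core")
  off <- !diag(52)
  incident <- (outer(dn, rep(TRUE, 52)) | outer(rep(TRUE, 52), dn)) & off
  expect_equal(ad$A[incident], 0.5 * ctrl$A[incident], tolerance = 1e-15)
  expect_identical(ad$A[!incident], ctrl$A[!incident])
})

test_that("AR(1) closed-form variance holds for the null process", {
  part <- toy_partition()
  coup <- build_coupling(part, "null", seed = 5)
  rec <- simulate_subject(coup, T = 5000, seed = 6)
  v_true <- 1 / (1 - diag(coup$A)^2)
  v_emp <- apply(rec$data, 2, var)
  expect_equal(unname(v_emp), unname(v_true), tolerance = 0.1)
})

test_that("simulation is bit-reproducible and seed-sensitive", {
  part <- tiny_partition()
  coup <- build_coupling(part, "control", seed = 7)
  a <- simulate_subject(coup, T = 100, seed = 8)
  b <- simulate_subject(coup, T = 100, seed = 8)
  expect_identical(a$data, b$data)
  c <- simulate_subject(coup, T = 100, seed = 9)
  expect_false(identical(a$data, c$data))
})

test_that("a neutral envelope reproduces the unmodulated simulation", {
  part <- tiny_partition()
  coup <- build_coupling(part, "control", seed = 10)
  sets <- list(data.frame(source = part$roi[1], target = part$roi[3]))
  mod <- list(sets = sets, envelopes = matrix(1, 100, 1))
  a <- simulate_subject(coup, T = 100, seed = 11, modulation = mod)
  b <- simulate_subject(coup, T = 100, seed = 11)
  expect_identical(a$data, b$data)
})

test_that("cohort defaults are 27 NC + 24 AD and deterministic in the master seed", {
  part <- default_partition()
  coh <- simulate_cohort(part, seed = 12)
  expect_length(coh, 51)
  groups <- vapply(coh, function(s) s$group, character(1))
  expect_equal(sum(groups == "NC"), 27)
  expect_equal(sum(groups == "AD"), 24)
  expect_equal(nrow(coh[[1]]$data), 190)
  expect_equal(coh[[1]]$tr_seconds, 2)

  small1 <- simulate_cohort(part, 2, 2, T = 60, seed = 1)
  small2 <- simulate_cohort(part, 2, 2, T = 60, seed = 1)
  small3 <- simulate_cohort(part, 2, 2, T = 60, seed = 2)
  expect_length(small1, 4)
  expect_equal(nrow(small1[[1]]$data), 60)
  expect_identical(small1[[1]]$data, small2[[1]]$data)
  expect_false(identical(small1[[1]]$data, small3[[1]]$data))
})

test_that("simulated series stay bounded over long horizons (stationarity)", {
  part <- tiny_partition()
  coup <- build_coupling(part, "control", seed = 13)
  rec <- simulate_subject(coup, T = 1900, seed = 14)   # 10x the usual length
  expect_lt(max(abs(rec$data)), 50)
})

test_that("optional smoothing is off by default and slows the series when on", {
  part <- tiny_partition()
  coup <- build_coupling(part, "control", seed = 17)
  plain <- simulate_subject(coup, T = 500, seed = 18)
  off <- simulate_subject(coup, T = 500, seed = 18, smooth_ma = 1)
  expect_identical(plain$data, off$data)
  smooth <- simulate_subject(coup, T = 500, seed = 18, smooth_ma = 5)
  lag1 <- function(m) mean(sapply(seq_len(ncol(m)), function(j)
    cor(m[-1, j], m[-nrow(m), j])))
  expect_gt(lag1(smooth$data), lag1(plain$data))
})

test_that("unstable coupling requests are rejected", {
  part <- toy_partition()
  coup <- build_coupling(part, "control", seed = 15)
  coup$A <- matrix(0.9, 4, 4, dimnames = dimnames(coup$A))
  expect_error(simulate_subject(coup, T = 50, seed = 1),
               class = "gcflow_unstable")
})

test_that("envelopes stay in range with slow spectral content", {
  set.seed(16)
  for (k in 1:5) {
    e <- envelope_series(600, tr_seconds = 2)
    expect_true(all(e >= 0.2 & e <= 1.8))
    sp <- abs(fft(e - mean(e)))[1:300]
    freqs <- (0:299) / (600 * 2)
    ## dominant spectral mass below 0.02 Hz
    expect_gt(sum(sp[freqs < 0.02]^2) / sum(sp^2), 0.9)
  }
})

test_that("planted-edge GC recovery: control coupling ranks edges above non-edges", {
  part <- default_partition()
  aucs <- vapply(1:5, function(s) {
    coup <- build_coupling(part, "control",
                           params = list(between_strength = 0.4), seed = s)
    rec <- simulate_subject(coup, T = 5000, seed = s + 100)
    F <- pairwise_gc(rec)$values
    planted <- matrix(FALSE, 52, 52, dimnames = dimnames(F))
    planted[cbind(coup$planted$source, coup$planted$target)] <- TRUE
    off <- !diag(52)
    roc_auc(F[off], ifelse(planted[off], "AD", "NC"))
  }, numeric(1))
  expect_gte(mean(aucs), 0.95)
})

test_that("mean GC over DN-incident planted edges grows with the coupling multiplier", {
  part <- default_partition()
  mean_gc <- function(mult) {
    vals <- vapply(1:20, function(s) {
      coup <- build_coupling(part, "ad", params = list(ad_attenuation = mult),
                             seed = s)
      rec <- simulate_subject(coup, T = 400, seed = s + 500)
      F <- pairwise_gc(rec)$values
      pl <- coup$planted[coup$planted$dn_incident, ]
      ctrl <- build_coupling(part, "control", seed = s)
      pl_all <- ctrl$planted[ctrl$planted$dn_incident, ]
      mean(F[cbind(pl_all$source, pl_all$target)])
    }, numeric(1))
    mean(vals)
  }
  ms <- vapply(c(0.3, 0.6, 1.0), mean_gc, numeric(1))
  expect_true(all(diff(ms) > 0))
})
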