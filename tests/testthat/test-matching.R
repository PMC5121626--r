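test_that("fingerprints are ratios with the noisy tail removed", {
  s <- c(1, 0.9, 0.8, 0.85, 0.9, 0.7, 0.6, 0.5)
  t_ms <- seq_along(s) * 3
  # post == pre: all-ones fingerprint
  fp <- make_fingerprint(s, s, n_drop = 2L)
  expect_equal(fp$ratio, rep(1, 6))
  expect_true(fp$valid)
  # 32-echo default drops 8, keeps 24
  p32 <- runif(32, 0.5, 1)
  expect_length(make_fingerprint(p32, p32)$ratio, 24L)
  # multiplicative decay common to both arms cancels exactly
  post <- s * 0.8
  dec <- exp(-t_ms / 40)
  fp1 <- make_fingerprint(s, post, n_drop = 2L)
  fp2 <- make_fingerprint(s * dec, post * dec, n_drop = 2L)
  expect_equal(fp1$ratio, fp2$ratio, tolerance = 1e-12)
  # non-positive pre signal on a kept echo flags the voxel invalid
  bad <- s; bad[3] <- 0
  expect_false(make_fingerprint(bad, post, n_drop = 2L)$valid)
  # a zero only in the dropped tail is harmless
  tail0 <- s; tail0[8] <- 0
  expect_true(make_fingerprint(tail0, post, n_drop = 2L)$valid)
})

test_that("in-plane smoothing is a unit-sum 3x3 Gaussian", {
  const <- array(3.7, c(8, 8, 2, 2))
  expect_equal(smooth_inplane(const), const, tolerance = 1e-12)
  # impulse response in the interior equals the kernel
  imp <- array(0, c(9, 9, 1, 1)); imp[5, 5, 1, 1] <- 1
  sm <- smooth_inplane(imp, sigma = 0.8)
  g1 <- exp(-((-1):1)^2 / (2 * 0.8^2)); k <- outer(g1, g1) / sum(outer(g1, g1))
  expect_equal(sm[4:6, 4:6, 1, 1], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # kernel sums to one
  expect_true(all(sm[-(4:6), , 1, 1] == 0))
  expect_error(smooth_inplane(array(1, c(2, 2, 1, 1))), "at least 3 x 3")
})

test_that("matching recovers exact rows and rejects degenerate input", {
  d <- tiny_dict()
  i <- 6L
  m <- match_voxel(d$entries[i, ], d)
  expect_equal(m$entry_index, i)
  expect_equal(m$bvf, d$params$bvf[i])
  expect_equal(m$radius, d$params$radius[i])
  expect_equal(m$sto2, d$params$sto2[i])
  expect_equal(m$r2, 1)
  expect_equal(m$chi2, 0)
  # constant fingerprint: SStot = 0, excluded
  mc <- match_voxel(rep(0.5, ncol(d$entries)), d)
  expect_true(mc$excluded)
  expect_identical(mc$r2, -Inf)
  # invalid fingerprint object
  bad <- make_fingerprint(rep(0, 8), rep(1, 8), n_drop = 2L)
  expect_true(match_voxel(bad, d)$excluded)
  expect_error(match_voxel(rep(1, 3), d), "does not match")
})

test_that("matching tolerates measurement noise in the sensitive regime", {
  # below ~1% blood volume, adjacent oxygenation entries differ by less than
  # the noise (the pre-contrast susceptibility contrast scales with BVf), so
  # same-row recovery is assessed over the fingerprint-sensitive entries
  d <- toy_dict()
  nkept <- ncol(d$entries)
  sens <- which(d$params$bvf >= 0.02)
  hits <- with_seed_test(101, {
    replicate(500, {
      i <- sample(sens, 1)
      fp <- d$entries[i, ] + rnorm(nkept, 0, 0.01)
      match_voxel(fp, d)$entry_index == i
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("ADC-aware matching searches the right hyperplane", {
  d <- tiny_dict_adc()
  idx600 <- which(d$params$adc == 600)[2]
  m <- match_voxel(d$entries[idx600, ], d, adc_measured = 580)
  expect_equal(m$entry_index, idx600)
  expect_equal(m$adc_plane, 600)
})

test_that("volume matching recovers a noise-free synthetic volume exactly", {
  d <- tiny_dict()
  shp <- c(4, 3, 1)
  idx <- array(rep_len(seq_len(nrow(d$entries)), prod(shp)), shp)
  ne <- length(d$manifest$sequence$echo_times)
  pre <- array(0, c(shp, ne)); post <- array(0, c(shp, ne))
  for (e in seq_len(ne)) {
    pre[, , , e] <- array(d$signals_pre[idx, e], shp)
    post[, , , e] <- array(d$signals_post[idx, e], shp)
  }
  maps <- match_volume(pre, post, NULL, d, smooth = FALSE)
  expect_equal(maps$bvf, array(d$params$bvf[idx], shp))
  expect_equal(maps$radius, array(d$params$radius[idx], shp))
  expect_equal(maps$sto2, array(d$params$sto2[idx], shp))
  expect_true(all(!maps$excluded))
  expect_equal(maps$r2, array(1, shp), tolerance = 1e-9)
  # a common per-voxel multiplicative factor changes nothing
  fac <- array(rep(runif(prod(shp), 0.5, 2), ne), c(shp, ne))
  maps2 <- match_volume(pre * fac, post * fac, NULL, d, smooth = FALSE)
  expect_identical(maps2$bvf, maps$bvf)
  expect_identical(maps2$radius, maps$radius)
  expect_equal(maps2$r2, maps$r2, tolerance = 1e-9)
  # all-zero volumes: every voxel excluded
  z <- array(0, c(shp, ne))
  expect_true(all(match_volume(z, z, NULL, d, smooth = FALSE)$excluded))
  expect_error(match_volume(pre, post[, 1:2, , , drop = FALSE], NULL, d),
               "different shapes")
})

test_that("exclusions grow monotonically with noise", {
  d <- tiny_dict()
  shp <- c(6, 6, 1)
  idx <- array(rep_len(seq_len(nrow(d$entries)), prod(shp)), shp)
  ne <- length(d$manifest$sequence$echo_times)
  base_pre <- array(0, c(shp, ne)); base_post <- array(0, c(shp, ne))
  for (e in seq_len(ne)) {
    base_pre[, , , e] <- array(d$signals_pre[idx, e], shp)
    base_post[, , , e] <- array(d$signals_post[idx, e], shp)
  }
  frac <- vapply(seq_along(sig <- c(0.005, 0.02, 0.08)), function(j) {
    with_seed_test(300 + j, {
      pre <- base_pre + array(rnorm(length(base_pre), 0, sig[j]), dim(base_pre))
      post <- base_post + array(rnorm(length(base_post), 0, sig[j]),
                                dim(base_post))
      mean(match_volume(pre, post, NULL, d, smooth = FALSE)$excluded)
    })
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})
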