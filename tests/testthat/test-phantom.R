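test_that("region masks partition the field of view and presets make sense", {
  for (kind in c("none", "stroke_like", "tumor_like")) {
    sp <- phantom_spec(shape = c(24L, 24L, 1L), lesion_kind = kind)
    expect_true(all(sort(unique(as.vector(phantom_labels_t(sp)))) %in% 0:3))
    r <- sp$regions
    if (kind == "stroke_like") {
      expect_lt(r$bvf[3], r$bvf[2])
      expect_lt(r$sto2[3], r$sto2[2])
      expect_gt(r$radius[3], r$radius[2])
    }
    if (kind == "tumor_like") {
      expect_gt(r$bvf[3], r$bvf[2])
      expect_lt(r$sto2[3], r$sto2[2])
    }
  }
})

test_that("exact-mode phantoms are reproducible and carry their truth", {
  d <- tiny_dict()
  regions <- data.frame(label = 1:2, name = c("a", "b"),
                        bvf = c(0.02, 0.05), radius = c(4, 8),
                        sto2 = c(0.6, 1.0), adc = c(800, 800),
                        t2 = c(60, 50))
  sp <- phantom_spec(shape = c(12L, 12L, 1L), regions = regions,
                     noise_sigma = 0.01, seed = 5)
  p1 <- generate_phantom(sp, d)
  p2 <- generate_phantom(sp, d)
  expect_identical(p1$pre4d, p2$pre4d)
  expect_identical(p1$post4d, p2$post4d)
  # T2 decay is present in the raw signals: first-echo signal < 1
  sel <- p1$roi_labels == 1
  e1 <- p1$pre4d[, , , 1][sel]
  expect_true(all(e1 < 1))
  # truth maps carry the region parameters
  expect_true(all(p1$truth$bvf[sel] == 0.02))
  expect_true(all(p1$truth$radius[p1$roi_labels == 2] == 8))
  expect_true(all(p1$adc_map[sel] == 800))
})

test_that("off-axis parameters are rejected in exact mode, snapped otherwise", {
  d <- tiny_dict()
  regions <- data.frame(label = 1L, name = "a", bvf = 0.033, radius = 4,
                        sto2 = 0.6, adc = 800, t2 = 60)
  sp <- phantom_spec(shape = c(8L, 8L, 1L), regions = regions)
  expect_error(generate_phantom(sp, d, exact = TRUE), "not on the dictionary")
  p <- generate_phantom(sp, d, exact = FALSE)
  expect_true(all(p$truth$bvf[p$roi_labels == 1] %in% c(0.02, 0.05)))
})

test_that("noise-free exact phantoms are recovered perfectly end to end", {
  d <- tiny_dict()
  regions <- data.frame(label = 1:3, name = c("a", "b", "c"),
                        bvf = c(0.02, 0.05, 0.02), radius = c(4, 8, 8),
                        sto2 = c(0.6, 1.0, 0.6), adc = rep(800, 3),
                        t2 = c(60, 55, 50))
  sp <- phantom_spec(shape = c(14L, 14L, 1L), regions = regions,
                     noise_sigma = 0)
  p <- generate_phantom(sp, d)
  maps <- match_volume(p$pre4d, p$post4d, p$adc_map, d, smooth = FALSE)
  inb <- p$roi_labels > 0
  expect_identical(maps$bvf[inb], p$truth$bvf[inb])
  expect_identical(maps$radius[inb], p$truth$radius[inb])
  expect_identical(maps$sto2[inb], p$truth$sto2[inb])
  expect_true(all(!maps$excluded[inb]))
  expect_true(all(maps$excluded[!inb]))  # background has no signal
})

test_that("recovery error grows gracefully with noise", {
  d <- tiny_dict()
  regions <- data.frame(label = 1:2, name = c("a", "b"),
                        bvf = c(0.02, 0.05), radius = c(4, 8),
                        sto2 = c(0.6, 1.0), adc = c(800, 800),
                        t2 = c(60, 50))
  rmse <- vapply(seq_along(sig <- c(0, 0.01, 0.06)), function(j) {
    sp <- phantom_spec(shape = c(10L, 10L, 1L), regions = regions,
                       noise_sigma = sig[j], seed = 7)
    p <- generate_phantom(sp, d)
    maps <- match_volume(p$pre4d, p$post4d, p$adc_map, d, smooth = FALSE,
                         r2_threshold = -Inf)
    inb <- is.finite(p$truth$bvf) & is.finite(maps$bvf)
    sqrt(mean((maps$bvf[inb] - p$truth$bvf[inb])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) >= 0))
  expect_equal(rmse[1], 0)
})

test_that("ROI reports summarize non-excluded voxels and flag empty ROIs", {
  shp <- c(6, 6, 1)
  labels <- array(0L, shp); labels[1:3, , 1] <- 1L; labels[4:6, , 1] <- 2L
  maps <- list(bvf = array(0.04, shp), radius = array(6, shp),
               sto2 = array(0.7, shp),
               excluded = array(FALSE, shp))
  maps$excluded[labels == 2] <- TRUE
  rep <- roi_report(maps, labels)
  r1 <- rep[rep$roi == 1 & rep$parameter == "bvf", ]
  expect_equal(r1$mean, 0.04)
  expect_equal(r1$sd, 0)          # uniform map
  expect_equal(r1$excluded_fraction, 0)
  r2 <- rep[rep$roi == 2 & rep$parameter == "bvf", ]
  expect_true(r2$flagged)          # ROI fully excluded
  expect_equal(r2$excluded_fraction, 1)
})
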