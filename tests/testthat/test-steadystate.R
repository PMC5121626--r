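phys <- physics_constants()
scale_uspio <- phys$gamma * phys$b0 * phys$delta_chi_uspio * 1e-6  # 1/s

test_that("relaxation-rate changes are recovered from log-linear decays", {
  te <- sequence_params()$echo_times
  pre <- exp(-te * 1e-3 * 20)
  post50 <- pre * exp(-te * 1e-3 * 50)
  expect_equal(delta_r2star(pre, post50, echo_times = te), 50)
  expect_equal(delta_r2(pre, post50, echo_times = te), 50)
  expect_equal(delta_r2star(pre, pre, echo_times = te), 0)
  expect_equal(delta_r2(pre, pre, echo_times = te), 0)
  bad <- pre; bad[3] <- -1
  expect_true(is.na(delta_r2star(pre, bad, echo_times = te)))
})

test_that("steady-state BVf is the algebraic inverse of the rate model", {
  expect_equal(bvf_steadystate(0, phys), 0)
  for (x in c(0.01, 0.05, 0.17))
    expect_equal(bvf_steadystate(scale_uspio * x / 3, phys), x)
  # plug-in value: gamma B0 dchi / 3 * 5% = 73.34 1/s maps back to 5%
  expect_equal(bvf_steadystate(73.34013, phys), 0.05, tolerance = 1e-6)
})

test_that("VSI follows its closed form and exclusion rule", {
  # full numeric case, computed by hand:
  # 0.867 * sqrt(800 / 4400.40790) * (60/15)^1.5 = 0.867*0.42638172*8
  expect_equal(vsi(60, 15, 800, phys), 2.9573836, tolerance = 1e-6)
  # substitution dR2* = dR2
  expect_equal(vsi(20, 20, 800, phys), 0.867 * sqrt(800 / scale_uspio))
  # scales as (dR2*/dR2)^(3/2)
  expect_equal(vsi(120, 15, 800, phys), 2^1.5 * vsi(60, 15, 800, phys))
  expect_true(is.na(vsi(60, 0, 800, phys)))
  expect_true(is.na(vsi(60, -3, 800, phys)))
})

test_that("simulated voxels sit near the static-dephasing plateau", {
  pair <- plateau_pair()  # BVf 5%, radius 5 um, ADC 800
  dr2s <- delta_r2star(pair$pre, pair$post)
  plateau <- scale_uspio * 0.05 / 3
  expect_lt(abs(dr2s - plateau) / plateau, 0.25)
  # irreversible component is smaller for small, diffusion-narrowed vessels
  dr2 <- delta_r2(pair$pre, pair$post)
  expect_gt(dr2, 0)
  expect_lt(dr2, dr2s)
})

test_that("qBOLD oxygenation fits invert their generative model", {
  te <- seq(4.5, 67.5, by = 4.5)  # multi-gradient-echo times, ms
  t2 <- 55; bvf <- 0.035
  gen <- function(sto2, hct = phys$hct) {
    A <- bvf * phys$gamma * phys$b0 * phys$delta_chi0 * 1e-6 * hct / 3
    1.7 * exp(-te / t2) * exp(-A * (1 - sto2) * te * 1e-3)
  }
  expect_equal(qbold_sto2(gen(0.70), te, t2, bvf, phys), 0.70,
               tolerance = 0.01)
  # fully oxygenated blood: decay rate is exactly 1/T2
  expect_equal(t2_fit(gen(1), te), t2, tolerance = 1e-9)
  expect_equal(qbold_sto2(gen(1), te, t2, bvf, phys), 1, tolerance = 1e-6)
  # hematocrit mismatch biases StO2 monotonically
  est <- vapply(c(0.357, 0.40, 0.42), function(h)
    qbold_sto2(gen(0.70, hct = h), te, t2, bvf, phys), numeric(1))
  expect_equal(est[1], 0.70, tolerance = 0.01)
  expect_true(all(diff(est) < 0))  # generating with higher Hct -> lower fit
  # out-of-range bvf is excluded
  expect_true(is.na(qbold_sto2(gen(0.7), te, t2, bvf = 0.3, phys)))
})

test_that("T2 fitting recovers mono-exponential decays", {
  te <- seq(12, 312, by = 12)
  expect_equal(t2_fit(100 * exp(-te / 48), te), 48, tolerance = 1e-9)
  expect_true(is.na(t2_fit(c(-1, 1, 1), c(1, 2, 3))))
})

test_that("validity ranges exclude out-of-range voxels exactly", {
  ex <- steadystate_exclusion(bvf = c(0.05, 0.18, -0.01, NA),
                              vsi = c(10, 10, 10, 10))
  expect_identical(ex, c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(steadystate_exclusion(vsi = c(49, 51)), c(FALSE, TRUE))
  expect_identical(steadystate_exclusion(adc = c(3400, 3600)), c(FALSE, TRUE))
  expect_identical(steadystate_exclusion(sto2 = c(0.5, 1.01)), c(FALSE, TRUE))
})

test_that("the volume wrapper maps exponential phantoms exactly", {
  te <- sequence_params()$echo_times
  shp <- c(3, 2, 1)
  k_true <- array(c(20, 40, 60, 80, 100, 120), shp)  # dR2* = dR2 = k
  ne <- length(te)
  pre <- array(rep(exp(-outer(array(10, shp), te * 1e-3)), 1), c(shp, ne))
  post <- pre * exp(-array(outer(k_true, te * 1e-3), c(shp, ne)))
  adc <- array(800, shp)
  maps <- steadystate_maps(pre, post, te, adc)
  expect_equal(maps$delta_r2_star, k_true, tolerance = 1e-9)
  expect_equal(maps$delta_r2, k_true, tolerance = 1e-9)
  expect_equal(maps$bvf_ss, 3 * k_true / scale_uspio, tolerance = 1e-9)
  expect_equal(maps$vsi, vsi(k_true, k_true, adc), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_false(any(maps$excluded))
})
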