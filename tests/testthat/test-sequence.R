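test_that("default sequence timing matches the GESFIDE layout", {
  s <- sequence_params()
  expect_equal(s$n_echoes, 32L)
  expect_equal(s$echo_times[1:8], 3.3 * (1:8))
  expect_equal(s$echo_times[9:32], 30 + 3.3 * (1:24))
  expect_error(sequence_params(n_fid = 10L), "precede the refocusing")
  expect_error(sequence_params(echo_times = c(5, 5, 10)),
               "strictly increasing")
})

test_that("evolution steps preserve the expected conserved quantities", {
  n <- 32L
  m0 <- matrix(complex(real = 1), n, n)
  omega0 <- matrix(0, n, n)
  # identity: no field, no diffusion
  expect_identical(evolve_step(m0, omega0, adc = 0, dt = 0.5), m0)
  # diffusion kernel conserves the total magnetization exactly
  m_r <- matrix(complex(real = runif(n * n), imaginary = runif(n * n)), n, n)
  m1 <- evolve_step(m_r, omega0, adc = 800, dt = 0.5, voxel_side = 100)
  expect_equal(sum(m1), sum(m_r), tolerance = 1e-12)
  # uniform field: global phase, magnitude of the sum unchanged
  w0 <- 100
  m2 <- evolve_step(m0, matrix(w0, n, n), adc = 0, dt = 0.5)
  expect_equal(m2, m0 * exp(-1i * w0 * 5e-4), tolerance = 1e-12)
  # oversized diffusion step is rejected
  expect_error(evolve_step(m0, omega0, adc = 1e9, dt = 0.5, voxel_side = 10),
               "unstable diffusion")
})

test_that("refocusing is an involution and realizes the Hahn echo", {
  m <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  expect_identical(apply_refocusing(apply_refocusing(m)), m)
  mr <- matrix(complex(real = rnorm(64)), 8, 8)
  expect_identical(apply_refocusing(mr), mr)
  # static dephasing: evolve tau, refocus, evolve tau -> full recovery
  omega <- matrix(rnorm(64, sd = 500), 8, 8)
  cache <- precompute_evolution(omega, adc = 0, dt = 0.5)
  m1 <- matrix(complex(real = 1), 8, 8)
  for (i in 1:20) m1 <- evolve_step(m1, cache = cache)
  m1 <- apply_refocusing(m1)
  for (i in 1:20) m1 <- evolve_step(m1, cache = cache)
  expect_equal(Mod(sum(m1)), 64, tolerance = 1e-9)
})

test_that("simulate_gesfide satisfies its limiting cases", {
  g <- build_microvessel_geometry(0.04, 6, 12L, 64L, seed = 3)
  s <- tiny_seq()
  # no susceptibility difference: unit signal at every echo (no decay model)
  flat <- simulate_gesfide(g, 0, adc = 800, seq = s)
  expect_equal(flat$signal, rep(1, s$n_echoes), tolerance = 1e-9)
  # determinism
  a <- simulate_gesfide(g, 1.2, adc = 800, seq = s)
  b <- simulate_gesfide(g, 1.2, adc = 800, seq = s)
  expect_identical(a$signal, b$signal)
  # sequence with no post-pulse echo is rejected
  expect_error(simulate_gesfide(g, 1, 0, sequence_params(
    echo_times = c(2, 4), se_time = 16)), "no echoes after")
})

test_that("with no diffusion the spin echo refocuses fully in both arms", {
  g <- build_microvessel_geometry(0.05, 5, 24L, 64L, seed = 7)
  s <- sequence_params(echo_times = c(4, 8, 16, 24), se_time = 16)
  pair <- simulate_pair(g, sto2 = 0.6, adc = 0, seq = s)
  i_se <- 3  # echo exactly at the spin-echo time
  expect_equal(pair$pre$signal[i_se], 1, tolerance = 1e-9)
  expect_equal(pair$post$signal[i_se], 1, tolerance = 1e-9)
  expect_equal(pair$post$signal[i_se] / pair$pre$signal[i_se], 1,
               tolerance = 0.005)
})

test_that("the pre/post pair responds to the contrast agent as expected", {
  g <- build_microvessel_geometry(0.05, 5, 24L, 64L, seed = 2)
  s <- tiny_seq()
  # no agent: identical arms
  p0 <- simulate_pair(g, 0.7, 800, s, physics_constants(delta_chi_uspio = 0))
  expect_identical(p0$pre$signal, p0$post$signal)
  # fully oxygenated blood: flat pre arm, decaying post arm
  p1 <- simulate_pair(g, 1, 800, s, physics_constants())
  expect_equal(p1$pre$signal, rep(1, s$n_echoes), tolerance = 1e-9)
  expect_lt(p1$post$signal[2], 0.999)
  # doubling the agent dose strengthens the FID dephasing (last FID echo)
  half <- simulate_pair(g, 1, 800, s, physics_constants(delta_chi_uspio = 1.75))
  full <- simulate_pair(g, 1, 800, s, physics_constants(delta_chi_uspio = 3.5))
  i_fid <- 2L  # last echo before the refocusing pulse in tiny_seq
  expect_lt(full$post$signal[i_fid], half$post$signal[i_fid])
})

test_that("spin-echo attenuation is non-increasing in ADC", {
  g <- build_microvessel_geometry(0.05, 5, 24L, 64L, seed = 5)
  s <- sequence_params(echo_times = c(4, 8, 16, 24), se_time = 16)
  se <- vapply(c(0, 400, 800, 1600), function(adc)
    simulate_gesfide(g, 2, adc, s)$signal[3], numeric(1))
  expect_true(all(diff(se) <= 1e-9))
})

test_that("echo signals are insensitive to lattice refinement", {
  # physics depends on (gamma delta_chi B0, ADC, geometry in um), not on the
  # lattice, once it resolves the vessels
  s <- tiny_seq()
  sig <- lapply(c(256L, 512L), function(n) {
    g <- build_microvessel_geometry(0.05, 8, 24L, n, seed = 11)
    simulate_gesfide(g, 1.5, 800, s)$signal
  })
  expect_lt(max(abs(sig[[1]] - sig[[2]])), 0.02)
})
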