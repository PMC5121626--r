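# Shared fixtures. Dictionaries are built once per test run and cached;
# everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Short sequence for fast unit tests: 8 echoes, pulse at 8 ms, SE at 16 ms.
tiny_seq <- function() sequence_params(n_echoes = 8L, delta_te = 3,
                                       se_time = 16, n_fid = 2L, dt = 0.5)

# The toy dictionary keeps the full acquisition timing (32 echoes, SE at
# 60 ms): discriminability between entries depends on sampling the whole
# spin-echo rebound, so the sequence is not shortened there.
toy_seq <- function() sequence_params()

tiny_grid <- function(adc = 800, lattice_n = 64L, base_seed = 11L)
  grid_spec(bvf_values = c(0.02, 0.05), radius_values = c(4, 8),
            sto2_values = c(0.6, 1.0), adc_values = adc,
            geometry_kind = "microvessel", n_vessels = 24L,
            lattice_n = lattice_n, base_seed = base_seed)

# 2 x 2 x 2 microvessel dictionary at 64^2 with the short sequence.
tiny_dict <- function() cached("tiny_dict", function()
  build_dictionary(tiny_grid(), seq = tiny_seq(), n_drop = 2L))

# Same grid with two ADC planes, for restrict_to_adc tests.
tiny_dict_adc <- function() cached("tiny_dict_adc", function()
  build_dictionary(tiny_grid(adc = c(600, 800)), seq = tiny_seq(),
                   n_drop = 2L))

# Toy 5 x 5 x 5 dictionary at 128^2: the microvessel dictionary's printed
# axis ranges (BVf 0.25-25 %, radius 0.5-100 um, StO2 0-100 %) at 5 nodes
# per axis. Used by the parameter-recovery and phantom acceptance checks.
toy_axes <- function() list(
  bvf = exp(seq(log(0.0025), log(0.25), length.out = 5)),
  radius = exp(seq(log(0.5), log(100), length.out = 5)),
  sto2 = seq(0, 1, length.out = 5))

toy_dict <- function() cached("toy_dict", function() {
  ax <- toy_axes()
  build_dictionary(
    grid_spec(bvf_values = ax$bvf, radius_values = ax$radius,
              sto2_values = ax$sto2, adc_values = 800,
              geometry_kind = "microvessel", n_vessels = 96L,
              lattice_n = 128L, base_seed = 42L),
    seq = toy_seq(), n_drop = 8L)
})

# Phantom region table sitting exactly on the toy dictionary axes:
# contralateral striatum-like tissue and a stroke-like lesion (lower BVf and
# StO2, larger vessels).
toy_regions <- function() {
  ax <- toy_axes()
  data.frame(label = c(1L, 2L, 3L),
             name = c("brain", "striatum_contra", "lesion"),
             bvf = c(ax$bvf[3], ax$bvf[3], ax$bvf[2]),
             radius = c(ax$radius[2], ax$radius[3], ax$radius[4]),
             sto2 = c(ax$sto2[4], ax$sto2[4], ax$sto2[2]),
             adc = c(800, 800, 800),
             t2 = c(60, 55, 50))
}

# One full-size pre/post pair (256^2, default sequence) shared by the
# steady-state plateau and ordering checks.
plateau_pair <- function() cached("plateau_pair", function() {
  g <- build_microvessel_geometry(0.05, 5, 96, 256, seed = 7)
  simulate_pair(g, sto2 = 1, adc = 800, seq = sequence_params())
})

# Independent per-point oracle for the field solver: scalar formulas with
# explicit polar coordinates, summed vessel by vessel.
oracle_field <- function(geometry, delta_chi, b0 = 4.7, gamma = 2.67502e8) {
  n <- geometry$lattice_n; L <- geometry$voxel_side
  A <- gamma * delta_chi * 1e-6 * b0
  co <- (seq_len(n) - 0.5) * (L / n)
  ras <- rasterize(geometry)
  out <- matrix(0, n, n)
  v <- geometry$vessels
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nrow(v))) {
      dx <- co[i] - v$cx[k]; dx <- dx - L * round(dx / L)
      dy <- co[j] - v$cy[k]; dy <- dy - L * round(dy / L)
      rho <- sqrt(dx^2 + dy^2)
      th <- v$theta[k] * pi / 180
      if (ras$labels[i, j] == k) {
        acc <- acc + (A / 6) * (3 * cos(th)^2 - 1)
      } else if (rho > v$radius[k]) {
        phip <- atan2(dy, dx) - v$phi[k] * pi / 180
        acc <- acc + (A / 2) * sin(th)^2 * (v$radius[k] / rho)^2 * cos(2 * phip)
      }
    }
    out[i, j] <- acc
  }
  out
}

# Normalized distance (in radii) to the nearest vessel, per lattice point.
vessel_distance_map <- function(geometry) {
  n <- geometry$lattice_n; L <- geometry$voxel_side
  co <- (seq_len(n) - 0.5) * (L / n)
  v <- geometry$vessels
  mind <- matrix(Inf, n, n)
  for (k in seq_len(nrow(v))) {
    dx <- min_image_h(co - v$cx[k], L)
    dy <- min_image_h(co - v$cy[k], L)
    d <- sqrt(outer(dx^2, dy^2, `+`)) / v$radius[k]
    mind <- pmin(mind, d)
  }
  mind
}

min_image_h <- function(d, L) d - L * round(d / L)

with_seed_test <- function(seed, expr) { set.seed(seed); expr }

phantom_labels_t <- function(sp) mrvf:::phantom_labels(sp$shape)
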