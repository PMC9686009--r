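# Shared fixtures, generated in code. Simulated pairs are cached per session
# because the FBP simulators are the slowest fixtures the suite uses.

.fixture_env <- new.env(parent = emptyenv())

# A simulated steel-insert pair (128 px, 1 mm) plus its phantom truth/masks.
steel_pair <- function(seed = 11) {
  key <- paste0("steel_", seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- phantom_spec(seed = seed, metal_inserts = list(
      list(position = NULL, radius = 3, material = "stainless_steel")))
    .fixture_env[[key]] <- simulate_pair(spec)
  }
  .fixture_env[[key]]
}

# A metal-free simulated pair.
clean_pair <- function(seed = 21) {
  key <- paste0("clean_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_pair(phantom_spec(seed = seed))
  }
  .fixture_env[[key]]
}

random_volume <- function(n = 16, modality = "kvct", seed = 1,
                          lo = -1000, hi = 3000) {
  set.seed(seed)
  image_volume(matrix(round(runif(n * n, lo, hi)), n), modality = modality)
}

# MV/CT paired training images for the toy translator benchmark:
# the CT side is a clamped phantom truth, the MV side the fixed monotone
# HU compression of it plus Gaussian noise.
toy_domain_pairs <- function(n, seed, shape = c(64, 64), noise_sd = 30) {
  spec_mv <- scaling_spec("P1", "MVCBCT")
  spec_ct <- scaling_spec("P1", "CT")
  a <- list(); b <- list(); ct_vols <- list(); mv_vols <- list()
  for (i in seq_len(n)) {
    ph <- make_phantom(phantom_spec(shape = shape, spacing = c(2, 2),
                                    seed = seed * 10000 + i))
    ct <- clamp_hu(ph$truth)
    set.seed(seed * 10000 + i)
    mvh <- mv_compress_hu(ct$values) +
      matrix(rnorm(prod(shape), sd = noise_sd), shape[1])
    mv <- clamp_hu(image_volume(mvh, spacing = c(2, 2), modality = "mvcbct"))
    a[[i]] <- forward_scale(mv, spec_mv)
    b[[i]] <- forward_scale(ct, spec_ct)
    ct_vols[[i]] <- ct; mv_vols[[i]] <- mv
  }
  list(a = a, b = b, ct = ct_vols, mv = mv_vols)
}
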