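#' Acquisition parameters for the slice simulators
#'
#' The kV side is polychromatic: the spectrum is approximated by a few
#' discrete energy bins (versioned constants file `kv_spectrum_v1.csv`),
#' each with a water attenuation coefficient and hardening factors for bone
#' and metal; this produces beam hardening. Photon starvation comes from
#' Poisson counting statistics at finite `kv_fluence` with a one-count
#' detector floor. The MV side is monochromatic (no hardening) with a lower
#' fluence (more noise) and a compressed soft-tissue contrast.
#'
#' @param n_angles number of parallel-beam projection angles over 180 deg.
#' @param kv_fluence photons per detector bin for the kV acquisition.
#' @param kv_spectrum data.frame with columns `energy_kev`, `weight`
#'   (summing to 1), `mu_water_mm`, `harden_bone`, `harden_metal`.
#' @param mv_fluence photons per detector bin for the MV acquisition
#'   (lower than `kv_fluence`: MV-CBCT is the noisier modality).
#' @param mv_mu_water water attenuation at the MV energy, per mm.
#' @param mv_contrast soft-tissue contrast compression factor applied to
#'   the MV-energy ground truth (1 = kV contrast).
#' @return an object of class `mvmar_acq`.
#' @export
acquisition_params <- function(n_angles = 180,
                               kv_fluence = 1e6,
                               kv_spectrum = NULL,
                               mv_fluence = 8e5,
                               mv_mu_water = 0.005,
                               mv_contrast = 0.6) {
  if (is.null(kv_spectrum)) {
    kv_spectrum <- read.csv(system.file("extdata", "kv_spectrum_v1.csv",
                                        package = "mvmar", mustWork = TRUE))
  }
  stopifnot(kv_fluence > 0, mv_fluence > 0, n_angles >= 1)
  if (abs(sum(kv_spectrum$weight) - 1) > 1e-8)
    stop("spectrum bin weights must sum to 1")
  structure(list(n_angles = as.integer(n_angles), kv_fluence = kv_fluence,
                 kv_spectrum = kv_spectrum, mv_fluence = mv_fluence,
                 mv_mu_water = mv_mu_water, mv_contrast = mv_contrast),
            class = "mvmar_acq")
}

# Ramp-filtered FBP of a sinogram (ndet x nang, line integrals per mm
# multiplied by detector sampling = spacing). Returns attenuation per mm.
fbp_reconstruct <- function(sino, angles, n, spacing) {
  ndet <- nrow(sino)
  m <- 2^ceiling(log2(2 * ndet))
  # frequency response of the real-space ramp kernel (correct DC handling)
  k <- c(0:(m / 2 - 1), -(m / 2):-1)
  h <- numeric(m)
  h[1] <- 0.25
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd])^2
  ramp <- 2 * Re(fft(h))
  pad <- rbind(sino, matrix(0, m - ndet, ncol(sino)))
  filt <- Re(stats::mvfft(stats::mvfft(pad) * ramp, inverse = TRUE)) / m
  filt <- filt[seq_len(ndet), , drop = FALSE]
  rec <- cpp_backproject(filt, angles, n) * pi / (2 * length(angles))
  rec / spacing
}

# Map an HU image to attenuation (per mm) at one spectral bin. `harden` is
# the bin's hardening multiplier on the HU excess for bone / metal pixels.
hu_to_mu_bin <- function(hu, mu_water, harden_bone, harden_metal) {
  c_fac <- matrix(1, nrow(hu), ncol(hu))
  c_fac[hu > 150 & hu < 2500] <- harden_bone
  c_fac[hu >= 2500] <- harden_metal
  pmax(mu_water * (1 + hu / 1000 * c_fac), 0)
}

#' Simulate a kV-CT acquisition of a ground-truth slice
#'
#' Forward model: per spectral bin, HU is mapped to attenuation and
#' projected with a parallel-beam Radon transform (180 angles by default);
#' the polychromatic transmission is summed over bins, Poisson noise is
#' applied at the stated fluence with a one-count floor (photon
#' starvation), and the log-transformed projections are passed through a
#' water-equivalent beam-hardening precorrection (the standard scanner
#' calibration) before ramp-filtered back-projection. Soft tissue
#' therefore reconstructs accurately while bone and especially metal
#' produce the bright/dark streaks characteristic of kV metal artifacts.
#'
#' @param truth ground-truth [image_volume()] (2-D slice, kV HU).
#' @param acq an [acquisition_params()].
#' @param seed integer seed for the Poisson noise.
#' @return simulated kV-CT [image_volume()], clamped to \[-1000, 3000\].
#' @export
simulate_kvct <- function(truth, acq = acquisition_params(), seed = 1) {
  stopifnot(inherits(truth, "mvmar_volume"), inherits(acq, "mvmar_acq"))
  if (length(dim(truth$values)) != 2L) stop("truth must be a 2-D slice")
  sp <- mean(truth$spacing)
  n <- nrow(truth$values)
  angles <- seq(0, pi, length.out = acq$n_angles + 1)[-(acq$n_angles + 1)]
  spec <- acq$kv_spectrum
  mu_ref <- sum(spec$weight * spec$mu_water_mm)
  trans <- 0
  for (b in seq_len(nrow(spec))) {
    mu_b <- hu_to_mu_bin(truth$values, spec$mu_water_mm[b],
                         spec$harden_bone[b], spec$harden_metal[b])
    L_b <- cpp_radon(mu_b, angles, 0) * sp
    trans <- trans + spec$weight[b] * exp(-L_b)
  }
  counts <- with_seed(seed, {
    matrix(rpois(length(trans), acq$kv_fluence * trans), nrow(trans))
  })
  counts <- pmax(counts, 1)  # detector floor: photon starvation
  p <- -log(counts / acq$kv_fluence)
  # water precorrection: invert the polychromatic water response
  Lgrid <- seq(0, 6 * n * sp, length.out = 6144)
  p_water <- -log(colSums(spec$weight *
                  exp(-outer(spec$mu_water_mm, Lgrid))))
  L_eq <- matrix(approx(p_water, Lgrid, xout = as.vector(p), rule = 2)$y,
                 nrow(p))
  p_corr <- mu_ref * L_eq
  mu_rec <- fbp_reconstruct(p_corr, angles, n, sp)
  hu <- 1000 * (mu_rec / mu_ref - 1)
  clamp_hu(image_volume(hu, spacing = truth$spacing, origin = truth$origin,
                        modality = "kvct"))
}

#' MV-energy ground truth from a kV ground truth
#'
#' Fixed piecewise-linear HU compression mapping the kV HU scale onto the
#' MV-CBCT scale (Compton-dominated contrast, capped at 1400 HU). The
#' soft-tissue section slope is the `contrast` factor.
#'
#' @param hu numeric array of kV HU.
#' @param contrast soft-tissue compression factor in (0, 1\].
#' @return array of MV-scale HU, capped at 1400.
#' @export
mv_compress_hu <- function(hu, contrast = 0.6) {
  kv <- c(-1000, -200, 150, 800, 1500, 2400, 3000, 4200)
  mv <- c(-1000, -200 * contrast, 150 * contrast, 500, 900, 1150, 1300, 1400)
  out <- approx(kv, mv, xout = as.vector(hu), rule = 2)$y
  array(pmin(out, 1400), dim = dim(hu))
}

#' Simulate an MV-CBCT acquisition of a ground-truth slice
#'
#' Monochromatic high-energy forward model: the kV ground truth is mapped
#' to the MV HU scale with [mv_compress_hu()], projected, degraded with
#' Poisson noise at the (lower) MV fluence, and reconstructed with the same
#' ramp-filtered back-projection. There is no spectral hardening, so metal
#' produces no streaks; the image is noisier than the kV simulation and is
#' clamped to \[-1000, 1400\].
#'
#' @inheritParams simulate_kvct
#' @return simulated MV-CBCT [image_volume()], values never above 1400 HU.
#' @export
simulate_mvcbct <- function(truth, acq = acquisition_params(), seed = 1) {
  stopifnot(inherits(truth, "mvmar_volume"), inherits(acq, "mvmar_acq"))
  if (length(dim(truth$values)) != 2L) stop("truth must be a 2-D slice")
  sp <- mean(truth$spacing)
  n <- nrow(truth$values)
  angles <- seq(0, pi, length.out = acq$n_angles + 1)[-(acq$n_angles + 1)]
  hu_mv <- mv_compress_hu(truth$values, acq$mv_contrast)
  mu <- pmax(acq$mv_mu_water * (1 + hu_mv / 1000), 0)
  L <- cpp_radon(mu, angles, 0) * sp
  counts <- with_seed(seed + 1L, {
    matrix(rpois(length(L), acq$mv_fluence * exp(-L)), nrow(L))
  })
  counts <- pmax(counts, 1)
  p <- -log(counts / acq$mv_fluence)
  mu_rec <- fbp_reconstruct(p, angles, n, sp)
  hu <- 1000 * (mu_rec / acq$mv_mu_water - 1)
  clamp_hu(image_volume(hu, spacing = truth$spacing, origin = truth$origin,
                        modality = "mvcbct"))
}

#' Simulate a paired phantom case
#'
#' Convenience wrapper: builds the phantom and runs both simulators on it,
#' giving an intrinsically registered kV-CT / MV-CBCT pair with ground
#' truth and masks.
#'
#' @param spec a [phantom_spec()].
#' @param acq an [acquisition_params()].
#' @return an object of class `mvmar_pair`: list with `truth`, `ct`, `mv`
#'   ([image_volume()]s on one grid), `masks`, `has_metal`.
#' @export
simulate_pair <- function(spec, acq = acquisition_params()) {
  ph <- make_phantom(spec)
  ct <- simulate_kvct(ph$truth, acq, seed = spec$seed)
  mv <- simulate_mvcbct(ph$truth, acq, seed = spec$seed)
  structure(list(truth = ph$truth, ct = ct, mv = mv, masks = ph$masks,
                 has_metal = any(ph$masks$metal$mask)),
            class = "mvmar_pair")
}

#' Generate a dataset of paired phantom cases
#'
#' Draws `n_cases` seeded phantoms, the first `round(n_cases *
#' metal_fraction)` of which carry one metal insert (material cycling
#' through aluminium alloy, titanium alloy, stainless steel), simulates
#' both modalities, optionally writes NIfTI volumes plus a JSON manifest,
#' and returns the pairs. Per-case seeds are `seed * 1000 + case index`,
#' so the whole dataset is reproducible from `seed` and two runs with the
#' same seed produce byte-identical manifests.
#'
#' @param n_cases number of cases (>= 1).
#' @param metal_fraction fraction of cases with a metal insert; the count
#'   is `round(n_cases * metal_fraction)`.
#' @param out_dir optional output directory; when given, volumes and masks
#'   are written as NIfTI and a `manifest.json` records per-case seed,
#'   metal flag and file paths.
#' @param seed master seed.
#' @param shape,spacing phantom grid geometry.
#' @param acq an [acquisition_params()].
#' @return invisible list of `mvmar_pair` objects (with `$manifest`
#'   attribute when `out_dir` is set).
#' @export
make_dataset <- function(n_cases, metal_fraction = 0, out_dir = NULL,
                         seed = 1, shape = c(128, 128), spacing = c(1, 1),
                         acq = acquisition_params()) {
  stopifnot(n_cases >= 1)
  n_metal <- round(n_cases * metal_fraction)
  materials <- c("stainless_steel", "titanium_alloy", "aluminium_alloy")
  pairs <- vector("list", n_cases)
  manifest <- list(master_seed = seed, n_cases = n_cases,
                   n_metal = n_metal,
                   metal_count_rule = "round(n_cases * metal_fraction)",
                   cases = list())
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (i in seq_len(n_cases)) {
    case_seed <- seed * 1000L + i
    inserts <- list()
    if (i <= n_metal) {
      mat <- materials[[1L + (i - 1L) %% 3L]]
      rad <- with_seed(case_seed, runif(1, 2.5, 3.5))
      inserts <- list(list(position = NULL, radius = rad, material = mat))
    }
    sp <- phantom_spec(shape = shape, spacing = spacing,
                       metal_inserts = inserts, seed = case_seed)
    pr <- simulate_pair(sp, acq)
    pairs[[i]] <- pr
    entry <- list(case = i, seed = case_seed, has_metal = i <= n_metal,
                  material = if (i <= n_metal) inserts[[1]]$material else NA)
    if (!is.null(out_dir)) {
      base <- sprintf("case%03d", i)
      paths <- list(truth = file.path(out_dir, paste0(base, "_truth.nii.gz")),
                    ct = file.path(out_dir, paste0(base, "_ct.nii.gz")),
                    mv = file.path(out_dir, paste0(base, "_mv.nii.gz")))
      write_volume(pr$truth, paths$truth)
      write_volume(pr$ct, paths$ct)
      write_volume(pr$mv, paths$mv)
      for (mn in names(pr$masks)) {
        mp <- file.path(out_dir, sprintf("%s_mask_%s.nii.gz", base, mn))
        write_mask(pr$masks[[mn]], mp)
        paths[[paste0("mask_", mn)]] <- mp
      }
      entry$paths <- lapply(paths, basename)
    }
    manifest$cases[[i]] <- entry
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    attr(pairs, "manifest") <- file.path(out_dir, "manifest.json")
  }
  invisible(pairs)
}
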