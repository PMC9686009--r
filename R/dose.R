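#' Dose grids
#'
#' @param dose non-negative numeric matrix (cGy).
#' @param spacing mm per axis.
#' @param origin physical origin, mm.
#' @param prescription prescription dose, cGy (> 0).
#' @return an object of class `mvmar_dose`.
#' @export
dose_grid <- function(dose, spacing = c(1, 1), origin = c(0, 0),
                      prescription = 6000) {
  stopifnot(is.matrix(dose), prescription > 0)
  if (any(dose < 0)) stop("dose must be non-negative everywhere")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  structure(list(dose = dose, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), prescription = prescription),
            class = "mvmar_dose")
}

as_dose <- function(x) if (inherits(x, "mvmar_dose")) x$dose else x

# Rotate a matrix about its centre by `theta` (radians) with bilinear
# interpolation; multiples of 90 degrees take exact index paths.
rotate_mat <- function(m, theta, fill = 0) {
  q <- (theta / (pi / 2)) %% 4
  if (abs(q - round(q)) < 1e-12) {
    out <- m
    k <- round(q) %% 4
    while (k > 0) { out <- t(apply(out, 2, rev)); k <- k - 1 }
    return(out)
  }
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  r <- matrix(seq_len(nr) - 1, nr, nc) - cr
  c <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - cc
  ca <- cos(theta); sa <- sin(theta)
  rs <- ca * r - sa * c + cr
  cs <- sa * r + ca * c + cc
  matrix(cpp_bilinear_sample(m, as.vector(rs), as.vector(cs), fill), nr, nc)
}

#' Toy exponential-attenuation dose engine
#'
#' A documented, deliberately simple photon model sufficient to make
#' electron-density differences move DVH metrics: each coplanar beam
#' deposits `exp(-k * radiological depth)` along its rays, where the
#' radiological depth to a voxel centre is the cumulative RED-weighted
#' path length from the grid edge, and the summed beam pattern is scaled
#' so the dose at `norm_point` (grid centre by default) equals the
#' prescription. No scatter kernel, no buildup, no divergence.
#'
#' @param red numeric matrix of relative electron densities.
#' @param beam_angles beam directions in degrees (0 = down the rows);
#'   default four coplanar fields.
#' @param k linear attenuation per mm per unit RED (default 0.005).
#' @param spacing mm per pixel.
#' @param prescription prescription dose, cGy.
#' @param norm_point `c(row, col)` pixel receiving exactly the
#'   prescription; defaults to the grid centre.
#' @return an [dose_grid()].
#' @export
toy_dose <- function(red, beam_angles = c(0, 90, 180, 270), k = 0.005,
                     spacing = c(1, 1), prescription = 6000,
                     norm_point = NULL) {
  red <- as_values(red)
  if (length(beam_angles) == 0) stop("zero beams")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  total <- matrix(0, nrow(red), ncol(red))
  for (ang in beam_angles) {
    th <- ang * pi / 180
    r_rot <- rotate_mat(red, th, fill = 0)
    # depth to voxel centre along columns of the rotated frame
    depth <- (apply(r_rot, 2, cumsum) - r_rot / 2) * spacing[1]
    contrib <- exp(-k * depth)
    total <- total + rotate_mat(contrib, -th, fill = 0)
  }
  if (is.null(norm_point)) norm_point <- round(dim(red) / 2)
  ref <- total[norm_point[1], norm_point[2]]
  if (ref <= 0) stop("normalisation point receives no dose")
  dose_grid(total * (prescription / ref), spacing = spacing,
            prescription = prescription)
}

#' Gamma-analysis criteria
#'
#' @param dta distance-to-agreement, mm (> 0).
#' @param dose_diff dose-difference criterion, percent of the
#'   normalisation dose (> 0).
#' @param normalization `"global-max"` (gamma normalised to the reference
#'   maximum, the common global-gamma convention) or `"prescription"`.
#' @param low_dose_cutoff percent of the normalisation dose below which
#'   reference points are excluded (default 0: evaluate everything).
#' @return an object of class `mvmar_gamma_criteria`.
#' @export
gamma_criteria <- function(dta = 2, dose_diff = 2,
                           normalization = c("global-max", "prescription"),
                           low_dose_cutoff = 0) {
  stopifnot(dta > 0, dose_diff > 0)
  structure(list(dta = dta, dose_diff = dose_diff,
                 normalization = match.arg(normalization),
                 low_dose_cutoff = low_dose_cutoff),
            class = "mvmar_gamma_criteria")
}

#' Global gamma analysis
#'
#' For each evaluated reference point, gamma is the minimum over test
#' points of sqrt((distance/dta)^2 + (dose difference / (dose_diff% of
#' Dnorm))^2); a point passes when gamma <= 1. The search enumerates grid
#' offsets in order of increasing distance and stops once the pure
#' distance term exceeds the worst running minimum, which makes the result
#' exactly equal to an exhaustive search over all test points. Grids with
#' unequal spacing are resampled to the finer spacing first. With
#' `refine`, the test grid is bilinearly upsampled by that factor before
#' the search (finer interpolation can only increase the pass rate).
#'
#' @param ref,test [dose_grid()]s.
#' @param crit a [gamma_criteria()].
#' @param refine integer upsampling factor for the test grid (1 = off).
#' @return list with `pass_rate` (percent), `gamma` (matrix, `NA` where
#'   excluded by the cutoff), and `n_evaluated`.
#' @export
gamma_pass_rate <- function(ref, test, crit = gamma_criteria(), refine = 1) {
  stopifnot(inherits(ref, "mvmar_dose"), inherits(test, "mvmar_dose"))
  rd <- ref$dose; td <- test$dose
  sp <- ref$spacing
  if (any(abs(ref$spacing - test$spacing) > 1e-9)) {
    fine <- pmin(ref$spacing, test$spacing)
    rs <- function(d, s) {
      v <- image_volume(d$dose, spacing = d$spacing, modality = "kvct")
      resample_crop(v, fine, round(dim(d$dose) * d$spacing / fine),
                    fill = 0)$values
    }
    rd <- rs(ref, fine); td <- rs(test, fine); sp <- fine
  }
  tsp <- sp
  if (refine > 1) {
    v <- image_volume(td, spacing = sp, modality = "kvct")
    tsp <- sp / refine
    td <- resample_crop(v, tsp, (dim(td) - 1) * refine + 1,
                        center = v$origin + (dim(td) - 1) / 2 * sp,
                        fill = 0)$values
  }
  dnorm_val <- if (crit$normalization == "global-max") max(rd)
               else ref$prescription
  den <- crit$dose_diff / 100 * dnorm_val
  evaluated <- rd >= crit$low_dose_cutoff / 100 * dnorm_val
  if (!any(evaluated)) stop("no evaluable reference points after cutoff")
  nr <- nrow(rd); nc <- ncol(rd)
  ntr <- nrow(td); ntc <- ncol(td)
  # offsets of test-grid nodes relative to each ref node, in test-grid steps
  scale_r <- sp[1] / tsp[1]; scale_c <- sp[2] / tsp[2]
  max_off_r <- ntr - 1; max_off_c <- ntc - 1
  offs <- expand.grid(dr = -max_off_r:max_off_r, dc = -max_off_c:max_off_c)
  offs$d2 <- (offs$dr * tsp[1])^2 + (offs$dc * tsp[2])^2
  offs <- offs[order(offs$d2), ]
  g2 <- matrix(Inf, nr, nc)
  rid <- matrix(seq_len(nr), nr, nc)
  cid <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  base_r <- (rid - 1) * scale_r + 1  # ref node position on test grid
  base_c <- (cid - 1) * scale_c + 1
  for (i in seq_len(nrow(offs))) {
    dterm <- offs$d2[i] / crit$dta^2
    worst <- suppressWarnings(max(g2[evaluated]))
    if (dterm >= worst) break
    tr <- round(base_r + offs$dr[i])
    tc <- round(base_c + offs$dc[i])
    ok <- tr >= 1 & tr <= ntr & tc >= 1 & tc <= ntc
    if (!any(ok)) next
    idx <- cbind(tr[ok], tc[ok])
    cand <- dterm + ((rd[ok] - td[idx]) / den)^2
    g2[ok] <- pmin(g2[ok], cand)
  }
  gam <- sqrt(g2)
  gam[!evaluated] <- NA
  list(pass_rate = 100 * mean(gam[evaluated] <= 1),
       gamma = gam, n_evaluated = sum(evaluated))
}

#' DVH metrics for one structure
#'
#' `Dx` is the dose exceeded by exactly x% of the ROI volume (interpolated
#' between sorted voxels), `Vx%` the percentage of the ROI receiving at
#' least x% of the prescription, `D0.1cc` the dose exceeded by 0.1 cm3 of
#' the ROI (reported as the maximum with a warning when the ROI is smaller
#' than 0.1 cm3). Slices are treated as having `thickness_mm` extent.
#'
#' @param dose an [dose_grid()].
#' @param roi an [structure_mask()] (or logical matrix), nonempty.
#' @param prescription cGy; defaults to the grid's prescription.
#' @param thickness_mm slice thickness used for voxel volume, mm.
#' @return one-row data.frame: Dmean, D2, D5, D50, D95, D0.1cc (cGy),
#'   V95, V100, V110 (percent).
#' @export
dvh_metrics <- function(dose, roi, prescription = NULL, thickness_mm = 1) {
  stopifnot(inherits(dose, "mvmar_dose"))
  m <- if (inherits(roi, "mvmar_mask")) roi$mask else roi
  if (!identical(dim(m), dim(dose$dose))) stop("ROI/dose shape mismatch")
  if (!any(m)) stop("empty ROI")
  prescription <- prescription %||% dose$prescription
  d <- dose$dose[m]
  dx <- function(x) unname(quantile(d, 1 - x / 100, type = 7))
  vx <- function(x) 100 * mean(d >= x / 100 * prescription)
  vox_cc <- prod(dose$spacing) * thickness_mm / 1000
  roi_cc <- length(d) * vox_cc
  d01 <- if (roi_cc < 0.1) {
    warning("ROI smaller than 0.1 cc; D0.1cc reported as Dmax")
    max(d)
  } else dx(100 * 0.1 / roi_cc)
  data.frame(Dmean = mean(d), D2 = dx(2), D5 = dx(5), D50 = dx(50),
             D95 = dx(95), D0.1cc = d01, V95 = vx(95), V100 = vx(100),
             V110 = vx(110), check.names = FALSE)
}

# metric schema per ROI, mirroring the clinical evaluation protocol
dose_metric_schema <- function() {
  list(ptv = c("Dmean", "D5", "D95", "V95", "V100", "V110"),
       mandible = c("D2", "Dmean"),
       oral_cavity = c("D50", "Dmean"),
       parotid = c("D50", "Dmean"),
       spinal_cord = c("D0.1cc"))
}

#' Compare plans computed on two images
#'
#' Tabulates per-ROI absolute differences of the DVH metrics between a
#' dose grid computed on the reference image and one computed on the test
#' image (same beam specification). The metric set per ROI follows the
#' clinical protocol: PTV Dmean/D5/D95/V95/V100/V110, mandible D2/Dmean,
#' oral cavity and parotid D50/Dmean, spinal cord D0.1cc; ROIs absent
#' from `rois` are skipped.
#'
#' @param ref_dose,test_dose [dose_grid()]s from the same beam spec.
#' @param rois named list of [structure_mask()]s (names matched against
#'   ptv, mandible, oral_cavity, parotid, spinal_cord).
#' @param thickness_mm slice thickness for voxel volume.
#' @return data.frame with columns roi, metric, ref, test, abs_diff.
#' @export
dose_compare <- function(ref_dose, test_dose, rois, thickness_mm = 1) {
  schema <- dose_metric_schema()
  rows <- list()
  for (rn in names(schema)) {
    if (is.null(rois[[rn]])) next
    roi <- rois[[rn]]
    m <- if (inherits(roi, "mvmar_mask")) roi$mask else roi
    if (!any(m)) next
    a <- dvh_metrics(ref_dose, roi, thickness_mm = thickness_mm)
    b <- dvh_metrics(test_dose, roi, thickness_mm = thickness_mm)
    for (met in schema[[rn]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        roi = rn, metric = met, ref = a[[met]], test = b[[met]],
        abs_diff = abs(a[[met]] - b[[met]]))
    }
  }
  do.call(rbind, rows)
}
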