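#' Phantom specification
#'
#' Parameters of a head-like 2-D digital phantom covering the
#' temporomandibular-joint-to-mandible region: an elliptical head outline,
#' a mandible arc, a row of teeth, an oral cavity, two parotid glands and a
#' spinal cord, with optional cylindrical metal inserts (dental implants).
#' Anatomy sizes are jittered a few percent per seed so a dataset of
#' phantoms is not a single repeated image.
#'
#' Metal materials and their ground-truth kV HU / relative electron density:
#' aluminium alloy (3000 HU, RED 2.43), titanium alloy (3600 HU, RED 3.73),
#' stainless steel (4200 HU, RED 6.83). Metal HU is assigned pre-clamp; a
#' clamped kV-CT volume saturates at 3000 HU as a 12-bit scanner would.
#'
#' @param shape grid shape in pixels (rows, cols); default 128 x 128.
#' @param spacing pixel spacing in mm; default 1 mm.
#' @param metal_inserts list of inserts, each
#'   `list(position = c(row_mm, col_mm) relative to grid centre,
#'   radius = mm, material = "aluminium_alloy"|"titanium_alloy"|
#'   "stainless_steel")`. `position = NULL` places the insert on the dental
#'   arch.
#' @param seed integer seed controlling anatomy jitter and tissue texture.
#' @return an object of class `mvmar_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128), spacing = c(1, 1),
                         metal_inserts = list(), seed = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  materials <- c("aluminium_alloy", "titanium_alloy", "stainless_steel")
  for (ins in metal_inserts) {
    if (!is.list(ins) || is.null(ins$material) || is.null(ins$radius))
      stop("each metal insert needs $radius (mm) and $material")
    if (!ins$material %in% materials)
      stop("unknown metal material: ", ins$material)
    if (ins$radius <= 0) stop("insert radius must be > 0")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 metal_inserts = metal_inserts, seed = as.integer(seed)),
            class = "mvmar_phantom_spec")
}

metal_hu <- c(aluminium_alloy = 3000, titanium_alloy = 3600,
              stainless_steel = 4200)

# Evaluate RNG-consuming code under a seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 3x3 binomial blur with replicated edges: gives painted structures a
# ~1-pixel partial-volume transition so the phantom is quasi-band-limited
# (sharp ideal edges would dominate reconstruction error with aliasing).
binomial_blur <- function(m) {
  k <- c(1, 2, 1) / 4
  p <- rbind(m[1, ], m, m[nrow(m), ])
  p <- cbind(p[, 1], p, p[, ncol(p)])
  o <- p
  for (i in 2:(nrow(p) - 1))
    o[i, ] <- k[1] * p[i - 1, ] + k[2] * p[i, ] + k[3] * p[i + 1, ]
  p2 <- o
  for (j in 2:(ncol(p) - 1))
    o[, j] <- k[1] * p2[, j - 1] + k[2] * p2[, j] + k[3] * p2[, j + 1]
  o[2:(nrow(p) - 1), 2:(ncol(p) - 1)]
}

ellipse_mask <- function(shape, center_px, semi_px, angle = 0) {
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  dr <- r - center_px[1]; dc <- c - center_px[2]
  if (angle != 0) {
    ca <- cos(angle); sa <- sin(angle)
    tmp <- dr * ca - dc * sa
    dc <- dr * sa + dc * ca
    dr <- tmp
  }
  (dr / semi_px[1])^2 + (dc / semi_px[2])^2 <= 1
}

disk_mask <- function(shape, center_px, radius_px) {
  ellipse_mask(shape, center_px, c(radius_px, radius_px))
}

#' Build a ground-truth phantom slice
#'
#' Paints the anatomy of a [phantom_spec()] onto an HU grid: air -1000 HU,
#' soft tissue around 30--60 HU with smooth seeded texture, mandible bone
#' around 900 HU, teeth around 1500 HU, metal at its material HU (>= 3000).
#' Deterministic given the spec (same seed gives identical output). Metal
#' inserts falling outside the head outline are rejected.
#'
#' @param spec a [phantom_spec()].
#' @return list with `truth` (an [image_volume()], modality `"kvct"`,
#'   unclamped so metal keeps its material HU) and `masks` (named list of
#'   [structure_mask()]: soft_tissue, mandible, teeth, oral_cavity, parotid,
#'   spinal_cord, ptv, metal).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "mvmar_phantom_spec"))
  with_seed(spec$seed, {
    sh <- spec$shape; sp <- spec$spacing
    jit <- function(x, frac = 0.05) x * (1 + runif(1, -frac, frac))
    ctr <- (sh - 1) / 2
    # head outline: ellipse filling most of the grid
    head_semi <- c(jit(0.42 * sh[1]), jit(0.35 * sh[2]))
    head <- ellipse_mask(sh, ctr, head_semi)
    hu <- matrix(-1000, sh[1], sh[2])
    # smooth seeded soft-tissue texture (low-frequency sinusoids)
    rr <- matrix(seq_len(sh[1]) / sh[1], sh[1], sh[2])
    cc <- matrix(seq_len(sh[2]) / sh[2], sh[1], sh[2], byrow = TRUE)
    tex <- 8 * sin(2 * pi * (runif(1) + rr * runif(1, 1, 2))) +
           8 * cos(2 * pi * (runif(1) + cc * runif(1, 1, 2)))
    hu[head] <- 40 + tex[head]
    masks <- list()
    # mandible: lower arc, a thick partial elliptical annulus
    mand_ctr <- ctr + c(0.16 * sh[1], 0)
    mand_out <- c(jit(0.22 * sh[1]), jit(0.26 * sh[2]))
    outer_m <- ellipse_mask(sh, mand_ctr, mand_out)
    inner_m <- ellipse_mask(sh, mand_ctr, mand_out - 6 / sp)
    lower <- matrix(seq_len(sh[1]) - 1, sh[1], sh[2]) > mand_ctr[1] - 0.08 * sh[1]
    mandible <- outer_m & !inner_m & lower & head
    hu[mandible] <- jit(900, 0.08) + 60 * tex[mandible] / 8
    # teeth: disks along the anterior dental arch (front = high row index)
    nteeth <- 7L
    th <- seq(-0.55, 0.55, length.out = nteeth) * pi
    tooth_r <- 2.8 / mean(sp)
    arch_semi <- mand_out - 3 / sp
    teeth <- matrix(FALSE, sh[1], sh[2])
    tooth_centers <- list()
    for (i in seq_len(nteeth)) {
      tc <- mand_ctr + c(arch_semi[1] * cos(th[i]) * 0.55,
                         arch_semi[2] * sin(th[i]))
      teeth <- teeth | disk_mask(sh, tc, tooth_r)
      tooth_centers[[i]] <- tc
    }
    teeth <- teeth & head
    hu[teeth] <- jit(1500, 0.08)
    # oral cavity: ellipse enclosed by the dental arch
    oral <- ellipse_mask(sh, mand_ctr - c(0.02 * sh[1], 0),
                         pmax(mand_out - 10 / sp, 3)) & head & !teeth & !mandible
    hu[oral] <- 25 + tex[oral]
    # parotids: lateral ellipses at mid height
    par_semi <- c(jit(0.075 * sh[1]), jit(0.05 * sh[2]))
    par_l <- ellipse_mask(sh, ctr + c(0.05 * sh[1], -0.27 * sh[2]), par_semi)
    par_r <- ellipse_mask(sh, ctr + c(0.05 * sh[1],  0.27 * sh[2]), par_semi)
    parotid <- (par_l | par_r) & head & !mandible & !teeth
    hu[parotid] <- 48 + tex[parotid]
    # spinal cord: small posterior disk (posterior = low row index)
    cord <- disk_mask(sh, ctr + c(-0.26 * sh[1], 0), 4.5 / mean(sp)) & head
    hu[cord] <- 38 + tex[cord]
    # metal inserts
    metal <- matrix(FALSE, sh[1], sh[2])
    k <- 0L
    for (ins in spec$metal_inserts) {
      k <- k + 1L
      if (is.null(ins$position)) {
        tc <- tooth_centers[[1L + (k - 1L) %% nteeth]]
      } else {
        tc <- ctr + ins$position / sp
      }
      dm <- disk_mask(sh, tc, ins$radius / mean(sp))
      if (any(dm & !head))
        stop("metal insert extends outside the head outline")
      metal <- metal | dm
      hu[dm] <- metal_hu[[ins$material]]
    }
    teeth <- teeth & !metal
    mandible <- mandible & !metal
    soft <- head & !mandible & !teeth & !metal
    # PTV analog: region around the dental arch / oral cavity
    ptv <- ellipse_mask(sh, mand_ctr - c(0.04 * sh[1], 0),
                        mand_out + 2 / sp) & head
    hu <- binomial_blur(hu)
    truth <- image_volume(hu, spacing = sp, modality = "kvct")
    masks <- list(
      soft_tissue = structure_mask("soft_tissue", soft),
      mandible    = structure_mask("mandible", mandible),
      teeth       = structure_mask("teeth", teeth),
      oral_cavity = structure_mask("oral_cavity", oral & soft),
      parotid     = structure_mask("parotid", parotid & soft),
      spinal_cord = structure_mask("spinal_cord", cord & soft),
      ptv         = structure_mask("ptv", ptv),
      metal       = structure_mask("metal", metal)
    )
    list(truth = truth, masks = masks)
  })
}
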