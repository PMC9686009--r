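#' Tanh HU scaling specifications
#'
#' The translator is trained on intensities scaled into (-1, 1) with a
#' hyperbolic tangent, x = tanh((HU - shift) / divisor). Three scalings are
#' used, each emphasising a different part of the HU axis, with separate
#' constants for the kV-CT and MV-CBCT sides:
#'
#' | method | MV-CBCT (shift, divisor) | CT (shift, divisor) | emphasis |
#' |--------|--------------------------|---------------------|----------|
#' | P1     | (0, 400)                 | (0, 400)            | full range |
#' | P2     | (0, 150)                 | (0, 300)            | soft tissue |
#' | P3     | (800, 400)               | (1600, 960)         | bone / high HU |
#'
#' @param method `"P1"`, `"P2"` or `"P3"`.
#' @param modality `"CT"` (also accepts `"kvct"`/`"sct"`) or `"MVCBCT"`.
#' @return an object of class `mvmar_scaling` with fields `method`,
#'   `modality`, `shift` (HU) and `divisor` (HU).
#' @examples
#' scaling_spec("P3", "CT")
#' @export
scaling_spec <- function(method = c("P1", "P2", "P3"),
                         modality = c("CT", "MVCBCT")) {
  method <- match.arg(toupper(method), c("P1", "P2", "P3"))
  modality <- toupper(modality[1])
  if (modality %in% c("KVCT", "SCT")) modality <- "CT"
  if (modality == "MV") modality <- "MVCBCT"
  if (!modality %in% c("CT", "MVCBCT")) stop("unknown modality: ", modality)
  tab <- list(
    P1 = list(CT = c(0, 400),    MVCBCT = c(0, 400)),
    P2 = list(CT = c(0, 300),    MVCBCT = c(0, 150)),
    P3 = list(CT = c(1600, 960), MVCBCT = c(800, 400))
  )
  sd <- tab[[method]][[modality]]
  structure(list(method = method, modality = modality,
                 shift = sd[1], divisor = sd[2]),
            class = "mvmar_scaling")
}

#' @export
print.mvmar_scaling <- function(x, ...) {
  cat(sprintf("<mvmar_scaling> %s/%s  x = tanh((HU - %g) / %g)\n",
              x$method, x$modality, x$shift, x$divisor))
  invisible(x)
}

scaling_matches_modality <- function(spec, vol) {
  want <- if (vol$modality == "mvcbct") "MVCBCT" else "CT"
  if (spec$modality != want)
    stop(sprintf("scaling spec is for %s but volume modality is %s",
                 spec$modality, vol$modality))
  invisible(TRUE)
}

#' Scale HU into the (-1, 1) network domain
#'
#' Computes x = tanh((HU - shift) / divisor). The input should already be
#' clamped to its modality HU range; all outputs are then strictly inside
#' (-1, 1) in double precision.
#'
#' @param vol an [image_volume()] (clamped) or a numeric array of HU.
#' @param spec an [scaling_spec()]; its modality must match the volume's.
#' @return numeric array of scaled intensities, same shape as the input.
#' @export
forward_scale <- function(vol, spec) {
  stopifnot(inherits(spec, "mvmar_scaling"))
  if (inherits(vol, "mvmar_volume")) {
    scaling_matches_modality(spec, vol)
    v <- vol$values
  } else v <- vol
  tanh((v - spec$shift) / spec$divisor)
}

#' Map scaled intensities back to HU
#'
#' Computes HU = shift + divisor * atanh(x) and clamps to the spec
#' modality's HU range. Values with |x| >= 1 (a saturated network output)
#' are clamped to +/-(1 - 1e-7) before atanh so the inverse stays finite.
#'
#' @param x numeric array in (-1, 1).
#' @param spec an [scaling_spec()] identifying shift/divisor and modality.
#' @param modality modality tag for the returned volume; defaults to the
#'   spec's side (`"sct"` for CT, `"mvcbct"` for MVCBCT).
#' @param spacing,origin geometry for the returned volume.
#' @return an [image_volume()] in HU, clamped to the modality range.
#' @export
inverse_scale <- function(x, spec, modality = NULL,
                          spacing = c(1, 1), origin = c(0, 0)) {
  stopifnot(inherits(spec, "mvmar_scaling"))
  eps <- 1e-7
  sat <- abs(x) >= 1            # saturated network outputs only
  x[sat] <- sign(x[sat]) * (1 - eps)
  hu <- spec$shift + spec$divisor * atanh(x)
  if (is.null(modality))
    modality <- if (spec$modality == "MVCBCT") "mvcbct" else "sct"
  clamp_hu(image_volume(as.matrix(hu), spacing = spacing, origin = origin,
                        modality = modality))
}

#' All six scaling specifications
#'
#' @return named list of the six (method, modality) [scaling_spec()] objects.
#' @export
all_scaling_specs <- function() {
  out <- list()
  for (m in c("P1", "P2", "P3"))
    for (mod in c("CT", "MVCBCT"))
      out[[paste(m, mod, sep = "_")]] <- scaling_spec(m, mod)
  out
}
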