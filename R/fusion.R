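#' Candidate set for HU-range fusion
#'
#' Bundles the three synthetic-CT candidates produced under the P1/P2/P3
#' scalings, plus the selector image whose HU value classifies each pixel
#' into a fusion band. The selector defaults to the P3 candidate (the
#' scaling that performs best at high HU); `"p1"`, `"p2"` or `"median"`
#' (pixelwise median of the three) are also accepted.
#'
#' @param p1,p2,p3 sCT candidate [image_volume()]s on one grid.
#' @param selector `"p3"` (default), `"p1"`, `"p2"`, `"median"`, or an
#'   [image_volume()] to classify with.
#' @return an object of class `mvmar_candidates`.
#' @export
candidate_set <- function(p1, p2, p3, selector = "p3") {
  check_same_geometry(p1, p2, "candidates p1/p2")
  check_same_geometry(p1, p3, "candidates p1/p3")
  if (is.character(selector)) {
    selector <- switch(match.arg(selector, c("p3", "p1", "p2", "median")),
      p1 = p1, p2 = p2, p3 = p3,
      median = {
        v <- pmin(pmax(pmin(p1$values, p2$values), p3$values),
                  pmax(p1$values, p2$values))  # median of three
        image_volume(v, spacing = p1$spacing, origin = p1$origin,
                     modality = "sct")
      })
  }
  check_same_geometry(p1, selector, "candidates/selector")
  structure(list(p1 = p1, p2 = p2, p3 = p3, selector = selector),
            class = "mvmar_candidates")
}

#' Fuse the three scaled-model candidates by HU range (P4)
#'
#' Per pixel, with s the selector HU: s < 400 takes the P2 value,
#' 400 <= s < 800 the P1 value and s >= 800 the P3 value (half-open bands,
#' so the three ranges partition the HU axis and every pixel comes from
#' exactly one candidate).
#'
#' @param cands a [candidate_set()].
#' @return fused sCT [image_volume()].
#' @export
fuse_p4 <- function(cands) {
  stopifnot(inherits(cands, "mvmar_candidates"))
  s <- cands$selector$values
  out <- cands$p3$values
  out[s < 800] <- cands$p1$values[s < 800]
  out[s < 400] <- cands$p2$values[s < 400]
  image_volume(out, spacing = cands$p1$spacing, origin = cands$p1$origin,
               modality = "sct")
}

#' Dual-threshold metal segmentation
#'
#' Metal is the intersection of bright pixels in both modalities:
#' kV-CT HU > 2500 and MV-CBCT HU > 300. The MV condition rejects bright
#' kV streak artifacts, which have no counterpart in the (artifact-free)
#' MV image. An optional cleanup (off by default, for noisy data) removes
#' connected components smaller than `min_component` pixels.
#'
#' @param ct_m metal-containing kV-CT [image_volume()].
#' @param mv_m aligned MV-CBCT [image_volume()] (pre-clip values allowed).
#' @param ct_threshold,mv_threshold segmentation thresholds, HU.
#' @param min_component if > 0, drop 4-connected components with fewer
#'   pixels than this.
#' @return an object of class `mvmar_metal_mask`: a [structure_mask()] with
#'   a `provenance` field recording the thresholds.
#' @export
segment_metal <- function(ct_m, mv_m, ct_threshold = 2500,
                          mv_threshold = 300, min_component = 0) {
  check_same_geometry(ct_m, mv_m, "ct/mv")
  m <- (as_values(ct_m) > ct_threshold) & (as_values(mv_m) > mv_threshold)
  if (min_component > 0 && any(m))
    m <- drop_small_components(m, min_component)
  out <- structure_mask("metal", m)
  out$provenance <- c(ct_threshold = ct_threshold,
                      mv_threshold = mv_threshold)
  class(out) <- c("mvmar_metal_mask", class(out))
  out
}

# Remove 4-connected TRUE components smaller than min_px (flood fill).
drop_small_components <- function(m, min_px) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (start in which(m & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (lab[i] != 0L || !m[i]) next
      lab[i] <- cur
      r <- (i - 1L) %% nrow(m) + 1L
      c <- (i - 1L) %/% nrow(m) + 1L
      nb <- c(if (r > 1) i - 1L, if (r < nrow(m)) i + 1L,
              if (c > 1) i - nrow(m), if (c < ncol(m)) i + nrow(m))
      stack <- c(stack, nb[lab[nb] == 0L & m[nb]])
    }
  }
  keep <- which(tabulate(lab) >= min_px)
  m & matrix(lab %in% keep, nrow(m))
}

#' Full metal-artifact-reduction pipeline for one aligned pair
#'
#' Pipeline: clamp the MV image at 1400 HU, translate it to a synthetic CT
#' under each of the three scalings, fuse the candidates by HU range
#' ([fuse_p4()]), segment metal as (CT > 2500) AND (MV > 300), then copy
#' the original kV-CT values back onto the metal pixels. Off-mask pixels
#' equal the fused sCT exactly; on-mask pixels equal the input CT exactly.
#'
#' @param ct_m metal-containing (or metal-free) kV-CT [image_volume()].
#' @param mv_m aligned MV-CBCT [image_volume()].
#' @param translator an `mvmar_translator` (see [surrogate_translator()])
#'   or a named list of three translators `list(P1 =, P2 =, P3 =)`.
#' @param selector fusion selector, see [candidate_set()].
#' @param ... passed to [segment_metal()].
#' @return list with `sct` (the MAR [image_volume()]), `mask` (the
#'   [segment_metal()] result) and `fused` (pre-copy-back sCT).
#' @export
apply_mar <- function(ct_m, mv_m, translator = surrogate_translator(),
                      selector = "p3", ...) {
  check_same_geometry(ct_m, mv_m, "ct/mv")
  mv_c <- clamp_hu(mv_m)
  tr_for <- function(method) {
    tr <- if (inherits(translator, "mvmar_translator")) translator
          else translator[[method]]
    translate(tr, mv_c, method = method)
  }
  cands <- candidate_set(tr_for("P1"), tr_for("P2"), tr_for("P3"),
                         selector = selector)
  fused <- fuse_p4(cands)
  mask <- segment_metal(ct_m, mv_m, ...)
  out <- fused$values
  out[mask$mask] <- ct_m$values[mask$mask]
  sct <- image_volume(out, spacing = ct_m$spacing, origin = ct_m$origin,
                      modality = "sct")
  list(sct = sct, mask = mask, fused = fused)
}
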