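#' Translator model configuration
#'
#' Two configurations matter in practice. The clinical-mirror configuration
#' records the clinical-scale training protocol (batch size 6, learning rate
#' 2e-4 held for 100 epochs then decayed over 100 more); it is not meant to
#' be trained on a desk CPU. The toy configuration (the default) trains a
#' small residual U-Net generator pair with patch discriminators on 64x64
#' slices in minutes and is what the tests exercise.
#'
#' @param width generator/discriminator channel width.
#' @param cycle_weight cycle-consistency loss weight (lambda).
#' @param batch_size images per optimiser step.
#' @param epochs_constant epochs at constant learning rate.
#' @param epochs_decay epochs over which the rate is decayed.
#' @param lr0 initial learning rate.
#' @param decay `"linear"` (to zero over the decay phase, the canonical
#'   cycle-consistent-translation schedule) or `"geometric"` (x0.99 per
#'   epoch, the literal reading of "attenuated by 1% per epoch").
#' @param beta1 Adam first-moment decay (0.5, the GAN convention).
#' @param seed integer seed for initialisation and data order.
#' @return an object of class `mvmar_model_config`.
#' @export
model_config <- function(width = 6, cycle_weight = 10, batch_size = 1,
                         epochs_constant = 10, epochs_decay = 6,
                         lr0 = 2e-3, decay = c("linear", "geometric"),
                         beta1 = 0.5, seed = 1) {
  decay <- match.arg(decay)
  if (cycle_weight <= 0) stop("invalid cycle_weight: must be > 0")
  if (lr0 <= 0) stop("invalid lr0: must be > 0")
  if (batch_size < 1) stop("invalid batch_size: must be >= 1")
  if (width < 1) stop("invalid width: must be >= 1")
  structure(list(width = as.integer(width), cycle_weight = cycle_weight,
                 batch_size = as.integer(batch_size),
                 epochs_constant = as.integer(epochs_constant),
                 epochs_decay = as.integer(epochs_decay),
                 lr0 = lr0, decay = decay, beta1 = beta1,
                 seed = as.integer(seed)),
            class = "mvmar_model_config")
}

#' Clinical-mirror training configuration
#'
#' The clinical-scale protocol: batch size 6, learning rate 2e-4 constant for
#' 100 epochs then decayed over the last 100. Recorded for provenance; use
#' the default [model_config()] for desk-scale training.
#'
#' @param ... overrides passed to [model_config()].
#' @export
clinical_model_config <- function(...) {
  model_config(batch_size = 6, epochs_constant = 100, epochs_decay = 100,
               lr0 = 2e-4, ...)
}

#' Learning-rate schedule
#'
#' Constant at `lr0` for the first `epochs_constant` epochs, then decayed
#' over `epochs_decay` epochs: linearly to zero (default) or geometrically
#' by 1% per epoch (`decay = "geometric"`).
#'
#' @param epoch 0-based epoch index.
#' @param config a [model_config()].
#' @return learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  total <- config$epochs_constant + config$epochs_decay
  if (any(epoch < 0 | epoch >= total))
    stop(sprintf("epoch out of range [0, %d)", total))
  k <- pmax(epoch - config$epochs_constant + 1, 0)
  if (config$decay == "geometric") {
    config$lr0 * 0.99^k
  } else {
    config$lr0 * (1 - k / config$epochs_decay)
  }
}

#' Build an untrained cycle-consistent translator
#'
#' Two generators (MV to CT and CT to MV; depth-2 residual U-Nets with a
#' final tanh, so outputs stay in (-1, 1)) and two patch discriminators.
#' Initialisation is seeded and deterministic.
#'
#' @param config a [model_config()].
#' @param method the scaling method this model is trained for
#'   (`"P1"`, `"P2"`, `"P3"`).
#' @return an object of class `mvmar_translator`, kind `"cyclegan"`.
#' @export
build_translator <- function(config = model_config(), method = "P1") {
  stopifnot(inherits(config, "mvmar_model_config"))
  with_seed(config$seed, {
    structure(list(kind = "cyclegan", method = method, config = config,
                   g_ab = gen_init(config$width),
                   g_ba = gen_init(config$width),
                   d_a = disc_init(config$width),
                   d_b = disc_init(config$width),
                   trained = FALSE, history = NULL),
              class = "mvmar_translator")
  })
}

#' @export
print.mvmar_translator <- function(x, ...) {
  np <- if (x$kind == "cyclegan")
    n_params(x$g_ab) + n_params(x$g_ba) + n_params(x$d_a) + n_params(x$d_b)
  else 0L
  cat(sprintf("<mvmar_translator> kind=%s method=%s trained=%s params=%d\n",
              x$kind, x$method %||% "any",
              if (isTRUE(x$trained)) "yes" else "no", np))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic surrogate translator
#'
#' A training-free stand-in for the learned model, so the fusion / MAR /
#' evaluation stages can be exercised deterministically. Two kinds:
#' `"contrast"` (default) mimics the two things a trained MV-to-CT
#' generator does to an MV-CBCT slice — it denoises with a small median
#' filter (edge-preserving, deterministic) and restores tissue contrast
#' with a fixed piecewise-linear HU map inverting the MV-CBCT compression
#' (the inverse of [mv_compress_hu()]); `"identity"` passes the scaled
#' intensities through unchanged, so its output is exactly
#' `inverse_scale(forward_scale(mv), CT spec)` — a closed-form reference.
#'
#' @param kind `"contrast"` or `"identity"`.
#' @param contrast the compression factor the contrast surrogate inverts.
#' @param median_window odd window of the contrast surrogate's median
#'   filter (1 disables denoising).
#' @return an `mvmar_translator`.
#' @export
surrogate_translator <- function(kind = c("contrast", "identity"),
                                 contrast = 0.6, median_window = 3L) {
  kind <- match.arg(kind)
  structure(list(kind = paste0("surrogate_", kind), method = NULL,
                 contrast = contrast, median_window = as.integer(median_window),
                 trained = TRUE, history = NULL),
            class = "mvmar_translator")
}

# 2-D median filter with replicated edges.
median_filter <- function(m, w) {
  if (w <= 1L) return(m)
  pad <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2 * pad) - pad, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * pad) - pad, 1L), nc)
  mp <- m[ri, ci]
  stack <- array(NA_real_, dim = c(nr, nc, w * w))
  k <- 0L
  for (di in seq_len(w)) for (dj in seq_len(w)) {
    k <- k + 1L
    stack[, , k] <- mp[di:(di + nr - 1L), dj:(dj + nc - 1L)]
  }
  matrix(apply(stack, c(1, 2), stats::median), nr, nc)
}

# Inverse of the MV compression map, clamped to the CT range.
mv_restore_hu <- function(hu, contrast = 0.6) {
  kv <- c(-1000, -200, 150, 800, 1500, 2400, 3000)
  mv <- c(-1000, -200 * contrast, 150 * contrast, 500, 900, 1150, 1300)
  out <- approx(mv, kv, xout = as.vector(hu), rule = 2)$y
  array(out, dim = dim(hu))
}

#' Translate an MV-CBCT slice to a synthetic CT
#'
#' Pipeline: clamp the MV input, scale with the method's MV spec into
#' (-1, 1), run the MV-to-CT generator (or surrogate), then invert with
#' the method's CT spec and clamp to the CT range. Output geometry equals
#' input geometry.
#'
#' @param model an `mvmar_translator` (trained, or a surrogate; an
#'   untrained cyclegan needs `allow_untrained = TRUE`).
#' @param mv an MV-CBCT [image_volume()].
#' @param method scaling method; a trained cyclegan model insists on its
#'   own method.
#' @param allow_untrained set to use an untrained generator anyway.
#' @return synthetic-CT [image_volume()] (modality `"sct"`).
#' @export
translate <- function(model, mv, method = NULL, allow_untrained = FALSE) {
  stopifnot(inherits(model, "mvmar_translator"),
            inherits(mv, "mvmar_volume"))
  mv <- clamp_hu(mv)
  if (model$kind == "surrogate_contrast") {
    hu <- median_filter(mv$values, model$median_window %||% 3L)
    hu <- mv_restore_hu(hu, model$contrast)
    return(clamp_hu(image_volume(hu, spacing = mv$spacing,
                                 origin = mv$origin, modality = "sct")))
  }
  method <- method %||% model$method %||% "P1"
  if (model$kind == "cyclegan" && !is.null(model$method) &&
      method != model$method)
    stop(sprintf("model was trained for %s, asked to translate as %s",
                 model$method, method))
  spec_mv <- scaling_spec(method, "MVCBCT")
  spec_ct <- scaling_spec(method, "CT")
  x <- forward_scale(mv, spec_mv)
  y <- if (model$kind == "surrogate_identity") {
    x
  } else {
    if (!isTRUE(model$trained) && !allow_untrained)
      stop("model is untrained; pass allow_untrained = TRUE to override")
    gen_forward(model$g_ab, x)$y[, , 1]
  }
  inverse_scale(y, spec_ct, modality = "sct",
                spacing = mv$spacing, origin = mv$origin)
}

lsgan_d_loss <- function(o_real, o_fake) {
  0.5 * (mean((o_real - 1)^2) + mean(o_fake^2))
}

#' Train the cycle-consistent translator
#'
#' Optimises the least-squares adversarial objective plus
#' `cycle_weight` times the L1 cycle-consistency loss, with Adam
#' (beta1 from the config) and the [lr_schedule()]. Fully deterministic
#' given the config seed and data. Images must already be scaled into
#' (-1, 1); domain A is the MV side, domain B the CT side.
#'
#' @param a_images,b_images lists of equally sized matrices in (-1, 1).
#' @param config a [model_config()].
#' @param method scaling-method label stored on the model.
#' @param verbose print per-epoch losses.
#' @return a trained `mvmar_translator` with a `history` data.frame
#'   (epoch, lr, loss_g, loss_d, loss_cycle).
#' @export
train_translator <- function(a_images, b_images, config = model_config(),
                             method = "P1", verbose = FALSE) {
  stopifnot(length(a_images) >= 1, length(b_images) >= 1)
  model <- build_translator(config, method = method)
  lam <- config$cycle_weight
  n <- min(length(a_images), length(b_images))
  st <- list(g_ab = adam_init(model$g_ab), g_ba = adam_init(model$g_ba),
             d_a = adam_init(model$d_a), d_b = adam_init(model$d_b))
  t_adam <- 0L
  hist <- list()
  total_epochs <- config$epochs_constant + config$epochs_decay
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(total_epochs) - 1L) {
      lr <- lr_schedule(epoch, config)
      ord <- sample.int(n)
      ep_g <- ep_d <- ep_c <- 0; nb <- 0L
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        gg_ab <- gg_ba <- gd_a <- gd_b <- NULL
        b_g <- b_d <- b_c <- 0
        for (i in bs) {
          a <- nn_tensor(a_images[[i]]); b <- nn_tensor(b_images[[i]])
          # generator pass
          fb <- gen_forward(model$g_ab, a)   # fake B
          ra <- gen_forward(model$g_ba, fb$y)  # cycle back to A
          fa <- gen_forward(model$g_ba, b)   # fake A
          rb <- gen_forward(model$g_ab, fa$y)  # cycle back to B
          db_f <- disc_forward(model$d_b, fb$y)
          da_f <- disc_forward(model$d_a, fa$y)
          l_adv <- mean((db_f$o - 1)^2) + mean((da_f$o - 1)^2)
          l_cyc <- lam * (mean(abs(ra$y - a)) + mean(abs(rb$y - b)))
          if (!is.finite(l_adv + l_cyc))
            stop(sprintf("NaN loss at epoch %d (image %d)", epoch, i))
          # backward: adversarial heads (input grads only)
          d_fb <- disc_backward(model$d_b, db_f$cache,
                                2 * (db_f$o - 1) / length(db_f$o))$dx
          d_fa <- disc_backward(model$d_a, da_f$cache,
                                2 * (da_f$o - 1) / length(da_f$o))$dx
          # cycle A: a -> fb -> ra
          d_ra <- lam * sign(ra$y - a) / length(ra$y)
          bb <- gen_backward(model$g_ba, ra$cache, d_ra)
          gg_ba <- grads_add(gg_ba, bb$grads)
          ba <- gen_backward(model$g_ab, fb$cache, d_fb + bb$dx)
          gg_ab <- grads_add(gg_ab, ba$grads)
          # cycle B: b -> fa -> rb
          d_rb <- lam * sign(rb$y - b) / length(rb$y)
          bb2 <- gen_backward(model$g_ab, rb$cache, d_rb)
          gg_ab <- grads_add(gg_ab, bb2$grads)
          ba2 <- gen_backward(model$g_ba, fa$cache, d_fa + bb2$dx)
          gg_ba <- grads_add(gg_ba, ba2$grads)
          # discriminators on real vs detached fakes
          db_r <- disc_forward(model$d_b, b)
          da_r <- disc_forward(model$d_a, a)
          l_d <- lsgan_d_loss(db_r$o, db_f$o) + lsgan_d_loss(da_r$o, da_f$o)
          gd_b <- grads_add(gd_b, disc_backward(
            model$d_b, db_r$cache, (db_r$o - 1) / length(db_r$o))$grads)
          gd_b <- grads_add(gd_b, disc_backward(
            model$d_b, db_f$cache, db_f$o / length(db_f$o))$grads)
          gd_a <- grads_add(gd_a, disc_backward(
            model$d_a, da_r$cache, (da_r$o - 1) / length(da_r$o))$grads)
          gd_a <- grads_add(gd_a, disc_backward(
            model$d_a, da_f$cache, da_f$o / length(da_f$o))$grads)
          b_g <- b_g + l_adv; b_c <- b_c + l_cyc; b_d <- b_d + l_d
        }
        s <- 1 / length(bs)
        t_adam <- t_adam + 1L
        up <- adam_step(model$g_ab, grads_scale(gg_ab, s), st$g_ab, lr,
                        beta1 = config$beta1, t = t_adam)
        model$g_ab <- up$params; st$g_ab <- up$state
        up <- adam_step(model$g_ba, grads_scale(gg_ba, s), st$g_ba, lr,
                        beta1 = config$beta1, t = t_adam)
        model$g_ba <- up$params; st$g_ba <- up$state
        up <- adam_step(model$d_a, grads_scale(gd_a, s), st$d_a, lr,
                        beta1 = config$beta1, t = t_adam)
        model$d_a <- up$params; st$d_a <- up$state
        up <- adam_step(model$d_b, grads_scale(gd_b, s), st$d_b, lr,
                        beta1 = config$beta1, t = t_adam)
        model$d_b <- up$params; st$d_b <- up$state
        ep_g <- ep_g + b_g; ep_d <- ep_d + b_d; ep_c <- ep_c + b_c
        nb <- nb + length(bs)
      }
      hist[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, loss_g = ep_g / nb, loss_d = ep_d / nb,
        loss_cycle = ep_c / nb)
      if (verbose)
        message(sprintf("epoch %d lr %.2e G %.4f D %.4f cyc %.4f", epoch,
                        lr, ep_g / nb, ep_d / nb, ep_c / nb))
    }
  })
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model
}
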