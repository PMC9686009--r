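# Minimal convolutional network machinery for the toy cycle-consistent
# translator. Tensors are (H, W, C) arrays; convolutions are 3x3 with same
# (zero) padding, implemented in C++ (src/conv.cpp); everything else is
# plain R. Backward passes are hand-derived per architecture below.

nn_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

# He initialisation by default (keeps activation scale ~1 through ReLU
# stacks, which these small unnormalised nets need); pass `sd` to override.
conv_init <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (9 * cin))
  list(w = array(rnorm(9 * cin * cout, sd = sd), dim = c(3, 3, cin, cout)),
       b = numeric(cout))
}

relu  <- function(x) pmax(x, 0)
lrelu <- function(x, a = 0.2) pmax(x, 0) + a * pmin(x, 0)

avgpool2 <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  x1 <- x[seq(1, d[1], 2), , , drop = FALSE]
  x2 <- x[seq(2, d[1], 2), , , drop = FALSE]
  s <- x1 + x2
  (s[, seq(1, d[2], 2), , drop = FALSE] +
   s[, seq(2, d[2], 2), , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy) {
  d <- dim(dy)
  out <- array(0, dim = c(d[1] * 2, d[2] * 2, d[3]))
  g <- dy / 4
  for (i in 0:1) for (j in 0:1)
    out[seq(1 + i, d[1] * 2, 2), seq(1 + j, d[2] * 2, 2), ] <- g
  out
}

upsample2 <- function(x) {  # nearest neighbour x2
  d <- dim(x)
  out <- array(0, dim = c(d[1] * 2, d[2] * 2, d[3]))
  for (i in 0:1) for (j in 0:1)
    out[seq(1 + i, d[1] * 2, 2), seq(1 + j, d[2] * 2, 2), ] <- x
  out
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  x1 <- dy[seq(1, d[1], 2), , , drop = FALSE]
  x2 <- dy[seq(2, d[1], 2), , , drop = FALSE]
  s <- x1 + x2
  s[, seq(1, d[2], 2), , drop = FALSE] + s[, seq(2, d[2], 2), , drop = FALSE]
}

# ---- generator: depth-2 residual U-Net ------------------------------------
# e1 = relu(c1(x)); e2 = relu(c2(pool(e1))); m = up(e2) + e1
# h  = relu(c3(m)); y = tanh(c4(h) + atanh(x))
# The logit-residual skip makes the freshly initialised generator the
# identity map on the scaled domain (c4 starts near zero), so training is
# a perturbation of identity rather than a recovery from tanh-squashing.

gen_init <- function(width) {
  list(c1 = conv_init(1, width), c2 = conv_init(width, width),
       c3 = conv_init(width, width),
       c4 = conv_init(width, 1, sd = 0.02))  # near-identity start
}

atanh_eps <- 1e-6

gen_forward <- function(p, x) {
  x <- nn_tensor(x)
  xc <- pmin(pmax(x, -1 + atanh_eps), 1 - atanh_eps)
  a1 <- cpp_conv3x3_fwd(x, p$c1$w, p$c1$b);  e1 <- relu(a1)
  d1 <- avgpool2(e1)
  a2 <- cpp_conv3x3_fwd(d1, p$c2$w, p$c2$b); e2 <- relu(a2)
  m  <- upsample2(e2) + e1
  a3 <- cpp_conv3x3_fwd(m, p$c3$w, p$c3$b);  h <- relu(a3)
  z  <- cpp_conv3x3_fwd(h, p$c4$w, p$c4$b) + atanh(xc)
  y  <- tanh(z)
  list(y = y, cache = list(x = x, xc = xc, e1 = e1, d1 = d1, e2 = e2, m = m,
                           h = h, y = y))
}

gen_backward <- function(p, cache, dy) {
  dz <- dy * (1 - cache$y^2)
  b4 <- cpp_conv3x3_bwd(cache$h, p$c4$w, dz)
  dh <- b4$dx * (cache$h > 0)
  b3 <- cpp_conv3x3_bwd(cache$m, p$c3$w, dh)
  dm <- b3$dx
  de2 <- upsample2_bwd(dm) * (cache$e2 > 0)
  b2 <- cpp_conv3x3_bwd(cache$d1, p$c2$w, de2)
  de1 <- avgpool2_bwd(b2$dx) + dm
  de1 <- de1 * (cache$e1 > 0)
  b1 <- cpp_conv3x3_bwd(cache$x, p$c1$w, de1)
  skip <- abs(cache$x) < 1 - atanh_eps
  dx <- b1$dx + dz / (1 - cache$xc^2) * skip
  list(dx = dx,
       grads = list(c1 = list(w = b1$dw, b = b1$db),
                    c2 = list(w = b2$dw, b = b2$db),
                    c3 = list(w = b3$dw, b = b3$db),
                    c4 = list(w = b4$dw, b = b4$db)))
}

# ---- discriminator: 3-layer patch classifier ------------------------------
# f1 = lrelu(c1(x)); f2 = lrelu(c2(pool(f1))); out = c3(pool(f2))
# Output is an (H/4, W/4, 1) patch-logit map (least-squares GAN).

disc_init <- function(width) {
  list(c1 = conv_init(1, width), c2 = conv_init(width, width),
       c3 = conv_init(width, 1))
}

disc_forward <- function(p, x) {
  x <- nn_tensor(x)
  a1 <- cpp_conv3x3_fwd(x, p$c1$w, p$c1$b); f1 <- lrelu(a1)
  p1 <- avgpool2(f1)
  a2 <- cpp_conv3x3_fwd(p1, p$c2$w, p$c2$b); f2 <- lrelu(a2)
  p2 <- avgpool2(f2)
  o  <- cpp_conv3x3_fwd(p2, p$c3$w, p$c3$b)
  list(o = o, cache = list(x = x, a1 = a1, f1 = f1, p1 = p1, a2 = a2,
                           f2 = f2, p2 = p2))
}

disc_backward <- function(p, cache, do) {
  b3 <- cpp_conv3x3_bwd(cache$p2, p$c3$w, do)
  df2 <- avgpool2_bwd(b3$dx) * ifelse(cache$a2 > 0, 1, 0.2)
  b2 <- cpp_conv3x3_bwd(cache$p1, p$c2$w, df2)
  df1 <- avgpool2_bwd(b2$dx) * ifelse(cache$a1 > 0, 1, 0.2)
  b1 <- cpp_conv3x3_bwd(cache$x, p$c1$w, df1)
  list(dx = b1$dx,
       grads = list(c1 = list(w = b1$dw, b = b1$db),
                    c2 = list(w = b2$dw, b = b2$db),
                    c3 = list(w = b3$dw, b = b3$db)))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = "ANY")
}

# params/grads/state share nesting: list of layers, each list(w, b).
adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (ly in names(params)) {
    for (pn in names(params[[ly]])) {
      g <- grads[[ly]][[pn]]
      st <- state[[ly]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[ly]][[pn]] <- params[[ly]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      state[[ly]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (ly in names(b)) for (pn in names(b[[ly]]))
    a[[ly]][[pn]] <- a[[ly]][[pn]] + b[[ly]][[pn]]
  a
}

grads_scale <- function(a, s) {
  for (ly in names(a)) for (pn in names(a[[ly]]))
    a[[ly]][[pn]] <- a[[ly]][[pn]] * s
  a
}

n_params <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
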