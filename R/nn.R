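# Network internals: layer wrappers around the compiled kernels, the
# inception block and full U-shaped forward/backward passes, the per-pixel
# softmax cross-entropy, and Adam.  Feature maps are (H, W, C) arrays.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

channel_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

init_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_inception_params <- function(cin, branch, cout) {
  list(b1w = init_conv(1, 1, cin, branch), b1b = numeric(branch),
       b2aw = init_conv(1, 1, cin, branch), b2ab = numeric(branch),
       b2bw = init_conv(3, 3, branch, branch), b2bb = numeric(branch),
       redw = init_conv(1, 1, 2 * branch, cout), redb = numeric(cout))
}

# forward through one inception block; returns activations needed by the
# backward pass
incep_fwd <- function(x, p) {
  a1 <- relu(cpp_conv2d_fwd(x, p$b1w, p$b1b))
  a2 <- relu(cpp_conv2d_fwd(x, p$b2aw, p$b2ab))
  a3 <- relu(cpp_conv2d_fwd(a2, p$b2bw, p$b2bb))
  cc <- channel_concat(a1, a3)
  out <- relu(cpp_conv2d_fwd(cc, p$redw, p$redb))
  list(out = out, x = x, a1 = a1, a2 = a2, a3 = a3, cc = cc)
}

incep_bwd <- function(g, cache, p) {
  g <- g * (cache$out > 0)
  rb <- cpp_conv2d_bwd(cache$cc, p$redw, g)
  c1 <- dim(cache$a1)[3]
  ga1 <- rb$gx[, , seq_len(c1), drop = FALSE] * (cache$a1 > 0)
  ga3 <- rb$gx[, , c1 + seq_len(c1), drop = FALSE] * (cache$a3 > 0)
  b2b <- cpp_conv2d_bwd(cache$a2, p$b2bw, ga3)
  ga2 <- b2b$gx * (cache$a2 > 0)
  b2a <- cpp_conv2d_bwd(cache$x, p$b2aw, ga2)
  b1 <- cpp_conv2d_bwd(cache$x, p$b1w, ga1)
  list(gx = b1$gx + b2a$gx,
       grads = list(b1w = b1$gw, b1b = b1$gb, b2aw = b2a$gw, b2ab = b2a$gb,
                    b2bw = b2b$gw, b2bb = b2b$gb, redw = rb$gw, redb = rb$gb))
}

# Full forward pass.  x: (H, W, 3) in [0, 1], H and W divisible by
# 2^n_downsamplings.  Returns logits plus (optionally) every cache the
# backward pass needs.
unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  nd <- cfg$n_downsamplings
  d <- dim(x)
  if (d[1] %% 2^nd != 0 || d[2] %% 2^nd != 0) {
    stop_input("input %dx%d not divisible by %d; pad explicitly (predict_mask does)",
               d[2], d[1], 2^nd)
  }
  p <- model$params
  enc_out <- vector("list", nd)
  enc_cache <- if (keep_cache) vector("list", nd) else NULL
  pool_idx <- vector("list", nd)
  cur <- x
  for (k in seq_len(nd)) {
    ic <- incep_fwd(cur, p[[paste0("enc", k)]])
    enc_out[[k]] <- ic$out
    mp <- cpp_maxpool_fwd(ic$out)
    if (keep_cache) enc_cache[[k]] <- ic
    pool_idx[[k]] <- mp$idx
    cur <- mp$out
  }
  bt <- incep_fwd(cur, p$bott)
  cur <- bt$out
  dec_cache <- if (keep_cache) vector("list", nd) else NULL
  for (k in rev(seq_len(nd))) {
    dp <- p[[paste0("dec", k)]]
    up <- cpp_upconv_fwd(cur, dp$upw, dp$upb)
    cc <- channel_concat(up, enc_out[[k]])
    act <- relu(cpp_conv2d_fwd(cc, dp$convw, dp$convb))
    if (keep_cache) dec_cache[[k]] <- list(xin = cur, cc = cc, act = act)
    cur <- act
  }
  logits <- cpp_conv2d_fwd(cur, p$head$w, p$head$b)
  res <- list(logits = logits)
  if (keep_cache) {
    res$cache <- list(enc = enc_cache, pool_idx = pool_idx, bott = bt,
                      dec = dec_cache)
  }
  res
}

unet_backward <- function(model, cache, glogits) {
  cfg <- model$config
  nd <- cfg$n_downsamplings
  p <- model$params
  grads <- list()

  hb <- cpp_conv2d_bwd(cache$dec[[1]]$act, p$head$w, glogits)
  grads$head <- list(w = hb$gw, b = hb$gb)
  g <- hb$gx
  gskip <- vector("list", nd)
  for (k in seq_len(nd)) {
    dc <- cache$dec[[k]]
    dp <- p[[paste0("dec", k)]]
    g <- g * (dc$act > 0)
    cb <- cpp_conv2d_bwd(dc$cc, dp$convw, g)
    cup <- dim(dp$upw)[4]  # upconv output channels
    gcc <- cb$gx
    gup <- gcc[, , seq_len(cup), drop = FALSE]
    gskip[[k]] <- gcc[, , cup + seq_len(dim(gcc)[3] - cup), drop = FALSE]
    ub <- cpp_upconv_bwd(dc$xin, dp$upw, gup)
    grads[[paste0("dec", k)]] <- list(upw = ub$gw, upb = ub$gb,
                                      convw = cb$gw, convb = cb$gb)
    g <- ub$gx
  }
  bt <- incep_bwd(g, cache$bott, p$bott)
  grads$bott <- bt$grads
  g <- bt$gx
  for (k in rev(seq_len(nd))) {
    ec <- cache$enc[[k]]
    d_e <- dim(ec$out)
    ge <- cpp_maxpool_bwd(g, cache$pool_idx[[k]], d_e[1], d_e[2]) + gskip[[k]]
    eb <- incep_bwd(ge, ec, p[[paste0("enc", k)]])
    grads[[paste0("enc", k)]] <- eb$grads
    g <- eb$gx
  }
  grads
}

# numerically stable per-pixel softmax cross-entropy for the 2-class head;
# labels: (H, W) integer matrix in {0, 1}
softmax_ce <- function(logits, labels) {
  l0 <- logits[, , 1]; l1 <- logits[, , 2]
  m <- pmax(l0, l1)
  e0 <- exp(l0 - m); e1 <- exp(l1 - m)
  s <- e0 + e1
  logp0 <- (l0 - m) - log(s)
  logp1 <- (l1 - m) - log(s)
  loss <- -mean(labels * logp1 + (1 - labels) * logp0)
  npix <- length(labels)
  p0 <- e0 / s; p1 <- e1 / s
  glogits <- array(c((p0 - (1 - labels)) / npix, (p1 - labels) / npix),
                   dim(logits))
  # tie (p1 == p0) decodes to background, matching predict_mask
  acc <- mean((p1 > p0) == (labels == 1))
  list(loss = loss, glogits = glogits, accuracy = acc)
}

softmax_probs <- function(logits) {
  l0 <- logits[, , 1]; l1 <- logits[, , 2]
  m <- pmax(l0, l1)
  e0 <- exp(l0 - m); e1 <- exp(l1 - m)
  s <- e0 + e1
  array(c(e0 / s, e1 / s), dim(logits))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(stage) lapply(stage, function(a) a * 0))
  list(t = 0L, m = zeros, v = zeros)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (sn in names(params)) {
    for (pn in names(params[[sn]])) {
      g <- grads[[sn]][[pn]]
      m <- beta1 * state$m[[sn]][[pn]] + (1 - beta1) * g
      v <- beta2 * state$v[[sn]][[pn]] + (1 - beta2) * g * g
      state$m[[sn]][[pn]] <- m
      state$v[[sn]][[pn]] <- v
      params[[sn]][[pn]] <- params[[sn]][[pn]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (sn in names(grads)) {
    for (pn in names(grads[[sn]])) {
      acc[[sn]][[pn]] <- acc[[sn]][[pn]] + grads[[sn]][[pn]]
    }
  }
  acc
}

scale_grads <- function(grads, f) {
  lapply(grads, function(stage) lapply(stage, function(a) a * f))
}
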