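# Minimal neural-network engine for the phase-branch classifier.
#
# One branch maps a window tensor [B, n_win, win_len, n_sweeps] to class
# logits: per window a valid 1-D convolution over time (n_sweeps input
# channels) -> ReLU -> max pooling -> dense -> ReLU gives a window embedding;
# the window sequence runs through a BiLSTM (forward and backward passes
# concatenated) -> dropout -> additive attention over windows (normalized
# weights) -> attention-weighted sequence -> global max pooling over windows
# -> dense logits. All gradients are derived by hand and verified against
# numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# parameter initialization for one branch; draws from the current RNG state
init_branch <- function(cfg, win_len, n_sweeps) {
  k <- cfg$conv_kernel; f <- cfg$conv_filters
  if (k > win_len)
    stop(sprintf("conv kernel (%d samples) exceeds the window length (%d samples)",
                 k, win_len))
  lc <- win_len - k + 1L
  lp <- lc %/% cfg$pool_size
  if (lp < 1L) stop("pooling leaves no time positions; reduce pool_size or kernel")
  d <- cfg$dense_units; h <- cfg$lstm_units; a <- cfg$attn_units
  nc <- cfg$n_classes
  lstm_init <- function() {
    b <- rep(0, 4 * h); b[(h + 1):(2 * h)] <- 1  # forget-gate bias at 1
    list(Wx = glorot(d, 4 * h), Wh = glorot(h, 4 * h), b = b)
  }
  list(conv_W = glorot(k * n_sweeps, f), conv_b = rep(0, f),
       d1_W = glorot(lp * f, d), d1_b = rep(0, d),
       fw = lstm_init(), bw = lstm_init(),
       attn_W = glorot(2 * h, a), attn_b = rep(0, a), attn_v = glorot(a, 1)[, 1],
       out_W = glorot(2 * h, nc), out_b = rep(0, nc),
       dims = list(win_len = win_len, n_sweeps = n_sweeps, lc = lc, lp = lp,
                   pool_size = cfg$pool_size))
}

# ---- forward ---------------------------------------------------------------

lstm_run <- function(par, xs, reverse = FALSE) {
  # xs: list of [B, D] inputs per step; returns hidden states + caches
  nw <- length(xs); b <- nrow(xs[[1]]); h <- nrow(par$Wh)
  ord <- if (reverse) rev(seq_len(nw)) else seq_len(nw)
  hs <- vector("list", nw); cache <- vector("list", nw)
  h_prev <- matrix(0, b, h); c_prev <- matrix(0, b, h)
  for (w in ord) {
    z <- xs[[w]] %*% par$Wx + h_prev %*% par$Wh +
      matrix(par$b, b, 4 * h, byrow = TRUE)
    i <- sigmoid(z[, 1:h, drop = FALSE])
    f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    hh <- o * tc
    cache[[w]] <- list(i = i, f = f, g = g, o = o, c = cc, tc = tc,
                       h_prev = h_prev, c_prev = c_prev, x = xs[[w]])
    hs[[w]] <- hh
    h_prev <- hh; c_prev <- cc
  }
  list(hs = hs, cache = cache, order = ord)
}

branch_forward <- function(par, x, dropout_rate = 0, train = FALSE) {
  dm <- dim(x)  # [B, nw, wl, C]
  b <- dm[1]; nw <- dm[2]; wl <- dm[3]; cin <- dm[4]
  dd <- par$dims; lc <- dd$lc; lp <- dd$lp
  k <- nrow(par$conv_W) / cin
  f <- ncol(par$conv_W)
  bnw <- b * nw
  # window batch matrix [bnw, wl*cin]; row index b + (w-1)*B
  xm <- matrix(x, bnw, wl * cin)
  # im2col: column of patch r = (c-1)*k + j+1 maps to xm column (c-1)*wl + l + j
  colidx <- matrix(0L, lc, k * cin)
  for (c_ in seq_len(cin)) for (j in seq_len(k))
    colidx[, (c_ - 1L) * k + j] <- (c_ - 1L) * wl + seq_len(lc) + (j - 1L)
  patches <- matrix(0, bnw * lc, k * cin)  # row = bw + (l-1)*bnw
  for (r in seq_len(k * cin))
    patches[, r] <- as.vector(xm[, colidx[, r]])
  zc <- patches %*% par$conv_W +
    matrix(par$conv_b, nrow(patches), f, byrow = TRUE)
  ac <- pmax(zc, 0)
  aca <- array(ac, dim = c(bnw, lc, f))
  # max pool over time positions
  pooled <- array(0, dim = c(bnw, lp, f))
  argmax <- array(0L, dim = c(bnw, lp, f))
  s <- dd$pool_size  # positions beyond lp*s are dropped (valid pooling)
  for (q in seq_len(lp)) {
    sl <- aca[, ((q - 1L) * s + 1L):(q * s), , drop = FALSE]
    mx <- sl[, 1L, , drop = FALSE]; am <- array(1L, dim = c(bnw, 1L, f))
    if (dim(sl)[2] > 1L) for (j in 2:dim(sl)[2]) {
      upd <- sl[, j, , drop = FALSE] > mx
      mx[upd] <- sl[, j, , drop = FALSE][upd]
      am[upd] <- j
    }
    pooled[, q, ] <- mx[, 1L, ]
    argmax[, q, ] <- am[, 1L, ]
  }
  flat <- matrix(pooled, bnw, lp * f)
  z1 <- flat %*% par$d1_W + matrix(par$d1_b, bnw, length(par$d1_b), byrow = TRUE)
  h1 <- pmax(z1, 0)
  xs <- lapply(seq_len(nw), function(w) h1[((w - 1L) * b + 1L):(w * b), , drop = FALSE])
  lf <- lstm_run(par$fw, xs, reverse = FALSE)
  lb <- lstm_run(par$bw, xs, reverse = TRUE)
  h <- nrow(par$fw$Wh)
  hcat <- lapply(seq_len(nw), function(w) cbind(lf$hs[[w]], lb$hs[[w]])) # [B,2H] x nw
  if (train && dropout_rate > 0) {
    masks <- lapply(seq_len(nw), function(w)
      matrix(stats::rbinom(b * 2 * h, 1L, 1 - dropout_rate), b, 2 * h) /
        (1 - dropout_rate))
    hd <- lapply(seq_len(nw), function(w) hcat[[w]] * masks[[w]])
  } else {
    masks <- NULL
    hd <- hcat
  }
  # additive attention over windows
  tt <- vector("list", nw)
  e <- matrix(0, b, nw)
  for (w in seq_len(nw)) {
    pre <- hd[[w]] %*% par$attn_W +
      matrix(par$attn_b, b, length(par$attn_b), byrow = TRUE)
    tt[[w]] <- tanh(pre)
    e[, w] <- tt[[w]] %*% par$attn_v
  }
  alpha <- softmax_rows(e)
  context <- matrix(0, b, 2 * h)
  for (w in seq_len(nw)) context <- context + alpha[, w] * hd[[w]]
  # attention-weighted sequence, then global max pool over windows
  # weights scaled by nw so uniform attention leaves magnitudes unchanged
  g_val <- (nw * alpha[, 1]) * hd[[1]]
  g_arg <- matrix(1L, b, 2 * h)
  if (nw > 1L) for (w in 2:nw) {
    sw <- (nw * alpha[, w]) * hd[[w]]
    upd <- sw > g_val
    g_val[upd] <- sw[upd]
    g_arg[upd] <- w
  }
  logits <- g_val %*% par$out_W +
    matrix(par$out_b, b, length(par$out_b), byrow = TRUE)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, alpha = alpha, context = context,
       cache = list(x = x, xm = xm, colidx = colidx, patches = patches,
                    zc = zc, argmax = argmax, s = s, flat = flat, z1 = z1,
                    h1 = h1, lf = lf, lb = lb, hcat = hcat, hd = hd,
                    masks = masks, tt = tt, alpha = alpha, g_val = g_val,
                    g_arg = g_arg, b = b, nw = nw, wl = wl, cin = cin))
}

# ---- backward --------------------------------------------------------------

lstm_backward <- function(par, run, dhs) {
  # dhs: list of [B, H] output gradients per step (in sequence order)
  nw <- length(dhs); b <- nrow(dhs[[1]]); h <- nrow(par$Wh)
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dxs <- vector("list", nw)
  dh_next <- matrix(0, b, h); dc_next <- matrix(0, b, h)
  for (w in rev(run$order)) {
    cc <- run$cache[[w]]
    dh <- dhs[[w]] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + t(cc$x) %*% dz
    dWh <- dWh + t(cc$h_prev) %*% dz
    db <- db + colSums(dz)
    dxs[[w]] <- dz %*% t(par$Wx)
    dh_next <- dz %*% t(par$Wh)
    dc_next <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dxs = dxs)
}

branch_backward <- function(par, fwd, dlogits) {
  cc <- fwd$cache
  b <- cc$b; nw <- cc$nw; wl <- cc$wl; cin <- cc$cin
  dd <- par$dims; lc <- dd$lc; lp <- dd$lp
  f <- ncol(par$conv_W); h <- nrow(par$fw$Wh)
  bnw <- b * nw
  grads <- list()
  grads$out_W <- t(cc$g_val) %*% dlogits
  grads$out_b <- colSums(dlogits)
  dg <- dlogits %*% t(par$out_W)  # [B, 2H]
  # scatter through global max pool, then split into attention / hidden paths
  dhd <- lapply(seq_len(nw), function(w) matrix(0, b, 2 * h))
  dalpha <- matrix(0, b, nw)
  for (w in seq_len(nw)) {
    sel <- (cc$g_arg == w) * dg       # gradient landing on window w
    dalpha[, w] <- nw * rowSums(sel * cc$hd[[w]])
    dhd[[w]] <- dhd[[w]] + sel * (nw * fwd$alpha[, w])
  }
  # attention scores
  de <- fwd$alpha * (dalpha - rowSums(dalpha * fwd$alpha))
  grads$attn_W <- par$attn_W * 0
  grads$attn_b <- par$attn_b * 0
  grads$attn_v <- par$attn_v * 0
  for (w in seq_len(nw)) {
    tw <- cc$tt[[w]]
    grads$attn_v <- grads$attn_v + as.vector(t(tw) %*% de[, w])
    dpre <- (de[, w] %o% par$attn_v) * (1 - tw^2)
    grads$attn_W <- grads$attn_W + t(cc$hd[[w]]) %*% dpre
    grads$attn_b <- grads$attn_b + colSums(dpre)
    dhd[[w]] <- dhd[[w]] + dpre %*% t(par$attn_W)
  }
  # dropout
  dhcat <- if (!is.null(cc$masks))
    lapply(seq_len(nw), function(w) dhd[[w]] * cc$masks[[w]]) else dhd
  dh_f <- lapply(dhcat, function(m) m[, 1:h, drop = FALSE])
  dh_b <- lapply(dhcat, function(m) m[, (h + 1):(2 * h), drop = FALSE])
  bf <- lstm_backward(par$fw, cc$lf, dh_f)
  bb <- lstm_backward(par$bw, cc$lb, dh_b)
  grads$fw <- bf[c("Wx", "Wh", "b")]
  grads$bw <- bb[c("Wx", "Wh", "b")]
  # back into window embeddings
  dh1 <- matrix(0, bnw, ncol(par$d1_W))
  for (w in seq_len(nw)) {
    rows <- ((w - 1L) * b + 1L):(w * b)
    dh1[rows, ] <- bf$dxs[[w]] + bb$dxs[[w]]
  }
  dz1 <- dh1 * (cc$z1 > 0)
  grads$d1_W <- t(cc$flat) %*% dz1
  grads$d1_b <- colSums(dz1)
  dflat <- dz1 %*% t(par$d1_W)
  dpool <- array(dflat, dim = c(bnw, lp, f))
  dac <- array(0, dim = c(bnw, lc, f))
  s <- cc$s
  for (q in seq_len(lp)) {
    base_l <- (q - 1L) * s
    for (j in seq_len(s)) {
      hit <- cc$argmax[, q, ] == j
      tmp <- dac[, base_l + j, ]
      tmp[hit] <- tmp[hit] + dpool[, q, ][hit]
      dac[, base_l + j, ] <- tmp
    }
  }
  dzc <- matrix(dac, bnw * lc, f) * (cc$zc > 0)
  grads$conv_W <- t(cc$patches) %*% dzc
  grads$conv_b <- colSums(dzc)
  grads
}

# ---- optimiser -------------------------------------------------------------

# flatten nested parameter lists (branch lists contain fw/bw sublists)
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    if (nm == "dims") next
    v <- p[[nm]]
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(prefix, nm, ".")))
    else out[[paste0(prefix, nm)]] <- v
  }
  out
}

assign_flat <- function(p, flat, prefix = "") {
  for (nm in names(p)) {
    if (nm == "dims") next
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v)) p[[nm]] <- assign_flat(v, flat, paste0(key, "."))
    else p[[nm]] <- flat[[key]]
  }
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(flat = flat, state = state)
}

n_branch_params <- function(par) {
  sum(vapply(flatten_params(par), length, integer(1)))
}
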