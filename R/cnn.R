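# Minimal 2-D convolutional network engine: same-padding 3x3 convolutions,
# per-channel batch normalization, 2x2 max pooling, inverted dropout, dense
# layers and softmax cross-entropy, trained with Adam. Inputs are arrays of
# shape (N, H, W) single-channel feature grids. Convolution is vectorized
# as a sum of per-kernel-offset matrix products, which is fast at the small
# grid sizes (8 x 14) this package works with.

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(y, x) 1 - y^2),
    relu = list(f = function(x) pmax(x, 0), df = function(y, x) (x > 0) * 1),
    selu = {
      a <- 1.6732632423543772; l <- 1.0507009873554805
      list(f = function(x) l * ifelse(x > 0, x, a * (exp(x) - 1)),
           df = function(y, x) l * ifelse(x > 0, 1, a * exp(x)))
    },
    linear = list(f = identity, df = function(y, x) 1),
    stopf("unknown activation '%s'", name))
}

conv_init <- function(cin, f, k, gen) {
  fan_in <- k * k * cin; fan_out <- k * k * f
  sd_ <- sqrt(2 / (fan_in + fan_out))
  list(W = array(gen(k * k * cin * f) * sd_, c(k, k, cin, f)),
       b = numeric(f))
}

# im2col gather indices are pure shape functions; cache them per shape so a
# training run pays the construction cost once per batch geometry.
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(N, H, W_, cin, k) {
  key <- paste(N, H, W_, cin, k, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (k - 1L) %/% 2L
  HW <- H * W_
  pos_i <- rep(seq_len(H), W_)
  pos_j <- rep(seq_len(W_), each = H)
  # spatial source index per kernel offset; offset order (dj outer, di
  # inner) matches the flattening of the (k, k, cin, f) weight array
  sp <- matrix(NA_integer_, HW, k * k)
  o <- 0L
  for (dj in -r:r) for (di in -r:r) {
    o <- o + 1L
    si <- pos_i + di; sj <- pos_j + dj
    ok <- si >= 1L & si <= H & sj >= 1L & sj <= W_
    sp[ok, o] <- si[ok] + H * (sj[ok] - 1L)
  }
  rn <- rep(seq_len(N), HW)
  rp <- rep(seq_len(HW), each = N)
  m1 <- rn + N * (sp[rp, , drop = FALSE] - 1L)      # (N*HW) x k^2, NA = pad
  idx <- m1[, rep(seq_len(k * k), cin), drop = FALSE] +
    matrix(rep((seq_len(cin) - 1L) * N * HW, each = k * k),
           N * HW, k * k * cin, byrow = TRUE)
  pad <- N * HW * cin + 1L                          # points at appended zero
  idx[is.na(idx)] <- pad
  out <- list(idx = idx, sp = sp, pad = pad)
  .im2col_cache[[key]] <- out
  out
}

conv_forward <- function(x, par) {
  d <- dim(x); N <- d[1]; H <- d[2]; W_ <- d[3]; cin <- d[4]
  k <- dim(par$W)[1]; f <- dim(par$W)[4]
  ic <- im2col_idx(N, H, W_, cin, k)
  cols <- matrix(c(x, 0)[ic$idx], N * H * W_, k * k * cin)
  out <- cols %*% matrix(par$W, k * k * cin, f)
  out <- sweep(out, 2L, par$b, "+")
  list(out = array(out, c(N, H, W_, f)),
       cache = list(cols = cols, dim = d, ic = ic))
}

conv_backward <- function(dout, par, cache) {
  d <- cache$dim; N <- d[1]; H <- d[2]; W_ <- d[3]; cin <- d[4]
  k <- dim(par$W)[1]; f <- dim(par$W)[4]
  HW <- H * W_
  dm <- matrix(dout, N * HW, f)
  dW <- array(crossprod(cache$cols, dm), dim(par$W))
  dcols <- dm %*% t(matrix(par$W, k * k * cin, f))
  # scatter columns back; within one offset the spatial map is injective,
  # so plain column addition on the (N, HW*cin) view is collision-free
  dxm <- matrix(0, N, HW * cin)
  sp <- cache$ic$sp
  cblock <- (seq_len(cin) - 1L)
  for (o in seq_len(k * k)) {
    ok <- which(!is.na(sp[, o]))
    if (!length(ok)) next
    bo <- dcols[, o + cblock * k * k, drop = FALSE]   # (N*HW) x cin
    dim(bo) <- c(N, HW * cin)                         # free reshape
    src <- rep(ok, cin) + rep(cblock * HW, each = length(ok))
    tgt <- rep(sp[ok, o], cin) + rep(cblock * HW, each = length(ok))
    dxm[, tgt] <- dxm[, tgt] + bo[, src, drop = FALSE]
  }
  list(dx = array(dxm, d), dW = dW, db = colSums(dm))
}

bn_forward <- function(x, par, training, eps = 1e-5, momentum = 0.9) {
  d <- dim(x); cc <- d[4]
  xm <- matrix(x, prod(d[1:3]), cc)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)
    par$run_mean <- momentum * par$run_mean + (1 - momentum) * mu
    par$run_var <- momentum * par$run_var + (1 - momentum) * v
  } else {
    mu <- par$run_mean; v <- par$run_var
  }
  xhat <- sweep(sweep(xm, 2L, mu), 2L, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  list(out = array(out, d), par = par,
       cache = list(xhat = xhat, v = v, eps = eps, dim = d))
}

bn_backward <- function(dout, par, cache) {
  d <- cache$dim; m <- prod(d[1:3])
  dm <- matrix(dout, m, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, par$gamma, "*")
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  dx <- sweep(dxhat, 2L, colMeans(dxhat)) -
    sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dx <- sweep(dx, 2L, inv_sd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

.pool_cache <- new.env(parent = emptyenv())

pool_idx <- function(N, H, W_, cc) {
  key <- paste(N, H, W_, cc, sep = "x")
  hit <- .pool_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W_ %/% 2L
  if (Ho < 1L || Wo < 1L) stopf("input too small for 2x2 max pooling")
  # linear indices into the (N,H,W,C) array for the 4 pooling candidates
  n_ <- rep(seq_len(N), times = Ho * Wo * cc)
  i_ <- rep(rep(seq_len(Ho), each = N), times = Wo * cc)
  j_ <- rep(rep(seq_len(Wo), each = N * Ho), times = cc)
  c_ <- rep(seq_len(cc), each = N * Ho * Wo)
  lin <- function(ii, jj) n_ + N * (ii - 1L) + N * H * (jj - 1L) +
    N * H * W_ * (c_ - 1L)
  idx <- list(lin(2L * i_ - 1L, 2L * j_ - 1L), lin(2L * i_, 2L * j_ - 1L),
              lin(2L * i_ - 1L, 2L * j_), lin(2L * i_, 2L * j_))
  out <- list(idx = idx, odim = c(N, Ho, Wo, cc))
  .pool_cache[[key]] <- out
  out
}

pool_forward <- function(x) {
  d <- dim(x)
  pi_ <- pool_idx(d[1], d[2], d[3], d[4])
  xv <- as.numeric(x)
  out <- xv[pi_$idx[[1]]]; arg <- rep.int(1L, length(out))
  for (k in 2:4) {
    ck <- xv[pi_$idx[[k]]]
    sel <- ck > out                 # ties keep the earlier candidate
    out[sel] <- ck[sel]
    arg[sel] <- k
  }
  list(out = array(out, pi_$odim),
       cache = list(arg = arg, dim = d, pi = pi_))
}

pool_backward <- function(dout, cache) {
  dx <- numeric(prod(cache$dim))
  dv <- as.numeric(dout)
  for (k in 1:4) {
    sel <- cache$arg == k
    dx[cache$pi$idx[[k]][sel]] <- dv[sel]
  }
  array(dx, cache$dim)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- network assembly -------------------------------------------------

layer_stack <- function(arch, n_classes, cfg) {
  conv <- function(f) list(type = "conv", filters = f,
                           act = cfg$conv_activation)
  dense <- function(u, act) list(type = "dense", units = u, act = act)
  bn <- list(type = "bn")
  pool <- list(type = "pool")
  drop <- list(type = "dropout", rate = cfg$dropout_rate)
  fl <- list(type = "flatten")
  out <- dense(n_classes, "linear")   # softmax applied with the loss
  switch(arch,
    "LM-CNN" = c(list(conv(cfg$conv_filters[1])), if (cfg$batch_norm) list(bn),
                 list(conv(cfg$conv_filters[2])), if (cfg$batch_norm) list(bn),
                 list(pool, drop, fl,
                      dense(cfg$dense_units, cfg$dense_activation), out)),
    "CNN2" = list(conv(cfg$conv_filters[1]), pool, conv(cfg$conv_filters[2]),
                  pool, fl, dense(100L, "selu"), out),
    "CNN3" = list(conv(cfg$conv_filters[1]), pool, fl, dense(256L, "selu"), out),
    "CNN4" = list(conv(cfg$conv_filters[1]), conv(cfg$conv_filters[2]), pool,
                  fl, dense(256L, "selu"), out),
    stopf("unknown architecture '%s'", arch))
}

init_network <- function(layers, input_shape) {
  H <- input_shape[1]; W_ <- input_shape[2]; cin <- 1L
  flat <- NA_integer_
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      layers[[i]]$par <- conv_init(cin, ly$filters, 3L, stats::rnorm)
      cin <- ly$filters
    } else if (ly$type == "bn") {
      layers[[i]]$par <- list(gamma = rep(1, cin), beta = numeric(cin),
                              run_mean = numeric(cin), run_var = rep(1, cin))
    } else if (ly$type == "pool") {
      if (H < 2L || W_ < 2L) stopf("input too small for the conv/pool stack")
      H <- H %/% 2L; W_ <- W_ %/% 2L
    } else if (ly$type == "flatten") {
      flat <- H * W_ * cin
    } else if (ly$type == "dense") {
      fan_in <- if (is.na(flat)) cin else flat
      sd_ <- sqrt(2 / (fan_in + ly$units))
      layers[[i]]$par <- list(W = matrix(stats::rnorm(fan_in * ly$units) * sd_,
                                         fan_in, ly$units),
                              b = numeric(ly$units))
      flat <- NA_integer_
      cin <- ly$units
    }
  }
  layers
}

network_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  h <- x                 # (N,H,W,1) array until flatten, then matrix
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(h, ly$par)
      a <- act_fun(ly$act)
      y <- a$f(cf$out)
      caches[[i]] <- list(conv = cf$cache, pre = cf$out, post = y)
      h <- y
    } else if (ly$type == "bn") {
      bf <- bn_forward(h, ly$par, training)
      layers[[i]]$par <- bf$par
      caches[[i]] <- bf$cache
      h <- bf$out
    } else if (ly$type == "pool") {
      pf <- pool_forward(h)
      caches[[i]] <- pf$cache
      h <- pf$out
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- array((stats::runif(length(h)) >= ly$rate) / (1 - ly$rate),
                      dim(h))
        caches[[i]] <- mask
        h <- h * mask
      }
    } else if (ly$type == "flatten") {
      d <- dim(h)
      caches[[i]] <- d
      h <- matrix(h, d[1], prod(d[-1]))
    } else if (ly$type == "dense") {
      pre <- sweep(h %*% ly$par$W, 2L, ly$par$b, "+")
      a <- act_fun(ly$act)
      y <- a$f(pre)
      caches[[i]] <- list(x = h, pre = pre, post = y)
      h <- y
    }
  }
  list(out = h, caches = caches, layers = layers)
}

network_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  g <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      a <- act_fun(ly$act)
      gpre <- g * a$df(caches[[i]]$post, caches[[i]]$pre)
      grads[[i]] <- list(dW = crossprod(caches[[i]]$x, gpre),
                         db = colSums(gpre))
      g <- gpre %*% t(ly$par$W)
    } else if (ly$type == "flatten") {
      g <- array(g, caches[[i]])
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) g <- g * caches[[i]]
    } else if (ly$type == "pool") {
      g <- pool_backward(g, caches[[i]])
    } else if (ly$type == "bn") {
      bb <- bn_backward(g, ly$par, caches[[i]])
      grads[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
      g <- bb$dx
    } else if (ly$type == "conv") {
      a <- act_fun(ly$act)
      gpre <- g * a$df(caches[[i]]$post, caches[[i]]$pre)
      cb <- conv_backward(gpre, ly$par, caches[[i]]$conv)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      g <- cb$dx
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(ly) {
    if (is.null(ly$par)) return(NULL)
    nm <- intersect(names(ly$par), c("W", "b", "gamma", "beta"))
    st <- lapply(ly$par[nm], function(p) list(m = p * 0, v = p * 0))
    st
  })
}

adam_update <- function(layers, grads, state, t, lr, b1, b2, eps = 1e-8) {
  map <- c(dW = "W", db = "b", dgamma = "gamma", dbeta = "beta")
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (gn in names(grads[[i]])) {
      pn <- map[[gn]]
      g <- grads[[i]][[gn]]
      st <- state[[i]][[pn]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      layers[[i]]$par[[pn]] <- layers[[i]]$par[[pn]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[pn]] <- st
    }
  }
  list(layers = layers, state = state)
}
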