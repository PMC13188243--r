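#' @include AllClasses.R
NULL

# Minimal neural-network engine: dense, 1-D conv, LSTM and GRU bodies with a
# shared two-layer perceptron head, trained by Adam on mean squared error.
# Everything is plain base-R matrix code so runs are deterministic and
# reproducible from a seed on any single-threaded BLAS.

.sigm <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) pmax(x, 0)

.unif <- function(n, fanIn) stats::runif(n, -1 / sqrt(fanIn), 1 / sqrt(fanIn))

.initBody <- function(architecture, inputLen, nVars, hyper) {
  switch(architecture,
    dnn = {
      U <- hyper$dnnUnits
      list(W1 = matrix(.unif(inputLen * nVars * U, inputLen * nVars),
                       inputLen * nVars, U),
           b1 = numeric(U))
    },
    cnn = {
      C <- hyper$channels; k <- 3L
      list(Wc1 = matrix(.unif(k * nVars * C, k * nVars), k * nVars, C),
           bc1 = numeric(C),
           Wc2 = matrix(.unif(k * C * C, k * C), k * C, C),
           bc2 = numeric(C))
    },
    lstm = {
      U <- hyper$units
      b <- numeric(4L * U)
      b[(U + 1L):(2L * U)] <- 1  # forget-gate bias init
      list(Wx = matrix(.unif(nVars * 4L * U, nVars), nVars, 4L * U),
           Wh = matrix(.unif(U * 4L * U, U), U, 4L * U),
           b = b)
    },
    gru = {
      U <- hyper$units
      list(Wx = matrix(.unif(nVars * 3L * U, nVars), nVars, 3L * U),
           Wh = matrix(.unif(U * 3L * U, U), U, 3L * U),
           b = numeric(3L * U))
    },
    stop("unknown architecture '", architecture, "'"))
}

.featureDim <- function(architecture, hyper) {
  switch(architecture,
         dnn = hyper$dnnUnits,
         cnn = hyper$channels,
         lstm = hyper$units,
         gru = hyper$units)
}

# ---- body forward/backward ----------------------------------------------

# X: B x L x V (scaled). Returns list(feat = B x F, cache).
.bodyForward <- function(architecture, body, X) {
  B <- dim(X)[1L]; L <- dim(X)[2L]; V <- dim(X)[3L]
  switch(architecture,
    dnn = {
      Xf <- matrix(X, B, L * V)
      Z <- sweep(Xf %*% body$W1, 2L, body$b1, `+`)
      H <- .relu(Z)
      list(feat = H, cache = list(Xf = Xf, Z = Z))
    },
    cnn = {
      c1 <- .convForward(X, body$Wc1, body$bc1)
      c2 <- .convForward(c1$A, body$Wc2, body$bc2)
      feat <- t(vapply(seq_len(B), function(b)
        colMeans(matrix(c2$A[b, , ], L, dim(c2$A)[3L])),
        numeric(dim(c2$A)[3L])))
      list(feat = feat, cache = list(c1 = c1, c2 = c2, L = L))
    },
    lstm = {
      U <- ncol(body$Wh) / 4L
      H <- matrix(0, B, U); Cc <- matrix(0, B, U)
      steps <- vector("list", L)
      for (t in seq_len(L)) {
        Xt <- matrix(X[, t, ], B, V)
        Z <- sweep(Xt %*% body$Wx + H %*% body$Wh, 2L, body$b, `+`)
        i <- .sigm(Z[, 1:U, drop = FALSE])
        f <- .sigm(Z[, (U + 1L):(2L * U), drop = FALSE])
        g <- tanh(Z[, (2L * U + 1L):(3L * U), drop = FALSE])
        o <- .sigm(Z[, (3L * U + 1L):(4L * U), drop = FALSE])
        Cn <- f * Cc + i * g
        tC <- tanh(Cn)
        Hn <- o * tC
        steps[[t]] <- list(Xt = Xt, Hprev = H, Cprev = Cc, i = i, f = f,
                           g = g, o = o, tC = tC)
        H <- Hn; Cc <- Cn
      }
      list(feat = H, cache = list(steps = steps, U = U))
    },
    gru = {
      U <- ncol(body$Wh) / 3L
      H <- matrix(0, B, U)
      steps <- vector("list", L)
      iz <- 1:U; ir <- (U + 1L):(2L * U); inn <- (2L * U + 1L):(3L * U)
      for (t in seq_len(L)) {
        Xt <- matrix(X[, t, ], B, V)
        Ax <- sweep(Xt %*% body$Wx, 2L, body$b, `+`)
        z <- .sigm(Ax[, iz, drop = FALSE] + H %*% body$Wh[, iz, drop = FALSE])
        r <- .sigm(Ax[, ir, drop = FALSE] + H %*% body$Wh[, ir, drop = FALSE])
        rH <- r * H
        n <- tanh(Ax[, inn, drop = FALSE] + rH %*% body$Wh[, inn, drop = FALSE])
        Hn <- (1 - z) * n + z * H
        steps[[t]] <- list(Xt = Xt, Hprev = H, z = z, r = r, n = n, rH = rH)
        H <- Hn
      }
      list(feat = H, cache = list(steps = steps, U = U))
    })
}

# 1-D convolution, kernel 3, zero same-padding. X: B x L x Cin,
# W: (3*Cin) x Cout. Returns activation (B x L x Cout) plus cache.
.convForward <- function(X, W, b) {
  B <- dim(X)[1L]; L <- dim(X)[2L]; Cin <- dim(X)[3L]
  Cout <- ncol(W)
  Xp <- array(0, c(B, L + 2L, Cin))
  Xp[, 2L:(L + 1L), ] <- X
  M <- matrix(0, B * L, 3L * Cin)
  for (k in 0:2)
    M[, (k * Cin + 1L):((k + 1L) * Cin)] <-
      matrix(Xp[, (1L + k):(L + k), , drop = FALSE], B * L, Cin)
  Z <- sweep(M %*% W, 2L, b, `+`)
  A <- array(.relu(Z), c(B, L, Cout))
  list(A = A, M = M, Z = Z, dims = c(B, L, Cin, Cout))
}

.convBackward <- function(cache, W, dA) {
  B <- cache$dims[1L]; L <- cache$dims[2L]
  Cin <- cache$dims[3L]; Cout <- cache$dims[4L]
  dZ <- matrix(dA, B * L, Cout) * (cache$Z > 0)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dXp <- array(0, c(B, L + 2L, Cin))
  for (k in 0:2)
    dXp[, (1L + k):(L + k), ] <- dXp[, (1L + k):(L + k), , drop = FALSE] +
      array(dM[, (k * Cin + 1L):((k + 1L) * Cin)], c(B, L, Cin))
  list(dW = dW, db = db, dX = dXp[, 2L:(L + 1L), , drop = FALSE])
}

# dFeat: B x F. Returns list(grads = body-shaped list).
.bodyBackward <- function(architecture, body, cache, dFeat) {
  switch(architecture,
    dnn = {
      dZ <- dFeat * (cache$Z > 0)
      list(W1 = crossprod(cache$Xf, dZ), b1 = colSums(dZ))
    },
    cnn = {
      B <- nrow(dFeat); L <- cache$L; Cout <- ncol(dFeat)
      dA2 <- array(0, c(B, L, Cout))
      for (t in seq_len(L)) dA2[, t, ] <- dFeat / L
      g2 <- .convBackward(cache$c2, body$Wc2, dA2)
      g1 <- .convBackward(cache$c1, body$Wc1, g2$dX)
      list(Wc1 = g1$dW, bc1 = g1$db, Wc2 = g2$dW, bc2 = g2$db)
    },
    lstm = {
      U <- cache$U
      dWx <- 0 * body$Wx; dWh <- 0 * body$Wh; db <- 0 * body$b
      dH <- dFeat; dC <- matrix(0, nrow(dFeat), U)
      for (t in rev(seq_along(cache$steps))) {
        s <- cache$steps[[t]]
        do <- dH * s$tC * s$o * (1 - s$o)
        dC <- dC + dH * s$o * (1 - s$tC^2)
        di <- dC * s$g * s$i * (1 - s$i)
        df <- dC * s$Cprev * s$f * (1 - s$f)
        dg <- dC * s$i * (1 - s$g^2)
        dZ <- cbind(di, df, dg, do)
        dWx <- dWx + crossprod(s$Xt, dZ)
        dWh <- dWh + crossprod(s$Hprev, dZ)
        db <- db + colSums(dZ)
        dH <- dZ %*% t(body$Wh)
        dC <- dC * s$f
      }
      list(Wx = dWx, Wh = dWh, b = db)
    },
    gru = {
      U <- cache$U
      iz <- 1:U; ir <- (U + 1L):(2L * U); inn <- (2L * U + 1L):(3L * U)
      dWx <- 0 * body$Wx; dWh <- 0 * body$Wh; db <- 0 * body$b
      dH <- dFeat
      for (t in rev(seq_along(cache$steps))) {
        s <- cache$steps[[t]]
        dz <- dH * (s$Hprev - s$n) * s$z * (1 - s$z)
        dan <- dH * (1 - s$z) * (1 - s$n^2)
        dHnext <- dH * s$z
        drH <- dan %*% t(body$Wh[, inn, drop = FALSE])
        dr <- drH * s$Hprev * s$r * (1 - s$r)
        dWx[, iz] <- dWx[, iz] + crossprod(s$Xt, dz)
        dWx[, ir] <- dWx[, ir] + crossprod(s$Xt, dr)
        dWx[, inn] <- dWx[, inn] + crossprod(s$Xt, dan)
        dWh[, iz] <- dWh[, iz] + crossprod(s$Hprev, dz)
        dWh[, ir] <- dWh[, ir] + crossprod(s$Hprev, dr)
        dWh[, inn] <- dWh[, inn] + crossprod(s$rH, dan)
        db <- db + c(colSums(dz), colSums(dr), colSums(dan))
        dH <- dHnext + drH * s$r +
          dz %*% t(body$Wh[, iz, drop = FALSE]) +
          dr %*% t(body$Wh[, ir, drop = FALSE])
      }
      list(Wx = dWx, Wh = dWh, b = db)
    })
}

# ---- head ---------------------------------------------------------------

.headForward <- function(head, feat) {
  Z1 <- sweep(feat %*% head$W1, 2L, head$b1, `+`)
  H1 <- .relu(Z1)
  out <- sweep(H1 %*% head$W2, 2L, head$b2, `+`)
  list(out = out, cache = list(feat = feat, Z1 = Z1, H1 = H1))
}

.headBackward <- function(head, cache, dOut) {
  dW2 <- crossprod(cache$H1, dOut)
  db2 <- colSums(dOut)
  dH1 <- (dOut %*% t(head$W2)) * (cache$Z1 > 0)
  dW1 <- crossprod(cache$feat, dH1)
  db1 <- colSums(dH1)
  dFeat <- dH1 %*% t(head$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dFeat = dFeat)
}

# ---- full model forward/backward ----------------------------------------

.modelForward <- function(model, X) {
  bf <- .bodyForward(model@architecture, model@body, X)
  hf <- .headForward(model@head, bf$feat)
  list(out = hf$out, bodyCache = bf$cache, headCache = hf$cache)
}

.modelBackward <- function(model, fw, dOut, headOnly = FALSE) {
  hb <- .headBackward(model@head, fw$headCache, dOut)
  bodyGrads <- NULL
  if (!headOnly)
    bodyGrads <- .bodyBackward(model@architecture, model@body, fw$bodyCache,
                               hb$dFeat)
  list(head = hb$grads, body = bodyGrads)
}

# ---- Adam ---------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
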