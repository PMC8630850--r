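## Internal convolutional-network engine.
##
## All layer tensors use channel-major layout: conv stages carry an array
## (channels, positions, batch); dense stages a matrix (units, batch).
## Convolutions run as shifted accumulating GEMMs through R's BLAS, and
## the elementwise layers (batchnorm, ReLU, pooling, dropout, Adam) are
## fused single-pass loops, all in src/. Everything is double precision
## and single-threaded-deterministic; dropout draws from R's RNG stream.

.convPadding <- function(K, pad) {
    if (pad == "valid") c(0L, 0L)
    else c((K - 1L) %/% 2L, K - 1L - (K - 1L) %/% 2L)  # "same"
}

## X: (C, T, B); W: (F, C, K); b: length F. The backward cache is simply
## the layer input.
.convForward <- function(X, W, b, pad = "valid") {
    K <- dim(W)[3L]
    pp <- .convPadding(K, pad)
    if (dim(X)[2L] + pp[1L] + pp[2L] - K + 1L < 1L)
        stop("input length ", dim(X)[2L], " too short for kernel size ", K)
    Y <- .convForwardCpp(X, W, as.numeric(b), pp[1L], pp[2L])
    list(Y = Y, X = X, pad = pp)
}

## dY: (F, To, B). Returns dW, db, and dX shaped like the layer input.
.convBackward <- function(dY, cache, W) {
    .convBackwardCpp(dY, cache$X, W, cache$pad[1L])
}

.BN_EPS <- 1e-3
.BN_MOMENTUM <- 0.9

## ---- network assembly ----------------------------------------------------

.initConv <- function(Fo, C, K) {
    fanIn <- C * K
    list(type = "conv", W = array(stats::rnorm(Fo * C * K, 0,
                                               sqrt(2 / fanIn)),
                                  c(Fo, C, K)),
         b = numeric(Fo), pad = "valid")
}

.initBn <- function(Fo) {
    list(type = "bn", gamma = rep(1, Fo), beta = numeric(Fo),
         runMean = numeric(Fo), runVar = rep(1, Fo))
}

.initDense <- function(Fo, D, act) {
    list(type = "dense", W = matrix(stats::rnorm(Fo * D, 0, sqrt(2 / D)),
                                    Fo, D),
         b = numeric(Fo), act = act)
}

## Layer list for a NetworkSpec; consumes the current RNG stream.
.buildLayers <- function(spec, inputLength) {
    layers <- list()
    C <- 5L; Tcur <- as.integer(inputLength)
    for (blk in seq_len(spec@nBlocks)) {
        Fo <- spec@blockFilters[blk]
        ## first conv unpadded, second length-preserving
        layers <- c(layers, list(.initConv(Fo, C, spec@kernelSize)))
        Tcur <- Tcur - spec@kernelSize + 1L
        if (Tcur < 1L)
            stop("input too short: block ", blk, " valid convolution needs ",
                 "length >= ", spec@kernelSize, " at this depth; ",
                 "minimum input length for this spec is ",
                 .minInputLength(spec))
        layers <- c(layers, list(.initBn(Fo), list(type = "relu")))
        conv2 <- .initConv(Fo, Fo, spec@kernelSize)
        conv2$pad <- "same"
        layers <- c(layers, list(conv2, .initBn(Fo), list(type = "relu")))
        Tcur <- Tcur %/% spec@poolSize
        if (Tcur < 1L)
            stop("input too short for pooling at block ", blk,
                 "; minimum input length for this spec is ",
                 .minInputLength(spec))
        layers <- c(layers, list(list(type = "pool", size = spec@poolSize),
                                 list(type = "dropout",
                                      rate = spec@dropoutRate)))
        C <- Fo
    }
    layers <- c(layers, list(list(type = "flatten")))
    D <- C * Tcur
    for (n in spec@denseSizes) {
        layers <- c(layers, list(.initDense(n, D, "relu")))
        D <- n
    }
    layers <- c(layers, list(.initDense(spec@outputNodes, D, "linear")))
    layers
}

## Smallest input length that survives the conv/pool chain of a spec.
.minInputLength <- function(spec) {
    Tcur <- 1L
    for (blk in rev(seq_len(spec@nBlocks))) {
        Tcur <- Tcur * spec@poolSize
        Tcur <- Tcur + spec@kernelSize - 1L
    }
    Tcur
}

## Forward pass. Returns output matrix (outputNodes, B), per-layer caches
## (training mode), and layers with refreshed batchnorm running stats.
.nnForward <- function(layers, X, training = FALSE, stopAfter = NA_integer_) {
    caches <- vector("list", length(layers))
    for (i in seq_along(layers)) {
        ly <- layers[[i]]
        switch(ly$type,
            conv = {
                cf <- .convForward(X, ly$W, ly$b, ly$pad)
                X <- cf$Y
                if (training) caches[[i]] <- cf[c("X", "pad")]
            },
            bn = {
                d <- dim(X)
                dim(X) <- c(d[1L], prod(d[-1L]))
                bf <- .bnForwardCpp(X, ly$gamma, ly$beta, ly$runMean,
                                    ly$runVar, training, .BN_MOMENTUM,
                                    .BN_EPS)
                X <- bf$y
                dim(X) <- d
                if (training) {
                    ly$runMean <- bf$runMean
                    ly$runVar <- bf$runVar
                    layers[[i]] <- ly
                    caches[[i]] <- list(xhat = bf$xhat, istd = bf$istd)
                }
            },
            relu = {
                rf <- .reluForwardCpp(X, training)
                if (training) caches[[i]] <- list(mask = rf$mask)
                X <- rf$y
            },
            pool = {
                Tin <- dim(X)[2L]
                pf <- .poolForwardCpp(X, ly$size)
                if (training) caches[[i]] <- list(arg = pf$arg, Tin = Tin)
                X <- pf$Y
            },
            dropout = {
                if (training && ly$rate > 0) {
                    df <- .dropoutForwardCpp(X, ly$rate)
                    caches[[i]] <- list(keep = df$keep)
                    X <- df$y
                }
            },
            flatten = {
                d <- dim(X)
                caches[[i]] <- list(d = d)
                dim(X) <- c(d[1L] * d[2L], d[3L])
            },
            dense = {
                if (training) caches[[i]] <- list(X = X)
                X <- ly$W %*% X + ly$b
                if (ly$act == "relu") {
                    rf <- .reluForwardCpp(X, training)
                    if (training) caches[[i]]$mask <- rf$mask
                    X <- rf$y
                }
            })
        if (!is.na(stopAfter) && i == stopAfter) break
    }
    list(out = X, caches = caches, layers = layers)
}

## Softmax probabilities from logits (columns are examples).
.softmax <- function(Z) {
    Z <- Z - rep(apply(Z, 2L, max), each = nrow(Z))
    E <- exp(Z)
    E / rep(colSums(E), each = nrow(E))
}

## Weighted cross-entropy loss and logit gradient. y: integer class index
## (1-based) per column; w: per-example weights.
.softmaxLoss <- function(Z, y, w) {
    B <- ncol(Z)
    P <- .softmax(Z)
    picked <- P[cbind(y, seq_len(B))]
    loss <- -sum(w * log(pmax(picked, 1e-12))) / B
    dZ <- P
    dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
    dZ <- dZ * rep(w / B, each = nrow(Z))
    list(loss = loss, dZ = dZ)
}

## Backward pass; returns per-layer gradients (NULL for parameterless).
.nnBackward <- function(layers, caches, dZ) {
    grads <- vector("list", length(layers))
    dX <- dZ
    for (i in rev(seq_along(layers))) {
        ly <- layers[[i]]
        switch(ly$type,
            dense = {
                if (ly$act == "relu")
                    dX <- .maskMultiplyCpp(dX, caches[[i]]$mask)
                grads[[i]] <- list(dW = tcrossprod(dX, caches[[i]]$X),
                                   db = rowSums(dX))
                dX <- crossprod(ly$W, dX)
            },
            flatten = {
                dim(dX) <- caches[[i]]$d
            },
            dropout = {
                if (!is.null(caches[[i]])) dX <- dX * caches[[i]]$keep
            },
            pool = {
                dX <- .poolBackwardCpp(dX, caches[[i]]$arg, ly$size,
                                       caches[[i]]$Tin)
            },
            relu = {
                dX <- .maskMultiplyCpp(dX, caches[[i]]$mask)
            },
            bn = {
                d <- dim(dX)
                dim(dX) <- c(d[1L], prod(d[-1L]))
                bb <- .bnBackwardCpp(dX, caches[[i]]$xhat,
                                     caches[[i]]$istd, ly$gamma)
                grads[[i]] <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
                dX <- bb$dX
                dim(dX) <- d
            },
            conv = {
                cb <- .convBackward(dX, caches[[i]], ly$W)
                grads[[i]] <- cb[c("dW", "db")]
                dX <- cb$dX
            })
    }
    grads
}

## ---- Adam ---------------------------------------------------------------

.adamInit <- function(layers) {
    lapply(layers, function(ly) {
        switch(ly$type,
            conv = list(mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
                        mb = numeric(length(ly$b)),
                        vb = numeric(length(ly$b))),
            dense = list(mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
                         mb = numeric(length(ly$b)),
                         vb = numeric(length(ly$b))),
            bn = list(mg = numeric(length(ly$gamma)),
                      vg = numeric(length(ly$gamma)),
                      mb = numeric(length(ly$beta)),
                      vb = numeric(length(ly$beta))),
            NULL)
    })
}

.adamStep <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    corr1 <- 1 - beta1^t
    corr2 <- 1 - beta2^t
    for (i in seq_along(layers)) {
        g <- grads[[i]]
        if (is.null(g)) next
        ly <- layers[[i]]
        st <- state[[i]]
        if (ly$type %in% c("conv", "dense")) {
            u <- .adamUpdateCpp(ly$W, st$mW, st$vW, g$dW, lr, beta1, beta2,
                                eps, corr1, corr2)
            ly$W <- u$par; st$mW <- u$m; st$vW <- u$v
            u <- .adamUpdateCpp(ly$b, st$mb, st$vb, g$db, lr, beta1, beta2,
                                eps, corr1, corr2)
            ly$b <- u$par; st$mb <- u$m; st$vb <- u$v
        } else if (ly$type == "bn") {
            u <- .adamUpdateCpp(ly$gamma, st$mg, st$vg, g$dgamma, lr, beta1,
                                beta2, eps, corr1, corr2)
            ly$gamma <- u$par; st$mg <- u$m; st$vg <- u$v
            u <- .adamUpdateCpp(ly$beta, st$mb, st$vb, g$dbeta, lr, beta1,
                                beta2, eps, corr1, corr2)
            ly$beta <- u$par; st$mb <- u$m; st$vb <- u$v
        }
        layers[[i]] <- ly
        state[[i]] <- st
    }
    list(layers = layers, state = state)
}

## Count of trainable parameters per layer (for the structural audit).
.layerParamCount <- function(ly) {
    switch(ly$type,
        conv = length(ly$W) + length(ly$b),
        dense = length(ly$W) + length(ly$b),
        bn = length(ly$gamma) + length(ly$beta),
        0L)
}
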