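#' 1-D CNN architecture description
#'
#' Exactly three convolutional blocks, each a 1-d convolution (ReLU)
#' followed by one max-pooling layer, then a dense ReLU head and a single
#' sigmoid output unit trained with binary cross-entropy under the Adam
#' optimizer. The feature vector of a window is treated as a 1-d sequence
#' with one input channel. Defaults are a conventional small network sized
#' for 100-250 input features; every field is overridable.
#'
#' @param filters Integer vector of length 3: filters per conv block.
#' @param kernel_size Convolution kernel length (default 3).
#' @param pool_size Max-pool width/stride (default 2).
#' @param dense Width of the dense head (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 32).
#' @param seed Seed for weight init and shuffling.
#' @return A list of class `emo_cnn_arch`.
#' @export
cnn_architecture <- function(filters = c(32L, 64L, 128L), kernel_size = 3L,
                             pool_size = 2L, dense = 64L, lr = 1e-3,
                             epochs = 50L, batch_size = 32L, seed = 0L) {
  stopifnot(length(filters) == 3L, all(filters >= 1L), kernel_size >= 2L,
            pool_size >= 2L, dense >= 1L, lr > 0, epochs >= 0L,
            batch_size >= 1L)
  structure(list(filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size), dense = as.integer(dense),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "emo_cnn_arch")
}

# ---- array helpers (activations are B x L x C arrays) ----

conv_fwd <- function(X, W, b, k) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; Cin <- d[3L]
  Lo <- L - k + 1L
  Xcol <- array(0, c(B, Lo, k * Cin))
  for (o in seq_len(k))
    Xcol[, , ((o - 1L) * Cin + 1L):(o * Cin)] <- X[, o:(o + Lo - 1L), ,
                                                   drop = FALSE]
  M <- matrix(Xcol, B * Lo, k * Cin)
  Y <- M %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = array(Y, c(B, Lo, ncol(W))), M = M, dims = d)
}

conv_bwd <- function(cache, dY, W, k) {
  d <- cache$dims; B <- d[1L]; L <- d[2L]; Cin <- d[3L]
  Lo <- L - k + 1L
  dYm <- matrix(dY, B * Lo, dim(dY)[3L])
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(W)
  dMarr <- array(dM, c(B, Lo, k * Cin))
  dX <- array(0, d)
  for (o in seq_len(k))
    dX[, o:(o + Lo - 1L), ] <- dX[, o:(o + Lo - 1L), , drop = FALSE] +
      dMarr[, , ((o - 1L) * Cin + 1L):(o * Cin), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

pool_fwd <- function(X, size) {
  d <- dim(X); Lp <- d[2L] %/% size
  idx <- lapply(seq_len(size), function(o) seq.int(o, by = size,
                                                   length.out = Lp))
  P <- X[, idx[[1L]], , drop = FALSE]
  arg <- array(1L, dim(P))
  for (o in 2L:size) {
    cand <- X[, idx[[o]], , drop = FALSE]
    better <- cand > P
    P[better] <- cand[better]
    arg[better] <- o
  }
  list(out = P, arg = arg, idx = idx, dims = d)
}

pool_bwd <- function(cache, dP) {
  dX <- array(0, cache$dims)
  for (o in seq_along(cache$idx)) {
    m <- cache$arg == o
    block <- array(0, dim(dP))
    block[m] <- dP[m]
    dX[, cache$idx[[o]], ] <- block
  }
  dX
}

adam_step <- function(state, params, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

cnn_lengths <- function(p, arch) {
  L <- p
  for (i in 1:3) {
    L <- L - arch$kernel_size + 1L
    if (L < 1L) return(NULL)
    L <- L %/% arch$pool_size
    if (L < 1L) return(NULL)
  }
  L
}

cnn_init <- function(p, arch) {
  k <- arch$kernel_size
  cins <- c(1L, arch$filters[1L], arch$filters[2L])
  Lfin <- cnn_lengths(p, arch)
  if (is.null(Lfin))
    stop("input length ", p, " too short for three conv+pool blocks")
  flat <- Lfin * arch$filters[3L]
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  params <- list()
  for (i in 1:3) {
    params[[paste0("Wc", i)]] <- he(k * cins[i], arch$filters[i])
    params[[paste0("bc", i)]] <- numeric(arch$filters[i])
  }
  params$Wd <- he(flat, arch$dense)
  params$bd <- numeric(arch$dense)
  params$Wo <- he(arch$dense, 1L)
  params$bo <- 0
  params
}

cnn_forward <- function(X, params, arch, keep = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  for (i in 1:3) {
    cv <- conv_fwd(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]],
                   arch$kernel_size)
    R <- cv$out
    mask <- R > 0
    R[!mask] <- 0
    pl <- pool_fwd(R, arch$pool_size)
    if (keep) caches[[i]] <- list(conv = cv, mask = mask, pool = pl)
    A <- pl$out
  }
  flat <- matrix(A, B, prod(dim(A)[2:3]))
  H <- flat %*% params$Wd
  H <- sweep(H, 2L, params$bd, "+")
  hmask <- H > 0
  H[!hmask] <- 0
  z <- drop(H %*% params$Wo) + params$bo
  prob <- 1 / (1 + exp(-z))
  if (!keep) return(prob)
  list(prob = prob, z = z, H = H, hmask = hmask, flat = flat,
       caches = caches, Adim = dim(A))
}

#' Train the 1-D convolutional network
#'
#' @param X Numeric matrix of feature vectors (rows = windows); must be
#'   finite.
#' @param y Binary labels (low/high factor, 0/1, or raw ratings).
#' @param arch A [cnn_architecture()].
#' @return An object of class `emo_cnn` with the learned parameters, the
#'   per-epoch mean training loss (`loss_trace`) and the input
#'   standardization statistics. Use [predict_cnn()] or wrap via
#'   [train_classifier()].
#' @export
train_cnn <- function(X, y, arch = cnn_architecture()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  y01 <- if (is.numeric(y) && all(y %in% c(0, 1))) as.numeric(y)
         else as_binary01(y)
  stopifnot(nrow(X) == length(y01))
  set.seed(arch$seed)
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  params <- cnn_init(ncol(X), arch)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- nrow(Xs)
  loss_trace <- numeric(arch$epochs)
  for (ep in seq_len(arch$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq.int(1L, n, by = arch$batch_size)) {
      rows <- ord[start:min(start + arch$batch_size - 1L, n)]
      xb <- Xs[rows, , drop = FALSE]
      yb <- y01[rows]
      fw <- cnn_forward(xb, params, arch, keep = TRUE)
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      losses <- c(losses, -mean(yb * log(p) + (1 - yb) * log(1 - p)))
      B <- length(rows)
      dz <- (fw$prob - yb) / B
      grads <- list()
      grads$Wo <- crossprod(fw$H, dz)
      grads$bo <- sum(dz)
      dH <- tcrossprod(dz, drop(params$Wo))
      dH[!fw$hmask] <- 0
      grads$Wd <- crossprod(fw$flat, dH)
      grads$bd <- colSums(dH)
      dflat <- dH %*% t(params$Wd)
      dA <- array(dflat, fw$Adim)
      for (i in 3:1) {
        cc <- fw$caches[[i]]
        dR <- pool_bwd(cc$pool, dA)
        dR[!cc$mask] <- 0
        bw <- conv_bwd(cc$conv, dR, params[[paste0("Wc", i)]],
                       arch$kernel_size)
        grads[[paste0("Wc", i)]] <- bw$dW
        grads[[paste0("bc", i)]] <- bw$db
        dA <- bw$dX
      }
      st <- adam_step(state, params, grads, arch$lr)
      state <- st$state
      params <- st$params
    }
    loss_trace[ep] <- if (length(losses)) mean(losses) else NA_real_
  }
  structure(list(params = params, arch = arch, mu = mu, sg = sg,
                 loss_trace = loss_trace),
            class = "emo_cnn")
}

predict_cnn_prob <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2L, fit$mu), 2L, fit$sg, "/")
  cnn_forward(Xs, fit$params, fit$arch, keep = FALSE)
}

#' Predict with a trained 1-D CNN
#'
#' @param fit An `emo_cnn` from [train_cnn()].
#' @param newdata Feature matrix.
#' @param type `"label"` (threshold 0.5) or `"prob"`.
#' @return Factor low/high, or probabilities of the high class.
#' @export
predict_cnn <- function(fit, newdata, type = c("label", "prob")) {
  type <- match.arg(type)
  prob <- predict_cnn_prob(fit, newdata)
  if (type == "prob") return(prob)
  factor(ifelse(prob > 0.5, "high", "low"), levels = c("low", "high"))
}
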