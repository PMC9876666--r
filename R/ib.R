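#' Fit the variational information-bottleneck encoder
#'
#' Trains a stochastic Gaussian encoder \eqn{T | X^s} (one hidden ReLU
#' layer, then posterior mean and log-variance heads) together with a
#' categorical (softmax) decoder for the class label. Full-batch Adam
#' minimizes
#' \deqn{CE(Y, decoder(T)) + \beta \cdot KL(q(T|X^s) \| N(0, I)),}
#' whose two terms are, respectively, a lower-bound surrogate for
#' \eqn{-I(T;Y)} (recorded as \code{iTY = H(Y) - CE}) and a variational
#' upper bound on \eqn{I(X^s;T)} (recorded as \code{iXT}). At
#' \eqn{\beta = 0} the compression term is absent and training reduces to
#' purely label-predictive fitting.
#'
#' @param x numeric matrix of secondary-indicator values (samples x d).
#' @param y integer class ids in \code{1..K}.
#' @param latentDim latent width |z| (default 10).
#' @param beta compression multiplier (>= 0, default 0.1).
#' @param epochs full-batch epochs (default 200).
#' @param hidden hidden-layer width (default 64).
#' @param learningRate Adam step size.
#' @param seed RNG seed; training is fully reproducible.
#' @return An [IBEncoder-class] with a per-epoch training history.
#' @export
fitIBEncoder <- function(x, y, latentDim = 10L, beta = 0.1, epochs = 200L,
                         hidden = 64L, learningRate = 0.01, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  K <- max(y)
  n <- nrow(x)
  d <- ncol(x)
  if (beta < 0) stop("beta must be >= 0")
  if (!length(y) || n != length(y)) stop("labels are required")
  z <- as.integer(latentDim)
  H <- as.integer(hidden)
  Y <- oneHot(y, K)
  py <- colMeans(Y)
  entY <- -sum(py[py > 0] * log(py[py > 0]))

  withSeed(seed, {
    gl <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / a)), a, b)
    par <- list(W1 = gl(d, H), b1 = rep(0, H),
                Wm = gl(H, z), bm = rep(0, z),
                Wv = gl(H, z) * 0.01, bv = rep(-1, z),
                Wd = gl(z, K), bd = rep(0, K))
    mAdam <- lapply(par, function(p) p * 0)
    vAdam <- lapply(par, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; epsA <- 1e-8
    hist <- data.frame(epoch = integer(0), loss = numeric(0),
                       crossEntropy = numeric(0), kl = numeric(0),
                       iTY = numeric(0), iXT = numeric(0))

    for (ep in seq_len(epochs)) {
      h1a <- x %*% par$W1
      h1 <- relu(sweep(h1a, 2, par$b1, "+"))
      mu <- sweep(h1 %*% par$Wm, 2, par$bm, "+")
      lv <- sweep(h1 %*% par$Wv, 2, par$bv, "+")
      lv <- pmin(pmax(lv, -10), 10)
      sd_ <- exp(0.5 * lv)
      eps <- matrix(stats::rnorm(n * z), n, z)
      tz <- mu + eps * sd_
      logits <- sweep(tz %*% par$Wd, 2, par$bd, "+")
      lmax <- apply(logits, 1, max)
      p <- exp(logits - lmax)
      p <- p / rowSums(p)
      ce <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
      kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - lv - 1))
      loss <- ce + beta * kl
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep)
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = loss, crossEntropy = ce, kl = kl,
        iTY = entY - ce, iXT = kl))

      dlogits <- (p - Y) / n
      gWd <- crossprod(tz, dlogits)
      gbd <- colSums(dlogits)
      dz <- dlogits %*% t(par$Wd)
      dmu <- dz + (beta / n) * mu
      dlv <- dz * eps * sd_ * 0.5 + (beta / n) * 0.5 * (exp(lv) - 1)
      gWm <- crossprod(h1, dmu)
      gbm <- colSums(dmu)
      gWv <- crossprod(h1, dlv)
      gbv <- colSums(dlv)
      dh1 <- (dmu %*% t(par$Wm) + dlv %*% t(par$Wv)) * (h1 > 0)
      gW1 <- crossprod(x, dh1)
      gb1 <- colSums(dh1)
      grads <- list(W1 = gW1, b1 = gb1, Wm = gWm, bm = gbm,
                    Wv = gWv, bv = gbv, Wd = gWd, bd = gbd)
      corr1 <- 1 - b1a^ep
      corr2 <- 1 - b2a^ep
      for (nm in names(par)) {
        mAdam[[nm]] <- b1a * mAdam[[nm]] + (1 - b1a) * grads[[nm]]
        vAdam[[nm]] <- b2a * vAdam[[nm]] + (1 - b2a) * grads[[nm]]^2
        par[[nm]] <- par[[nm]] - learningRate *
          (mAdam[[nm]] / corr1) / (sqrt(vAdam[[nm]] / corr2) + epsA)
      }
    }

    new("IBEncoder", params = par, latentDim = z, beta = as.numeric(beta),
        hidden = H, K = as.integer(K), history = hist,
        inputNames = colnames(x) %||% sprintf("x%d", seq_len(d)),
        seed = as.integer(seed))
  })
}

#' Encode secondary indicators
#'
#' Deterministic posterior-mean encoding of the fitted Gaussian encoder.
#' An optional boolean mask zeroes out the de-selected features before
#' encoding — this realizes the eta-resampling of the boosted transform
#' with a single trained encoder.
#'
#' @param enc a fitted [IBEncoder-class].
#' @param x matrix with the encoder's input schema (columns matched by
#'   name when present).
#' @param mask optional logical vector over the secondary indicators;
#'   \code{FALSE} entries are zeroed. All-\code{TRUE} is identical to no
#'   mask.
#' @return numeric matrix n x latentDim (columns \code{T1..T|z|}).
#' @export
encodeSecondary <- function(enc, x, mask = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x))) {
    x <- alignColumns(x, enc@inputNames)
  } else if (ncol(x) != length(enc@inputNames)) {
    stop("expected ", length(enc@inputNames), " secondary columns, got ",
         ncol(x))
  }
  if (!is.null(mask)) {
    if (length(mask) != ncol(x)) {
      stop("mask length must equal the number of secondary indicators")
    }
    x[, !mask] <- 0
  }
  par <- enc@params
  h1 <- relu(sweep(x %*% par$W1, 2, par$b1, "+"))
  mu <- sweep(h1 %*% par$Wm, 2, par$bm, "+")
  colnames(mu) <- sprintf("T%d", seq_len(enc@latentDim))
  mu
}

setMethod("show", "IBEncoder", function(object) {
  last <- utils::tail(object@history, 1)
  cat(sprintf(
    "IBEncoder: %d -> %d (hidden %d), beta = %g, %d epochs\n",
    length(object@inputNames), object@latentDim, object@hidden,
    object@beta, nrow(object@history)))
  if (nrow(last)) {
    cat(sprintf("final loss %.4f | I(T,Y) est %.4f | I(X,T) bound %.4f\n",
                last$loss, last$iTY, last$iXT))
  }
})
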