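# Small MLP classifier: one hidden layer of ReLU units, one sigmoid output,
# binary cross-entropy loss, Adam optimiser. Written out explicitly because
# the architecture (ReLU hidden layer + Adam) is part of the evaluated model
# specification. Inputs are standardised by training-set mean and SD.

mlp_fit <- function(x, y, hidden = 12, epochs = 100, batch = 16, lr = 1e-3,
                    seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  n <- nrow(xs); q <- ncol(xs)
  with_seed(seed, {
    W1 <- matrix(rnorm(q * hidden, sd = sqrt(2 / q)), q, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    adam <- list()
    for (nm in c("W1", "b1", "W2", "b2"))
      adam[[nm]] <- list(m = 0, v = 0)
    b1v <- 0.9; b2v <- 0.999; eps <- 1e-8; step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch)) {
        idx <- ord[s:min(s + batch - 1, n)]
        xb <- xs[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        z1 <- sweep(xb %*% W1, 2, b1, "+")
        a1 <- pmax(z1, 0)
        z2 <- as.vector(a1 %*% W2) + b2
        p <- 1 / (1 + exp(-z2))
        dz2 <- (p - yb) / nb                       # d(BCE)/dz2
        gW2 <- crossprod(a1, dz2)
        gb2 <- sum(dz2)
        da1 <- outer(dz2, as.vector(W2))
        dz1 <- da1 * (z1 > 0)
        gW1 <- crossprod(xb, dz1)
        gb1 <- colSums(dz1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        step <- step + 1
        for (nm in names(grads)) {
          a <- adam[[nm]]
          a$m <- b1v * a$m + (1 - b1v) * grads[[nm]]
          a$v <- b2v * a$v + (1 - b2v) * grads[[nm]]^2
          mh <- a$m / (1 - b1v^step)
          vh <- a$v / (1 - b2v^step)
          upd <- lr * mh / (sqrt(vh) + eps)
          adam[[nm]] <- a
          if (nm == "W1") W1 <- W1 - upd
          else if (nm == "b1") b1 <- b1 - upd
          else if (nm == "W2") W2 <- W2 - upd
          else b2 <- b2 - upd
        }
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, mu = mu, sg = sg)
  })
}

mlp_predict <- function(model, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sg, "/")
  a1 <- pmax(sweep(xs %*% model$W1, 2, model$b1, "+"), 0)
  z2 <- as.vector(a1 %*% model$W2) + model$b2
  1 / (1 + exp(-z2))
}
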