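# Minimal fully connected network (15 -> 28 -> 28 -> 28 -> 15, ReLU) with
# Adam, written in base R. This is the Q-value approximator of the bolus
# calculator; the architecture is part of the method's contract.

#' Create a Q-network
#'
#' Fully connected network with \code{layers} giving all layer widths
#' (input, hidden..., output), ReLU activations on hidden layers and a
#' linear output. Weights use small-variance symmetric (He-style)
#' initialisation under the given seed for reproducibility.
#'
#' @param layers integer vector of layer sizes; default 15-28-28-28-15
#' @param seed initialisation seed
#' @return object of class \code{qnet}
#' @export
qnet_init <- function(layers = c(15L, 28L, 28L, 28L, 15L), seed = 1L) {
  L <- length(layers) - 1L
  with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      # near-zero output weights with a pessimistic bias: Q starts flat at
      # the worst scaled reward, so actions without replay evidence are
      # never preferred over learned ones (and bootstrap targets at states
      # the network was never fitted on stay bounded)
      sd <- if (l == L) 0.01 * sqrt(2 / layers[l]) else sqrt(2 / layers[l])
      W[[l]] <- matrix(stats::rnorm(layers[l] * layers[l + 1], sd = sd),
                       layers[l], layers[l + 1])
      b[[l]] <- if (l == L) rep(-1, layers[l + 1]) else rep(0, layers[l + 1])
    }
    structure(list(W = W, b = b, layers = layers,
                   adam = NULL, t = 0L), class = "qnet")
  })
}

# forward pass; X is n x d_in. Returns list(out, cache) when cache = TRUE.
qnet_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  A <- list(X)
  Z <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    Zl <- sweep(H %*% net$W[[l]], 2, net$b[[l]], "+")
    H <- if (l < L) pmax(Zl, 0) else Zl
    Z[[l]] <- Zl
    A[[l + 1L]] <- H
  }
  if (cache) list(out = H, A = A, Z = Z) else H
}

# one Adam step on squared error of the chosen actions.
# X: n x d_in, actions: integer n (1-based), targets: numeric n.
# Returns list(net, loss).
qnet_train_step <- function(net, X, actions, targets, lr = 1e-3,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(X)
  L <- length(net$W)
  fw <- qnet_forward(net, X, cache = TRUE)
  Q <- fw$out
  idx <- cbind(seq_len(n), actions)
  err <- Q[idx] - targets
  loss <- mean(err^2)
  # gradient of mean squared error wrt outputs: only chosen actions
  dOut <- matrix(0, n, ncol(Q))
  dOut[idx] <- 2 * err / n
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (fw$Z[[l - 1L]] > 0)
  }
  if (is.null(net$adam)) {
    net$adam <- list(mW = lapply(net$W, function(w) w * 0),
                     vW = lapply(net$W, function(w) w * 0),
                     mb = lapply(net$b, function(x) x * 0),
                     vb = lapply(net$b, function(x) x * 0))
  }
  net$t <- net$t + 1L
  bc1 <- 1 - beta1^net$t; bc2 <- 1 - beta2^net$t
  a <- net$adam
  for (l in seq_len(L)) {
    a$mW[[l]] <- beta1 * a$mW[[l]] + (1 - beta1) * gW[[l]]
    a$vW[[l]] <- beta2 * a$vW[[l]] + (1 - beta2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (a$mW[[l]] / bc1) /
      (sqrt(a$vW[[l]] / bc2) + eps)
    a$mb[[l]] <- beta1 * a$mb[[l]] + (1 - beta1) * gb[[l]]
    a$vb[[l]] <- beta2 * a$vb[[l]] + (1 - beta2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (a$mb[[l]] / bc1) /
      (sqrt(a$vb[[l]] / bc2) + eps)
  }
  net$adam <- a
  if (any(!vapply(net$W, function(w) all(is.finite(w)), logical(1))))
    stop("Q-network weights diverged (non-finite)")
  list(net = net, loss = loss)
}

# copy of the learnable parameters (target network)
qnet_weights <- function(net) list(W = net$W, b = net$b)
qnet_set_weights <- function(net, wts) {
  net$W <- wts$W; net$b <- wts$b; net
}
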