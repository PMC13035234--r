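# Internal numerical utilities: seeded-RNG scoping and a plain Adam
# optimizer over named lists of numeric arrays.

# set the seed, returning a restore function for on.exit()
.withSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

.adamInit <- function(theta) {
  list(m = lapply(theta, function(x) 0 * x),
       v = lapply(theta, function(x) 0 * x),
       t = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adamStep <- function(theta, grads, state, lr) {
  state$t <- state$t + 1
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(theta = theta, state = state)
}

# cosine-annealed learning rate with warm restarts; epoch is 1-based,
# period the restart length in epochs, lrMin the floor.
.cosineRestartLR <- function(epoch, lr0, period, lrMin = 0) {
  tcur <- (epoch - 1) %% period
  lrMin + 0.5 * (lr0 - lrMin) * (1 + cos(pi * tcur / period))
}

# smooth gradient clipping: rescales the concatenated gradient to
# gmax * tanh(||g|| / gmax); norm-preserving for small norms, asymptotically
# bounded by gmax.
.smoothClipScale <- function(norm, gmax) {
  if (norm < .Machine$double.eps) return(1)
  gmax * tanh(norm / gmax) / norm
}

.flattenGrads <- function(grads) unlist(grads, use.names = FALSE)

# Pearson correlation that refuses degenerate inputs rather than returning NA
.pearson <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}
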