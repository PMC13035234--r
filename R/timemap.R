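#' Upper bound of the time-mapping anchors
#'
#' `u = L * sigmoid(uRaw)`: a smooth parameterization keeping the last anchor
#' inside the simulated range of `L` recurrent steps.
#'
#' @param uRaw raw scalar parameter.
#' @param L total number of recurrent steps (>= 2).
#' @return scalar in `(0, L)`.
#' @export
computeUpperBound <- function(uRaw, L) {
  stopifnot(L >= 2)
  L * stats::plogis(uRaw)
}

# exponential reweighting g(alpha, c) on [0,1] -> [0,1], monotone in c with
# g(alpha, 1) = 1; alpha -> 0 limit is the identity, taken analytically.
# variant "literal" keeps the alternative (e^{alpha c}+1)/(e^{alpha}+1)
# reading of the published expression behind a flag; it does not satisfy
# g(alpha, 0) = 0 and is retained for comparison only.
.anchorReweight <- function(alpha, cn, variant = c("exp", "literal")) {
  variant <- match.arg(variant)
  if (variant == "literal") return((exp(alpha * cn) + 1) / (exp(alpha) + 1))
  if (abs(alpha) < 1e-6) cn + alpha * cn * (cn - 1) / 2
  else expm1(alpha * cn) / expm1(alpha)
}

#' Compute fractional-step anchors for experimental timepoints
#'
#' Transforms raw per-timepoint offsets into strictly increasing fractional
#' recurrent-step positions: `c = cumsum(softplus(deltaRaw))` is normalized
#' to `[0, 1]`, exponentially reweighted by `alpha`, and scaled by the upper
#' bound `u`; the first anchor is then fixed to step 0 (time zero is the
#' first recurrent step). Softplus positivity makes the cumulative sum, and
#' hence the anchors, strictly increasing for any raw offsets.
#'
#' @param deltaRaw numeric vector of raw offsets, one per timepoint (>= 2).
#' @param alpha scalar exponential-reweighting parameter.
#' @param u upper bound (see [computeUpperBound()]).
#' @param variant which reading of the reweighting to use; `"exp"` (default)
#'   maps `[0,1]` onto `[0,1]`, `"literal"` is kept for comparison.
#' @return strictly increasing numeric vector of anchors with first element 0
#'   and last element `u`.
#' @export
computeAnchors <- function(deltaRaw, alpha, u, variant = "exp") {
  K <- length(deltaRaw)
  if (K < 2) stop("at least 2 timepoints are required")
  cs <- cumsum(.softplus(deltaRaw))
  D <- cs[K] - cs[1]
  if (!is.finite(D) || D <= 0) stop("flat offsets")
  cn <- (cs - cs[1]) / D
  m <- u * .anchorReweight(alpha, cn, variant)
  m[1] <- 0
  m
}

# anchors plus partial derivatives wrt deltaRaw (K x K Jacobian), alpha and
# u. Used by the trainer; the first anchor is fixed so its row is zero.
.anchorsWithGrad <- function(deltaRaw, alpha, uRaw, L, variant = "exp") {
  K <- length(deltaRaw)
  sig <- stats::plogis(uRaw)
  u <- L * sig
  du_duRaw <- L * sig * (1 - sig)
  sp <- .softplus(deltaRaw)
  cs <- cumsum(sp)
  D <- cs[K] - cs[1]
  cn <- (cs - cs[1]) / D
  g <- .anchorReweight(alpha, cn, variant)
  if (variant == "literal") {
    ea <- exp(alpha)
    gc <- alpha * exp(alpha * cn) / (ea + 1)
    ga <- (cn * exp(alpha * cn) * (ea + 1) - (exp(alpha * cn) + 1) * ea) /
      (ea + 1)^2
  } else if (abs(alpha) < 1e-6) {
    gc <- 1 + alpha * (cn - 0.5)
    ga <- cn * (cn - 1) / 2
  } else {
    em <- expm1(alpha)
    gc <- alpha * exp(alpha * cn) / em
    ga <- (cn * exp(alpha * cn) * em - expm1(alpha * cn) * exp(alpha)) / em^2
  }
  m <- u * g
  m[1] <- 0
  # dcn_k/dc_j = (1{j=k} - 1{j=1})/D - cn_k (1{j=K} - 1{j=1})/D
  # dc_j/ddelta_i = sigmoid(delta_i) for i <= j
  dm_ddelta <- matrix(0, K, K)   # rows: anchors, cols: deltaRaw entries
  sigd <- stats::plogis(deltaRaw)
  for (k in seq_len(K)) {
    if (k == 1) next
    dcn_dc <- numeric(K)
    dcn_dc[k] <- dcn_dc[k] + 1 / D
    dcn_dc[1] <- dcn_dc[1] - 1 / D
    dcn_dc[K] <- dcn_dc[K] - cn[k] / D
    dcn_dc[1] <- dcn_dc[1] + cn[k] / D
    # chain through the cumulative sum: d/ddelta_i = sigd_i * sum_{j>=i} dcn_dc_j
    tailSum <- rev(cumsum(rev(dcn_dc)))
    dm_ddelta[k, ] <- u * gc[k] * tailSum * sigd
  }
  dm_dalpha <- u * ga
  dm_dalpha[1] <- 0
  dm_du <- g
  dm_du[1] <- 0
  list(anchors = m, u = u, dDelta = dm_ddelta,
       dAlpha = dm_dalpha, dURaw = dm_du * du_duRaw)
}

#' Soft indexing: read values at fractional recurrent steps
#'
#' Linearly interpolates between the two integer steps bracketing each
#' fractional anchor `m` (0-based): with `d = m - floor(m)`, the value is
#' `(1-d) * x[floor(m)] + d * x[ceil(m)]`. Exact at integer steps,
#' piecewise-linear and differentiable in `m` between them, which keeps the
#' learned time map trainable end to end. Anchors outside `[0, L-1]` are
#' clamped with a warning.
#'
#' @param values numeric vector of length L, or a matrix/array whose *last*
#'   dimension indexes the L recurrent steps.
#' @param m numeric vector of fractional step positions (0-based).
#' @return interpolated values; the step dimension is replaced by one entry
#'   per anchor.
#' @export
softIndex <- function(values, m) {
  wasVector <- is.vector(values)
  if (wasVector) values <- matrix(values, nrow = 1)
  d <- dim(values)
  L <- d[length(d)]
  V <- matrix(values, ncol = L)   # flatten leading dims
  if (any(m < 0 | m > L - 1)) {
    warning("fractional steps clamped to [0, L-1]")
    m <- pmin(pmax(m, 0), L - 1)
  }
  f <- floor(m)
  dm <- m - f
  lo <- V[, f + 1, drop = FALSE]
  hi <- V[, pmin(f + 2, L), drop = FALSE]
  out <- sweep(lo, 2, 1 - dm, `*`) + sweep(hi, 2, dm, `*`)
  if (wasVector) return(as.numeric(out))
  array(out, c(d[-length(d)], length(m)))
}

#' One-to-one anchors: k-th timepoint at recurrent step k
#'
#' @param times experimental times (only their count matters).
#' @param L total recurrent steps; an error is raised when there are more
#'   times than steps.
#' @return integer anchors `0, 1, ..., K-1`.
#' @export
oneToOneAnchors <- function(times, L) {
  K <- length(times)
  if (K > L) stop("more timepoints (", K, ") than recurrent steps (", L, ")")
  seq_len(K) - 1
}

#' Estimate anchors for held-out times from a dense reference site
#'
#' Given a trained model's step-level trajectory for a single reference
#' phosphosite and dense measurements of that site at the target times, finds
#' for each time the fractional step (on a 0.01-step grid) minimizing the
#' squared error to the measurement, constrained to stay strictly between the
#' neighboring anchors so the time map remains monotone. Anchors already
#' known (e.g. time 0 at step 0) can be passed as `fixed`.
#'
#' A flat reference trajectory carries no timing information (every step
#' matches equally well), so it is rejected.
#'
#' @param refTrajectory numeric vector: the model's reference-site intensity
#'   at each integer recurrent step (length L).
#' @param measurements numeric vector: the dense measurement of the
#'   reference site at each target time.
#' @param fixed optional numeric vector, same length, with known anchors at
#'   some positions and `NA` where an anchor is to be estimated; defaults to
#'   fixing the first time at step 0.
#' @param resolution grid resolution in steps (default 0.01).
#' @return numeric vector of fractional-step anchors, strictly increasing.
#' @export
fitAnchorsFromReferenceSite <- function(refTrajectory, measurements,
                                        fixed = NULL, resolution = 0.01) {
  L <- length(refTrajectory)
  K <- length(measurements)
  if (diff(range(refTrajectory)) < 1e-8)
    stop("flat reference trajectory: timing cannot be recovered")
  if (is.null(fixed)) fixed <- c(0, rep(NA_real_, K - 1))
  stopifnot(length(fixed) == K)
  grid <- seq(0, L - 1, by = resolution)
  predGrid <- softIndex(refTrajectory, grid)
  anchors <- fixed
  for (k in seq_len(K)) {
    if (!is.na(fixed[k])) next
    loAnchor <- if (k > 1) max(anchors[seq_len(k - 1)], na.rm = TRUE) else -resolution
    nxt <- which(!is.na(fixed) & seq_len(K) > k)
    hiAnchor <- if (length(nxt)) min(fixed[nxt]) else L - 1 + resolution
    ok <- grid > loAnchor & grid < hiAnchor
    if (!any(ok)) stop("no admissible grid points for timepoint ", k)
    err <- (predGrid[ok] - measurements[k])^2
    anchors[k] <- grid[ok][which.min(err)]
  }
  anchors
}

#' Export anchors as a two-column TSV
#'
#' @param times experimental times in minutes.
#' @param anchors fractional-step anchors.
#' @param path output file.
#' @export
writeAnchors <- function(times, anchors, path) {
  utils::write.table(data.frame(time_minutes = times,
                                fractional_step = anchors),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
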