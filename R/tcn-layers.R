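#' @include utils.R
NULL

#' Causal dilated 1-D convolution
#'
#' Computes, at every output position `t`,
#' `F(x)(t) = sum_{i=0}^{K-1} f(i) . x[t - d*i]`, with `x` taken as zero
#' left of position 1 (implicit left zero-padding of `(K-1)*d`). The output
#' has the same length as the input, and no output position depends on any
#' later input position; with `d = 1` this is the standard causal
#' convolution.
#'
#' @param x input feature map: a numeric vector (one channel) or a
#'   `C_in x n` matrix.
#' @param f filter weights: a numeric vector of length `K` (one-in,
#'   one-out), a `C_in x K` matrix (one output channel), or a
#'   `C_out x C_in x K` array.
#' @param d dilation factor, a positive integer.
#' @return a numeric vector (vector in, single output channel) or a
#'   `C_out x n` matrix.
#' @examples
#' causalDilatedConv(c(1, 2, 3, 4), c(1, 1), d = 1)  # 1 3 5 7
#' causalDilatedConv(c(1, 2, 3, 4), c(1, 1), d = 2)  # 1 2 4 6
#' @export
causalDilatedConv <- function(x, f, d = 1L) {
    if (length(d) != 1L || is.na(d) || d < 1L)
        stop("dilation 'd' must be a positive integer")
    d <- as.integer(d)
    vec_in <- is.null(dim(x))
    X <- if (vec_in) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
    if (is.null(dim(f)))
        f <- array(as.numeric(f), dim = c(1L, 1L, length(f)))
    else if (length(dim(f)) == 2L)
        f <- array(as.numeric(f), dim = c(1L, dim(f)))
    stopifnot(length(dim(f)) == 3L)
    Cin <- nrow(X); n <- ncol(X); K <- dim(f)[3L]
    if (dim(f)[2L] != Cin)
        stop("filter C_in does not match input channels")
    Cout <- dim(f)[1L]
    Y <- matrix(0, Cout, n)
    for (i in 0:(K - 1L)) {
        Wi <- matrix(f[, , i + 1L], Cout, Cin)
        valid <- seq_len(n) - d * i
        keep <- valid >= 1L
        if (!any(keep)) next
        Y[, keep] <- Y[, keep] + Wi %*% X[, valid[keep], drop = FALSE]
    }
    if (vec_in && Cout == 1L) as.numeric(Y) else Y
}

#' ReLU activation
#'
#' Elementwise `max(0, x)`, preserving shape.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape as `x`.
#' @export
reluActivation <- function(x) {
    y <- pmax(x, 0)
    dim(y) <- dim(x)
    y
}

#' Spatial (channel-wise) dropout for 1-D feature maps
#'
#' In training mode each channel (row) is zeroed across all positions
#' independently with probability `rate`, and the surviving channels are
#' scaled by `1/(1-rate)` so the expected activation is unchanged. In
#' inference mode the input is returned untouched. Uses the current RNG
#' stream.
#'
#' @param x `C x n` numeric matrix (a vector is treated as one channel).
#' @param rate drop probability in `[0, 1)`.
#' @param training logical; dropout is only active when `TRUE`.
#' @return same shape as `x`.
#' @export
spatialDropout <- function(x, rate, training = TRUE) {
    if (length(rate) != 1L || is.na(rate) || rate < 0 || rate >= 1)
        stop("dropout 'rate' must lie in [0, 1)")
    if (!training || rate == 0)
        return(x)
    vec_in <- is.null(dim(x))
    X <- if (vec_in) matrix(x, nrow = 1L) else x
    keep <- runif(nrow(X)) >= rate
    X <- X * (keep / (1 - rate))
    if (vec_in) as.numeric(X) else X
}

#' Weight normalization
#'
#' Re-parameterizes a weight vector as a scale times a unit direction:
#' `w = g * v / ||v||` (Euclidean norm over the filter's coefficients), so
#' that `||w|| = |g|` regardless of `v`. Decoupling length from direction
#' stabilizes gradients during optimization.
#'
#' @param v direction: a numeric vector, or a matrix whose rows are filters.
#' @param g scale: scalar, or a vector with one entry per filter row.
#' @return effective weights, same shape as `v`.
#' @examples
#' weightNormApply(c(3, 4), 5)   # c(3, 4): ||v|| = 5
#' @export
weightNormApply <- function(v, g) {
    if (is.null(dim(v))) {
        nv <- sqrt(sum(v^2))
        if (nv == 0)
            stop("zero-norm direction vector")
        return(g * v / nv)
    }
    nv <- sqrt(rowSums(v^2))
    if (any(nv == 0))
        stop("zero-norm direction vector")
    (g / nv) * v
}

#' One residual block of the network
#'
#' Applies `convsPerBlock` repetitions of [weight-normalized
#' dilated causal convolution][causalDilatedConv] followed by
#' [ReLU][reluActivation] and [spatial dropout][spatialDropout], then adds
#' the skip path and applies a final ReLU:
#' `o = ReLU(skip(x) + F(x))`. The skip is the identity when input and
#' output channel counts match, and a 1x1 convolution otherwise.
#'
#' This is the reference composition of the exported layer primitives; the
#' training loop uses an internally vectorized path that is tested to agree
#' with it.
#'
#' @param x `C_in x n` feature map (a vector is one channel).
#' @param params one block's parameter list: `convs`, a list with one
#'   element per convolution, each holding `V` (`C_out x (C_in*K)` direction
#'   matrix), `g` (per-filter scale) and `b` (bias); and optionally `proj`
#'   (`W`, `b`) for the 1x1 skip projection.
#' @param d dilation factor for all convolutions in the block.
#' @param kernelSize taps per filter (K).
#' @param dropoutRate spatial dropout probability.
#' @param training logical; enables dropout.
#' @return `C_out x n` feature map.
#' @export
residualBlock <- function(x, params, d, kernelSize, dropoutRate = 0,
                          training = FALSE) {
    X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else x
    h <- X
    for (cv in params$convs) {
        Wmat <- weightNormApply(cv$V, cv$g)
        f <- wmat_to_array(Wmat, nrow(h), kernelSize)
        h <- causalDilatedConv(h, f, d) + cv$b
        h <- reluActivation(h)
        h <- spatialDropout(h, dropoutRate, training)
    }
    skip <- if (nrow(h) == nrow(X)) {
        X
    } else {
        if (is.null(params$proj))
            stop("channel mismatch between input and output with no 1x1 projection configured")
        params$proj$W %*% X + params$proj$b
    }
    reluActivation(skip + h)
}

## weight layout: the flat conv weight matrix is C_out x (C_in*K) with
## column (i_tap - 1)*C_in + c_in, matching the im2col row order used by
## the batched path. These two helpers convert to/from the 3-d array form
## consumed by causalDilatedConv.
wmat_to_array <- function(Wmat, Cin, K) {
    Cout <- nrow(Wmat)
    array(Wmat, dim = c(Cout, Cin, K))
}

array_to_wmat <- function(f) {
    d <- dim(f)
    matrix(f, nrow = d[1L], ncol = d[2L] * d[3L])
}
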