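# Internal helpers: seeding, convolution wrappers, small numerics.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Expand one user seed into named per-purpose sub-seeds so that adding a new
# noise source does not shift the draws of existing ones.
derive_seeds <- function(seed, purposes) {
  if (is.null(seed)) return(setNames(rep(list(NULL), length(purposes)), purposes))
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(purposes)))
  setNames(as.list(s), purposes)
}

# Separable convolution of a 2-D or 3-D array with 1-D kernels (reflective
# boundaries). Kernels of length 1 act as scalar gains.
sep_conv <- function(x, k1, k2, k3 = 1) {
  d <- dim(x)
  if (is.null(d)) stop("x must be a matrix or 3-D array")
  if (length(d) == 2) d <- c(d, 1L)
  out <- sep_conv3_cpp(as.double(x), as.integer(d),
                       as.double(k1), as.double(k2), as.double(k3))
  if (length(dim(x)) == 2) dim(out) <- dim(x) else dim(out) <- d
  out
}

# Dense correlation with a full 2-D/3-D kernel; flip = TRUE gives true
# convolution.
dense_conv <- function(x, kernel, flip = FALSE) {
  d <- dim(x); kd <- dim(kernel)
  if (length(d) == 2) { d <- c(d, 1L) }
  if (is.null(kd)) kd <- c(length(kernel), 1L, 1L)
  if (length(kd) == 2) kd <- c(kd, 1L)
  k <- if (flip) rev(as.double(kernel)) else as.double(kernel)
  out <- corr3_cpp(as.double(x), as.integer(d), k, as.integer(kd))
  if (length(dim(x)) == 2) dim(out) <- dim(x) else dim(out) <- d
  out
}

# Normalized 1-D Gaussian kernel sampled at integer offsets, radius
# ceiling(truncate * sigma). sigma = 0 collapses to a delta.
gauss_kernel_1d <- function(sigma, truncate = 3) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Otsu's threshold on a numeric vector (histogram-based, 256 bins).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(min(x, Inf))
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
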