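#' Block-diagonal correlation matrix, flat or nested
#'
#' Builds the reference correlation structure of the synthetic benchmarks:
#' ones on the diagonal, `rho` inside the blocks, zero outside. With a
#' nested layout (a list of per-level block sizes, outermost first, each
#' level refining the previous one) the inner blocks override the outer
#' values, so inner blocks carry the larger correlations.
#'
#' @param sizes Integer vector of block sizes (flat), or a list of such
#'   vectors, one per nesting level, outermost first; sizes at each level
#'   must sum to the same total N and refine the previous level.
#' @param rho Intra-block correlation, one value per level, in `[0, 1)`;
#'   strictly increasing inward for nested layouts.
#' @return An N x N correlation matrix with attribute `labels`: a tibble of
#'   ground-truth block memberships, one column per level.
#' @examples
#' C <- block_correlation(c(3, 3), rho = 0.5)
#' C <- block_correlation(list(c(4, 4), rep(2, 4)), rho = c(0.3, 0.7))
#' @export
block_correlation <- function(sizes, rho) {
  if (!is.list(sizes)) sizes <- list(sizes)
  nlev <- length(sizes)
  if (length(rho) != nlev) {
    stop("need one rho per nesting level", call. = FALSE)
  }
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)", call. = FALSE)
  if (nlev > 1L && any(diff(rho) <= 0)) {
    stop("nested rho must increase inward (outer < inner)", call. = FALSE)
  }
  n <- sum(sizes[[1L]])
  labs <- matrix(0L, n, nlev)
  for (l in seq_len(nlev)) {
    if (sum(sizes[[l]]) != n) {
      stop("level ", l, " block sizes do not sum to N", call. = FALSE)
    }
    labs[, l] <- rep(seq_along(sizes[[l]]), sizes[[l]])
  }
  for (l in seq_len(nlev)[-1L]) {
    if (any(stats::ave(labs[, l - 1L], labs[, l], FUN = function(z) length(unique(z))) != 1L)) {
      stop("level ", l, " does not refine level ", l - 1L, call. = FALSE)
    }
  }
  C <- matrix(0, n, n)
  for (l in seq_len(nlev)) {
    same <- outer(labs[, l], labs[, l], "==")
    C[same] <- rho[l] # inner levels overwrite outer values
  }
  diag(C) <- 1
  colnames(labs) <- paste0("level", seq_len(nlev))
  attr(C, "labels") <- tibble::as_tibble(as.data.frame(labs))
  C
}

#' Add random off-block correlations
#'
#' Plants `n_random` symmetric correlations unrelated to the block structure
#' at uniformly sampled off-block positions (entries that are exactly zero),
#' then repairs positive semi-definiteness if the insertion broke it.
#'
#' @param C Correlation matrix from [block_correlation()].
#' @param n_random Number of off-block pairs to set.
#' @param magnitude Correlation value placed at the sampled pairs.
#' @param seed RNG seed for the position sampling.
#' @return The modified (and, if needed, PSD-repaired) matrix; the `labels`
#'   attribute is preserved.
#' @export
add_random_correlations <- function(C, n_random, magnitude, seed = NULL) {
  labs <- attr(C, "labels")
  n <- nrow(C)
  free <- which(upper.tri(C) & C == 0)
  if (n_random > length(free)) {
    stop("n_random exceeds the available off-block pairs", call. = FALSE)
  }
  if (n_random > 0L) {
    pick <- with_seed(seed, sample(free, n_random))
    rc <- arrayInd(pick, dim(C))
    C[rc] <- magnitude
    C[rc[, c(2L, 1L), drop = FALSE]] <- magnitude
    C <- psd_repair(C)
  }
  attr(C, "labels") <- labs
  C
}

#' Clip-and-rescale PSD repair
#'
#' Nested or randomly perturbed constructions can leave the target matrix
#' slightly indefinite; negative eigenvalues are clipped to 1e-10 and the
#' result rescaled back to unit diagonal.
#' @param C Symmetric matrix.
#' @return A positive semi-definite correlation matrix.
#' @export
psd_repair <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) >= 0) {
    return(C)
  }
  vals <- pmax(eg$values, 1e-10)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  s <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(s)
  (out + t(out)) / 2
}

#' Sample correlated Gaussian series
#'
#' Multivariate Gaussian generator: N zero-mean unit-variance series of
#' length T whose population correlation matrix is `C` (sample correlations
#' converge to `C` as T grows). The matrix square root is taken by symmetric
#' eigendecomposition, so slightly semi-definite repaired matrices are
#' accepted.
#'
#' @param C Target correlation matrix (PSD).
#' @param t_len Series length T.
#' @param seed RNG seed.
#' @return An N x T matrix; the `labels` attribute of `C` is carried over.
#' @export
mvg_sample <- function(C, t_len, seed = NULL) {
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(nrow(C) * t_len), nrow(C), t_len)
    root %*% z
  })
  attr(x, "labels") <- attr(C, "labels")
  x
}

#' Sample correlated log-normal series
#'
#' Exponentiates Gaussian series drawn from a *reference* correlation chosen
#' so that the exponentiated series approximate the target correlation `C`:
#' for unit-variance log-normal margins built from standard normals, the
#' correlation of \eqn{e^{z_i}} and \eqn{e^{z_j}} with Gaussian correlation
#' \eqn{r} is \eqn{(e^r - 1)/(e - 1)}, inverted here as
#' \eqn{r = \log(1 + \rho (e - 1))}. Targets of 0 and 1 map to 0 and 1
#' exactly.
#'
#' @inheritParams mvg_sample
#' @return An N x T matrix of log-normal series.
#' @export
lognormal_sample <- function(C, t_len, seed = NULL) {
  ref <- log(1 + C * (exp(1) - 1))
  if (any(!is.finite(ref))) {
    stop("target correlation unattainable with log-normal margins", call. = FALSE)
  }
  diag(ref) <- 1
  ref <- psd_repair(ref)
  x <- exp(mvg_sample(ref, t_len, seed = seed))
  attr(x, "labels") <- attr(C, "labels")
  x
}

#' Standardized noise draw from a named family
#' @noRd
noise_draw <- function(n, family, nu) {
  switch(family,
    normal = stats::rnorm(n),
    lognormal = {
      # exp(Z) centred and scaled to zero mean, unit variance
      (exp(stats::rnorm(n)) - exp(0.5)) / sqrt(exp(2) - exp(1))
    },
    powerlaw = {
      # symmetric Pareto tail: density ~ |x|^-nu beyond x_min, random sign;
      # x_min chosen so the inter-quartile range matches a standard normal's
      if (is.null(nu) || nu <= 2) stop("powerlaw noise needs nu > 2", call. = FALSE)
      xmin <- stats::qnorm(0.75) / 2^(1 / (nu - 1))
      mag <- xmin * stats::runif(n)^(-1 / (nu - 1))
      sign <- sample(c(-1, 1), n, replace = TRUE)
      sign * mag
    },
    stop("unknown noise family '", family, "'", call. = FALSE)
  )
}

#' Add relative-amplitude noise to series
#'
#' Produces `y_i(t) = x_i(t) + a * sd(x_i) * eps_i(t)` with `eps` drawn
#' i.i.d. from the chosen family: standard normal, centred log-normal, or a
#' symmetric power-law with tail exponent `nu` (density decaying as
#' `|x|^-nu`), location-scaled so its inter-quartile range matches the
#' standard normal's. `a` tunes the noise amplitude relative to each
#' series' own scale; `a = 0` returns the input unchanged.
#'
#' @param x N x T data matrix.
#' @param family `"none"`, `"normal"`, `"lognormal"`, or `"powerlaw"`.
#' @param a Relative noise amplitude, `a >= 0`.
#' @param nu Tail exponent for the power-law family (`nu > 2`).
#' @param seed RNG seed.
#' @return The noisy matrix, `labels` attribute preserved.
#' @export
add_noise <- function(x, family = c("none", "normal", "lognormal", "powerlaw"),
                      a = 0, nu = NULL, seed = NULL) {
  family <- match.arg(family)
  if (a < 0) stop("a must be non-negative", call. = FALSE)
  if (family == "none" || a == 0) {
    return(x)
  }
  labs <- attr(x, "labels")
  sds <- apply(x, 1L, stats::sd)
  eps <- with_seed(seed, {
    matrix(noise_draw(nrow(x) * ncol(x), family, nu), nrow(x), ncol(x))
  })
  y <- x + a * sds * eps
  attr(y, "labels") <- labs
  y
}

#' The nested-hierarchy benchmark dataset
#'
#' Generates one replicate of the nested synthetic benchmark: 256 series in
#' 4 large blocks of 64, each containing 2 medium blocks of 32, each
#' containing 2 small blocks of 16, with intra-block correlations rising
#' inward, sampled as multivariate Gaussian series and degraded with
#' symmetric power-law noise. Ground-truth partitions at the three nesting
#' levels ride along. Defaults define the benchmark's study conditions; see
#' the methods vignette for their rationale.
#'
#' @param seed RNG seed for the replicate.
#' @param sizes Nested block layout (list, outermost level first).
#' @param rho Intra-block correlation per level, increasing inward.
#' @param t_len Series length.
#' @param noise Noise family.
#' @param a Relative noise amplitude (power-law noise is heavy-tailed, so
#'   benchmark amplitudes stay an order of magnitude below Gaussian ones).
#' @param nu Power-law tail exponent.
#' @param marginal `"gaussian"` or `"lognormal"` series statistics.
#' @return List with `data` (N x T matrix), `labels` (tibble with one
#'   ground-truth partition per level), and `C` (the target correlation).
#' @export
nested_benchmark <- function(seed,
                             sizes = list(rep(64L, 4), rep(32L, 8), rep(16L, 16)),
                             rho = c(0.3, 0.6, 0.9),
                             t_len = 2000L,
                             noise = "powerlaw",
                             a = 0.1,
                             nu = 3,
                             marginal = c("gaussian", "lognormal")) {
  marginal <- match.arg(marginal)
  C <- block_correlation(sizes, rho)
  sampler <- if (marginal == "gaussian") mvg_sample else lognormal_sample
  x <- sampler(C, t_len, seed = seed)
  x <- add_noise(x, noise, a = a, nu = nu, seed = if (is.null(seed)) NULL else seed + 1L)
  list(data = x, labels = attr(C, "labels"), C = C)
}

#' A flat blocks-plus-noise benchmark dataset
#'
#' Flat block-diagonal benchmark in the style of the dis-homogeneous
#' synthetic tests: blocks of the given sizes with intra-block correlation
#' `rho`, optional unclustered singleton series, optional random off-block
#' correlations, and additive noise. Ground truth labels the blocks
#' (singletons get their own labels).
#'
#' @param seed RNG seed.
#' @param sizes Block sizes.
#' @param rho Intra-block correlation.
#' @param n_singletons Number of additional uncorrelated series.
#' @param n_random Random off-block correlations planted (magnitude `rho`).
#' @param t_len Series length.
#' @inheritParams nested_benchmark
#' @return List with `data`, `labels` (tibble, one column), and `C`.
#' @export
flat_benchmark <- function(seed,
                           sizes = c(64L, rep(5L, 8)),
                           rho = 0.9,
                           n_singletons = 25L,
                           n_random = 0L,
                           t_len = 1000L,
                           noise = "none",
                           a = 0,
                           nu = 3,
                           marginal = c("gaussian", "lognormal")) {
  marginal <- match.arg(marginal)
  all_sizes <- c(sizes, rep(1L, n_singletons))
  C <- block_correlation(all_sizes, rho)
  if (n_random > 0L) {
    C <- add_random_correlations(C, n_random, magnitude = rho, seed = if (is.null(seed)) NULL else seed + 2L)
  }
  sampler <- if (marginal == "gaussian") mvg_sample else lognormal_sample
  x <- sampler(C, t_len, seed = seed)
  x <- add_noise(x, noise, a = a, nu = nu, seed = if (is.null(seed)) NULL else seed + 1L)
  labs <- attr(C, "labels")[, 1L, drop = FALSE]
  names(labs) <- "block"
  list(data = x, labels = labs, C = C)
}
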