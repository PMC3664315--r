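#' Conjugate prior for the polynomial-mean Gaussian observation model
#'
#' Each segment of a trajectory is modeled as L-dimensional Gaussian
#' observations whose mean is a polynomial of order S in time since the
#' segment start, with a full (segment-wise) precision matrix P. The
#' conjugate prior is an extended Gauss-Wishart: P follows a Wishart
#' density `W(P; nu, V) ~ |P|^((nu-L-1)/2) exp(-tr(V^-1 P)/2)`, and the
#' (S+1) x L coefficient matrix A given P is matrix-normal with mean
#' `coeff_bias` and precision `B (x) P` (Kronecker product of the
#' (S+1) x (S+1) concentration matrix with P). The Kronecker structure is
#' never materialized; all algebra is done in the (S+1) and L factors.
#'
#' @param order Polynomial order S (non-negative integer).
#' @param dim Observation dimension L (3 for wrist positions).
#' @param coeff_bias Prior mean of the coefficient matrix, (S+1) x L
#'   (default all zero). Note: despite the conventional symbol clash, this
#'   has nothing to do with the power-law gain factor.
#' @param coeff_concentration Symmetric positive-definite (S+1) x (S+1)
#'   concentration matrix B (default `0.1 * I`).
#' @param wishart_dof Degrees of freedom nu (must be `>= dim`). Default
#'   `dim + 2`, the smallest value for which the prior mean covariance
#'   `E[P^-1] = V^-1 / (nu - L - 1)` is finite.
#' @param wishart_scale Symmetric positive-definite L x L scale matrix V.
#'   Default identity. The standard data-calibrated choice sets V to the
#'   diagonal of the empirical coordinate variances; see
#'   [default_obs_prior()].
#' @return An object of class `obs_prior`.
#' @seealso [default_obs_prior()], [posterior_update()],
#'   [segment_log_evidence()]
#' @export
obs_prior <- function(order, dim = 3L,
                      coeff_bias = NULL,
                      coeff_concentration = NULL,
                      wishart_dof = dim + 2,
                      wishart_scale = diag(dim)) {
  order <- as.integer(order)
  dim <- as.integer(dim)
  stopifnot(order >= 0L, dim >= 1L)
  S1 <- order + 1L
  if (is.null(coeff_bias)) coeff_bias <- matrix(0, S1, dim)
  coeff_bias <- as.matrix(coeff_bias)
  stopifnot(nrow(coeff_bias) == S1, ncol(coeff_bias) == dim)
  if (is.null(coeff_concentration)) coeff_concentration <- 0.1 * diag(S1)
  coeff_concentration <- as.matrix(coeff_concentration)
  stopifnot(nrow(coeff_concentration) == S1,
            ncol(coeff_concentration) == S1)
  if (max(abs(coeff_concentration - t(coeff_concentration))) > 1e-10)
    stop("coeff_concentration must be symmetric", call. = FALSE)
  if (wishart_dof < dim)
    stop("wishart_dof must be >= dim", call. = FALSE)
  wishart_scale <- as.matrix(wishart_scale)
  stopifnot(nrow(wishart_scale) == dim, ncol(wishart_scale) == dim)
  if (max(abs(wishart_scale - t(wishart_scale))) > 1e-10)
    stop("wishart_scale must be symmetric", call. = FALSE)
  ev <- eigen(wishart_scale, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("wishart_scale must be positive definite",
                         call. = FALSE)
  structure(list(order = order, dim = dim, coeff_bias = coeff_bias,
                 coeff_concentration = coeff_concentration,
                 wishart_dof = wishart_dof, wishart_scale = wishart_scale,
                 wishart_inv_scale = chol2inv(chol(wishart_scale))),
            class = "obs_prior")
}

#' Data-calibrated default prior
#'
#' Standard hyperparameters for trajectory segmentation: zero coefficient
#' bias, concentration `0.1 * I` (in the orthonormal segment basis), and a
#' diagonal Wishart scale matrix carrying the empirical per-coordinate data
#' variances. Under the `W(P; nu, V) ~ |P|^((nu-L-1)/2) exp(-tr(V^-1 P)/2)`
#' convention the rate matrix `V^-1 = diag(1/var)` is then far below the
#' residual sum of squares of any densely sampled segment, so the evidence
#' resolves per-segment residuals at the measurement-noise scale - the
#' property that makes boundary and order recovery possible at all. (Were
#' the variances placed on the rate side instead, the modeled covariance
#' would be pinned near the path scale and fits differing by fractions of
#' a centimeter would be indistinguishable.)
#'
#' @param X Observation matrix (n x L), e.g. trajectory positions.
#' @param order Polynomial order S.
#' @param wishart_dof Degrees of freedom; default `ncol(X) + 2`, the
#'   smallest value for which the prior mean covariance is finite.
#' @return An [obs_prior()].
#' @export
default_obs_prior <- function(X, order, wishart_dof = ncol(X) + 2) {
  X <- as.matrix(X)
  v <- apply(X, 2L, stats::var)
  v <- pmax(v, 1e-12 * max(v, 1))
  obs_prior(order, dim = ncol(X),
            wishart_dof = wishart_dof,
            wishart_scale = diag(v, nrow = ncol(X)))
}

#' Polynomial basis matrix for a segment
#'
#' Row t of the basis is `(1, u, u^2, ..., u^S)` with
#' `u = (t - t_start) / scale`. Rescaling the elapsed time to the unit
#' interval (by passing `scale` = segment duration) keeps high-order bases
#' numerically well-conditioned; coefficients are then expressed in the
#' rescaled units.
#'
#' @param times Sample times (seconds) inside the segment.
#' @param t_start Segment start time (the left edge of the segment).
#' @param order Polynomial order S.
#' @param scale Time rescaling divisor (seconds); default 1 (raw elapsed
#'   seconds).
#' @return An `n x (S+1)` matrix.
#' @export
polynomial_basis <- function(times, t_start, order, scale = 1) {
  u <- (times - t_start) / scale
  outer(u, 0:order, `^`)
}

#' Orthonormal (shifted-Legendre) polynomial basis for a segment
#'
#' Row t is `(P0(u), ..., PS(u))` with `u = (t - t_start) / scale` and
#' `Pk` the shifted Legendre polynomial of degree k normalized to unit
#' norm under the uniform measure on `[0, 1]` (`Pk(u) = sqrt(2k+1)
#' Lk(2u-1)`). For densely sampled segments `Phi'Phi ~ n I`, so every
#' coefficient direction is identified equally well: the isotropic
#' coefficient concentration prior is interpreted in this basis, and the
#' ill-conditioning of raw monomial bases (whose Gram has eigenvalues far
#' below the concentration already at moderate orders) cannot distort the
#' evidence.
#'
#' @inheritParams polynomial_basis
#' @return An `n x (S+1)` matrix.
#' @seealso [polynomial_basis()] for the raw monomial basis.
#' @export
legendre_basis <- function(times, t_start, order, scale = 1) {
  x <- 2 * (times - t_start) / scale - 1
  n <- length(x)
  Phi <- matrix(0, n, order + 1L)
  Phi[, 1L] <- 1
  if (order >= 1L) Phi[, 2L] <- x
  if (order >= 2L) for (k in 1L:(order - 1L))
    Phi[, k + 2L] <- ((2 * k + 1) * x * Phi[, k + 1L] - k * Phi[, k]) /
      (k + 1)
  sweep(Phi, 2L, sqrt(2 * seq_len(order + 1L) - 1), `*`)
}

## Coefficient matrix of the normalized shifted Legendre basis in powers of
## u: row k holds the coefficients of Pk(u), so Phi_legendre = Phi_u %*% t(C).
legendre_coef_matrix <- function(order) {
  polys <- vector("list", order + 1L)
  polys[[1L]] <- 1
  if (order >= 1L) polys[[2L]] <- c(-1, 2)      # 2u - 1
  if (order >= 2L) for (k in 1L:(order - 1L)) {
    a <- poly_mult(c(-1, 2), polys[[k + 1L]]) * (2 * k + 1)
    b <- c(polys[[k]], 0, 0) * k
    polys[[k + 2L]] <- (a - b[seq_along(a)]) / (k + 1)
  }
  C <- matrix(0, order + 1L, order + 1L)
  for (k in 0:order)
    C[k + 1L, seq_along(polys[[k + 1L]])] <-
      polys[[k + 1L]] * sqrt(2 * k + 1)
  C
}

## log multivariate gamma function
lmvgamma <- function(a, L) {
  L * (L - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(L)) / 2))
}

## log normalizer of the extended Gauss-Wishart (up to terms that cancel
## between prior and posterior): -(L/2) log|B| + (nu L / 2) log 2
## + (nu/2) log|V| + log Gamma_L(nu/2), with log|V| = -log|Vinv|.
gw_log_normalizer <- function(ldetB, nu, ldetVinv, L) {
  -(L / 2) * ldetB + (nu * L / 2) * log(2) - (nu / 2) * ldetVinv +
    lmvgamma(nu / 2, L)
}

#' Conjugate posterior update and marginal evidence for one segment
#'
#' Observes `n` samples `X` with basis rows `Phi` under an [obs_prior()] and
#' returns the posterior hyperparameters together with the log marginal
#' likelihood (evidence) of the segment, computed in closed form as the
#' ratio of posterior to prior normalizers.
#'
#' @param prior An [obs_prior()].
#' @param X Observations, n x L matrix (n may be 0).
#' @param Phi Basis matrix, n x (S+1), typically from [polynomial_basis()].
#' @return An object of class `segment_posterior` with the updated
#'   `coeff_bias` (posterior mean coefficients), `coeff_concentration`,
#'   `wishart_dof`, `wishart_scale` (and its inverse), plus `n_obs` and
#'   `log_evidence` (nats).
#' @details Updates are the natural-conjugate multivariate Bayesian linear
#'   regression recursions: `B' = B + Phi'Phi`,
#'   `A' = B'^-1 (B A0 + Phi'X)`, `nu' = nu + n`, and the inverse scale
#'   absorbs `X'X + A0'B A0 - A''B'A'`. With `n = 0` the posterior equals
#'   the prior and the evidence is 0 (log of 1).
#' @export
posterior_update <- function(prior, X, Phi) {
  stopifnot(inherits(prior, "obs_prior"))
  X <- as.matrix(X)
  Phi <- as.matrix(Phi)
  L <- prior$dim
  S1 <- prior$order + 1L
  n <- nrow(X)
  stopifnot(nrow(Phi) == n, ncol(Phi) == S1, ncol(X) == L)
  B <- prior$coeff_concentration
  A0 <- prior$coeff_bias
  Vinv <- prior$wishart_inv_scale
  nu <- prior$wishart_dof

  Bp <- B + crossprod(Phi)
  cBp <- chol(Bp)
  Ap <- backsolve(cBp, backsolve(cBp, B %*% A0 + crossprod(Phi, X),
                                 transpose = TRUE))
  nup <- nu + n
  R <- crossprod(X) + t(A0) %*% B %*% A0 - t(Ap) %*% Bp %*% Ap
  Vinvp <- Vinv + (R + t(R)) / 2

  cB <- chol(B)
  cVinv <- chol(Vinv)
  cVinvp <- chol(Vinvp)
  ldet <- function(ch) 2 * sum(log(diag(ch)))
  lev <- -(n * L / 2) * log(2 * pi) +
    gw_log_normalizer(ldet(cBp), nup, ldet(cVinvp), L) -
    gw_log_normalizer(ldet(cB), nu, ldet(cVinv), L)
  structure(list(order = prior$order, dim = L,
                 coeff_bias = Ap, coeff_concentration = Bp,
                 wishart_dof = nup, wishart_scale = chol2inv(cVinvp),
                 wishart_inv_scale = Vinvp,
                 n_obs = n, log_evidence = lev),
            class = c("segment_posterior", "obs_prior"))
}

#' Posterior for the samples of one time segment
#'
#' Convenience wrapper: builds the rescaled polynomial basis for samples
#' inside `[t_start, t_end]` and runs [posterior_update()]. The basis
#' rescaling (elapsed time divided by the segment duration) is recorded in
#' the result so that [posterior_mean_trajectory()] can evaluate the fitted
#' polynomial consistently.
#'
#' @param times Sample times inside the segment.
#' @param X Observations (n x L).
#' @param prior An [obs_prior()].
#' @param t_start,t_end Segment edges in seconds (defaults: range of
#'   `times`).
#' @param basis `"legendre"` (default; orthonormal in the rescaled segment
#'   time, see [legendre_basis()]) or `"monomial"` (raw rescaled powers).
#' @return A `segment_posterior` with basis metadata (`t_start`, `t_scale`,
#'   `basis`).
#' @export
segment_posterior <- function(times, X, prior,
                              t_start = NULL, t_end = NULL,
                              basis = c("legendre", "monomial")) {
  X <- as.matrix(X)
  basis <- match.arg(basis)
  if (is.null(t_start)) t_start <- if (length(times)) min(times) else 0
  if (is.null(t_end)) t_end <- if (length(times)) max(times) else t_start + 1
  scale <- max(t_end - t_start, .Machine$double.eps)
  Phi <- if (basis == "legendre")
    legendre_basis(times, t_start, prior$order, scale)
  else polynomial_basis(times, t_start, prior$order, scale)
  post <- posterior_update(prior, X, Phi)
  post$t_start <- t_start
  post$t_scale <- scale
  post$basis <- basis
  post
}

#' Log marginal likelihood (evidence) of a segment's samples
#'
#' @inheritParams segment_posterior
#' @return Log evidence in nats; 0 if the segment contains no samples.
#' @export
segment_log_evidence <- function(times, X, prior,
                                 t_start = NULL, t_end = NULL,
                                 basis = c("legendre", "monomial")) {
  segment_posterior(times, X, prior, t_start, t_end, basis)$log_evidence
}

#' Posterior mean trajectory of a fitted segment
#'
#' Evaluates the posterior expected polynomial `Phi(times) A'` of a
#' [segment_posterior()] at the given times.
#'
#' @param posterior A `segment_posterior` carrying basis metadata.
#' @param times Times (seconds) at which to evaluate; should lie inside the
#'   segment.
#' @return Matrix of predicted positions (length(times) x L).
#' @export
posterior_mean_trajectory <- function(posterior, times) {
  stopifnot(inherits(posterior, "segment_posterior"))
  if (is.null(posterior$t_start))
    stop("posterior carries no basis metadata; build it with ",
         "segment_posterior()", call. = FALSE)
  Phi <- if (identical(posterior$basis, "monomial"))
    polynomial_basis(times, posterior$t_start, posterior$order,
                     posterior$t_scale)
  else legendre_basis(times, posterior$t_start, posterior$order,
                      posterior$t_scale)
  Phi %*% posterior$coeff_bias
}

#' Serialize observation-model hyperparameters to JSON
#' @param prior An [obs_prior()].
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
obs_prior_to_json <- function(prior, path = NULL) {
  x <- list(order = prior$order, dim = prior$dim,
            coeff_bias = prior$coeff_bias,
            coeff_concentration = prior$coeff_concentration,
            wishart_dof = prior$wishart_dof,
            wishart_scale = prior$wishart_scale)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize observation-model hyperparameters from JSON
#' @param json JSON string or path to a JSON file.
#' @return An [obs_prior()].
#' @export
obs_prior_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  obs_prior(order = x$order, dim = x$dim,
            coeff_bias = matrix(unlist(x$coeff_bias), x$order + 1, x$dim),
            coeff_concentration = matrix(unlist(x$coeff_concentration),
                                         x$order + 1, x$order + 1),
            wishart_dof = x$wishart_dof,
            wishart_scale = matrix(unlist(x$wishart_scale), x$dim, x$dim))
}
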