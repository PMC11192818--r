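# Dirichlet-process Gaussian mixture over 2D tool placements.
#
# Model: partition ~ CRP(alpha); each block's points are iid Gaussian with
# a conjugate normal-inverse-Wishart prior on (mean, covariance), so block
# marginal likelihoods and per-point posterior predictives (bivariate
# Student-t) are available in closed form and assignments can be sampled
# by collapsed Gibbs.

#' Normal-inverse-Wishart base measure
#'
#' Conjugate prior on a cluster's Gaussian mean and covariance. With prior
#' mean `mu0` (strength `kappa0`) and scale matrix `psi0` (`nu0` degrees of
#' freedom), the prior covariance mean is `psi0 / (nu0 - 3)` in 2D, which
#' is why `nu0 > 3` is required.
#'
#' @param mu0 length-2 prior mean (px).
#' @param kappa0 prior strength on the mean (> 0).
#' @param nu0 degrees of freedom (> 3).
#' @param psi0 2x2 symmetric positive-definite scale matrix (px^2).
#' @return An object of class `niw_params`.
#' @export
niw_params <- function(mu0, kappa0, nu0, psi0) {
  mu0 <- as.numeric(mu0)
  psi0 <- as.matrix(psi0)
  if (length(mu0) != 2L) stop("mu0 must have length 2", call. = FALSE)
  if (kappa0 <= 0) stop("kappa0 must be > 0", call. = FALSE)
  if (nu0 <= 3) stop("nu0 must exceed 3 (dimension + 1)", call. = FALSE)
  if (!isTRUE(all.equal(psi0, t(psi0))) ||
      det(psi0) <= 0 || psi0[1, 1] <= 0)
    stop("psi0 must be symmetric positive-definite", call. = FALSE)
  structure(list(mu0 = mu0, kappa0 = kappa0, nu0 = nu0, psi0 = psi0),
            class = "niw_params")
}

#' Data-scaled default base measure
#'
#' `mu0` is the empirical mean of the points; `psi0` is the diagonal of the
#' empirical variances times `nu0 - 3`, so the prior covariance mean
#' matches the data scale; `kappa0 = 0.1` keeps the prior mean weak.
#'
#' @param points n x 2 matrix of placements.
#' @param kappa0,nu0 see [niw_params()].
#' @return A `niw_params`.
#' @export
default_niw <- function(points, kappa0 = 0.1, nu0 = 4) {
  points <- as.matrix(points)
  v <- if (nrow(points) >= 2) apply(points, 2, stats::var) else c(1, 1)
  v <- pmax(v, 1e-6)
  niw_params(colMeans(points), kappa0, nu0, diag(v * (nu0 - 3), 2))
}

# log of the 2-dimensional multivariate gamma function
lmvgamma2 <- function(a) 0.5 * log(pi) + lgamma(a) + lgamma(a - 0.5)

# NIW marginal log-likelihood of a block of 2D points (closed form).
niw_log_marginal <- function(X, base) {
  X <- matrix(X, ncol = 2)
  n <- nrow(X)
  if (n == 0L) return(0)
  d <- 2
  kap_n <- base$kappa0 + n
  nu_n <- base$nu0 + n
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar))
  dev <- xbar - base$mu0
  psi_n <- base$psi0 + S + (base$kappa0 * n / kap_n) * tcrossprod(dev)
  -n * d / 2 * log(pi) + lmvgamma2(nu_n / 2) - lmvgamma2(base$nu0 / 2) +
    base$nu0 / 2 * log(det(base$psi0)) - nu_n / 2 * log(det(psi_n)) +
    d / 2 * (log(base$kappa0) - log(kap_n))
}

# CRP log-probability of a partition given its block sizes.
crp_log_prior <- function(sizes, alpha, n = sum(sizes)) {
  length(sizes) * log(alpha) + sum(lgamma(sizes)) -
    sum(log(alpha + 0:(n - 1)))
}

#' Expected number of CRP clusters
#'
#' Closed form `sum_{i=1..n} alpha / (alpha + i - 1)` for the expected
#' number of occupied tables after `n` customers.
#'
#' @param alpha concentration parameter (> 0).
#' @param n number of points.
#' @return Expected cluster count.
#' @export
crp_expected_clusters <- function(alpha, n) {
  sum(alpha / (alpha + seq_len(n) - 1))
}

#' Sample a partition from the Chinese restaurant process
#'
#' Sequential seating: customer i joins an existing table of size m with
#' probability proportional to m, or a new table with probability
#' proportional to `alpha`.
#'
#' @param n number of customers.
#' @param alpha concentration (> 0).
#' @return Integer vector of table labels, contiguous from 1.
#' @export
rcrp <- function(n, alpha) {
  z <- integer(n)
  sizes <- numeric(0)
  for (i in seq_len(n)) {
    p <- c(sizes, alpha)
    k <- sample.int(length(p), 1, prob = p)
    if (k > length(sizes)) sizes <- c(sizes, 1) else sizes[k] <- sizes[k] + 1
    z[i] <- k
  }
  z
}

# Vectorized posterior-predictive log-density of point x under clusters
# summarised by sufficient-statistic vectors (n may be 0: prior predictive).
logpred_vec <- function(x, ns, sx, sy, sxx, syy, sxy, base) {
  kap <- base$kappa0 + ns
  nu <- base$nu0 + ns
  mux <- (base$kappa0 * base$mu0[1] + sx) / kap
  muy <- (base$kappa0 * base$mu0[2] + sy) / kap
  pos <- ns > 0
  xbx <- ifelse(pos, sx / pmax(ns, 1), 0)
  xby <- ifelse(pos, sy / pmax(ns, 1), 0)
  Sxx <- ifelse(pos, sxx - sx * xbx, 0)
  Syy <- ifelse(pos, syy - sy * xby, 0)
  Sxy <- ifelse(pos, sxy - sx * xby, 0)
  w <- base$kappa0 * ns / kap
  pxx <- base$psi0[1, 1] + Sxx + w * (xbx - base$mu0[1])^2
  pyy <- base$psi0[2, 2] + Syy + w * (xby - base$mu0[2])^2
  pxy <- base$psi0[1, 2] + Sxy + w * (xbx - base$mu0[1]) * (xby - base$mu0[2])
  detp <- pxx * pyy - pxy^2
  df <- nu - 1
  cc <- (kap + 1) / (kap * df)
  dx <- x[1] - mux
  dy <- x[2] - muy
  maha <- (dx * dx * pyy - 2 * dx * dy * pxy + dy * dy * pxx) / detp / cc
  lgamma((df + 2) / 2) - lgamma(df / 2) - log(df * pi) -
    0.5 * (2 * log(cc) + log(detp)) - (df + 2) / 2 * log1p(maha / df)
}

# log_joint of a labeled partition: CRP prior + sum of block marginals.
partition_log_joint <- function(points, z, alpha, base) {
  sizes <- tabulate(z)
  sizes <- sizes[sizes > 0]
  crp_log_prior(sizes, alpha, nrow(points)) +
    sum(vapply(unique(z), function(k)
      niw_log_marginal(points[z == k, , drop = FALSE], base), numeric(1)))
}

#' Fit a Dirichlet-process Gaussian mixture by collapsed Gibbs sampling
#'
#' Cluster assignments are resampled one point at a time: an existing
#' cluster k is proposed with weight `n_k^(-i)` times the bivariate
#' Student-t posterior predictive of the cluster without point i, and a new
#' cluster with weight `alpha` times the prior predictive. The returned
#' state is the retained (post burn-in) sweep with maximal joint
#' log-probability (CRP prior + NIW block marginals), so the point estimate
#' is reproducible and can be checked against exact enumeration.
#' Responsibilities are posterior-predictive membership probabilities of
#' each point under the returned partition's clusters (weighted by cluster
#' size, renormalized over existing clusters only).
#'
#' @param points n x 2 matrix (or data frame) of placements.
#' @param alpha DP concentration (> 0).
#' @param base a `niw_params`, or `NULL` for [default_niw()] on the data.
#' @param n_sweeps total Gibbs sweeps; must exceed `burn_in`.
#' @param burn_in sweeps discarded before tracking the best partition.
#' @param seed integer seed; the fit is deterministic given it.
#' @param keep_samples also record the canonical partition string of every
#'   retained sweep (in `samples`), for posterior diagnostics.
#' @return An object of class `cogstyle_dpmm`: `points`, `alpha`, `base`,
#'   `assignments` (contiguous labels 1..K), `log_joint`,
#'   `responsibilities` (n x K, rows sum to 1), `retained` (per-sweep
#'   log-joints after burn-in), and `samples` if requested.
#' @export
fit_dpmm <- function(points, alpha = 1, base = NULL, n_sweeps = 500,
                     burn_in = 250, seed = 1, keep_samples = FALSE) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || !all(is.finite(points)))
    stop("points must be a finite n x 2 numeric matrix", call. = FALSE)
  n <- nrow(points)
  if (n < 1L) stop("need at least one point", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (n_sweeps <= burn_in) stop("n_sweeps must exceed burn_in", call. = FALSE)
  if (is.null(base)) base <- default_niw(points)
  stopifnot(inherits(base, "niw_params"))

  with_seed(seed, {
    # slotted sufficient statistics, initialized with every point in its
    # own cluster: merging under collapsed Gibbs is far easier than
    # splitting, so singleton starts avoid under-segmented local modes
    max_slots <- n + 1L
    ns <- numeric(max_slots)
    sx <- sy <- sxx <- syy <- sxy <- numeric(max_slots)
    z <- seq_len(n)
    ns[z] <- 1
    sx[z] <- points[, 1]; sy[z] <- points[, 2]
    sxx[z] <- points[, 1]^2; syy[z] <- points[, 2]^2
    sxy[z] <- points[, 1] * points[, 2]

    best_z <- z
    best_lj <- -Inf
    retained <- numeric(0)
    samples <- character(0)

    for (sweep in seq_len(n_sweeps)) {
      for (i in seq_len(n)) {
        xi <- points[i, ]
        k <- z[i]
        ns[k] <- ns[k] - 1
        sx[k] <- sx[k] - xi[1]; sy[k] <- sy[k] - xi[2]
        sxx[k] <- sxx[k] - xi[1]^2; syy[k] <- syy[k] - xi[2]^2
        sxy[k] <- sxy[k] - xi[1] * xi[2]

        active <- which(ns > 0)
        empty <- if (ns[k] == 0) k else which(ns == 0)[1]
        slots <- c(active, empty)
        lp <- logpred_vec(xi, ns[slots], sx[slots], sy[slots], sxx[slots],
                          syy[slots], sxy[slots], base)
        lw <- lp + log(c(ns[active], alpha))
        w <- exp(lw - max(lw))
        knew <- slots[sample.int(length(slots), 1, prob = w)]
        z[i] <- knew
        ns[knew] <- ns[knew] + 1
        sx[knew] <- sx[knew] + xi[1]; sy[knew] <- sy[knew] + xi[2]
        sxx[knew] <- sxx[knew] + xi[1]^2; syy[knew] <- syy[knew] + xi[2]^2
        sxy[knew] <- sxy[knew] + xi[1] * xi[2]
      }
      if (sweep > burn_in) {
        lj <- partition_log_joint(points, z, alpha, base)
        retained <- c(retained, lj)
        if (keep_samples)
          samples <- c(samples, paste(match(z, unique(z)), collapse = "."))
        if (lj > best_lj) { best_lj <- lj; best_z <- z }
      }
    }

    # relabel best partition contiguously by order of first appearance
    labels <- match(best_z, unique(best_z))
    K <- max(labels)
    resp <- matrix(0, n, K)
    cn <- csx <- csy <- csxx <- csyy <- csxy <- numeric(K)
    for (k in seq_len(K)) {
      idx <- labels == k
      cn[k] <- sum(idx)
      csx[k] <- sum(points[idx, 1]); csy[k] <- sum(points[idx, 2])
      csxx[k] <- sum(points[idx, 1]^2); csyy[k] <- sum(points[idx, 2]^2)
      csxy[k] <- sum(points[idx, 1] * points[idx, 2])
    }
    for (i in seq_len(n)) {
      lw <- log(cn) + logpred_vec(points[i, ], cn, csx, csy, csxx, csyy,
                                  csxy, base)
      w <- exp(lw - max(lw))
      resp[i, ] <- w / sum(w)
    }

    structure(list(points = points, alpha = alpha, base = base,
                   assignments = labels, log_joint = best_lj,
                   responsibilities = resp, retained = retained,
                   samples = if (keep_samples) samples else NULL,
                   n_sweeps = n_sweeps, burn_in = burn_in, seed = seed),
              class = "cogstyle_dpmm")
  })
}

#' @export
print.cogstyle_dpmm <- function(x, ...) {
  cat(sprintf("<cogstyle_dpmm> n = %d, K = %d, alpha = %g, log joint = %.3f\n",
              nrow(x$points), max(x$assignments), x$alpha, x$log_joint))
  cat(sprintf("  cluster sizes: %s\n",
              paste(tabulate(x$assignments), collapse = ", ")))
  invisible(x)
}

#' Highest-responsibility cluster labels
#'
#' Label of point i is the argmax of its responsibility row; exact ties go
#' to the lowest cluster index.
#'
#' @param state a fitted `cogstyle_dpmm`.
#' @return Integer label vector.
#' @export
map_labels <- function(state) {
  stopifnot(inherits(state, "cogstyle_dpmm"))
  max.col(state$responsibilities, ties.method = "first")
}

# All set partitions of 1..n as a list of label vectors (restricted
# growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, maxk) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (k in seq_len(maxk + 1L))
      rec(c(labels, k), max(maxk, k))
    invisible()
  }
  rec(integer(0), 0L)
  out
}

#' Exact partition posterior by enumeration
#'
#' Test oracle for the collapsed Gibbs sampler: enumerates every set
#' partition of the points (feasible for n <= 8; Bell(8) = 4140), scores
#' each by CRP prior times the product of NIW block marginal likelihoods,
#' and normalizes.
#'
#' @param points n x 2 matrix, n <= 8.
#' @param alpha DP concentration.
#' @param base a `niw_params`, or `NULL` for [default_niw()].
#' @return List with `partitions` (list of label vectors) and `prob`
#'   (matching probabilities, summing to 1).
#' @export
partition_posterior_bruteforce <- function(points, alpha, base = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n > 8L) stop("brute-force enumeration limited to n <= 8", call. = FALSE)
  if (is.null(base)) base <- default_niw(points)
  parts <- all_partitions(n)
  ll <- vapply(parts, function(z) partition_log_joint(points, z, alpha, base),
               numeric(1))
  m <- max(ll)
  p <- exp(ll - m)
  list(partitions = parts, prob = p / sum(p))
}
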