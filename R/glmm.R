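# Internal machinery for Poisson / NB2 / zero-inflated-NB2 mixed models with
# independent Gaussian random intercepts, fitted by Laplace approximation.
#
# Layout: eta = X beta + Z b, b ~ N(0, D) with D diagonal, one variance per
# grouping factor. Inner loop: penalized Newton on (beta, b) jointly given
# the dispersion / zero-inflation / variance parameters (fixed effects are
# profiled at the joint mode). Outer loop: L-BFGS-B on
# (log theta, logit pi, log sigma_g). The Laplace log-likelihood is
#   l(eta-hat) - b'D^{-1}b/2 - log det(I_q + D^{1/2} Z'WZ D^{1/2}) / 2,
# with W the observed information of the conditional log-likelihood in eta;
# the determinant form is stable as sigma_g -> 0 and collapses to the plain
# fixed-effects likelihood there.

# Per-observation conditional log-likelihood and its first two derivatives
# in eta, by family. theta is the NB2 dispersion (variance mu + mu^2/theta),
# pi the zero-inflation probability.
.fam_derivs <- function(y, eta, family, theta = NULL, pi = NULL) {
  mu <- exp(eta)
  if (family == "poisson") {
    ll <- stats::dpois(y, mu, log = TRUE)
    g <- y - mu
    h <- -mu
  } else if (family == "nb2") {
    ll <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
    g <- theta * (y - mu) / (theta + mu)
    h <- -theta * mu * (y + theta) / (theta + mu)^2
  } else if (family == "zinb2") {
    ll <- g <- h <- numeric(length(y))
    pos <- y > 0
    if (any(pos)) {
      mp <- mu[pos]; yp <- y[pos]
      ll[pos] <- log1p(-pi) +
        stats::dnbinom(yp, size = theta, mu = mp, log = TRUE)
      g[pos] <- theta * (yp - mp) / (theta + mp)
      h[pos] <- -theta * mp * (yp + theta) / (theta + mp)^2
    }
    if (any(!pos)) {
      m0 <- mu[!pos]
      logp0 <- theta * (log(theta) - log(theta + m0))
      p0 <- exp(logp0)
      A <- pi + (1 - pi) * p0
      u <- theta * m0 / (theta + m0)
      dp0 <- -p0 * u                                   # d p0 / d eta
      d2p0 <- p0 * u^2 - p0 * theta^2 * m0 / (theta + m0)^2
      g0 <- (1 - pi) * dp0 / A
      ll[!pos] <- log(A)
      g[!pos] <- g0
      h[!pos] <- (1 - pi) * d2p0 / A - g0^2
    }
  } else stop("unknown family: ", family)
  list(ll = sum(ll), g = g, h = h, mu = mu)
}

# Probability of a zero count under the fitted conditional distribution.
.fam_pzero <- function(mu, family, theta = NULL, pi = NULL) {
  switch(family,
         poisson = exp(-mu),
         nb2 = exp(theta * (log(theta) - log(theta + mu))),
         zinb2 = pi + (1 - pi) * exp(theta * (log(theta) - log(theta + mu))),
         stop("unknown family: ", family))
}

# Conditional variance of y given the random effects.
.fam_var <- function(mu, family, theta = NULL, pi = NULL) {
  switch(family,
         poisson = mu,
         nb2 = mu + mu^2 / theta,
         zinb2 = (1 - pi) * mu * (1 + mu / theta + pi * mu),
         stop("unknown family: ", family))
}

# Mean of y given the random effects (zero-inflation thins the NB mean).
.fam_mean <- function(mu, family, pi = NULL) {
  if (family == "zinb2") (1 - pi) * mu else mu
}

# Sparse indicator matrix for the random-intercept blocks.
# groups: data.frame of grouping keys (one column per factor).
# Returns Z (n x q sparse), the level labels, and the factor index per column.
.build_z <- function(groups) {
  if (is.null(groups) || ncol(groups) == 0L)
    return(list(Z = NULL, levels = character(0), block = integer(0)))
  n <- nrow(groups)
  cols <- list(); labs <- character(0); block <- integer(0)
  off <- 0L
  iidx <- list(); jidx <- list()
  for (k in seq_len(ncol(groups))) {
    f <- factor(as.character(groups[[k]]))
    nl <- nlevels(f)
    iidx[[k]] <- seq_len(n)
    jidx[[k]] <- off + as.integer(f)
    labs <- c(labs, paste(names(groups)[k], levels(f), sep = ":"))
    block <- c(block, rep.int(k, nl))
    off <- off + nl
  }
  Z <- Matrix::sparseMatrix(i = unlist(iidx), j = unlist(jidx), x = 1,
                            dims = c(n, off))
  list(Z = Z, levels = labs, block = block)
}

# Penalized Newton for the joint mode of (beta, b) given family parameters.
# dvec: prior variance per random-effect column (length q). Returns the mode,
# the conditional log-likelihood there, the penalty, and the pieces needed
# for the Laplace determinant and Wald covariance.
.inner_mode <- function(X, Z, y, family, theta, pi, dvec,
                        start = NULL, tol = 1e-8, maxit = 200L) {
  n <- nrow(X); p <- ncol(X); q <- if (is.null(Z)) 0L else ncol(Z)
  u <- if (!is.null(start) && length(start) == p + q) start else {
    b0 <- c(log(mean(y) + 0.1), rep(0, p - 1L))
    c(b0, rep(0, q))
  }
  pen_inv <- if (q) 1 / dvec else numeric(0)
  obj <- function(u) {
    eta <- drop(X %*% u[seq_len(p)]) +
      (if (q) as.numeric(Z %*% u[p + seq_len(q)]) else 0)
    fd <- .fam_derivs(y, eta, family, theta, pi)
    pen <- if (q) 0.5 * sum(u[p + seq_len(q)]^2 * pen_inv) else 0
    list(val = fd$ll - pen, fd = fd, eta = eta)
  }
  cur <- obj(u)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    g_eta <- cur$fd$g
    w <- pmax(-cur$fd$h, 1e-10)
    gX <- drop(crossprod(X, g_eta))
    XtWX <- crossprod(X * w, X)
    if (q) {
      b <- u[p + seq_len(q)]
      gZ <- as.numeric(Matrix::crossprod(Z, g_eta)) - b * pen_inv
      ZtWX <- as.matrix(Matrix::crossprod(Z, X * w))
      ZtWZ <- as.matrix(Matrix::crossprod(Z, Z * w))
      H <- rbind(cbind(XtWX, t(ZtWX)),
                 cbind(ZtWX, ZtWZ + diag(pen_inv, q)))
      grad <- c(gX, gZ)
    } else {
      H <- XtWX
      grad <- gX
    }
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), grad)
    })
    # step-halving: the zero-inflated objective is not globally concave
    ok <- FALSE
    for (half in 0:30) {
      cand <- u + step / 2^half
      new <- obj(cand)
      if (is.finite(new$val) && new$val >= cur$val - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    moved <- max(abs(cand - u))
    u <- cand; cur <- new
    if (max(abs(grad)) < tol * (1 + abs(cur$val)) || moved < 1e-12) {
      converged <- TRUE
      break
    }
  }
  w <- pmax(-cur$fd$h, 1e-10)
  list(u = u, eta = cur$eta, mu = cur$fd$mu, ll = cur$fd$ll,
       val = cur$val, w = w, converged = converged, p = p, q = q)
}

# Laplace log-likelihood given the variance / dispersion / zi parameters.
.laplace_obj <- function(mode, Z, dvec) {
  if (mode$q == 0L) return(mode$ll)
  s <- sqrt(dvec)
  ZtWZ <- as.matrix(Matrix::crossprod(Z, Z * mode$w))
  M <- diag(mode$q) + (s %o% s) * ZtWZ
  ld <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  mode$val - 0.5 * ld
}

# Wald covariance of beta from the joint penalized Hessian at the mode.
.beta_vcov <- function(X, Z, mode, dvec) {
  p <- mode$p; q <- mode$q
  w <- mode$w
  XtWX <- crossprod(X * w, X)
  if (q == 0L) return(solve(XtWX))
  ZtWX <- as.matrix(Matrix::crossprod(Z, X * w))
  ZtWZ <- as.matrix(Matrix::crossprod(Z, Z * w))
  H <- rbind(cbind(XtWX, t(ZtWX)),
             cbind(ZtWX, ZtWZ + diag(1 / dvec, q)))
  V <- solve(H)
  V[seq_len(p), seq_len(p), drop = FALSE]
}
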