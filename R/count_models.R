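#' Specify a count model for species-interest data
#'
#' @param response `"papers"` (scientific interest) or `"views"` (societal
#'   interest); selects the response column when fitting an
#'   [prepare_design()] object.
#' @param family `"poisson"`, `"nb2"` (negative binomial, variance
#'   `mu + mu^2/theta`), or `"zinb2"` (zero-inflated NB2 with an
#'   intercept-only inflation probability).
#' @param fixed_terms Ordered character vector of fixed-effect design
#'   columns; defaults to [fixed_terms()] for `variant`.
#' @param random_terms Character vector of grouping-key columns (nested
#'   taxonomy expanded to composite keys, crossed region); defaults to
#'   [random_terms()] for `variant`. Use `character(0)` for a
#'   fixed-effects-only model.
#' @param variant `"eq1"` or `"eq2"`; sets the term defaults.
#' @param zi_structure `"none"` or `"intercept_only"`; `"zinb2"` requires
#'   (and defaults to) `"intercept_only"`.
#' @return An object of class `count_model_spec`.
#' @export
count_model_spec <- function(response = c("papers", "views"),
                             family = c("nb2", "poisson", "zinb2"),
                             fixed_terms = NULL,
                             random_terms = NULL,
                             variant = c("eq1", "eq2"),
                             zi_structure = NULL) {
  response <- match.arg(response)
  family <- match.arg(family)
  variant <- match.arg(variant)
  if (is.null(fixed_terms)) fixed_terms <- biointerest::fixed_terms(variant)
  if (is.null(random_terms)) random_terms <- biointerest::random_terms(variant)
  if (!length(fixed_terms)) stop("fixed_terms must be nonempty")
  if (is.null(zi_structure))
    zi_structure <- if (family == "zinb2") "intercept_only" else "none"
  if (family == "zinb2" && zi_structure != "intercept_only")
    stop("zinb2 requires zi_structure = 'intercept_only'")
  if (family != "zinb2" && zi_structure != "none")
    stop("zero inflation is only available with family = 'zinb2'")
  structure(list(response = response, family = family,
                 fixed_terms = fixed_terms, random_terms = random_terms,
                 variant = variant, zi_structure = zi_structure),
            class = "count_model_spec")
}

.resolve_design <- function(design, y, spec) {
  if (inherits(design, "interest_design")) {
    Xdf <- design$design
    groups <- design$groups
    if (is.null(y))
      y <- switch(spec$response, papers = design$y_papers,
                  views = design$y_views)
  } else {
    Xdf <- as.data.frame(design)
    groups <- if (length(spec$random_terms) &&
                  all(spec$random_terms %in% names(Xdf)))
      Xdf[, spec$random_terms, drop = FALSE] else NULL
  }
  miss <- setdiff(spec$fixed_terms, names(Xdf))
  if (length(miss))
    stop("design is missing fixed-effect columns: ",
         paste(miss, collapse = ", "))
  if (length(spec$random_terms)) {
    if (is.null(groups) || !all(spec$random_terms %in% names(groups)))
      stop("design carries no grouping columns for random terms: ",
           paste(spec$random_terms, collapse = ", "))
    groups <- groups[, spec$random_terms, drop = FALSE]
  } else groups <- NULL
  if (is.null(y)) stop("no response supplied")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(Xdf[, spec$fixed_terms, drop = FALSE]))
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response")
  if (nrow(X) != length(y)) stop("design rows do not match response length")
  if (any(y < 0) || any(y != floor(y))) stop("response must be counts")
  list(X = X, y = as.numeric(y), groups = groups)
}

#' Fit a mixed count model by Laplace approximation
#'
#' Fits the log-link Poisson, NB2 or zero-inflated NB2 model with
#' independent Gaussian random intercepts per grouping factor. Fixed effects
#' and random-effect modes are found jointly by penalized Newton iteration;
#' the dispersion `theta` (log scale), zero-inflation probability `pi`
#' (logit scale) and random-intercept variances (log-SD scale) are optimized
#' on the Laplace-approximated marginal log-likelihood (L-BFGS-B). With no
#' random terms the fit is exact maximum likelihood.
#'
#' @param design An [prepare_design()] object, or a data.frame holding the
#'   fixed-effect columns (and grouping columns, if random terms are used).
#' @param y Integer response counts; may be omitted when `design` is an
#'   `interest_design` (then chosen by `spec$response`).
#' @param spec A [count_model_spec()].
#' @param opts List of optional controls: `inner_tol` (Newton gradient
#'   tolerance, default 1e-8), `outer_maxit` (default 200), `theta_fix`,
#'   `pi_fix`, `sigma_fix` (fix the corresponding parameters rather than
#'   estimating them; `sigma_fix` is a scalar SD recycled over grouping
#'   factors), `verbose`.
#' @return Object of class `count_model_fit`: named coefficients `beta`,
#'   `se`, `ci95` (Wald), `theta`, `zi_prob`, `sigma2_g` (named variance per
#'   grouping factor), `loglik`, `aic` (penalty counts beta, theta, pi and
#'   every estimated variance), `n_obs`, `converged`, conditional fitted
#'   means `fitted_mu`, random-effect modes `ranef`, and bookkeeping fields.
#' @export
fit_count_model <- function(design, y = NULL, spec = count_model_spec(),
                            opts = list()) {
  o <- utils::modifyList(list(inner_tol = 1e-8, inner_maxit = 200L,
                              outer_maxit = 200L, theta_fix = NULL,
                              pi_fix = NULL, sigma_fix = NULL,
                              verbose = FALSE), opts)
  d <- .resolve_design(design, y, spec)
  X <- d$X; yv <- d$y
  zb <- .build_z(d$groups)
  Z <- zb$Z
  q <- if (is.null(Z)) 0L else ncol(Z)
  n_factors <- if (q) max(zb$block) else 0L
  factor_names <- if (q) names(d$groups) else character(0)
  p <- ncol(X)

  has_theta <- spec$family %in% c("nb2", "zinb2") && is.null(o$theta_fix)
  has_pi <- spec$family == "zinb2" && is.null(o$pi_fix)
  est_sigma <- n_factors > 0L && is.null(o$sigma_fix)

  # starting values: Poisson fixed-effects fit for beta (via the inner
  # Newton itself), method-of-moments theta, sigma0 = 0.1
  mu0 <- mean(yv) + 0.1
  theta0 <- if (spec$family %in% c("nb2", "zinb2")) {
    v <- stats::var(yv); m <- mean(yv)
    t0 <- if (v > m) m^2 / (v - m) else 1
    min(max(t0, 0.05), 50)
  } else NULL
  pi0 <- 0.05

  lo_sig <- -5; hi_sig <- 3
  phi <- c(if (has_theta) log(theta0),
           if (has_pi) stats::qlogis(pi0),
           if (est_sigma) rep(log(0.1), n_factors))
  lower <- c(if (has_theta) -5, if (has_pi) -10,
             if (est_sigma) rep(lo_sig, n_factors))
  upper <- c(if (has_theta) 15, if (has_pi) 5,
             if (est_sigma) rep(hi_sig, n_factors))

  unpack <- function(phi) {
    i <- 0L
    theta <- if (has_theta) exp(phi[i <- i + 1L]) else
      if (!is.null(o$theta_fix)) o$theta_fix else NULL
    pi <- if (has_pi) stats::plogis(phi[i <- i + 1L]) else
      if (!is.null(o$pi_fix)) o$pi_fix else
        if (spec$family == "zinb2") NULL else NULL
    sig <- if (n_factors) {
      if (est_sigma) exp(phi[i + seq_len(n_factors)])
      else rep_len(o$sigma_fix, n_factors)
    } else numeric(0)
    list(theta = theta, pi = pi, sigma = sig)
  }

  env <- new.env()
  env$start <- NULL
  eval_obj <- function(phi) {
    pr <- unpack(phi)
    dvec <- if (q) pmax(pr$sigma[zb$block]^2, 1e-12) else numeric(0)
    mode <- .inner_mode(X, Z, yv, spec$family, pr$theta, pr$pi, dvec,
                        start = env$start, tol = o$inner_tol,
                        maxit = o$inner_maxit)
    env$start <- mode$u
    env$mode <- mode
    .laplace_obj(mode, Z, dvec)
  }

  if (length(phi)) {
    opt <- stats::optim(phi, function(ph) -eval_obj(ph),
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = o$outer_maxit,
                                       factr = 1e7))
    phi_hat <- opt$par
    outer_conv <- opt$convergence == 0
    loglik <- -opt$value
    # honest convergence: central-difference gradient of the Laplace
    # objective at the optimum (interior parameters only)
    at_bound <- phi_hat <= lower + 1e-6 | phi_hat >= upper - 1e-6
    gmax <- 0
    for (j in which(!at_bound)) {
      h <- 1e-4
      e <- phi_hat; e[j] <- e[j] + h; f1 <- eval_obj(e)
      e[j] <- phi_hat[j] - h; f0 <- eval_obj(e)
      gmax <- max(gmax, abs((f1 - f0) / (2 * h)))
    }
    grad_ok <- gmax < 0.05 * (1 + abs(loglik) / 1e3)
  } else {
    phi_hat <- numeric(0)
    loglik <- eval_obj(phi_hat)
    outer_conv <- TRUE
    grad_ok <- TRUE
    at_bound <- logical(0)
  }
  loglik <- eval_obj(phi_hat)  # leave env$mode at the optimum
  mode <- env$mode
  pr <- unpack(phi_hat)
  dvec <- if (q) pmax(pr$sigma[zb$block]^2, 1e-12) else numeric(0)

  sigma2_g <- if (n_factors) {
    s2 <- pr$sigma^2
    names(s2) <- factor_names
    if (est_sigma) {
      pinned <- phi_hat[(has_theta + has_pi) + seq_len(n_factors)] <=
        lo_sig + 1e-6
      if (any(pinned)) {
        warning("singular random-effect variance pinned at 0 for: ",
                paste(factor_names[pinned], collapse = ", "))
        s2[pinned] <- 0
      }
    }
    s2
  } else numeric(0)

  V <- .beta_vcov(X, Z, mode, dvec)
  se <- sqrt(pmax(diag(V), 0))
  beta <- mode$u[seq_len(p)]
  names(beta) <- names(se) <- colnames(X)
  zq <- stats::qnorm(0.975)
  ci95 <- cbind(lo = beta - zq * se, hi = beta + zq * se)

  # fixed (non-estimated) parameters are not counted in the AIC penalty
  k <- as.integer(p + has_theta + has_pi + (if (est_sigma) n_factors else 0L))
  aic <- 2 * k - 2 * loglik

  ranef <- NULL
  if (q) {
    bvec <- mode$u[p + seq_len(q)]
    ranef <- split(stats::setNames(bvec, zb$levels), zb$block)
    names(ranef) <- factor_names
  }

  structure(list(beta = beta, se = se, ci95 = ci95,
                 theta = if (!is.null(pr$theta)) pr$theta else NA_real_,
                 zi_prob = if (spec$family == "zinb2") pr$pi else 0,
                 sigma2_g = sigma2_g,
                 loglik = loglik, aic = aic, n_obs = length(yv),
                 n_fixed = p, n_params = k,
                 converged = outer_conv && grad_ok && mode$converged,
                 family = spec$family, spec = spec,
                 fitted_mu = mode$mu, eta = mode$eta, ranef = ranef,
                 y = yv, X = X),
            class = "count_model_fit")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat("Mixed count model (", x$family, "), n = ", x$n_obs,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  tab <- data.frame(estimate = round(x$beta, 4), se = round(x$se, 4),
                    lo95 = round(x$ci95[, "lo"], 4),
                    hi95 = round(x$ci95[, "hi"], 4))
  print(tab)
  if (is.finite(x$theta)) cat("theta (NB dispersion):", round(x$theta, 4), "\n")
  if (x$family == "zinb2")
    cat("zero-inflation probability:", round(x$zi_prob, 4), "\n")
  if (length(x$sigma2_g)) {
    cat("random-intercept variances:\n")
    print(round(x$sigma2_g, 4))
  }
  cat("logLik:", round(x$loglik, 2), "  AIC:", round(x$aic, 2), "\n")
  invisible(x)
}

#' Overdispersion diagnostic for a fitted count model
#'
#' Pearson chi-square ratio against the residual degrees of freedom: values
#' well above 1 indicate the conditional variance model is too tight (the
#' classic symptom that escalates a Poisson fit to NB2).
#'
#' @param fit A converged [fit_count_model()] result.
#' @param design,y Optional; defaults to the data stored in `fit`.
#' @return List with `dispersion_ratio`, `pearson_chi2`, `df`
#'   (`n_obs - n_fixed_params`), and `p_overdispersion` (upper-tail
#'   chi-square probability).
#' @export
overdispersion_check <- function(fit, design = NULL, y = NULL) {
  if (!fit$converged) stop("fit did not converge")
  yv <- if (is.null(y)) fit$y else y
  mu <- fit$fitted_mu
  m <- .fam_mean(mu, fit$family, fit$zi_prob)
  v <- .fam_var(mu, fit$family, fit$theta, fit$zi_prob)
  pearson <- (yv - m) / sqrt(v)
  df <- fit$n_obs - fit$n_fixed
  if (df <= 0) stop("non-positive residual degrees of freedom")
  chi2 <- sum(pearson^2)
  list(dispersion_ratio = chi2 / df, pearson_chi2 = chi2, df = df,
       p_overdispersion = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Zero-count calibration diagnostic
#'
#' Compares the observed number of zero counts with the number the fitted
#' model expects (`sum_i P(y_i = 0)`). A ratio well below 1 flags
#' zero-underfitting and motivates the zero-inflated model.
#'
#' @inheritParams overdispersion_check
#' @return List with `observed_zeros`, `predicted_zeros` and `zero_ratio`
#'   (predicted / observed; `NA` with a note when no zeros are observed).
#' @export
zero_check <- function(fit, design = NULL, y = NULL) {
  if (!fit$converged) stop("fit did not converge")
  yv <- if (is.null(y)) fit$y else y
  observed <- sum(yv == 0)
  predicted <- sum(.fam_pzero(fit$fitted_mu, fit$family, fit$theta,
                              fit$zi_prob))
  ratio <- if (observed == 0) NA_real_ else predicted / observed
  note <- if (observed == 0) "no observed zeros; ratio undefined" else NULL
  list(observed_zeros = observed, predicted_zeros = predicted,
       zero_ratio = ratio, note = note)
}

#' Variance inflation factors of a fixed-effects design
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column j on all other columns
#' (with intercept). Factor dummies are assessed per column. Perfectly
#' collinear columns are reported as `Inf` with a warning.
#'
#' @param design Numeric design (data.frame or matrix) of covariate columns,
#'   without intercept, or an `interest_design` object.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- if (inherits(design, "interest_design")) as.matrix(design$design)
       else as.matrix(design)
  if (ncol(X) < 2L) stop("need at least 2 covariate columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) stop("constant column in design: ",
                             paste(colnames(X)[sds < 1e-12], collapse = ", "))
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10) {
      warning("column ", colnames(X)[j], " is perfectly collinear; VIF = Inf")
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

#' Rank candidate fits of the same response by AIC
#'
#' @param fits List of [fit_count_model()] results on identical data.
#' @return data.frame ordered by ascending AIC with `family`, `aic`,
#'   `delta_aic`, `loglik`, `n_params`.
#' @export
compare_fits <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1L) stop("fits have mismatched n_obs")
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, character(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  rownames(tab) <- NULL
  tab
}

#' Wald significance flags at a conservative alpha
#'
#' Large-sample two-sided z-tests per coefficient. The analysis convention
#' is alpha = 0.01 rather than 0.05, reflecting the large sample size.
#'
#' @param fit A [fit_count_model()] (or residual-model) result with `beta`
#'   and `se`.
#' @param alpha Significance level (default 0.01).
#' @return Named logical vector.
#' @export
significance_flags <- function(fit, alpha = 0.01) {
  z <- abs(fit$beta / fit$se)
  flags <- z > stats::qnorm(1 - alpha / 2)
  flags[!is.finite(z)] <- FALSE
  flags
}

#' Forest-plot-ready coefficient table
#'
#' @param fit A fit with `beta`, `se`, `ci95`.
#' @param alpha Significance level for the `significant` column.
#' @return data.frame with `term`, `estimate`, `lo95`, `hi95`, `significant`.
#' @export
coef_table <- function(fit, alpha = 0.01) {
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             lo95 = unname(fit$ci95[, "lo"]),
             hi95 = unname(fit$ci95[, "hi"]),
             significant = unname(significance_flags(fit, alpha)),
             row.names = NULL)
}

#' Leave-one-out influence screen on the largest residuals
#'
#' Refits the model leaving out, one at a time, the `k` observations with
#' the largest absolute Pearson residuals and reports the maximum absolute
#' change in each coefficient. Observations are reported, never auto-removed
#' (in the original analysis two influential species were removed manually
#' after inspection).
#'
#' @param design,y,spec,opts As in [fit_count_model()].
#' @param k Number of high-residual observations to screen (default 10).
#' @return data.frame with the screened row index, its residual, and the
#'   largest coefficient shift caused by its removal.
#' @export
influence_screen <- function(design, y = NULL, spec = count_model_spec(),
                             k = 10L, opts = list()) {
  fit <- fit_count_model(design, y, spec, opts)
  m <- .fam_mean(fit$fitted_mu, fit$family, fit$zi_prob)
  v <- .fam_var(fit$fitted_mu, fit$family, fit$theta, fit$zi_prob)
  r <- (fit$y - m) / sqrt(v)
  worst <- order(abs(r), decreasing = TRUE)[seq_len(min(k, fit$n_obs))]
  d <- .resolve_design(design, y, spec)
  out <- lapply(worst, function(i) {
    keep <- setdiff(seq_len(fit$n_obs), i)
    Xdf <- if (inherits(design, "interest_design")) {
      dd <- design
      dd$design <- dd$design[keep, , drop = FALSE]
      dd$groups <- dd$groups[keep, , drop = FALSE]
      dd$y_papers <- dd$y_papers[keep]; dd$y_views <- dd$y_views[keep]
      dd
    } else as.data.frame(design)[keep, , drop = FALSE]
    refit <- fit_count_model(Xdf, if (is.null(y)) NULL else y[keep],
                             spec, opts)
    data.frame(row = i, pearson_resid = r[i],
               max_coef_shift = max(abs(refit$beta - fit$beta)))
  })
  do.call(rbind, out)
}
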