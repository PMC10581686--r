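# Scientific-vs-societal imbalance: a penalized-spline smooth of societal on
# scientific interest, per-species residuals from it, and a Gaussian mixed
# model of those residuals against traits.

#' Penalized cubic B-spline smoother (P-spline)
#'
#' Gaussian smooth of `y` on `x`: cubic B-spline basis on equally spaced
#' knots with a second-order difference penalty on the coefficients. The
#' penalty null space is the degree-1 polynomials, so as the smoothing
#' parameter grows the fit collapses to the ordinary least-squares line.
#' `lambda` is selected by generalized cross-validation on a log-spaced grid
#' (10^-6 to 10^6, 61 points) unless supplied.
#'
#' @param x,y Numeric vectors of equal length; `n` must exceed `basis_size`
#'   and `x` must not be constant.
#' @param basis_size Number of B-spline basis functions (default 10).
#' @param lambda Optional fixed smoothing parameter; skips GCV selection.
#' @param lambda_grid Grid searched by GCV (default `10^seq(-6, 6, by = 0.2)`).
#' @return Object of class `pspline_fit`: `coef` (spline coefficients),
#'   `lambda`, `edf` (effective degrees of freedom, trace of the smoother
#'   matrix), `gcv`, `fitted`, `residuals`, `knots`, `basis_size`, and the
#'   searched `gcv_path`.
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(200); y <- sin(2 * pi * x) + rnorm(200, 0, 0.2)
#' f <- fit_pspline(x, y)
#' f$edf
fit_pspline <- function(x, y, basis_size = 10,
                        lambda = NULL,
                        lambda_grid = 10^seq(-6, 6, by = 0.2)) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n <= basis_size) stop("need more points than basis functions")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  rng <- range(x)
  if (diff(rng) < 1e-12) stop("degenerate x: all values equal")
  K <- as.integer(basis_size)
  if (K < 4L) stop("basis_size must be at least 4 (cubic splines)")
  # equally spaced knots with cubic extension beyond each boundary;
  # the tiny margin keeps boundary x values inside the valid knot span
  n_seg <- K - 3L
  eps <- 1e-8 * diff(rng)
  lo <- rng[1] - eps; hi <- rng[2] + eps
  h <- (hi - lo) / n_seg
  knots <- lo + h * seq(-3L, n_seg + 3L)
  B <- splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
  D <- diff(diag(K), differences = 2L)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  fit_at <- function(lam) {
    M <- BtB + lam * P
    cf <- solve(M, Bty)
    fitted <- drop(B %*% cf)
    # trace of the hat matrix B (B'B + lam P)^-1 B' = tr((B'B+lamP)^-1 B'B)
    edf <- sum(diag(solve(M, BtB)))
    rss <- sum((y - fitted)^2)
    gcv <- n * rss / (n - edf)^2
    list(coef = drop(cf), fitted = fitted, edf = edf, gcv = gcv, lambda = lam)
  }
  if (is.null(lambda)) {
    path <- vapply(lambda_grid, function(l) fit_at(l)$gcv, numeric(1))
    best <- fit_at(lambda_grid[which.min(path)])
    gcv_path <- data.frame(lambda = lambda_grid, gcv = path)
  } else {
    stopifnot(lambda >= 0)
    best <- fit_at(lambda)
    gcv_path <- NULL
  }
  structure(list(coef = best$coef, lambda = best$lambda, edf = best$edf,
                 gcv = best$gcv, fitted = best$fitted,
                 residuals = y - best$fitted,
                 knots = knots, basis_size = K, x_range = rng,
                 gcv_path = gcv_path),
            class = "pspline_fit")
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat("P-spline smooth: basis size", x$basis_size,
      " lambda =", signif(x$lambda, 4),
      " edf =", round(x$edf, 2),
      " GCV =", signif(x$gcv, 4), "\n")
  invisible(x)
}

#' Predict from a fitted P-spline
#'
#' @param object A `pspline_fit`.
#' @param newdata Numeric vector of x values (clamped to the training range).
#' @param ... Unused.
#' @return Fitted values at `newdata`.
#' @export
predict.pspline_fit <- function(object, newdata, ...) {
  xr <- pmin(pmax(newdata, object$x_range[1]), object$x_range[2])
  B <- splines::splineDesign(object$knots, xr, ord = 4L, outer.ok = FALSE)
  drop(B %*% object$coef)
}

#' Per-species scientific-vs-societal imbalance scores
#'
#' Smooths societal interest on scientific interest (both on a
#' `log10(1 + count)` scale; natural-log available) with [fit_pspline()] and
#' returns the residual for each species. Positive residuals mark species
#' drawing more societal than scientific attention; negative residuals mark
#' species of predominantly scientific interest.
#'
#' @param profiles data.frame with `n_papers` and `n_views` columns (and
#'   optionally `species_id`), or an `interest_design`.
#' @param log_base `"log10"` (default) or `"ln"`.
#' @param basis_size Passed to [fit_pspline()].
#' @return data.frame with `species_id` and `residual`, ordered as the
#'   input; the smoother is attached as attribute `"smooth"`.
#' @export
imbalance_scores <- function(profiles, log_base = c("log10", "ln"),
                             basis_size = 10) {
  log_base <- match.arg(log_base)
  if (inherits(profiles, "interest_design")) {
    papers <- profiles$y_papers; views <- profiles$y_views
    sid <- profiles$species_id
  } else {
    pf <- as.data.frame(profiles)
    if (!all(c("n_papers", "n_views") %in% names(pf)))
      stop("profiles must carry n_papers and n_views")
    papers <- pf$n_papers; views <- pf$n_views
    sid <- if ("species_id" %in% names(pf)) pf$species_id
           else seq_len(nrow(pf))
  }
  if (length(papers) < 30L) stop("insufficient data for smooth (< 30 species)")
  tr <- if (log_base == "log10") function(v) log10(1 + v)
        else function(v) log1p(v)
  x <- tr(papers); y <- tr(views)
  sm <- fit_pspline(x, y, basis_size = basis_size)
  out <- data.frame(species_id = sid, residual = y - sm$fitted)
  attr(out, "smooth") <- sm
  out
}

#' Gaussian mixed model of imbalance residuals on traits
#'
#' REML linear mixed model (via lme4) of the per-species imbalance residual
#' on the same fixed-effect design and random-intercept structure as the
#' count models, reported through the same surface (`beta`, `se`, Wald
#' `ci95`, `sigma2_g`, `loglik`, `aic`) so the downstream forest-plot and
#' R-squared machinery applies unchanged.
#'
#' @param scores Output of [imbalance_scores()] (or any vector/data.frame
#'   with a `residual` column) in the same row order as `design`.
#' @param design An [prepare_design()] object, or data.frame of fixed-effect
#'   columns plus grouping columns.
#' @param random_terms Grouping-key columns; default [random_terms()] of the
#'   design's variant (or `"eq1"`).
#' @param fixed Fixed-effect columns; default [fixed_terms()] likewise.
#' @return Object of class `count_model_fit` with `family = "gaussian"`,
#'   plus `sigma2_resid` (residual variance).
#' @export
fit_residual_lmm <- function(scores, design, random_terms = NULL,
                             fixed = NULL) {
  r <- if (is.data.frame(scores)) scores$residual else as.numeric(scores)
  if (inherits(design, "interest_design")) {
    variant <- design$variant
    Xdf <- design$design
    groups <- design$groups
  } else {
    variant <- "eq1"
    Xdf <- as.data.frame(design)
    groups <- Xdf
  }
  if (is.null(fixed)) fixed <- intersect(fixed_terms(variant), names(Xdf))
  if (is.null(random_terms))
    random_terms <- intersect(biointerest::random_terms(variant),
                              names(groups))
  if (length(r) != nrow(Xdf)) stop("scores and design rows do not match")
  dat <- Xdf[, fixed, drop = FALSE]
  dat$.resid <- r
  for (g in random_terms) dat[[g]] <- factor(groups[[g]])
  fml <- stats::as.formula(paste(
    ".resid ~",
    if (length(fixed)) paste(fixed, collapse = " + ") else "1",
    if (length(random_terms))
      paste("+", paste(sprintf("(1 | %s)", random_terms), collapse = " + "))
    else ""))
  fit <- if (length(random_terms)) {
    lme4::lmer(fml, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                 lme4::.makeCC(action = "message", tol = 1e-4)))
  } else stats::lm(fml, data = dat)

  if (inherits(fit, "lm")) {
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    sigma2_g <- numeric(0)
    sigma2_resid <- summary(fit)$sigma^2
    ll <- as.numeric(stats::logLik(fit))
    fitted_mu <- stats::fitted(fit)
    conv <- TRUE
  } else {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- lme4::VarCorr(fit)
    sigma2_g <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
    if (any(sigma2_g < 1e-8)) {
      warning("singular random-effect variance pinned at 0 for: ",
              paste(names(sigma2_g)[sigma2_g < 1e-8], collapse = ", "))
      sigma2_g[sigma2_g < 1e-8] <- 0
    }
    sigma2_resid <- attr(vc, "sc")^2
    ll <- as.numeric(stats::logLik(fit))
    fitted_mu <- stats::fitted(fit)
    conv <- length(fit@optinfo$conv$lme4) == 0 ||
      is.null(fit@optinfo$conv$lme4$messages)
  }
  k <- length(beta) + length(sigma2_g) + 1L
  zq <- stats::qnorm(0.975)
  structure(list(beta = beta, se = se,
                 ci95 = cbind(lo = beta - zq * se, hi = beta + zq * se),
                 theta = NA_real_, zi_prob = 0,
                 sigma2_g = sigma2_g, sigma2_resid = sigma2_resid,
                 loglik = ll, aic = 2 * k - 2 * ll,
                 n_obs = length(r), n_fixed = length(beta), n_params = k,
                 converged = conv, family = "gaussian",
                 fitted_mu = fitted_mu,
                 X = cbind(`(Intercept)` = 1, as.matrix(dat[, fixed,
                                                            drop = FALSE])),
                 y = r, lme4_fit = if (!inherits(fit, "lm")) fit else NULL),
            class = "count_model_fit")
}
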