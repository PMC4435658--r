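#' Control parameters for the penalized IRLS fitter
#'
#' @param epsilon Relative penalized-deviance change declaring convergence.
#' @param maxit Maximum Fisher-scoring iterations.
#' @param lambda_grid Common smoothing-parameter grid searched before
#'   refinement (21 log-spaced points on `[1e-4, 1e6]` by default).
#' @param refine Refine per-term smoothing parameters after the grid search
#'   (Nelder-Mead on log-lambda; golden-section for a single smooth).
#' @param refine_maxit Maximum criterion evaluations during refinement.
#' @param sep_threshold,sep_frac Quasi-separation guard: if more than
#'   `sep_frac` of linear predictors exceed `sep_threshold` in absolute value
#'   (23 puts the fitted probability within 1e-10 of the boundary), a warning
#'   is issued and a small ridge is applied to the constant block.
#' @param ridge Relative ridge used when a penalized normal matrix is not
#'   positive definite (escalated until Cholesky succeeds).
#' @return A list of class `"vcm_control"`.
#' @export
vcm_control <- function(epsilon = 1e-8, maxit = 100L,
                        lambda_grid = 10^seq(-4, 6, length.out = 21),
                        refine = TRUE, refine_maxit = 100L,
                        sep_threshold = 23, sep_frac = 0.01, ridge = 1e-7) {
  structure(list(epsilon = epsilon, maxit = as.integer(maxit),
                 lambda_grid = lambda_grid, refine = refine,
                 refine_maxit = as.integer(refine_maxit),
                 sep_threshold = sep_threshold, sep_frac = sep_frac,
                 ridge = ridge),
            class = "vcm_control")
}

# Cholesky solve with escalating ridge for rank-deficient penalized systems
# (exact confounding between level smooths and a varying intercept leaves an
# unpenalized null direction; a proportional ridge resolves it).
chol_solve <- function(A, b = NULL, ridge0 = 1e-7) {
  d <- mean(diag(A))
  ridge <- 0
  L <- tryCatch(chol(A), error = function(e) NULL)
  while (is.null(L)) {
    ridge <- if (ridge == 0) ridge0 * d else ridge * 100
    if (ridge > 1e-1 * d)
      stop("rank-deficient penalized system: try larger smoothing parameters")
    L <- tryCatch(chol(A + diag(ridge, nrow(A))), error = function(e) NULL)
  }
  out <- list(L = L, ridge = ridge)
  if (!is.null(b)) out$x <- backsolve(L, forwardsolve(t(L), b))
  out
}

binomial_dev <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-16), 1 - 1e-16)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Core penalized IRLS / Fisher scoring. Minimizes
#   deviance + sum_j lambda_j || Delta_d gamma_j ||^2
# with step-halving, so the penalized deviance is non-increasing across
# iterations. Gaussian-identity fits converge in one step (weights fixed).
pirls_core <- function(design, lambda, control = vcm_control(),
                       beta_init = NULL, finalize_tol = TRUE) {
  y <- design$y; X <- design$X; n <- design$n
  family <- design$spec$family
  nsm <- length(design$smooth_idx)
  lambda <- rep_len(as.numeric(lambda), nsm)
  if (nsm && any(lambda < 0)) stop("smoothing parameters must be nonnegative")
  S <- penalty_matrix(design, lambda)
  sep_warned <- FALSE

  eta_of <- function(beta) as.numeric(X %*% expand_beta(beta, design))
  if (family == "gaussian") {
    M0 <- as.matrix(Matrix::crossprod(X))
    u0 <- as.numeric(Matrix::crossprod(X, y))
    M <- transform_M(M0, design)
    u <- transform_u(u0, design)
    cs <- chol_solve(M + S, u, control$ridge)
    beta <- cs$x
    eta <- eta_of(beta)
    dev <- sum((y - eta)^2)
    return(list(beta = beta, eta = eta, mu = eta, dev = dev, M = M,
                S = S, w = rep(1, n), iter = 1L, converged = TRUE,
                lambda = lambda, dev_trace = dev,
                pdev = dev + sum(beta * (S %*% beta)), ridge_used = cs$ridge))
  }

  beta <- if (is.null(beta_init)) numeric(design$pc) else beta_init
  if (is.null(beta_init)) {
    mu <- (y + 0.5) / 2
    eta <- log(mu / (1 - mu))
  } else {
    eta <- eta_of(beta)
    mu <- stats::plogis(eta)
  }
  dev <- binomial_dev(y, mu)
  # the heuristic starting mu is not attainable by any coefficient vector, so
  # the first Fisher step is accepted unconditionally (baseline +Inf); from
  # then on step-halving keeps the penalized deviance monotone
  pdev <- if (is.null(beta_init)) Inf else dev + sum(beta * (S %*% beta))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  M <- NULL
  ridge_used <- 0
  repeat {
    iter <- iter + 1L
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Xsw <- Matrix::Diagonal(design$n, sqrt(w)) %*% X
    M0 <- as.matrix(Matrix::crossprod(Xsw))
    u0 <- as.numeric(Matrix::crossprod(X, w * z))
    M <- transform_M(M0, design)
    u <- transform_u(u0, design)
    cs <- chol_solve(M + S, u, control$ridge)
    ridge_used <- max(ridge_used, cs$ridge)
    beta_new <- cs$x
    # step-halving keeps the penalized deviance monotone
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- eta_of(beta_try)
      mu_try <- stats::plogis(eta_try)
      pdev_try <- binomial_dev(y, mu_try) + sum(beta_try * (S %*% beta_try))
      if (is.finite(pdev_try) && pdev_try <= pdev + 1e-10) break
      step <- step / 2
      if (step < 2^-30) { beta_try <- beta; eta_try <- eta; mu_try <- mu
        pdev_try <- pdev; break }
    }
    beta <- beta_try; eta <- eta_try; mu <- mu_try
    dev <- binomial_dev(y, mu)
    trace <- c(trace, pdev_try)
    if (!sep_warned && mean(abs(eta) > control$sep_threshold) > control$sep_frac) {
      warning("quasi-separation detected (large linear predictors); ",
              "applying a small ridge to the constant block")
      sep_warned <- TRUE
      cb <- design$blocks[[1]]$cols_c
      S[cb, cb] <- S[cb, cb] + diag(1e-6 * max(1, mean(diag(M))), length(cb))
    }
    if (abs(pdev - pdev_try) < control$epsilon * (abs(pdev_try) + 0.1)) {
      converged <- TRUE; pdev <- pdev_try; break
    }
    pdev <- pdev_try
    if (iter >= control$maxit) break
  }
  if (!converged && finalize_tol) {
    cond <- simpleError(paste0("PIRLS failed to converge in ", control$maxit,
                               " iterations"))
    cond$dev_trace <- trace
    class(cond) <- c("vcm_convergence_error", class(cond))
    stop(cond)
  }
  list(beta = beta, eta = eta, mu = mu, dev = dev, M = M, S = S, w = w,
       iter = iter, converged = converged, lambda = lambda,
       dev_trace = trace, pdev = pdev, ridge_used = ridge_used)
}

# Turn a converged core into a full "vcm" fit: effective df per block,
# posterior covariance, likelihood summaries.
finalize_fit <- function(core, design, method = "fixed", keep_design = TRUE,
                         call = NULL) {
  n <- design$n
  family <- design$spec$family
  A <- core$M + core$S
  if (core$ridge_used > 0) A <- A + diag(core$ridge_used, nrow(A))
  L <- chol(A)
  Vb0 <- chol2inv(L)                    # (X'WX + P)^{-1}
  Fmat <- Vb0 %*% core$M                # influence matrix in coef space
  edf_diag <- diag(Fmat)
  edf_total <- sum(edf_diag)
  # test-oriented effective df, tr(2F - F F): the residual-df convention of
  # the reference GAM software, used as the df of nested likelihood-ratio
  # tests (it credits the fit for smoothing-induced shrinkage bias)
  edf2_diag <- 2 * edf_diag - rowSums(Fmat * t(Fmat))
  blocks <- design$blocks
  edf_by_block <- vapply(blocks, function(b) sum(edf_diag[b$cols_c]),
                         numeric(1))
  names(edf_by_block) <- vapply(blocks, `[[`, "", "name")
  edf2_by_block <- vapply(blocks, function(b) sum(edf2_diag[b$cols_c]),
                          numeric(1))
  names(edf2_by_block) <- names(edf_by_block)

  dev <- core$dev
  if (family == "binomial") {
    phi <- 1
    mu <- core$mu
    loglik <- sum(design$y * log(pmax(mu, 1e-16)) +
                  (1 - design$y) * log(pmax(1 - mu, 1e-16)))
    aic <- dev + 2 * edf_total
  } else {
    phi <- dev / max(n - edf_total, 1)
    loglik <- -n / 2 * (log(2 * pi * dev / n) + 1)
    aic <- -2 * loglik + 2 * (edf_total + 1)
  }
  Vb <- Vb0 * phi

  b_hat <- core$beta[blocks[[1]]$cols_c]
  names(b_hat) <- design$Z_names
  gamma <- lapply(design$smooth_idx, function(i) {
    as.numeric(design$Zn %*% core$beta[blocks[[i]]$cols_c])
  })
  names(gamma) <- vapply(design$smooth_idx,
                         function(i) blocks[[i]]$name, "")
  lambda <- core$lambda
  if (length(lambda)) names(lambda) <- names(gamma)

  fit <- structure(
    list(coefficients = b_hat, gamma = gamma, beta = core$beta,
         lambda = lambda, method = method,
         edf = list(total = edf_total, by_term = edf_by_block,
                    total2 = sum(edf2_diag), by_term2 = edf2_by_block),
         deviance = dev, loglik = loglik, aic = aic, phi = phi,
         gcv = n * dev / (n - edf_total)^2,
         Vb = Vb, fitted.values = core$mu,
         linear.predictors = core$eta,
         n_obs = n, converged = core$converged, n_iter = core$iter,
         dev_trace = core$dev_trace, ridge_used = core$ridge_used,
         family = family, spec = design$spec, call = call),
    class = "vcm")
  fit$design <- if (keep_design) design else
    design[c("Z_names", "const_map", "blocks", "smooth_idx", "Zn", "S0c",
             "levels", "spec", "pu", "pc")]
  fit
}

#' Fit a Gaussian varying coefficient model by penalized least squares
#'
#' Solves the P-spline penalized least-squares problem in closed form:
#' `gamma_hat = (R'R + P)^{-1} R'y` with `P = blockdiag(lambda_j D'D)` (zero
#' blocks for the unpenalized constant columns). The deviance is the residual
#' sum of squares and the scale is estimated as `RSS / (n - edf)`.
#'
#' @param design A [build_design()] result with a continuous response.
#' @param lambda Nonnegative smoothing parameter(s), recycled across smooth
#'   blocks.
#' @param control A [vcm_control()].
#' @return A fitted `"vcm"` object.
#' @export
fit_gaussian <- function(design, lambda, control = vcm_control()) {
  stopifnot(inherits(design, "vcm_design"))
  if (design$spec$family != "gaussian")
    stop("design was built for family '", design$spec$family, "'")
  core <- pirls_core(design, lambda, control)
  finalize_fit(core, design, method = "fixed")
}

#' Fit a generalized varying coefficient model by penalized IRLS
#'
#' Maximizes the penalized log-likelihood (the difference penalty subtracted
#' from the log-likelihood) by Fisher scoring: iteratively reweighted penalized
#' least squares with step-halving, iterated until the relative change in
#' penalized deviance falls below `control$epsilon`. With the Gaussian family
#' the weights are constant and the first iteration reproduces the
#' [fit_gaussian()] closed form exactly.
#'
#' @inheritParams fit_gaussian
#' @return A fitted `"vcm"` object.
#' @export
fit_pirls <- function(design, lambda, control = vcm_control()) {
  stopifnot(inherits(design, "vcm_design"))
  core <- pirls_core(design, lambda, control)
  finalize_fit(core, design, method = "fixed")
}

# log pseudo-determinant of the penalty (positive eigenvalues only)
penalty_logdet <- function(design, lambda) {
  ev <- eigen(design$S0c, symmetric = TRUE, only.values = TRUE)$values
  r <- design$spec$basis$n_basis - design$spec$penalty_order  # rank of S0c
  ldS0 <- sum(log(ev[seq_len(r)]))
  sum(vapply(lambda, function(l) r * log(l) + ldS0, numeric(1)))
}

# criterion value for a converged core at given lambda
selection_score <- function(core, design, method) {
  n <- design$n
  A <- core$M + core$S
  cs <- chol_solve(A, ridge0 = 1e-7)
  if (cs$ridge > 0) A <- A + diag(cs$ridge, nrow(A))
  L <- cs$L
  edf <- sum(diag(chol2inv(L) %*% core$M))
  if (method == "gcv")
    return(list(score = n * core$dev / (n - edf)^2, edf = edf))
  # approximate (Laplace) restricted likelihood on the working model
  phi <- if (design$spec$family == "gaussian")
    core$dev / max(n - edf, 1) else 1
  pen <- sum(core$beta * (core$S %*% core$beta))
  score <- (core$dev + pen) / phi + (n - edf) * log(phi) +
    2 * sum(log(diag(L))) - penalty_logdet(design, pmax(core$lambda, 1e-300))
  list(score = score, edf = edf)
}

#' Select smoothing parameters by GCV or approximate REML
#'
#' Searches a common log-spaced smoothing-parameter grid (each point a full
#' penalized IRLS fit, warm-started from the previous one) and then refines
#' per-term smoothing parameters by Nelder-Mead on the log scale (golden
#' section when there is a single smooth). The GCV criterion is
#' `n * deviance / (n - edf_total)^2`; REML uses a Laplace-approximate
#' restricted likelihood. The search is deterministic given the grid.
#'
#' @inheritParams fit_gaussian
#' @param method `"gcv"` (default) or `"reml"`.
#' @return A fitted `"vcm"` object carrying the selected `lambda` and the
#'   criterion value in `$selection`.
#' @export
select_lambda <- function(design, method = c("gcv", "reml"),
                          control = vcm_control()) {
  stopifnot(inherits(design, "vcm_design"))
  method <- match.arg(method)
  nsm <- length(design$smooth_idx)
  if (nsm == 0L) {
    core <- pirls_core(design, numeric(0), control)
    return(finalize_fit(core, design, method = "unpenalized"))
  }
  warm <- NULL
  eval_at <- function(lambda) {
    core <- tryCatch(
      pirls_core(design, lambda, control, beta_init = warm,
                 finalize_tol = FALSE),
      error = function(e) NULL)
    if (is.null(core)) return(list(score = Inf, core = NULL))
    warm <<- core$beta
    sc <- tryCatch(selection_score(core, design, method),
                   error = function(e) list(score = Inf))
    list(score = sc$score, core = core)
  }
  grid <- sort(control$lambda_grid)
  scores <- numeric(length(grid))
  for (i in seq_along(grid))
    scores[i] <- eval_at(rep(grid[i], nsm))$score
  if (!any(is.finite(scores)))
    stop("selection error: smoothing criterion non-finite over entire grid")
  best <- which.min(scores)
  lam <- rep(grid[best], nsm)
  if (isTRUE(control$refine)) {
    lo <- log(min(grid)) - 2; hi <- log(max(grid)) + 2
    obj <- function(lv) eval_at(exp(pmin(pmax(lv, lo), hi)))$score
    if (nsm == 1L) {
      op <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-3)
      if (op$objective <= scores[best]) lam <- exp(op$minimum)
    } else {
      op <- stats::optim(log(lam), obj, method = "Nelder-Mead",
                         control = list(maxit = control$refine_maxit,
                                        reltol = 1e-7))
      if (op$value <= scores[best])
        lam <- exp(pmin(pmax(op$par, lo), hi))
    }
  }
  core <- pirls_core(design, lam, control, beta_init = warm)
  fit <- finalize_fit(core, design, method = method)
  sc <- selection_score(core, design, method)
  fit$selection <- list(method = method, score = sc$score,
                        grid = grid, grid_scores = scores)
  fit
}

#' Fit a time-varying coefficient model
#'
#' The main fitting interface. The formula names the response and the
#' covariates, all of which receive constant coefficients (treatment-coded
#' against each factor's first level); the `varying` argument lists the
#' covariates whose effects are additionally allowed to change smoothly with
#' the `modifier` (calendar time), one centered P-spline per level. On the
#' logit scale the model is
#' \deqn{g(\mu) = b_0 + \sum_j b_j Z_j + a_0(t) + \sum_j X_j a_j(t),}
#' each `a(t)` a penalized B-spline expansion with a difference penalty on
#' adjacent coefficients. Smoothing parameters are selected by GCV (default)
#' or approximate REML unless `lambda` is supplied.
#'
#' @param formula `response ~ covariate1 + covariate2 + ...` (main effects of
#'   categorical covariates only).
#' @param data A data frame.
#' @param modifier Name of the time column.
#' @param varying Character vector of covariates with time-varying
#'   coefficients.
#' @param varying_intercept Logical; add a time-varying intercept `a_0(t)`.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param k Basis dimension per smooth (default 55).
#' @param degree B-spline degree (default 3).
#' @param penalty_order Difference-penalty order (default 2).
#' @param domain Modifier domain; defaults to the observed range.
#' @param lambda Optional fixed smoothing parameter(s); if `NULL` they are
#'   selected by `method`.
#' @param method Smoothing-parameter criterion, `"gcv"` or `"reml"`.
#' @param control A [vcm_control()].
#' @param keep_design Keep the full design (needed by [anova.vcm()] refits of
#'   stored designs and posterior band computations; default `TRUE`).
#' @return An object of class `"vcm"`.
#' @examples
#' cfg <- brfs_config(preset = "null", monthly_n = 60, n_waves = 12,
#'                    covariates = list(sex = c(Female = 0.5, Male = 0.5)))
#' d <- simulate_brfs(cfg, seed = 1)
#' f <- vcm(smoker ~ sex, d, modifier = "wave", varying = "sex", k = 6)
#' summary(f)
#' @export
vcm <- function(formula, data, modifier, varying = character(),
                varying_intercept = FALSE,
                family = c("binomial", "gaussian"),
                k = 55, degree = 3, penalty_order = 2, domain = NULL,
                lambda = NULL, method = c("gcv", "reml"),
                control = vcm_control(), keep_design = TRUE) {
  family <- match.arg(family)
  method <- match.arg(method)
  cl <- match.call()
  tf <- stats::terms(formula, data = data)
  response <- all.vars(formula)[1]
  covariates <- attr(tf, "term.labels")
  if (any(grepl("[:*()]", covariates)))
    stop("only main effects are supported in the model formula")
  used <- c(response, covariates, modifier)
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("schema error: column(s) missing from data: ",
         paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[used])
  if (!all(cc)) {
    message("listwise deletion: dropped ", sum(!cc),
            " of ", length(cc), " rows with missing values")
    data <- data[cc, , drop = FALSE]
  }
  tvals <- as.numeric(data[[modifier]])
  if (is.null(domain)) domain <- range(tvals)
  spec <- vcm_spec(response = response, covariates = covariates,
                   varying = varying, varying_intercept = varying_intercept,
                   modifier = modifier, family = family,
                   basis = basis_spec(k, degree, domain),
                   penalty_order = penalty_order)
  design <- build_design(data, spec)
  fit <- if (length(design$smooth_idx) == 0L) {
    core <- pirls_core(design, numeric(0), control)
    finalize_fit(core, design, method = "unpenalized")
  } else if (!is.null(lambda)) {
    core <- pirls_core(design, lambda, control)
    finalize_fit(core, design, method = "fixed")
  } else {
    select_lambda(design, method = method, control = control)
  }
  fit$call <- cl
  if (!keep_design)
    fit$design <- fit$design[c("Z_names", "const_map", "blocks", "smooth_idx",
                               "Zn", "S0c", "levels", "spec", "pu", "pc")]
  fit
}
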