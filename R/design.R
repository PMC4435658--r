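#' Varying coefficient model specification
#'
#' Describes a time-varying coefficient model before it touches data: the
#' binary (or continuous) response, the categorical covariates with constant
#' coefficients, the subset whose coefficients are allowed to vary smoothly
#' with time, an optional time-varying intercept, and the P-spline
#' configuration. Every varying covariate keeps its constant dummy
#' coefficients; on top of those, one centered smooth per level (reference
#' level included) captures the departure of that level's effect from its
#' period-average.
#'
#' @param response Name of the response column. For `family = "binomial"` it
#'   must be 0/1 numeric, logical, or a two-level factor (first level = 0).
#' @param covariates Character vector of covariate column names; each enters
#'   with constant coefficients (treatment coding, reference = first factor
#'   level).
#' @param varying Character vector, subset of `covariates`, whose coefficients
#'   additionally vary with time.
#' @param varying_intercept Logical; include a time-varying intercept smooth.
#' @param modifier Name of the time column (wave/month index).
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity link).
#' @param basis A [basis_spec()] for all smooth terms.
#' @param penalty_order Difference-penalty order (default 2).
#' @return An object of class `"vcm_spec"`.
#' @export
vcm_spec <- function(response, covariates, varying = character(),
                     varying_intercept = FALSE, modifier,
                     family = c("binomial", "gaussian"),
                     basis = basis_spec(), penalty_order = 2L) {
  family <- match.arg(family)
  stopifnot(inherits(basis, "basis_spec"))
  penalty_order <- as.integer(penalty_order)
  if (penalty_order < 1L || penalty_order >= basis$n_basis)
    stop("invalid penalty: order must be in [1, n_basis)")
  if (!all(varying %in% covariates))
    stop("`varying` must be a subset of `covariates`: ",
         paste(setdiff(varying, covariates), collapse = ", "))
  structure(
    list(response = response, covariates = covariates, varying = varying,
         varying_intercept = isTRUE(varying_intercept), modifier = modifier,
         family = family, basis = basis, penalty_order = penalty_order),
    class = "vcm_spec"
  )
}

# Coerce the response column to 0/1 (binomial) or numeric (gaussian).
response_vector <- function(y, family) {
  if (family == "gaussian") {
    if (!is.numeric(y)) stop("gaussian response must be numeric")
    return(as.numeric(y))
  }
  if (is.factor(y)) {
    if (nlevels(y) != 2L)
      stop("binomial response factor must have exactly 2 levels")
    return(as.numeric(y) - 1)
  }
  if (is.logical(y)) return(as.numeric(y))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("binomial response must be coded 0/1")
  y
}

#' Assemble design matrices for a varying coefficient model
#'
#' Builds the constant-effects columns (intercept plus treatment-coded
#' dummies), and for every varying term one B-spline block per level,
#' row-masked by that level's indicator. Each smooth block is centered — the
#' smooth, summed over the observed modifier values, is constrained to zero
#' via an absorbed linear constraint — so the paired constant coefficient
#' stays identifiable and the smooth reads as a departure from the
#' period-average effect. Centered blocks have `n_basis - 1` columns.
#'
#' @param data A data frame containing all columns named in `spec`.
#' @param spec A [vcm_spec()].
#' @return An object of class `"vcm_design"`; a list holding the response,
#'   the sparse (uncentered) design matrix, the per-block centering transform,
#'   penalty building blocks and a column index mapping columns to
#'   (term, level).
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "vcm_spec"))
  need <- c(spec$response, spec$covariates, spec$modifier)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("schema error: column(s) missing from data: ",
         paste(miss, collapse = ", "))
  n <- nrow(data)
  if (anyNA(data[need]))
    stop("data contain missing values in model columns; drop them first ",
         "(vcm() and read_brfs() apply listwise deletion)")
  y <- response_vector(data[[spec$response]], spec$family)
  tval <- as.numeric(data[[spec$modifier]])

  # constant-effects block: intercept + treatment dummies
  fac <- lapply(spec$covariates, function(v) {
    x <- data[[v]]
    if (!is.factor(x)) x <- factor(x)
    x <- droplevels(x)
    if (nlevels(x) < 2L)
      stop("degenerate design: covariate '", v,
           "' is constant in the data supplied")
    x
  })
  names(fac) <- spec$covariates
  Zparts <- list(`(Intercept)` = matrix(1, n, 1))
  const_names <- "(Intercept)"
  const_map <- data.frame(variable = "(Intercept)", level = "",
                          stringsAsFactors = FALSE)
  for (v in spec$covariates) {
    x <- fac[[v]]
    lev <- levels(x)
    d <- stats::model.matrix(~ x)[, -1, drop = FALSE]
    colnames(d) <- paste0(v, ":", lev[-1])
    Zparts[[v]] <- d
    const_names <- c(const_names, colnames(d))
    const_map <- rbind(const_map,
                       data.frame(variable = v, level = lev[-1],
                                  stringsAsFactors = FALSE))
  }
  Z <- do.call(cbind, Zparts)
  colnames(Z) <- const_names

  # smooth blocks: basis rows masked by level indicators
  B <- bspline_basis(tval, spec$basis, sparse = TRUE)
  k <- spec$basis$n_basis
  csum <- Matrix::colSums(B)
  qrc <- qr(matrix(csum, ncol = 1))
  Zn <- qr.Q(qrc, complete = TRUE)[, -1, drop = FALSE]  # k x (k-1) null basis
  Dd <- difference_matrix(k, spec$penalty_order)
  S0 <- crossprod(Dd)                 # uncentered penalty, k x k
  S0c <- crossprod(Zn, S0 %*% Zn)     # penalty in constrained coordinates

  blocks <- list(list(name = "(constant)", type = "const",
                      variable = NA_character_, level = NA_character_))
  Xparts <- list(methods::as(Matrix::Matrix(Z, sparse = TRUE), "CsparseMatrix"))
  if (spec$varying_intercept)
    blocks[[length(blocks) + 1L]] <- list(name = "s(t)", type = "smooth",
                                          variable = ".intercept", level = "")
  if (spec$varying_intercept) Xparts[[length(Xparts) + 1L]] <- B
  for (v in spec$varying) {
    x <- fac[[v]]
    for (lev in levels(x)) {
      ind <- as.numeric(x == lev)
      Xparts[[length(Xparts) + 1L]] <- Matrix::Diagonal(n, ind) %*% B
      blocks[[length(blocks) + 1L]] <-
        list(name = paste0("s(t):", v, ":", lev), type = "smooth",
             variable = v, level = lev)
    }
  }
  X <- do.call(cbind, Xparts)

  # column bookkeeping (uncentered and centered coordinate systems)
  pu_sizes <- vapply(blocks, function(b) if (b$type == "const") ncol(Z) else k,
                     integer(1))
  pc_sizes <- vapply(blocks, function(b) if (b$type == "const") ncol(Z)
                     else k - 1L, integer(1))
  end_u <- cumsum(pu_sizes); start_u <- c(1L, utils::head(end_u, -1L) + 1L)
  end_c <- cumsum(pc_sizes); start_c <- c(1L, utils::head(end_c, -1L) + 1L)
  for (i in seq_along(blocks)) {
    blocks[[i]]$cols_u <- seq.int(start_u[i], end_u[i])
    blocks[[i]]$cols_c <- seq.int(start_c[i], end_c[i])
  }
  smooth_idx <- which(vapply(blocks, function(b) b$type == "smooth",
                             logical(1)))

  structure(
    list(y = y, t = tval, n = n, X = X, Z_names = const_names,
         const_map = const_map, blocks = blocks, smooth_idx = smooth_idx,
         Zn = Zn, S0c = S0c, levels = lapply(fac, levels), spec = spec,
         pu = sum(pu_sizes), pc = sum(pc_sizes)),
    class = "vcm_design"
  )
}

#' @export
print.vcm_design <- function(x, ...) {
  cat(sprintf(
    "VCM design: n = %d, %d constant columns, %d smooth block(s) of %d basis functions\n",
    x$n, length(x$Z_names), length(x$smooth_idx), x$spec$basis$n_basis))
  invisible(x)
}

# T' M0 T and T' u computed blockwise (T = blockdiag(I, Zn, Zn, ...)).
transform_M <- function(M0, design) {
  M <- matrix(0, design$pc, design$pc)
  bl <- design$blocks
  Zn <- design$Zn
  for (i in seq_along(bl)) {
    for (j in seq_along(bl)) {
      sub <- M0[bl[[i]]$cols_u, bl[[j]]$cols_u, drop = FALSE]
      if (bl[[i]]$type == "smooth") sub <- crossprod(Zn, sub)
      if (bl[[j]]$type == "smooth") sub <- sub %*% Zn
      M[bl[[i]]$cols_c, bl[[j]]$cols_c] <- sub
    }
  }
  M
}

transform_u <- function(u0, design) {
  u <- numeric(design$pc)
  for (b in design$blocks) {
    sub <- u0[b$cols_u]
    if (b$type == "smooth") sub <- as.numeric(crossprod(design$Zn, sub))
    u[b$cols_c] <- sub
  }
  u
}

# expand constrained coefficients to the uncentered basis coordinates
expand_beta <- function(beta, design) {
  g <- numeric(design$pu)
  for (b in design$blocks) {
    sub <- beta[b$cols_c]
    if (b$type == "smooth") sub <- as.numeric(design$Zn %*% sub)
    g[b$cols_u] <- sub
  }
  g
}

# block-diagonal penalty in constrained coordinates for smoothing parameters
# lambda (one per smooth block, in design$smooth_idx order)
penalty_matrix <- function(design, lambda) {
  S <- matrix(0, design$pc, design$pc)
  for (s in seq_along(design$smooth_idx)) {
    b <- design$blocks[[design$smooth_idx[s]]]
    S[b$cols_c, b$cols_c] <- lambda[s] * design$S0c
  }
  S
}
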