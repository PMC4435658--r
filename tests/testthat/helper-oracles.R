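# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Cox-de Boor recursion, written directly from the recurrence:
# B_{i,0}(x) = 1 on [k_i, k_{i+1}), closing the last interval;
# B_{i,d} = (x - k_i)/(k_{i+d} - k_i) B_{i,d-1}
#         + (k_{i+d+1} - x)/(k_{i+d+1} - k_{i+1}) B_{i+1,d-1}.
cdb_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  right <- knots[length(knots) - degree]  # domain right end
  one <- function(i, d, x) {
    if (d == 0) {
      upper <- if (abs(knots[i + 1] - right) < 1e-12)
        x <= knots[i + 1] + 1e-12 else x < knots[i + 1]
      # only intervals strictly left of the domain end can be active
      return(as.numeric(x >= knots[i] & upper & knots[i] < right - 1e-12))
    }
    a <- 0; b <- 0
    den1 <- knots[i + d] - knots[i]
    den2 <- knots[i + d + 1] - knots[i + 1]
    if (den1 > 0) a <- (x - knots[i]) / den1 * one(i, d - 1, x)
    if (den2 > 0) b <- (knots[i + d + 1] - x) / den2 * one(i + 1, d - 1, x)
    a + b
  }
  vapply(seq_len(nb), function(i) one(i, degree, x), numeric(length(x)))
}

# dense centered design matrix and block penalty, built from the design
# object's raw ingredients (used to pose the optimization oracles)
dense_design <- function(design) {
  X <- as.matrix(design$X)
  p <- design$pc
  Xc <- matrix(0, design$n, p)
  for (b in design$blocks) {
    sub <- X[, b$cols_u, drop = FALSE]
    if (b$type == "smooth") sub <- sub %*% design$Zn
    Xc[, b$cols_c] <- sub
  }
  Xc
}

dense_penalty <- function(design, lambda) {
  S <- matrix(0, design$pc, design$pc)
  lambda <- rep_len(lambda, length(design$smooth_idx))
  for (s in seq_along(design$smooth_idx)) {
    b <- design$blocks[[design$smooth_idx[s]]]
    S[b$cols_c, b$cols_c] <- lambda[s] * design$S0c
  }
  S
}

# penalized deviance -2 l(beta) + beta' S beta for Bernoulli-logit data
pen_dev_logistic <- function(beta, Xc, y, S) {
  eta <- as.numeric(Xc %*% beta)
  -2 * sum(y * eta - log1p(exp(eta))) + sum(beta * (S %*% beta))
}

# generic numerical maximizer of the penalized log-likelihood (BFGS with
# analytic gradient), independent of the PIRLS path
optim_logistic <- function(Xc, y, S, start = NULL) {
  p <- ncol(Xc)
  if (is.null(start)) start <- numeric(p)
  fn <- function(beta) pen_dev_logistic(beta, Xc, y, S)
  gr <- function(beta) {
    mu <- stats::plogis(as.numeric(Xc %*% beta))
    -2 * as.numeric(crossprod(Xc, y - mu)) + 2 * as.numeric(S %*% beta)
  }
  stats::optim(start, fn, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
}

# penalized least squares via an augmented ordinary regression: stacking
# sqrt-penalty pseudo-observations and calling lm.fit is an independent route
# to the same minimizer
augmented_ls <- function(Xc, y, S) {
  eg <- eigen(S, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  L <- if (any(pos))
    t(eg$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(eg$values[pos]), sum(pos)))
  else matrix(0, 0, ncol(Xc))
  fit <- stats::lm.fit(rbind(Xc, L), c(y, rep(0, nrow(L))))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  co
}
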