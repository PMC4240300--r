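# Independent oracle for the marginal log-likelihood of the crossed
# random-intercepts logistic model: adaptive Gauss-Hermite quadrature over
# the joint random-effects vector (participants + candidate letters).
# Used only to validate the Laplace fits; never part of the fitting path.

# Gauss-Hermite nodes/weights (physicists', weight exp(-x^2)) via
# Golub-Welsch on the Jacobi matrix.
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Joint penalized log-likelihood h(w), its mode and Hessian.
.glmm_parts <- function(y, X, beta, Z, dvar) {
  eta0 <- drop(X %*% beta)
  list(
    h = function(w) {
      eta <- eta0 + drop(Z %*% w)
      sum(y * eta - log1p(exp(eta))) - sum(w^2 / dvar) / 2
    },
    grad = function(w) {
      eta <- eta0 + drop(Z %*% w)
      drop(crossprod(Z, y - plogis(eta))) - w / dvar
    },
    hess = function(w) {
      eta <- eta0 + drop(Z %*% w)
      mu <- plogis(eta)
      -(crossprod(Z * (mu * (1 - mu)), Z) + diag(1 / dvar,
                                                 length(dvar)))
    },
    eta0 = eta0
  )
}

# Marginal log-likelihood by adaptive product Gauss-Hermite quadrature.
# y: 0/1; X: fixed design; beta: fixed effects; participant, letter:
# factors; var_p, var_l: random-intercept variances; n_nodes per dim.
agq_loglik <- function(y, X, beta, participant, letter, var_p, var_l,
                       n_nodes = 15) {
  participant <- factor(participant); letter <- factor(letter)
  Zp <- stats::model.matrix(~ 0 + participant)
  Zl <- stats::model.matrix(~ 0 + letter)
  Z <- cbind(Zp, Zl)
  d <- ncol(Z)
  dvar <- c(rep(max(var_p, 1e-12), ncol(Zp)),
            rep(max(var_l, 1e-12), ncol(Zl)))
  parts <- .glmm_parts(y, X, beta, Z, dvar)
  # Newton to the joint mode
  w <- rep(0, d)
  for (it in 1:100) {
    step <- solve(parts$hess(w), parts$grad(w))
    w <- w - step
    if (max(abs(step)) < 1e-10) break
  }
  H <- -parts$hess(w)              # positive definite precision at mode
  L <- chol(H)                     # H = L'L, upper triangular chol
  rule <- gh_rule(n_nodes)
  # grid of node indices
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(n_nodes)), d)))
  Znodes <- matrix(rule$nodes[grid], nrow(grid), d)
  logw <- matrix(log(rule$weights)[grid], nrow(grid), d)
  # w_k = mode + sqrt(2) * solve(L) %*% z_k
  W <- t(w + sqrt(2) * backsolve(L, t(Znodes)))
  hvals <- apply(W, 1, parts$h)
  # integral of exp(h) over prior-normalized density:
  # log integral = log sum w_k exp(h(w_k) + |z_k|^2) + d/2 log 2 - log det L
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  log_int <- lse(rowSums(logw) + hvals + rowSums(Znodes^2)) +
    (d / 2) * log(2) - sum(log(diag(L)))
  # subtract the RE prior normalizing constant
  log_int - (d / 2) * log(2 * pi) - sum(log(dvar)) / 2
}
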