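`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles and small fixture builders. These deliberately avoid
# the code paths (and, where possible, the libraries) they are used to check.

# Hand-written Cox partial log-likelihood with Breslow tie handling.
oracle_cox_loglik <- function(beta, X, time, event) {
  lp <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(event == 1 & time == t)
    at_risk <- which(time >= t)
    ll <- ll + sum(lp[d]) - length(d) * log(sum(exp(lp[at_risk])))
  }
  ll
}

# Brute-force maximiser of the partial likelihood via a generic optimiser.
oracle_cox_fit <- function(X, time, event) {
  optim(rep(0, ncol(X)), function(b) -oracle_cox_loglik(b, X, time, event),
        method = "BFGS", control = list(reltol = 1e-14, maxit = 2000))
}

# Dense-matrix REML criterion for a random-intercept+slope mixed model,
# maximised by a generic optimiser over (log sds, z-corr, log resid sd).
oracle_reml <- function(y, X, id, tt) {
  n <- length(y)
  ids <- unique(id)
  loglik <- function(par) {
    sd0 <- exp(par[1]); sd1 <- exp(par[2]); rho <- tanh(par[3]); s <- exp(par[4])
    G <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
    V <- diag(s^2, n)
    for (i in ids) {
      j <- which(id == i)
      Z <- cbind(1, tt[j])
      V[j, j] <- V[j, j] + Z %*% G %*% t(Z)
    }
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
              t(r) %*% Vi %*% r + (n - ncol(X)) * log(2 * pi))
  }
  opt <- optim(c(0, -1, 0, 0), function(p) -loglik(p), method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  sd0 <- exp(opt$par[1]); sd1 <- exp(opt$par[2]); rho <- tanh(opt$par[3])
  s <- exp(opt$par[4])
  G <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
  V <- diag(s^2, n)
  for (i in ids) {
    j <- which(id == i)
    Z <- cbind(1, tt[j])
    V[j, j] <- V[j, j] + Z %*% G %*% t(Z)
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(logLik = -opt$value, beta = drop(beta), G = G, sigma2 = s^2)
}

# Exhaustive Harrell concordance: loop over all pairs.
oracle_concordance <- function(risk, time, event) {
  n <- length(risk)
  num <- den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # usable pair: the one with the shorter follow-up had the event
    ti <- time[i]; tj <- time[j]
    if (ti == tj && event[i] == 1 && event[j] == 1) next  # tied event times
    if (ti < tj && event[i] == 1) { e <- i; l <- j }
    else if (tj < ti && event[j] == 1) { e <- j; l <- i }
    else if (ti == tj && xor(event[i] == 1, event[j] == 1)) {
      e <- if (event[i] == 1) i else j; l <- if (event[i] == 1) j else i
    } else next
    den <- den + 1
    if (risk[e] > risk[l]) num <- num + 1
    else if (risk[e] == risk[l]) num <- num + 0.5
  }
  num / den
}

# Exhaustive Mann-Whitney AUC for a binary outcome.
oracle_auc <- function(risk, outcome) {
  pos <- risk[outcome == 1]; neg <- risk[outcome == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Minimal prepared-cohort-like object for longitudinal fits.
toy_prepared <- function(patients, measurements) {
  structure(list(patients = patients, measurements = measurements,
                 flow = list()), class = "fbc_prepared")
}

# Quick default simulate+prepare at recovery scale.
sim_prep <- function(n, sex, seed, multiplier = 10) {
  co <- simulate_cohort(simulation_config(n, sex, seed = seed,
                                          event_rate_multiplier = multiplier))
  list(cohort = co, prep = prepare_cohort(co$patients, co$measurements))
}
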