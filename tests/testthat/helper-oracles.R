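## Independent oracles: naive loop implementations of the drift equations
## and a plain-R RK4 reference for the full cascade. These deliberately
## avoid the package's vectorised/compiled code paths.

oracleSigmoid <- function(x, alpha) 1 / (1 + exp(-alpha * x)) - 0.5

oracleBilinear <- function(z, u, A, B, C) {
  l <- length(z)
  out <- numeric(l)
  for (i in seq_len(l)) {
    acc <- 0
    for (j in seq_len(l)) {
      w <- A[i, j]
      for (k in seq_along(u)) w <- w + u[k] * B[[k]][i, j]
      acc <- acc + w * z[j]
    }
    for (k in seq_along(u)) acc <- acc + C[i, k] * u[k]
    out[i] <- acc
  }
  out
}

oracleWc <- function(z, u, A, B, C, alpha) {
  x <- oracleBilinear(z, u, A, B, C)
  out <- numeric(length(z))
  for (i in seq_along(z))
    out[i] <- -z[i] + oracleSigmoid(x[i], alpha[i])
  out
}

oracleTwoBilinear <- function(zE, zI, u, wEE, bEE, wSE, wSI, wIE, wEI, bIE, C) {
  l <- length(zE)
  dE <- dI <- numeric(l)
  for (i in seq_len(l)) {
    ext <- 0
    for (j in seq_len(l)) {
      if (i == j) next
      b <- 0
      for (k in seq_along(u)) b <- b + u[k] * bEE[[k]][i, j]
      ext <- ext + wEE[i, j] * exp(b) * zE[j]
    }
    e <- 0
    for (k in seq_along(u)) e <- e + u[k] * bIE[[k]][i]
    cu <- 0
    for (k in seq_along(u)) cu <- cu + C[i, k] * u[k]
    dE[i] <- ext - wSE[i] * zE[i] - wIE[i] * exp(e) * zI[i] + cu
    dI[i] <- wEI[i] * zE[i] - wSI[i] * zI[i]
  }
  list(E = dE, I = dI)
}

oracleTwoWc <- function(zE, zI, u, wEE, bEE, wSE, wSI, wIE, wEI, bIE, C,
                        alphaE, alphaI) {
  l <- length(zE)
  dE <- dI <- numeric(l)
  for (i in seq_len(l)) {
    ext <- 0
    for (j in seq_len(l)) {
      if (i == j) next
      b <- 0
      for (k in seq_along(u)) b <- b + u[k] * bEE[[k]][i, j]
      ext <- ext + wEE[i, j] * exp(b) * zE[j]
    }
    e <- 0
    for (k in seq_along(u)) e <- e + u[k] * bIE[[k]][i]
    cu <- 0
    for (k in seq_along(u)) cu <- cu + C[i, k] * u[k]
    xE <- ext + wSE[i] * zE[i] - wIE[i] * exp(e) * zI[i] + cu
    xI <- wEI[i] * zE[i] - wSI[i] * zI[i]
    dE[i] <- -zE[i] + oracleSigmoid(xE, alphaE[i])
    dI[i] <- -zI[i] + oracleSigmoid(xI, alphaI[i])
  }
  list(E = dE, I = dI)
}

## Reference RK4 for the full single-state cascade, in plain R, built on
## the package's exported drift functions. Hemodynamics use the same log
## coordinates as the compiled path so the discretisations agree exactly.
oracleIntegrate <- function(spec, np, hp, inputs, TR, duration = NULL) {
  l <- nRegions(spec)
  dt <- inputs@dt
  if (is.null(duration)) duration <- ncol(inputs@u) * dt
  stepsPerTR <- round(TR / dt)
  nSamp <- floor(duration / TR + 1e-9)
  nSteps <- nSamp * stepsPerTR
  kap <- rep_len(hp@kappa, l); gam <- rep_len(hp@gamma, l)
  tau <- rep_len(hp@tauH, l)
  state <- c(rep(0, l), rep(0, l), rep(0, 3 * l))  # z, s, lf, lv, lq
  drift <- function(st, u) {
    z <- st[1:l]; s <- st[l + 1:l]
    lf <- st[2 * l + 1:l]; lv <- st[3 * l + 1:l]; lq <- st[4 * l + 1:l]
    dz <- if (spec@variant == "bilinear") bilinearDrift(z, u, np)
          else wcDrift(z, u, np)
    f <- exp(lf); v <- exp(lv); q <- exp(lq)
    dnat <- matrix(0, l, 4)
    for (i in seq_len(l))
      dnat[i, ] <- balloonDrift(c(s[i], f[i], v[i], q[i]), z[i],
                                hemodynamicParams(kappa = kap[i], gamma = gam[i],
                                                  tauH = tau[i], alphaG = hp@alphaG,
                                                  rho = hp@rho, V0 = hp@V0,
                                                  k1 = hp@k1, k2 = hp@k2, k3 = hp@k3))
    c(dz, dnat[, 1], dnat[, 2] / f, dnat[, 3] / v, dnat[, 4] / q)
  }
  y <- matrix(0, nSamp, l)
  sIdx <- 1
  for (step in seq_len(nSteps)) {
    u <- inputs@u[, min(step, ncol(inputs@u))]
    k1 <- drift(state, u)
    k2 <- drift(state + 0.5 * dt * k1, u)
    k3 <- drift(state + 0.5 * dt * k2, u)
    k4 <- drift(state + dt * k3, u)
    state <- state + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (step %% stepsPerTR == 0) {
      for (i in seq_len(l)) {
        v <- exp(state[3 * l + i]); q <- exp(state[4 * l + i])
        y[sIdx, i] <- boldObserve(c(v, q), hp)
      }
      sIdx <- sIdx + 1
    }
  }
  y
}

## random single-state instance for drift-oracle checks
randomSingleInstance <- function(l = 3, m = 2) {
  A <- matrix(rnorm(l * l, sd = 0.5), l, l)
  B <- replicate(m, matrix(rnorm(l * l, sd = 0.3), l, l), simplify = FALSE)
  C <- matrix(rnorm(l * m, sd = 0.5), l, m)
  alpha <- runif(l, 0.5, 8)
  list(p = neuronalParams(A, B, C, alpha = alpha),
       A = A, B = B, C = C, alpha = alpha,
       z = rnorm(l), u = rnorm(m))
}

randomTwoStateInstance <- function(l = 3, m = 2) {
  wEE <- matrix(runif(l * l, 0, 1), l, l)
  bEE <- replicate(m, matrix(rnorm(l * l, sd = 0.3), l, l), simplify = FALSE)
  bIE <- replicate(m, rnorm(l, sd = 0.3), simplify = FALSE)
  wSE <- runif(l, 0.1, 1); wSI <- runif(l, 0.1, 1)
  wIE <- runif(l, 0.1, 1); wEI <- runif(l, 0.1, 1)
  C <- matrix(rnorm(l * m, sd = 0.5), l, m)
  aE <- runif(l, 1, 8); aI <- runif(l, 1, 8)
  list(p = twoStateParams(wEE, wSE, wSI, wIE, wEI, C, bEE = bEE, bIE = bIE,
                          alphaE = aE, alphaI = aI),
       wEE = wEE, bEE = bEE, wSE = wSE, wSI = wSI, wIE = wIE, wEI = wEI,
       bIE = bIE, C = C, alphaE = aE, alphaI = aI,
       zE = rnorm(l), zI = rnorm(l), u = rnorm(m))
}
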