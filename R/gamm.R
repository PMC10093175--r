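# Persistence-velocity mixed model: Gaussian response, identity link;
# linear fixed effects, a penalized thin-plate-style radial smoother of
# (latitude, longitude), per-animal random intercepts (as a ridge-penalized
# block) and ARMA(p, q)-correlated daily residuals within animal. The
# whole model is fit as penalized generalized least squares: given the
# residual correlation, smoothing/ridge parameters are chosen by GCV on
# the whitened problem; given the fit, pooled ARMA coefficients are
# estimated by Gaussian maximum likelihood across the per-animal residual
# series; the two steps alternate to convergence. Backward elimination of
# fixed effects by AIC mirrors the standard mixed-model selection recipe.

#' Specify the persistence GAMM
#'
#' @param fixed candidate fixed effects: subset of
#'   `c("cur_speed_kmday", "sst", "sargassum", "weight_kg", "period")`
#'   (columns of the persistence series; period enters as a two-level
#'   indicator with July as the reference when both periods are present).
#' @param k spatial basis dimension (number of radial knots, >= 3 plus
#'   the 3-column polynomial null space absorbed into the fixed part).
#' @param random_intercept per-animal random intercepts on/off.
#' @param arma_p,arma_q residual ARMA orders (0 <= p, q <= 6).
#' @param method smoothing-parameter criterion label ("GCV").
#' @return a `gamm_spec` list.
#' @export
gamm_spec <- function(fixed = c("cur_speed_kmday", "sst", "sargassum",
                                "weight_kg", "period"),
                      k = 30, random_intercept = TRUE,
                      arma_p = 0, arma_q = 0, method = "GCV") {
  if (k < 3) stop("k must be >= 3")
  if (arma_p > 6 || arma_q > 6 || arma_p < 0 || arma_q < 0)
    stop("ARMA orders must be in 0..6")
  structure(list(fixed = fixed, k = k,
                 random_intercept = random_intercept,
                 arma_p = arma_p, arma_q = arma_q, method = method),
            class = "gamm_spec")
}

## deterministic farthest-point sampling of k knots from unique rows
.fps_knots <- function(xy, k) {
  ux <- unique(xy)
  n <- nrow(ux)
  if (n <= k) return(ux)
  sel <- integer(k)
  sel[1] <- 1L
  d2 <- (ux[, 1] - ux[1, 1])^2 + (ux[, 2] - ux[1, 2])^2
  for (i in 2:k) {
    sel[i] <- which.max(d2)
    d2 <- pmin(d2, (ux[, 1] - ux[sel[i], 1])^2 +
                 (ux[, 2] - ux[sel[i], 2])^2)
  }
  ux[sel, , drop = FALSE]
}

.tps_eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)

## radial basis matrix between points (rows) and knots
.tps_E <- function(xy, knots) {
  r <- sqrt(outer(xy[, 1], knots[, 1], "-")^2 +
              outer(xy[, 2], knots[, 2], "-")^2)
  .tps_eta(r)
}

#' Build design matrices for the persistence GAMM
#'
#' Complete-case rows only (dropped count reported). Linear columns for
#' the retained fixed effects; a thin-plate-style radial basis for
#' (lat, lon) on `k` farthest-point knots with the linear null space kept
#' unpenalized; a per-animal indicator block for the random intercepts.
#' If the data hold a single period while `period` is in the spec, the
#' column is dropped with a note.
#'
#' @param series a `persistence_series` data.frame (response column
#'   `persistence`, coordinates `lat`/`lon`, animal `id`).
#' @param spec a [gamm_spec()].
#' @return list: `y`, `X` (unpenalized: intercept, linear effects, smooth
#'   null space), `B` (penalized radial columns), `S` (penalty matrix for
#'   `B`), `Zb` (animal indicators or NULL), `animal`, `day`, `notes`,
#'   `dropped`, plus the knot/scaling info needed for prediction.
#' @export
build_design <- function(series, spec) {
  cand <- spec$fixed
  num_cand <- setdiff(cand, "period")
  need <- c("persistence", "lat", "lon", "id",
            intersect(c(num_cand, if ("period" %in% cand) "period"),
                      names(series)))
  miss_cov <- setdiff(cand, c(names(series), "period"))
  if (length(miss_cov))
    stop("series lacks candidate covariate(s): ",
         paste(miss_cov, collapse = ", "))
  cc <- stats::complete.cases(series[, need])
  dat <- series[cc, , drop = FALSE]
  notes <- character()
  dropped <- sum(!cc)
  if (nrow(dat) < 10)
    stop("fewer than 10 complete-case rows (", nrow(dat), " of ",
         length(cc), "); check covariate missingness")
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in num_cand)
    X <- cbind(X, structure(dat[[v]], dim = c(nrow(dat), 1),
                            dimnames = list(NULL, v)))
  if ("period" %in% cand) {
    lev <- unique(as.character(dat$period))
    if (length(lev) < 2) {
      notes <- c(notes, "single period in data: period column dropped")
    } else {
      ref <- if ("Jul" %in% lev) "Jul" else sort(lev)[length(lev)]
      other <- setdiff(lev, ref)[1]
      X <- cbind(X, structure(as.numeric(dat$period == other),
                              dim = c(nrow(dat), 1),
                              dimnames = list(NULL,
                                              paste0("period", other))))
    }
  }
  # scaled coordinates for the smoother
  rng_lat <- range(dat$lat); rng_lon <- range(dat$lon)
  sc <- function(x, r) if (diff(r) > 0) (x - r[1]) / diff(r) else x * 0
  xy <- cbind(sc(dat$lat, rng_lat), sc(dat$lon, rng_lon))
  X <- cbind(X, lat_s = xy[, 1], lon_s = xy[, 2])
  knots <- .fps_knots(xy, spec$k)
  E <- .tps_E(xy, knots)
  Ekk <- .tps_E(knots, knots)
  Tk <- cbind(1, knots)
  qrT <- qr(Tk)
  Z <- qr.Q(qrT, complete = TRUE)[, -(1:3), drop = FALSE]
  B <- E %*% Z
  S <- t(Z) %*% Ekk %*% Z
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  S <- es$vectors %*% (ev * t(es$vectors))
  colnames(B) <- paste0("s", seq_len(ncol(B)))
  Zb <- NULL
  if (spec$random_intercept) {
    f <- factor(dat$id)
    Zb <- stats::model.matrix(~ f - 1)
    colnames(Zb) <- paste0("b_", levels(f))
  }
  list(y = dat$persistence, X = X, B = B, S = S, Zb = Zb,
       animal = as.character(dat$id), day = dat$day, data = dat,
       knots = knots, rng_lat = rng_lat, rng_lon = rng_lon,
       notes = notes, dropped = dropped)
}

## split a fit's residuals into per-animal runs of consecutive days
.residual_runs <- function(resid, animal, day) {
  out <- list()
  for (a in unique(animal)) {
    i <- which(animal == a)
    i <- i[order(day[i])]
    br <- c(0, which(diff(day[i]) != 1), length(i))
    for (s in seq_len(length(br) - 1)) {
      idx <- i[(br[s] + 1):br[s + 1]]
      if (length(idx) >= 2) out[[length(out) + 1]] <- resid[idx]
    }
  }
  out
}

## Jones parametrization: unconstrained reals -> stationary AR (or
## invertible MA) coefficients through partial autocorrelations
.pacf_to_coef <- function(par) {
  p <- length(par)
  if (p == 0) return(numeric(0))
  pk <- tanh(par)
  a <- numeric(0)
  for (k in seq_len(p)) {
    anew <- c(a, pk[k])
    if (k > 1) anew[1:(k - 1)] <- a - pk[k] * rev(a)
    a <- anew
  }
  a
}

## pooled Gaussian ARMA likelihood across residual runs (correlation
## form, sigma^2 profiled out); returns -2 loglik pieces and whitening
.arma_eval <- function(ar, ma, runs) {
  maxlen <- max(vapply(runs, length, integer(1)))
  rho <- if (length(ar) == 0 && length(ma) == 0)
    c(1, rep(0, maxlen - 1)) else
    as.numeric(stats::ARMAacf(ar = ar, ma = ma, lag.max = maxlen - 1))
  if (any(!is.finite(rho))) return(NULL)
  logdet <- 0; quad <- 0; N <- 0
  chols <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]; ni <- length(r)
    Ci <- stats::toeplitz(rho[1:ni])
    L <- tryCatch(chol(Ci), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    w <- backsolve(L, r, transpose = TRUE)
    logdet <- logdet + 2 * sum(log(diag(L)))
    quad <- quad + sum(w^2)
    N <- N + ni
    chols[[i]] <- L
  }
  sigma2 <- quad / N
  ll <- -0.5 * (N * log(2 * pi * sigma2) + logdet + N)
  list(loglik = ll, sigma2 = sigma2, chols = chols, rho = rho, N = N)
}

#' Pooled ARMA fit on per-animal residual series
#'
#' One shared ARMA(p, q) coefficient set, estimated by maximizing the sum
#' of exact Gaussian likelihoods over all equally spaced per-animal
#' residual runs. Stationarity/invertibility are enforced through the
#' partial-autocorrelation parametrization.
#'
#' @param runs list of numeric residual series (consecutive days).
#' @param p,q ARMA orders.
#' @param start optional warm-start vector (unconstrained scale).
#' @return list: `ar`, `ma`, `sigma2`, `loglik`, `p`, `q`, `npar`,
#'   `par` (the unconstrained optimum, reusable as a warm start).
#' @export
arma_mle <- function(runs, p, q, start = NULL) {
  if (p == 0 && q == 0) {
    ev <- .arma_eval(numeric(0), numeric(0), runs)
    return(list(ar = numeric(0), ma = numeric(0), sigma2 = ev$sigma2,
                loglik = ev$loglik, p = 0L, q = 0L, npar = 1L,
                par = numeric(0)))
  }
  fn <- function(par) {
    ar <- .pacf_to_coef(par[seq_len(p)])
    ma <- .pacf_to_coef(par[p + seq_len(q)])
    ev <- .arma_eval(ar, ma, runs)
    if (is.null(ev)) return(1e10)
    -ev$loglik
  }
  if (is.null(start) || length(start) != p + q) start <- rep(0, p + q)
  o <- if (p + q == 1)
    stats::optim(start, fn, method = "Brent", lower = -5, upper = 5) else
    stats::optim(start, fn, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-8))
  ar <- .pacf_to_coef(o$par[seq_len(p)])
  ma <- .pacf_to_coef(o$par[p + seq_len(q)])
  ev <- .arma_eval(ar, ma, runs)
  list(ar = ar, ma = ma, sigma2 = ev$sigma2, loglik = ev$loglik,
       p = as.integer(p), q = as.integer(q), npar = p + q + 1L,
       par = o$par)
}

#' Select ARMA orders from residual series
#'
#' Candidate (p, q) grid seeded by the last significant ACF/PACF lag of
#' the pooled residuals (95% bands +/- 1.96/sqrt(N)), winner by BIC over
#' exact pooled-likelihood fits (the log-n penalty keeps white-noise
#' residuals at (0, 0); an AIC penalty admits spurious orders whenever a
#' by-chance ACF lag crosses the band). All-short series select (0, 0)
#' with a note.
#'
#' @param runs list of residual series (from a fitted model).
#' @param p_max,q_max grid caps.
#' @return list: `p`, `q`, `table` (candidate BICs), `note`.
#' @export
select_arma <- function(runs, p_max = 4, q_max = 4) {
  lens <- vapply(runs, length, integer(1))
  if (!length(runs) || max(lens) < 20)
    return(list(p = 0L, q = 0L, table = NULL,
                note = "series too short; ARMA(0,0)"))
  pooled <- unlist(runs)
  N <- length(pooled)
  band <- 1.96 / sqrt(N)
  lag_max <- min(10, max(lens) - 1)
  ac <- stats::acf(pooled, lag.max = lag_max, plot = FALSE)$acf[-1]
  pc <- stats::pacf(pooled, lag.max = lag_max, plot = FALSE)$acf
  q0 <- if (any(abs(ac) > band)) max(which(abs(ac) > band)) else 0
  p0 <- if (any(abs(pc) > band)) max(which(abs(pc) > band)) else 0
  p_hi <- min(p0, p_max); q_hi <- min(q0, q_max)
  grid <- expand.grid(p = 0:p_hi, q = 0:q_hi)
  grid$bic <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    f <- tryCatch(arma_mle(runs, grid$p[g], grid$q[g]),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$loglik)) next
    grid$bic[g] <- -2 * f$loglik + log(N) * f$npar
    if (is.null(best) || grid$bic[g] < best$bic - 1e-9)
      best <- list(p = grid$p[g], q = grid$q[g], bic = grid$bic[g])
  }
  if (is.null(best))
    return(list(p = 0L, q = 0L, table = grid,
                note = "no candidate converged; ARMA(0,0)"))
  list(p = as.integer(best$p), q = as.integer(best$q), table = grid,
       note = "")
}

## one penalized weighted LS solve at fixed lambdas, from cached
## cross-products of the whitened problem (M = C'C, Cty = C'y, yty = y'y)
.pgls_solve <- function(dd, lam_s, lam_b, M, Cty, yty) {
  px <- ncol(dd$X); pb <- ncol(dd$B)
  pz <- if (is.null(dd$Zb)) 0L else ncol(dd$Zb)
  A <- M
  bi <- px + seq_len(pb)
  A[bi, bi] <- A[bi, bi] + lam_s * dd$S
  if (pz > 0) {
    zi <- px + pb + seq_len(pz)
    diag(A)[zi] <- diag(A)[zi] + lam_b
  }
  R <- tryCatch(chol(A + diag(1e-10, ncol(A))), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  theta <- backsolve(R, backsolve(R, Cty, transpose = TRUE))
  Ainv_M <- backsolve(R, backsolve(R, M, transpose = TRUE))
  trA <- sum(diag(Ainv_M))
  rss <- max(yty - 2 * sum(theta * Cty) +
               sum(theta * (M %*% theta)), 0)
  list(theta = as.vector(theta), trA = trA, rss = rss, R = R,
       edf_by_col = diag(Ainv_M))
}

## whiten rows of the stacked design given residual-run cholesky factors;
## rows not in any run (isolated days) stay unwhitened
.whiten <- function(mat, runs_idx, chols) {
  out <- mat
  if (is.null(runs_idx)) return(out)
  for (i in seq_along(runs_idx)) {
    idx <- runs_idx[[i]]
    out[idx, ] <- backsolve(chols[[i]], mat[idx, , drop = FALSE],
                            transpose = TRUE)
  }
  out
}

#' Fit the persistence GAMM
#'
#' Alternates (a) penalized weighted least squares for the fixed effects,
#' spatial smoother and random intercepts — smoothing and ridge parameters
#' by GCV on the whitened problem — with (b) pooled exact-likelihood
#' estimation of the ARMA(p, q) residual coefficients, until the AIC
#' changes by less than `tol` (or `max_iter`). Deterministic given data.
#' ARMA fits whose likelihood degenerates reduce their orders stepwise
#' with a warning trail.
#'
#' @param series a `persistence_series` data.frame.
#' @param spec a [gamm_spec()].
#' @param tol AIC convergence tolerance.
#' @param max_iter outer-iteration cap.
#' @return object of class `pgamm_fit`: coefficient table, smoother EDF
#'   and F, variance components, ARMA coefficients, AIC/logLik, fitted
#'   values and residuals (response scale), whitened residuals, the
#'   design (`dd`), chosen lambdas, convergence info.
#' @export
fit_pgamm <- function(series, spec, tol = 1e-4, max_iter = 50) {
  dd <- build_design(series, spec)
  n <- length(dd$y)
  px <- ncol(dd$X)
  npar_lin <- px + ncol(dd$B) +
    (if (is.null(dd$Zb)) 0 else ncol(dd$Zb))
  if (n < 10 * px)
    dd$notes <- c(dd$notes, "under-determined: fewer than 10 rows per parameter")
  C <- cbind(dd$X, dd$B, if (!is.null(dd$Zb)) dd$Zb)
  p_arma <- spec$arma_p; q_arma <- spec$arma_q
  runs_idx <- NULL; chols <- NULL; arma <- NULL
  aic_prev <- Inf; it <- 0; warn_trail <- character()
  lp_start <- if (is.null(dd$Zb)) 0 else c(0, 0)
  arma_start <- NULL
  repeat {
    it <- it + 1
    Cw <- .whiten(C, runs_idx, chols)
    yw <- as.vector(.whiten(matrix(dd$y), runs_idx, chols))
    M <- crossprod(Cw); Cty <- crossprod(Cw, yw); yty <- sum(yw^2)
    gcv <- function(lp) {
      f <- .pgls_solve(dd, exp(lp[1]),
                       if (length(lp) > 1) exp(lp[2]) else 1, M, Cty, yty)
      if (is.null(f)) return(1e12)
      n * f$rss / (n - f$trA)^2
    }
    if (is.null(dd$Zb)) {
      o <- stats::optim(lp_start, gcv, method = "Brent",
                        lower = -12, upper = 25)
      lam <- c(exp(o$par), 1)
    } else {
      o <- stats::optim(lp_start, gcv, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
      lam <- exp(o$par)
    }
    lp_start <- o$par
    sol <- .pgls_solve(dd, lam[1], lam[2], M, Cty, yty)
    fitted <- as.vector(C %*% sol$theta)
    resid <- dd$y - fitted
    # log-likelihood of the whitened Gaussian model (profile sigma^2)
    sigma2_ml <- sol$rss / n
    log_jac <- if (is.null(chols)) 0 else
      -sum(vapply(chols, function(L) sum(log(diag(L))), numeric(1)))
    ll <- -0.5 * n * (log(2 * pi * sigma2_ml) + 1) + log_jac
    edf_total <- sol$trA + p_arma + q_arma + 1
    aic <- -2 * ll + 2 * edf_total
    done <- abs(aic_prev - aic) < tol || it >= max_iter ||
      (p_arma == 0 && q_arma == 0 && it >= 1)
    aic_prev <- aic
    if (done) break
    # re-estimate ARMA from current residuals (warm-started)
    runs_idx <- .residual_runs(seq_len(n), dd$animal, dd$day)
    runs <- lapply(runs_idx, function(ix) resid[ix])
    pp <- p_arma; qq <- q_arma
    repeat {
      arma_try <- tryCatch(arma_mle(runs, pp, qq, start = arma_start),
                           error = function(e) NULL)
      bad <- is.null(arma_try) ||
        any(abs(c(arma_try$ar, arma_try$ma)) > 0.995)
      if (!bad) { arma <- arma_try; break }
      warn_trail <- c(warn_trail,
                      sprintf("ARMA(%d,%d) near-nonstationary; reduced",
                              pp, qq))
      arma_start <- NULL
      if (pp > 0) pp <- pp - 1 else if (qq > 0) qq <- qq - 1
      if (pp == 0 && qq == 0) { arma <- arma_mle(runs, 0, 0); break }
    }
    p_arma <- arma$p; q_arma <- arma$q
    arma_start <- arma$par
    if (p_arma == 0 && q_arma == 0) {
      runs_idx <- NULL; chols <- NULL
    } else {
      ev <- .arma_eval(arma$ar, arma$ma, runs)
      chols <- ev$chols
    }
  }
  if (length(warn_trail)) warning(paste(warn_trail, collapse = "; "))
  # marginal ML likelihood: smoother coefficients and random intercepts
  # integrated out at the estimated lambdas (the AIC used for fixed-effect
  # selection, as in mixed-model backward elimination)
  px_ix <- seq_len(px)
  Xw <- Cw[, px_ix, drop = FALSE]
  Bw <- Cw[, px + seq_len(ncol(dd$B)), drop = FALSE]
  es <- eigen(dd$S, symmetric = TRUE)
  pos <- es$values > max(es$values) * 1e-10
  S_pinv <- es$vectors[, pos, drop = FALSE] %*%
    ((1 / es$values[pos]) * t(es$vectors[, pos, drop = FALSE]))
  V0 <- diag(n) + Bw %*% S_pinv %*% t(Bw) / lam[1]
  if (!is.null(dd$Zb)) {
    Zbw <- Cw[, px + ncol(dd$B) + seq_len(ncol(dd$Zb)), drop = FALSE]
    V0 <- V0 + tcrossprod(Zbw) / lam[2]
  }
  V0 <- (V0 + t(V0)) / 2
  Rv <- tryCatch(chol(V0), error = function(e)
    chol(V0 + diag(1e-6 * max(diag(V0)), n)))
  logdetV <- 2 * sum(log(diag(Rv)))
  Xv <- backsolve(Rv, Xw, transpose = TRUE)
  yv <- backsolve(Rv, yw, transpose = TRUE)
  beta_ml <- qr.solve(Xv, yv)
  rss_v <- sum((yv - Xv %*% beta_ml)^2)
  sigma2_v <- rss_v / n
  log_jac <- if (is.null(chols)) 0 else
    -sum(vapply(chols, function(L) sum(log(diag(L))), numeric(1)))
  ll_ml <- -0.5 * (n * log(2 * pi * sigma2_v) + n + logdetV) + log_jac
  n_var <- 1 + (!is.null(dd$Zb)) + 1 + p_arma + q_arma  # lam_s, lam_b, sigma2, ARMA
  aic_ml <- -2 * ll_ml + 2 * (px + n_var)
  # inference pieces
  sigma2 <- sol$rss / max(n - sol$trA, 1)
  Vb <- sigma2 * chol2inv(sol$R)
  se <- sqrt(pmax(diag(Vb), 0))
  ix <- seq_len(px)
  # the two null-space coordinate columns belong to the smoother
  fixed_ix <- ix[!(colnames(dd$X) %in% c("lat_s", "lon_s"))]
  tval <- sol$theta[fixed_ix] / se[fixed_ix]
  df_res <- max(n - sol$trA, 1)
  coefs <- data.frame(term = colnames(dd$X)[fixed_ix],
                      estimate = sol$theta[fixed_ix],
                      se = se[fixed_ix],
                      t = tval,
                      p = 2 * stats::pt(-abs(tval), df_res))
  sm_ix <- c(which(colnames(dd$X) %in% c("lat_s", "lon_s")),
             px + seq_len(ncol(dd$B)))
  edf_s <- sum(sol$edf_by_col[sm_ix])
  th_s <- sol$theta[sm_ix]
  V_s <- Vb[sm_ix, sm_ix]
  wald <- tryCatch(as.numeric(t(th_s) %*% solve(V_s + diag(1e-10, length(sm_ix)),
                                                th_s)),
                   error = function(e) NA_real_)
  F_s <- wald / max(edf_s, 1e-8)
  p_s <- stats::pf(F_s, max(edf_s, 1e-8), df_res, lower.tail = FALSE)
  wres <- {
    Cw <- .whiten(C, runs_idx, chols)
    yw <- as.vector(.whiten(matrix(dd$y), runs_idx, chols))
    yw - as.vector(Cw %*% sol$theta)
  }
  out <- list(coefficients = coefs,
              smoother = list(edf = edf_s, F = F_s, p = p_s),
              lambda_s = lam[1], lambda_b = lam[2],
              sigma2 = sigma2,
              sigma2_b = if (!is.null(dd$Zb)) sigma2 / lam[2] else NA_real_,
              arma = list(p = p_arma, q = q_arma,
                          ar = if (!is.null(arma)) arma$ar else numeric(0),
                          ma = if (!is.null(arma)) arma$ma else numeric(0)),
              aic = aic, loglik = ll,
              aic_ml = aic_ml, loglik_ml = ll_ml,
              edf_total = edf_total,
              trA = sol$trA,
              fitted = fitted, residuals = resid,
              whitened_residuals = wres,
              theta = sol$theta, Vb = Vb, dd = dd, spec = spec,
              iterations = it, notes = dd$notes)
  class(out) <- "pgamm_fit"
  out
}

#' @export
print.pgamm_fit <- function(x, ...) {
  cat("Persistence GAMM (penalized GLS + ARMA residuals)\n")
  cat("  n =", length(x$dd$y), " AIC =", round(x$aic, 2),
      " total EDF =", round(x$edf_total, 2), "\n")
  cat("  ARMA(", x$arma$p, ",", x$arma$q, ")  sigma^2 =",
      signif(x$sigma2, 4), "\n", sep = "")
  print(transform(x$coefficients, estimate = signif(estimate, 3),
                  se = signif(se, 3), t = signif(t, 3),
                  p = signif(p, 3)), row.names = FALSE)
  cat("  s(lat,lon): EDF =", round(x$smoother$edf, 2),
      " F =", signif(x$smoother$F, 3),
      " p =", format.pval(x$smoother$p), "\n")
  invisible(x)
}

#' Backward elimination of fixed effects by AIC
#'
#' Repeatedly removes the fixed effect whose removal most lowers the
#' marginal ML AIC (smoother and random effects integrated out), until no
#' removal improves it; the smoother and the random effect are never
#' dropped. AIC ties within 1e-6 drop the covariate later in the declared
#' candidate order. Returns the final refit and the elimination trace.
#' An empty fixed-effect set is valid.
#'
#' @param series a `persistence_series` data.frame.
#' @param spec the full [gamm_spec()].
#' @return list: `fit` (final `pgamm_fit`), `spec`, `trace` (data.frame
#'   of step, candidate set, AIC, action).
#' @export
backward_eliminate <- function(series, spec) {
  current <- spec$fixed
  fit_with <- function(fx) {
    sp <- spec; sp$fixed <- fx
    fit_pgamm(series, sp)
  }
  fit <- fit_with(current)
  trace <- data.frame(step = 0L,
                      candidates = paste(current, collapse = "+"),
                      aic = fit$aic_ml, action = "full model")
  step <- 0L
  while (length(current) > 0) {
    step <- step + 1L
    aics <- vapply(seq_along(current), function(i)
      fit_with(current[-i])$aic_ml, numeric(1))
    best <- min(aics)
    if (best >= fit$aic_ml - 1e-6) break
    # tie rule: among candidates within 1e-6 of the best, drop the one
    # declared later in the candidate order
    cand <- which(aics <= best + 1e-6)
    drop_i <- max(cand)
    dropped <- current[drop_i]
    current <- current[-drop_i]
    fit <- fit_with(current)
    trace <- rbind(trace, data.frame(
      step = step, candidates = paste(current, collapse = "+"),
      aic = fit$aic_ml, action = paste("dropped", dropped)))
  }
  list(fit = fit, spec = {
    sp <- spec; sp$fixed <- current; sp
  }, trace = trace)
}

#' Predict persistence velocity from a fitted model
#'
#' Linear predictor with the smoother contribution; random intercepts are
#' excluded by default (population-level prediction); unknown animals
#' fall back to population level with a flag. Rows outside the fitted
#' covariate/coordinate ranges are flagged as extrapolation.
#'
#' @param object a `pgamm_fit`.
#' @param newdata data.frame with the model's covariates plus `lat`,
#'   `lon` (and `id` when `include_random`).
#' @param include_random add the per-animal intercept where known.
#' @param ... unused.
#' @return data.frame: `fit`, `se`, `extrapolated`, `population_level`.
#' @export
predict.pgamm_fit <- function(object, newdata, include_random = FALSE,
                              ...) {
  dd <- object$dd
  xn <- colnames(dd$X)
  n <- nrow(newdata)
  X <- matrix(0, n, length(xn), dimnames = list(NULL, xn))
  X[, "(Intercept)"] <- 1
  for (v in xn) {
    if (v %in% c("(Intercept)", "lat_s", "lon_s")) next
    if (startsWith(v, "period")) {
      lev <- sub("^period", "", v)
      X[, v] <- as.numeric(as.character(newdata$period) == lev)
    } else {
      if (is.null(newdata[[v]])) stop("newdata lacks covariate ", v)
      X[, v] <- newdata[[v]]
    }
  }
  sc <- function(x, r) (x - r[1]) / diff(r)
  xs <- sc(newdata$lat, dd$rng_lat); ys <- sc(newdata$lon, dd$rng_lon)
  X[, "lat_s"] <- xs; X[, "lon_s"] <- ys
  extrap <- xs < -0.05 | xs > 1.05 | ys < -0.05 | ys > 1.05
  E <- .tps_E(cbind(xs, ys), dd$knots)
  Tk <- cbind(1, dd$knots)
  Z <- qr.Q(qr(Tk), complete = TRUE)[, -(1:3), drop = FALSE]
  B <- E %*% Z
  C <- cbind(X, B)
  pop_flag <- rep(!include_random, n)
  if (!is.null(dd$Zb)) {
    Zb <- matrix(0, n, ncol(dd$Zb),
                 dimnames = list(NULL, colnames(dd$Zb)))
    if (include_random && !is.null(newdata$id)) {
      cols <- paste0("b_", as.character(newdata$id))
      known <- cols %in% colnames(Zb)
      for (i in which(known)) Zb[i, cols[i]] <- 1
      pop_flag <- !known
    }
    C <- cbind(C, Zb)
  }
  fit <- as.vector(C %*% object$theta)
  se <- sqrt(pmax(rowSums((C %*% object$Vb) * C), 0))
  data.frame(fit = fit, se = se, extrapolated = extrap,
             population_level = pop_flag)
}

#' Evaluate the fitted spatial surface on a grid
#'
#' Population-level predictions on an `n_grid` x `n_grid` lat/lon grid
#' spanning the fitted data (other covariates held at their means,
#' period at its reference level), for contour export.
#'
#' @param fit a `pgamm_fit`.
#' @param n_grid grid resolution per axis.
#' @return data.frame: `lat`, `lon`, `fit`, `se`.
#' @export
persistence_surface <- function(fit, n_grid = 40) {
  dd <- fit$dd
  lat <- seq(dd$rng_lat[1], dd$rng_lat[2], length.out = n_grid)
  lon <- seq(dd$rng_lon[1], dd$rng_lon[2], length.out = n_grid)
  g <- expand.grid(lat = lat, lon = lon)
  for (v in colnames(dd$X)) {
    if (v %in% c("(Intercept)", "lat_s", "lon_s")) next
    if (startsWith(v, "period")) g$period <- "ref" else
      g[[v]] <- mean(dd$data[[v]], na.rm = TRUE)
  }
  p <- predict(fit, g)
  cbind(g[, c("lat", "lon")], fit = p$fit, se = p$se)
}
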