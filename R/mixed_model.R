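#' Specification of the Stage-1 multivariate mixed model
#'
#' The Stage-1 model describes all four continuous risk factors jointly:
#' for subject i, factor k and measurement age a,
#' \deqn{y_{ik}(a) = \beta_{k0} + \beta_{k1}(a-50) + \beta_{k2}(a-50)^2
#'   + b_{0ik} + b_{1ik}(a-50) + \epsilon_{ik}(a),}
#' with the stacked person-level random effects
#' \eqn{b_i = (b_{0i1}, b_{1i1}, \ldots)} multivariate normal with
#' covariance G (8 x 8 when `cross_factor = "full"`; block-diagonal by
#' factor when `"diagonal"`, which is equivalent to four univariate
#' fits), and independent factor-specific residual variances.
#' Values are standardised per factor and ages centred at 50 internally;
#' all estimates are reported back on natural scales.
#'
#' @param cross_factor `"full"` for an unstructured cross-factor
#'   random-effect covariance, `"diagonal"` for independent per-factor
#'   (intercept, slope) blocks.
#' @param max_iter,tol EM control: maximum iterations and relative
#'   log-likelihood change declaring convergence.
#' @return an object of class `lmv_mixed_spec`.
#' @export
mixed_model_spec <- function(cross_factor = c("full", "diagonal"),
                             max_iter = 200, tol = 1e-6) {
  cross_factor <- match.arg(cross_factor)
  structure(list(cross_factor = cross_factor, max_iter = max_iter, tol = tol),
            class = "lmv_mixed_spec")
}

re_names <- function() {
  as.vector(t(outer(tolower(RISK_FACTORS), c("_b0", "_b1"), paste0)))
}

# standardized design rows for a set of (factor index, centred age)
fixed_row_block <- function(kidx, u, nfac) {
  n <- length(kidx)
  X <- matrix(0, n, 3 * nfac)
  for (j in seq_len(n)) {
    c0 <- 3 * (kidx[j] - 1)
    X[j, c0 + 1:3] <- c(1, u[j], u[j]^2)
  }
  X
}

random_row_block <- function(kidx, u, nfac) {
  n <- length(kidx)
  Z <- matrix(0, n, 2 * nfac)
  for (j in seq_len(n)) {
    c0 <- 2 * (kidx[j] - 1)
    Z[j, c0 + 1:2] <- c(1, u[j])
  }
  Z
}

#' Fit the Stage-1 multivariate mixed model for one sex
#'
#' Maximum-likelihood fit of the Gaussian linear mixed model of
#' [mixed_model_spec()] to all measurements of the given subjects taken
#' at ages in `[30, max_age)`, by an expectation/conditional-maximisation
#' algorithm. The fit is deterministic: fixed initialisation from
#' per-factor least squares, fixed tolerances, no random restarts.
#'
#' @param cohort an `lmv_cohort`.
#' @param sex `"M"` or `"F"`; subjects of this sex are used.
#' @param spec a [mixed_model_spec()].
#' @param subject_ids optional subset of subjects (e.g. the derivation
#'   set); default all subjects of that sex.
#' @param max_age upper age bound (exclusive) for training measurements;
#'   defaults to the last landmark age, 85.
#' @return an object of class `lmv_mixed_fit`: standardisation constants,
#'   fixed coefficients, random-effect covariance `G`, residual variances
#'   `sigma2` (all on the standardised scale), log-likelihood trace and
#'   convergence diagnostics.
#' @export
fit_mixed <- function(cohort, sex, spec = mixed_model_spec(),
                      subject_ids = NULL, max_age = 85) {
  stopifnot(inherits(spec, "lmv_mixed_spec"), sex %in% c("M", "F"))
  sub <- cohort$subjects
  ids <- sub$subject_id[sub$sex == sex]
  if (!is.null(subject_ids)) ids <- intersect(ids, subject_ids)
  meas <- cohort$measurements
  meas <- meas[meas$subject_id %in% ids & meas$age >= 30 & meas$age < max_age, ]
  if (nrow(meas) < 10)
    stop("too few measurements to fit the mixed model for sex ", sex,
         call. = FALSE)
  nfac <- length(RISK_FACTORS)

  center <- scale_ <- numeric(nfac); names(center) <- names(scale_) <- RISK_FACTORS
  for (k in RISK_FACTORS) {
    v <- meas$value[meas$factor == k]
    center[k] <- if (length(v)) mean(v) else 0
    s <- if (length(v) > 1) stats::sd(v) else 1
    scale_[k] <- if (is.finite(s) && s > 0) s else 1
  }
  kidx <- match(meas$factor, RISK_FACTORS)
  u <- meas$age - 50
  ystd <- (meas$value - center[kidx]) / scale_[kidx]

  # per-factor OLS start values
  beta <- numeric(3 * nfac)
  sigma2 <- rep(0.25, nfac)
  for (ki in seq_len(nfac)) {
    sel <- kidx == ki
    if (sum(sel) >= 4) {
      Xk <- cbind(1, u[sel], u[sel]^2)
      fit0 <- stats::lm.fit(Xk, ystd[sel])
      beta[3 * (ki - 1) + 1:3] <- fit0$coefficients
      rv <- stats::var(fit0$residuals)
      sigma2[ki] <- max(0.5 * rv, 1e-4)
    }
  }
  G <- diag(rep(c(0.5, 0.005), nfac))

  # pre-build per-subject design blocks once
  ord <- order(meas$subject_id, meas$age)
  kidx <- kidx[ord]; u <- u[ord]; ystd <- ystd[ord]
  sid <- meas$subject_id[ord]
  blocks <- split(seq_along(sid), sid)
  subj <- lapply(blocks, function(ix) {
    list(X = fixed_row_block(kidx[ix], u[ix], nfac),
         Z = random_row_block(kidx[ix], u[ix], nfac),
         y = ystd[ix], k = kidx[ix])
  })
  N <- length(subj)
  p <- 3 * nfac; q <- 2 * nfac

  loglik <- -Inf; ll_trace <- numeric(0)
  ridged <- FALSE
  converged <- FALSE
  for (it in seq_len(spec$max_iter)) {
    Gch <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(Gch)) {
      G <- G + diag(1e-8 * max(diag(G)), q)
      ridged <- TRUE
      Gch <- chol(G)
    }
    Ginv <- chol2inv(Gch)
    logdetG <- 2 * sum(log(diag(Gch)))

    Gacc <- matrix(0, q, q)
    sig_acc <- numeric(nfac); n_k <- numeric(nfac)
    A <- matrix(0, p, p); rhs <- numeric(p)
    ll <- 0
    for (si in seq_len(N)) {
      d <- subj[[si]]
      wobs <- 1 / sigma2[d$k]
      Zw <- d$Z * wobs
      ZtWZ <- crossprod(Zw, d$Z)
      Vinv <- ZtWZ + Ginv
      Vch <- chol(Vinv)
      V <- chol2inv(Vch)
      r <- d$y - drop(d$X %*% beta)
      ZtWr <- crossprod(Zw, r)
      bhat <- drop(V %*% ZtWr)
      Gacc <- Gacc + tcrossprod(bhat) + V
      e <- r - drop(d$Z %*% bhat)
      quadV <- rowSums((d$Z %*% V) * d$Z)
      for (ki in unique(d$k)) {
        sel <- d$k == ki
        sig_acc[ki] <- sig_acc[ki] + sum(e[sel]^2 + quadV[sel])
        n_k[ki] <- n_k[ki] + sum(sel)
      }
      Xw <- d$X * wobs
      XtWX <- crossprod(Xw, d$X)
      XtWZ <- crossprod(Xw, d$Z)
      A <- A + XtWX - XtWZ %*% V %*% t(XtWZ)
      ZtWy <- crossprod(Zw, d$y)
      rhs <- rhs + crossprod(Xw, d$y) - drop(XtWZ %*% (V %*% ZtWy))
      ll <- ll - 0.5 * (sum(log(sigma2[d$k])) + logdetG +
                          2 * sum(log(diag(Vch))) +
                          sum(r^2 * wobs) - drop(crossprod(ZtWr, V %*% ZtWr)) +
                          length(r) * log(2 * pi))
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(loglik) &&
        abs(ll - loglik) < spec$tol * (abs(loglik) + 1)) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll

    G <- Gacc / N
    if (spec$cross_factor == "diagonal") {
      mask <- matrix(0, q, q)
      for (ki in seq_len(nfac)) {
        ix <- 2 * (ki - 1) + 1:2
        mask[ix, ix] <- 1
      }
      G <- G * mask
    }
    sigma2 <- pmax(sig_acc / pmax(n_k, 1), 1e-10)
    beta <- drop(solve(A, rhs))
  }
  if (!converged)
    stop(sprintf(paste0("mixed-model EM did not converge in %d iterations ",
                        "(final log-likelihood %.6f, last change %.2e)"),
                 spec$max_iter, loglik,
                 if (length(ll_trace) > 1) diff(utils::tail(ll_trace, 2)) else NA),
         call. = FALSE)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("random-effect covariance estimated near-singular; ",
            "ridge stabilisation applied", call. = FALSE)
    ridged <- TRUE
  }
  dimnames(G) <- list(re_names(), re_names())
  names(beta) <- as.vector(t(outer(tolower(RISK_FACTORS),
                                   c("_int", "_age", "_age2"), paste0)))
  names(sigma2) <- RISK_FACTORS
  structure(list(sex = sex, spec = spec, center = center, scale = scale_,
                 beta = beta, G = G, sigma2 = sigma2,
                 loglik = loglik, iterations = length(ll_trace),
                 converged = converged, ridged = ridged,
                 n_subjects = N, n_obs = length(ystd)),
            class = "lmv_mixed_fit")
}

#' @export
print.lmv_mixed_fit <- function(x, ...) {
  cat(sprintf("<lmv_mixed_fit> sex %s, %d subjects, %d obs, logLik %.2f (%d EM iterations)\n",
              x$sex, x$n_subjects, x$n_obs, x$loglik, x$iterations))
  invisible(x)
}

#' BLUP current value and slope at a landmark age
#'
#' Empirical best linear unbiased prediction for one subject: the
#' posterior mean of the subject's random effects given the observed
#' pre-landmark history, plugged into the fixed-plus-random trajectory at
#' age s. With an empty history the prediction is the population (fixed
#' effects) trajectory. Only measurements at ages in `[30, s)` are used.
#'
#' @param fit an `lmv_mixed_fit`.
#' @param history data frame with `factor`, `age`, `value` for one
#'   subject (possibly missing some or all factors).
#' @param s landmark age, in `[40, 85]`.
#' @return data frame with one row per factor: `factor`, `est_current`
#'   (factor units), `est_slope` (units/year).
#' @export
predict_current_slope <- function(fit, history, s) {
  stopifnot(inherits(fit, "lmv_mixed_fit"))
  if (s < 40 || s > 85)
    stop("landmark age s must lie in [40, 85]", call. = FALSE)
  nfac <- length(RISK_FACTORS)
  h <- history[history$age >= 30 & history$age < s, , drop = FALSE]
  bhat <- numeric(2 * nfac)
  if (nrow(h)) {
    kidx <- match(h$factor, RISK_FACTORS)
    if (anyNA(kidx)) stop("unknown factor in history", call. = FALSE)
    u <- h$age - 50
    ystd <- (h$value - fit$center[kidx]) / fit$scale[kidx]
    X <- fixed_row_block(kidx, u, nfac)
    Z <- random_row_block(kidx, u, nfac)
    wobs <- 1 / fit$sigma2[kidx]
    Ginv <- chol2inv(chol(fit$G + diag(1e-12, 2 * nfac)))
    Zw <- Z * wobs
    r <- ystd - drop(X %*% fit$beta)
    bhat <- drop(solve(crossprod(Zw, Z) + Ginv, crossprod(Zw, r)))
  }
  us <- s - 50
  est_current <- est_slope <- numeric(nfac)
  for (ki in seq_len(nfac)) {
    bc <- fit$beta[3 * (ki - 1) + 1:3]
    cur_std <- bc[1] + bc[2] * us + bc[3] * us^2 +
      bhat[2 * (ki - 1) + 1] + bhat[2 * (ki - 1) + 2] * us
    slope_std <- bc[2] + 2 * bc[3] * us + bhat[2 * (ki - 1) + 2]
    est_current[ki] <- fit$center[ki] + fit$scale[ki] * cur_std
    est_slope[ki] <- fit$scale[ki] * slope_std
  }
  data.frame(factor = RISK_FACTORS, est_current = est_current,
             est_slope = est_slope, row.names = NULL)
}

#' Fill mixed-model summaries into a landmark dataset
#'
#' Computes the BLUP current value and individual-level slope for every
#' (subject, landmark age) record using the sex-specific fits, and writes
#' them into the `<factor>_current` / `<factor>_slope` columns. Histories
#' are accumulated incrementally across a subject's landmark ages, so the
#' cost is one rank-2 update and one 8 x 8 solve per record.
#'
#' @param records landmark dataset from [build_landmark_dataset()].
#' @param fits named list `list(M = , F = )` of `lmv_mixed_fit` objects.
#' @param cohort the `lmv_cohort` the records were built from.
#' @return `records` with the current/slope columns filled.
#' @export
add_mixed_summaries <- function(records, fits, cohort) {
  if (nrow(records) == 0) return(records)
  stopifnot(all(c("M", "F") %in% names(fits)) ||
              all(unique(records$sex) %in% names(fits)))
  nfac <- length(RISK_FACTORS)
  q <- 2 * nfac
  fkey <- tolower(RISK_FACTORS)
  meas <- cohort$measurements
  meas <- meas[meas$age >= 30, ]
  meas_split <- split(meas, meas$subject_id)

  ord <- order(records$subject_id, records$landmark_age)
  cur <- matrix(NA_real_, nrow(records), nfac)
  slp <- matrix(NA_real_, nrow(records), nfac)

  by_subj <- split(ord, records$subject_id[ord])
  for (sid in names(by_subj)) {
    rows <- by_subj[[sid]]
    sex <- records$sex[rows[1]]
    fit <- fits[[sex]]
    Ginv <- chol2inv(chol(fit$G + diag(1e-12, q)))
    h <- meas_split[[sid]]
    if (!is.null(h) && nrow(h)) {
      h <- h[order(h$age), ]
      kidx <- match(h$factor, RISK_FACTORS)
      u <- h$age - 50
      ystd <- (h$value - fit$center[kidx]) / fit$scale[kidx]
      X <- fixed_row_block(kidx, u, nfac)
      Z <- random_row_block(kidx, u, nfac)
      wobs <- 1 / fit$sigma2[kidx]
      r <- ystd - drop(X %*% fit$beta)
      ages <- h$age
    } else {
      ages <- numeric(0)
    }
    ZtWZ <- matrix(0, q, q); ZtWr <- numeric(q)
    j <- 0L
    for (rw in rows) {
      s <- records$landmark_age[rw]
      while (j < length(ages) && ages[j + 1L] < s) {
        j <- j + 1L
        zj <- Z[j, ]
        ZtWZ <- ZtWZ + (wobs[j] * zj) %o% zj
        ZtWr <- ZtWr + wobs[j] * r[j] * zj
      }
      bhat <- drop(solve(ZtWZ + Ginv, ZtWr))
      us <- s - 50
      for (ki in seq_len(nfac)) {
        bc <- fit$beta[3 * (ki - 1) + 1:3]
        cur_std <- bc[1] + bc[2] * us + bc[3] * us^2 +
          bhat[2 * (ki - 1) + 1] + bhat[2 * (ki - 1) + 2] * us
        cur[rw, ki] <- fit$center[ki] + fit$scale[ki] * cur_std
        slp[rw, ki] <- fit$scale[ki] * (bc[2] + 2 * bc[3] * us +
                                          bhat[2 * (ki - 1) + 2])
      }
    }
  }
  for (ki in seq_len(nfac)) {
    records[[paste0(fkey[ki], "_current")]] <- cur[, ki]
    records[[paste0(fkey[ki], "_slope")]] <- slp[, ki]
  }
  records
}
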