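## Bivariate random-effects pooling of logit sensitivity and specificity.
##
## Each study contributes (logit sens, logit spec) with within-study
## variances (1/tp + 1/fn, 1/tn + 1/fp); between-study variation is a
## bivariate normal with variances tau2 and correlation rho. The fixed
## effects are profiled out by GLS, so the (RE)ML objective is optimised
## over (tau_sens, tau_spec, atanh(rho)) only. The exact-binomial variant
## keeps the binomial within-study likelihood and integrates the random
## effects by Gauss-Hermite quadrature.

# per-study logit transforms, with 0.5 added to all four cells of any
# study containing a zero (the usual DTA continuity correction)
prep_studies <- function(studies, correction = 0.5) {
  studies <- as_tibble(studies)
  need <- setdiff(c("tp", "fp", "fn", "tn"), names(studies))
  if (length(need) > 0) {
    abort(paste0("missing study column(s): ", paste(need, collapse = ", ")))
  }
  if (!"study_id" %in% names(studies)) {
    studies$study_id <- paste0("study_", seq_len(nrow(studies)))
  }
  corrected <- with(studies, tp == 0 | fp == 0 | fn == 0 | tn == 0)
  add <- ifelse(corrected, correction, 0)
  tpc <- studies$tp + add; fpc <- studies$fp + add
  fnc <- studies$fn + add; tnc <- studies$tn + add
  tibble(study_id = studies$study_id,
         tp = studies$tp, fp = studies$fp, fn = studies$fn, tn = studies$tn,
         corrected = corrected,
         y1 = log(tpc / fnc), y2 = log(tnc / fpc),
         v1 = 1 / tpc + 1 / fnc, v2 = 1 / tnc + 1 / fpc)
}

# negative (restricted) log-likelihood of the normal-normal model, fixed
# effects profiled out; constants (2*pi terms) omitted
bivnorm_nll <- function(tau_s, tau_e, rho, y1, y2, v1, v2, Xs, Xe,
                        reml = TRUE, return_beta = FALSE) {
  a <- tau_s^2 + v1
  d <- tau_e^2 + v2
  b <- rho * tau_s * tau_e
  det <- a * d - b^2
  if (any(det <= 0)) return(Inf)
  w11 <- d / det; w22 <- a / det; w12 <- -b / det
  A <- rbind(cbind(crossprod(Xs, Xs * w11), crossprod(Xs, Xe * w12)),
             cbind(crossprod(Xe, Xs * w12), crossprod(Xe, Xe * w22)))
  bv <- c(crossprod(Xs, w11 * y1 + w12 * y2),
          crossprod(Xe, w12 * y1 + w22 * y2))
  Achol <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Achol)) return(Inf)
  beta <- backsolve(Achol, forwardsolve(t(Achol), bv))
  ydWy <- sum(w11 * y1^2 + 2 * w12 * y1 * y2 + w22 * y2^2)
  quad <- ydWy - sum(beta * bv)
  nll <- 0.5 * (sum(log(det)) + quad)
  if (reml) nll <- nll + 0.5 * 2 * sum(log(diag(Achol)))
  if (return_beta) {
    list(nll = nll, beta = beta, beta_vcov = chol2inv(Achol))
  } else {
    nll
  }
}

# negative log-likelihood of the binomial-normal model, Gauss-Hermite
# integration of the bivariate random effect (gh$x, gh$w on exp(-x^2))
bivbin_nll <- function(beta_s, beta_e, tau_s, tau_e, rho,
                       tp, np, tn, nn, Xs, Xe, gh) {
  L11 <- tau_s
  L21 <- rho * tau_e
  L22 <- tau_e * sqrt(max(1 - rho^2, 1e-12))
  g <- expand.grid(i = seq_along(gh$x), j = seq_along(gh$x))
  z1 <- sqrt(2) * gh$x[g$i]
  z2 <- sqrt(2) * gh$x[g$j]
  lw <- log(gh$w[g$i]) + log(gh$w[g$j]) - log(pi)
  mu1 <- drop(Xs %*% beta_s)
  mu2 <- drop(Xe %*% beta_e)
  eta1 <- outer(mu1, L11 * z1, "+")                      # k x G
  eta2 <- outer(mu2, L21 * z1 + L22 * z2, "+")
  ll <- dbinom(tp, np, plogis(eta1), log = TRUE) +
    dbinom(tn, nn, plogis(eta2), log = TRUE)
  ll <- sweep(ll, 2, lw, "+")
  m <- apply(ll, 1, max)
  -sum(m + log(rowSums(exp(ll - m))))
}

#' Fit a bivariate random-effects model to 2x2 study data
#'
#' Pools logit sensitivity and logit specificity across studies under a
#' bivariate normal between-study distribution with variances
#' `tau2_sens`, `tau2_spec` and correlation `rho`.
#'
#' Two likelihoods are available. The default, `method = "reml"`,
#' approximates each study's logit sensitivity/specificity as normal with
#' variances `1/tp + 1/fn` and `1/tn + 1/fp` (after adding `correction`
#' to all four cells of any study containing a zero) and maximises the
#' restricted likelihood; `method = "ml"` is the same model under full
#' maximum likelihood (used for likelihood-ratio tests).
#' `method = "ml_binomial"` keeps the exact binomial within-study
#' likelihood and integrates the random effects by Gauss-Hermite
#' quadrature with `gh_nodes` nodes per dimension; no continuity
#' correction is needed there. Optimisation is bounded quasi-Newton
#' (L-BFGS-B) from several deterministic starting points; `tau` is
#' floored at zero and `|rho|` capped at 0.999.
#'
#' @param studies Data frame with columns `tp`, `fp`, `fn`, `tn` and
#'   optionally `study_id`.
#' @param method `"reml"` (default), `"ml"`, or `"ml_binomial"`.
#' @param correction Continuity correction added to all cells of studies
#'   with a zero cell (normal methods only). Default 0.5.
#' @param fixed_tau Optional length-2 numeric: fix `(tau_sens, tau_spec)`
#'   instead of estimating them (e.g. `c(0, 0)` for a fixed-effect fit).
#' @param fixed_rho Optional scalar: fix the between-study correlation.
#' @param gh_nodes Gauss-Hermite nodes per dimension for
#'   `"ml_binomial"`; at least 21.
#' @return A `bivariate_fit` object with elements `mu` (pooled logits),
#'   `mu_vcov`, `tau`, `tau2`, `rho`, `vpar_se` (standard errors of the
#'   variance parameters, where estimable), `loglik`, `n_studies`,
#'   `method`, `converged`, and the per-study `data`. Use [tidy()],
#'   [glance()], [summarize_bivariate()] and [sroc_curve()] on it.
#' @examples
#' studies <- confusion_table(tp = c(40, 60), fp = c(8, 15),
#'                            fn = c(12, 18), tn = c(90, 160))
#' fit <- fit_bivariate(studies, fixed_tau = c(0, 0), fixed_rho = 0)
#' plogis(fit$mu)
#' @export
fit_bivariate <- function(studies, method = c("reml", "ml", "ml_binomial"),
                          correction = 0.5, fixed_tau = NULL,
                          fixed_rho = NULL, gh_nodes = 21) {
  method <- match.arg(method)
  fit_bivariate_impl(studies, Xrow_s = NULL, Xrow_e = NULL, method = method,
                     correction = correction, fixed_tau = fixed_tau,
                     fixed_rho = fixed_rho, gh_nodes = gh_nodes)
}

# Xrow_s / Xrow_e: optional k x p design rows for the two means (cell-means
# coding in meta_regression); NULL means intercept only.
fit_bivariate_impl <- function(studies, Xrow_s = NULL, Xrow_e = NULL,
                               method = "reml", correction = 0.5,
                               fixed_tau = NULL, fixed_rho = NULL,
                               gh_nodes = 21) {
  dat <- prep_studies(studies, correction)
  k <- nrow(dat)
  if (k < 2) abort("at least 2 studies are required")
  Xs <- if (is.null(Xrow_s)) matrix(1, k, 1) else as.matrix(Xrow_s)
  Xe <- if (is.null(Xrow_e)) matrix(1, k, 1) else as.matrix(Xrow_e)
  ps <- ncol(Xs); pe <- ncol(Xe)

  z_cap <- atanh(0.999)
  free <- c(tau_s = is.null(fixed_tau), tau_e = is.null(fixed_tau),
            rho = is.null(fixed_rho))
  th_fix <- c(tau_s = if (is.null(fixed_tau)) NA_real_ else fixed_tau[1],
              tau_e = if (is.null(fixed_tau)) NA_real_ else fixed_tau[2],
              z = if (is.null(fixed_rho)) NA_real_ else atanh(
                max(-0.999, min(0.999, fixed_rho))))

  expand_par <- function(par) {
    full <- th_fix
    full[which(free)] <- par
    full
  }

  nll_normal <- function(par) {
    full <- expand_par(par)
    bivnorm_nll(full["tau_s"], full["tau_e"], tanh(full["z"]),
                dat$y1, dat$y2, dat$v1, dat$v2, Xs, Xe,
                reml = (method == "reml"))
  }

  # deterministic starts: a moment-based one plus a small grid
  mom_ts <- sqrt(max(var(dat$y1) - mean(dat$v1), 0.01))
  mom_te <- sqrt(max(var(dat$y2) - mean(dat$v2), 0.01))
  mom_r <- if (k > 2 && sd(dat$y1) > 0 && sd(dat$y2) > 0) {
    max(-0.9, min(0.9, cor(dat$y1, dat$y2)))
  } else 0
  starts <- list(c(mom_ts, mom_te, atanh(mom_r)),
                 c(0.1, 0.1, 0), c(0.5, 0.5, -0.55),
                 c(0.5, 0.5, 0.55), c(1, 1, 0), c(0.05, 0.8, 0))

  run_optim <- function(fn, start, lower, upper) {
    tryCatch(optim(start, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(pgtol = 1e-8,
                                                 maxit = 500)),
             error = function(e) list(value = Inf, convergence = 99))
  }

  if (method %in% c("reml", "ml")) {
    idx <- which(free)
    lower <- c(tau_s = 0, tau_e = 0, z = -z_cap)[idx]
    upper <- c(tau_s = 5, tau_e = 5, z = z_cap)[idx]
    if (length(idx) == 0) {
      full <- th_fix
      best_par <- numeric(0)
      best <- list(value = nll_normal(numeric(0)), convergence = 0)
    } else {
      fits <- lapply(starts, function(s) run_optim(nll_normal, s[idx],
                                                   lower, upper))
      vals <- vapply(fits, `[[`, 0, "value")
      if (all(!is.finite(vals))) {
        abort("bivariate fit failed to converge from all starting points")
      }
      best <- fits[[which.min(vals)]]
      best_par <- best$par
      full <- expand_par(best_par)
    }
    tau_s <- unname(full["tau_s"]); tau_e <- unname(full["tau_e"])
    rho <- tanh(unname(full["z"]))
    sol <- bivnorm_nll(tau_s, tau_e, rho, dat$y1, dat$y2, dat$v1, dat$v2,
                       Xs, Xe, reml = (method == "reml"),
                       return_beta = TRUE)
    beta <- sol$beta
    beta_vcov <- sol$beta_vcov
    loglik <- -sol$nll - k * log(2 * pi)
    # SEs of the variance parameters from the observed information
    vpar_se <- c(tau_sens = NA_real_, tau_spec = NA_real_, rho = NA_real_)
    if (length(best_par) > 0) {
      H <- tryCatch(optimHess(best_par, nll_normal), error = function(e) NULL)
      if (!is.null(H)) {
        Vp <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(Vp) && all(diag(Vp) > 0)) {
          ses <- sqrt(diag(Vp))
          nm <- names(free)[free]
          vpar_se[c("tau_sens", "tau_spec", "rho")[match(nm, c("tau_s", "tau_e", "rho"))]] <-
            ses * c(tau_s = 1, tau_e = 1,
                    rho = 1 - rho^2)[nm]  # delta for z -> rho
        }
      }
    }
    converged <- is.finite(best$value) &&
      (length(best_par) == 0 || best$convergence %in% c(0, 1))
  } else {
    if (gh_nodes < 21) abort("gh_nodes must be at least 21")
    gh <- pracma::gaussHermite(gh_nodes)
    np <- dat$tp + dat$fn; nn <- dat$tn + dat$fp
    # start from the REML fit
    init <- fit_bivariate_impl(studies, Xrow_s, Xrow_e, method = "reml",
                               correction = correction,
                               fixed_tau = fixed_tau, fixed_rho = fixed_rho)
    b0 <- init$beta
    nll_bin <- function(par) {
      beta_s <- par[seq_len(ps)]
      beta_e <- par[ps + seq_len(pe)]
      full <- expand_par(par[-(seq_len(ps + pe))])
      bivbin_nll(beta_s, beta_e, full["tau_s"], full["tau_e"],
                 tanh(full["z"]), dat$tp, np, dat$tn, nn, Xs, Xe, gh)
    }
    idx <- which(free)
    lower <- c(rep(-10, ps + pe), c(tau_s = 1e-4, tau_e = 1e-4,
                                    z = -z_cap)[idx])
    upper <- c(rep(10, ps + pe), c(tau_s = 5, tau_e = 5, z = z_cap)[idx])
    vstart <- pmax(c(init$tau[1], init$tau[2], atanh(init$rho))[idx],
                   c(0.05, 0.05, -z_cap)[idx])
    start_sets <- list(c(b0, vstart),
                       c(b0, pmax(vstart * 0 + c(0.3, 0.3, 0)[idx], 1e-3)))
    fits <- lapply(start_sets, function(s) run_optim(nll_bin, s, lower, upper))
    vals <- vapply(fits, `[[`, 0, "value")
    if (all(!is.finite(vals))) {
      abort("exact-binomial bivariate fit failed to converge")
    }
    best <- fits[[which.min(vals)]]
    beta <- best$par[seq_len(ps + pe)]
    full <- expand_par(best$par[-(seq_len(ps + pe))])
    tau_s <- unname(full["tau_s"]); tau_e <- unname(full["tau_e"])
    rho <- tanh(unname(full["z"]))
    loglik <- -best$value
    H <- tryCatch(optimHess(best$par, nll_bin), error = function(e) NULL)
    beta_vcov <- matrix(NA_real_, ps + pe, ps + pe)
    vpar_se <- c(tau_sens = NA_real_, tau_spec = NA_real_, rho = NA_real_)
    if (!is.null(H)) {
      Vfull <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vfull) && all(diag(Vfull) > 0)) {
        beta_vcov <- Vfull[seq_len(ps + pe), seq_len(ps + pe), drop = FALSE]
        nm <- names(free)[free]
        ses <- sqrt(diag(Vfull))[-(seq_len(ps + pe))]
        vpar_se[c("tau_sens", "tau_spec", "rho")[match(nm, c("tau_s", "tau_e", "rho"))]] <-
          ses * c(tau_s = 1, tau_e = 1, rho = 1 - rho^2)[nm]
      }
    }
    converged <- is.finite(best$value) && best$convergence %in% c(0, 1)
  }

  names(beta) <- c(paste0("sens", if (ps > 1) paste0("_", seq_len(ps)) else ""),
                   paste0("spec", if (pe > 1) paste0("_", seq_len(pe)) else ""))
  intercept_only <- (ps == 1 && pe == 1)
  structure(list(
    mu = if (intercept_only) c(sens = unname(beta[1]), spec = unname(beta[2])) else NULL,
    beta = beta,
    beta_vcov = beta_vcov,
    ps = ps, pe = pe,
    tau = c(sens = tau_s, spec = tau_e),
    tau2 = c(sens = tau_s^2, spec = tau_e^2),
    rho = rho,
    vpar_se = vpar_se,
    loglik = loglik,
    n_studies = k,
    method = if (method == "ml_binomial") "ml_binomial" else
      paste0(method, "_normal"),
    correction = correction,
    converged = converged,
    data = dat
  ), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate random-effects fit (", x$method, ", ",
      x$n_studies, " studies)\n", sep = "")
  if (!is.null(x$mu)) {
    cat(sprintf("  pooled sensitivity: %.3f   pooled specificity: %.3f\n",
                plogis(x$mu["sens"]), plogis(x$mu["spec"])))
  }
  cat(sprintf("  tau (logit scale): sens %.3f, spec %.3f; rho %.3f\n",
              x$tau["sens"], x$tau["spec"], x$rho))
  cat(sprintf("  log-likelihood: %.3f%s\n", x$loglik,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

# clip a symmetric matrix to the nearest positive semi-definite one
fix_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, 1e-10), nrow(V)) %*% t(e$vectors)
}

#' Pooled accuracy and likelihood ratios from a bivariate fit
#'
#' Back-transforms the pooled logits with Wald intervals on the logit
#' scale, and derives pooled likelihood ratios as plug-in functions of
#' the pooled sensitivity and specificity, `LR+ = sens/(1-spec)` and
#' `LR- = (1-sens)/spec`, with intervals by the delta method on the
#' log-LR scale using the fitted covariance of the pooled logits (the
#' bivariate-model LR pooling of Zwinderman & Bossuyt). A parametric
#' bootstrap (normal draws of the pooled logits) is available as a
#' cross-check.
#'
#' @param fit A `bivariate_fit` from [fit_bivariate()] (intercept-only).
#' @param level Confidence level, default 0.95.
#' @param ci `"delta"` (default) or `"bootstrap"`.
#' @param boot_draws Bootstrap draws when `ci = "bootstrap"` (>= 2000).
#' @param seed Seed for the bootstrap draws.
#' @return A tibble with columns `statistic` (`sensitivity`,
#'   `specificity`, `lr_pos`, `lr_neg`), `estimate`, `conf_low`,
#'   `conf_high`, `level`.
#' @export
summarize_bivariate <- function(fit, level = 0.95,
                                ci = c("delta", "bootstrap"),
                                boot_draws = 2000, seed = NULL) {
  stopifnot(inherits(fit, "bivariate_fit"))
  ci <- match.arg(ci)
  if (is.null(fit$mu)) {
    abort("summarize_bivariate needs an intercept-only fit")
  }
  z <- qnorm(1 - (1 - level) / 2)
  mu <- fit$mu
  V <- fit$beta_vcov[1:2, 1:2, drop = FALSE]
  if (anyNA(V)) {
    abort("fit carries no covariance for the pooled logits")
  }
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    warn("degenerate covariance of pooled logits; clipped to nearest PSD")
    V <- fix_psd(V)
  }
  p_s <- plogis(mu["sens"]); p_e <- plogis(mu["spec"])
  lrp <- p_s / (1 - p_e)
  lrn <- (1 - p_s) / p_e
  se_mu <- sqrt(diag(V))

  if (ci == "delta") {
    # gradients of log LR wrt (mu_sens, mu_spec)
    g_p <- c(1 - p_s, p_e)
    g_n <- c(-p_s, -(1 - p_e))
    se_lp <- sqrt(drop(t(g_p) %*% V %*% g_p))
    se_ln <- sqrt(drop(t(g_n) %*% V %*% g_n))
    lo <- c(plogis(mu - z * se_mu), exp(log(lrp) - z * se_lp),
            exp(log(lrn) - z * se_ln))
    hi <- c(plogis(mu + z * se_mu), exp(log(lrp) + z * se_lp),
            exp(log(lrn) + z * se_ln))
  } else {
    if (boot_draws < 2000) abort("boot_draws must be at least 2000")
    sims <- with_seed_(seed, MASS::mvrnorm(boot_draws, mu, V))
    ps <- plogis(sims[, 1]); pe <- plogis(sims[, 2])
    qs <- function(x) stats::quantile(x, c((1 - level) / 2,
                                           1 - (1 - level) / 2),
                                      names = FALSE)
    b <- vapply(list(ps, pe, ps / (1 - pe), (1 - ps) / pe), qs, numeric(2))
    lo <- b[1, ]; hi <- b[2, ]
  }
  tibble(statistic = c("sensitivity", "specificity", "lr_pos", "lr_neg"),
         estimate = unname(c(p_s, p_e, lrp, lrn)),
         conf_low = unname(lo), conf_high = unname(hi),
         level = level)
}
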