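# Beta-binomial regression for differential relative abundance.
#
# Counts y_i out of library totals n_i follow a beta-binomial whose mean is
# linked to covariates by a logit: mu_i = plogis(x_i' beta), with a single
# dispersion parameter phi in (0,1) shared across samples (intercept-only
# dispersion). The beta parameters are a_i = mu_i (1-phi)/phi and
# b_i = (1-mu_i)(1-phi)/phi; phi -> 0 recovers the binomial.

.MU_EPS <- 1e-10
.U_LO <- -15   # logit(phi) lower bound; phi ~ 3e-7, effectively binomial
.U_HI <- 8
.B_BOUND <- 20 # |beta| bound for the L-BFGS-B optimizer (separation guard)

# negative log-likelihood at theta = c(beta, u) with phi = plogis(u)
.bb_negll <- function(theta, X, y, n) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% theta[seq_len(p)]))
  mu <- pmin(pmax(mu, .MU_EPS), 1 - .MU_EPS)
  disp <- exp(-theta[p + 1L])          # (1-phi)/phi
  a <- mu * disp
  b <- (1 - mu) * disp
  -sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

# analytic gradient of .bb_negll
.bb_neggrad <- function(theta, X, y, n) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, .MU_EPS), 1 - .MU_EPS)
  disp <- exp(-theta[p + 1L])
  a <- mu * disp
  b <- (1 - mu) * disp
  la <- digamma(y + a) - digamma(n + a + b) - digamma(a) + digamma(a + b)
  lb <- digamma(n - y + b) - digamma(n + a + b) - digamma(b) + digamma(a + b)
  dmu <- mu * (1 - mu)
  gbeta <- -colSums(((la - lb) * disp * dmu) * X)
  gu <- sum(la * a + lb * b)           # d(-ll)/du = +sum(la*a + lb*b)
  c(gbeta, gu)
}

#' Fit a beta-binomial differential relative-abundance model for one taxon
#'
#' Maximum likelihood for beta-binomial counts with a logit mean link and a
#' single (intercept-only) dispersion parameter, the model behind all three
#' trait-defining contrasts. The optimizer is bounded quasi-Newton
#' (L-BFGS-B) on (beta, logit phi) with an analytic gradient and three
#' starting points (moment estimate, null start, jittered moment estimate) to
#' reduce the risk of local optima.
#'
#' Covariates are centred internally, so the intercept and group coefficients
#' describe the contrast at mean covariate values; [log2_fold_change] relies
#' on this.
#'
#' @param counts integer vector of per-sample counts for the taxon.
#' @param totals per-sample library sizes (totals >= counts).
#' @param group 0/1 contrast-arm indicator per sample, or `NULL` for an
#'   intercept/covariate-only (null) model.
#' @param covariates optional numeric matrix or vector of per-sample
#'   covariates (for trait contrasts this is pH); centred before fitting.
#' @param maxit optimizer iteration cap.
#' @return object of class `"beta_binomial_fit"`: coefficients (mean-model
#'   betas and `phi`), observed-information covariance, log-likelihood,
#'   convergence and estimability flags.
#' @seealso [log2_fold_change()], [wald_test()], [diff_abundance()]
#' @export
fit_beta_binomial <- function(counts, totals, group = NULL, covariates = NULL,
                              maxit = 500L) {
  y <- as.numeric(counts)
  n <- as.numeric(totals)
  if (length(y) != length(n)) stop("counts and totals differ in length")
  if (any(n <= 0)) stop("all library totals must be positive")
  if (any(y < 0) || any(y > n)) stop("counts must satisfy 0 <= count <= total")
  if (!is.null(group)) {
    group <- as.numeric(group)
    if (!all(group %in% c(0, 1))) stop("group must be a 0/1 indicator")
    if (length(group) != length(y)) stop("group length mismatch")
    if (min(table(factor(group, levels = c(0, 1)))) < 1)
      stop("both contrast arms must be non-empty")
  }
  X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(group)) X <- cbind(X, group = group)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    cv <- scale(cv, center = TRUE, scale = FALSE)
    X <- cbind(X, cv)
  }
  p <- ncol(X)
  out <- structure(
    list(coefficients = stats::setNames(rep(NA_real_, p + 1L), c(colnames(X), "phi")),
         beta = stats::setNames(rep(NA_real_, p), colnames(X)),
         phi = NA_real_,
         vcov = matrix(NA_real_, p + 1L, p + 1L,
                       dimnames = list(c(colnames(X), "logit_phi"),
                                       c(colnames(X), "logit_phi"))),
         logLik = NA_real_, converged = FALSE, estimable = TRUE,
         separation = FALSE, n_samples = length(y),
         X = X, y = y, totals = n, has_group = !is.null(group)),
    class = "beta_binomial_fit")

  if (all(y == 0)) {                 # taxon never observed: non-estimable
    out$estimable <- FALSE
    return(out)
  }
  if (!is.null(group)) {
    present <- tapply(y > 0, group, any)
    out$separation <- !all(present)  # observed in only one arm; fit is bounded
  }

  # starting points
  pooled <- sum(y) / sum(n)
  b_start <- numeric(p)
  b_start[1] <- stats::qlogis(min(max(pooled, 1e-6), 1 - 1e-6))
  start_moment <- b_start
  if (!is.null(group)) {
    p0 <- (sum(y[group == 0]) + 0.5) / (sum(n[group == 0]) + 1)
    p1 <- (sum(y[group == 1]) + 0.5) / (sum(n[group == 1]) + 1)
    start_moment[1] <- stats::qlogis(p0)
    start_moment[2] <- stats::qlogis(p1) - stats::qlogis(p0)
  }
  u0 <- stats::qlogis(0.02)
  starts <- list(c(start_moment, u0), c(b_start, stats::qlogis(0.1)))
  set_jitter <- start_moment + c(0.25, rep(-0.25, p - 1L))
  starts[[3]] <- c(set_jitter, stats::qlogis(0.005))

  lower <- c(rep(-.B_BOUND, p), .U_LO)
  upper <- c(rep(.B_BOUND, p), .U_HI)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, .bb_negll, .bb_neggrad, X = X, y = y, n = n,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e4, pgtol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(out)
  # restart once from the winner: settles the convergence diagnostic when the
  # best start used all its iterations
  refit <- tryCatch(
    stats::optim(best$par, .bb_negll, .bb_neggrad, X = X, y = y, n = n,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 1e4, pgtol = 1e-8)),
    error = function(e) NULL)
  if (!is.null(refit) && refit$value <= best$value) best <- refit

  theta <- best$par
  out$beta[] <- theta[seq_len(p)]
  out$phi <- stats::plogis(theta[p + 1L])
  out$coefficients[] <- c(out$beta, out$phi)
  out$logLik <- -best$value
  out$converged <- best$convergence == 0 && !out$separation
  H <- tryCatch(stats::optimHess(theta, .bb_negll, .bb_neggrad, X = X, y = y, n = n),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      dimnames(V) <- list(c(colnames(X), "logit_phi"), c(colnames(X), "logit_phi"))
      out$vcov <- V
    } else out$converged <- FALSE
  } else out$converged <- FALSE
  out
}

#' @export
print.beta_binomial_fit <- function(x, ...) {
  cat("Beta-binomial fit (logit mean link, intercept-only dispersion)\n")
  if (!x$estimable) {
    cat("  non-estimable: taxon absent from every sample\n")
    return(invisible(x))
  }
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik %.4f | n = %d | converged: %s%s\n", x$logLik,
              x$n_samples, x$converged,
              if (x$separation) " | separation flagged" else ""))
  invisible(x)
}

#' @export
coef.beta_binomial_fit <- function(object, ...) object$coefficients

#' @export
vcov.beta_binomial_fit <- function(object, ...) object$vcov

#' @export
logLik.beta_binomial_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n_samples, class = "logLik")
}

#' @export
fitted.beta_binomial_fit <- function(object, ...) {
  drop(stats::plogis(object$X %*% object$beta))
}

#' @export
residuals.beta_binomial_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  n <- object$totals
  r <- object$y - n * mu
  if (type == "raw") return(r)
  rho <- object$phi
  v <- n * mu * (1 - mu) * (1 + (n - 1) * rho)
  r / sqrt(v)
}

#' @export
summary.beta_binomial_fit <- function(object, ...) {
  p <- length(object$beta)
  se <- sqrt(diag(object$vcov))[seq_len(p)]
  z <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, phi = object$phi, logLik = object$logLik,
                 converged = object$converged), class = "summary.beta_binomial_fit")
}

#' @export
print.summary.beta_binomial_fit <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("phi = %.4g, logLik = %.4f, converged = %s\n",
              x$phi, x$logLik, x$converged))
  invisible(x)
}

#' Log2 fold change of relative abundance between contrast arms
#'
#' Evaluated at mean covariate values (covariates are centred in the fit):
#' log2 of the ratio of fitted mean relative abundances, group 1 over group 0,
#' with a delta-method standard error.
#'
#' @param fit a converged [fit_beta_binomial] object with a group term.
#' @return list with `log2fc` and `se` (both `NA` if the fit did not converge).
#' @export
log2_fold_change <- function(fit) {
  stopifnot(inherits(fit, "beta_binomial_fit"))
  if (!fit$has_group) stop("fit has no group term")
  if (!fit$estimable || anyNA(fit$beta)) return(list(log2fc = NA_real_, se = NA_real_))
  b0 <- fit$beta[["(Intercept)"]]
  bg <- fit$beta[["group"]]
  mu0 <- stats::plogis(b0)
  mu1 <- stats::plogis(b0 + bg)
  l2 <- log2(mu1 / mu0)
  # gradient of log2(mu1/mu0) wrt (b0, bg); other covariates centred -> 0
  g <- c((1 - mu1) - (1 - mu0), 1 - mu1) / log(2)
  V <- fit$vcov[c("(Intercept)", "group"), c("(Intercept)", "group")]
  se <- if (anyNA(V)) NA_real_ else sqrt(drop(t(g) %*% V %*% g))
  list(log2fc = l2, se = se)
}

#' Two-sided Wald test on the group coefficient
#'
#' The statistic is referred to a t distribution with n minus the number of
#' model parameters degrees of freedom (the usual finite-sample reference
#' for beta-binomial Wald tests; a normal reference is anti-conservative at
#' the sample sizes of paired-core designs).
#'
#' @param fit a [fit_beta_binomial] object with a group term.
#' @return p-value in [0,1], or `NA` if the covariance is unavailable.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "beta_binomial_fit"))
  if (!fit$has_group) stop("fit has no group term")
  if (!fit$estimable || anyNA(fit$beta)) return(NA_real_)
  se <- sqrt(fit$vcov["group", "group"])
  if (!is.finite(se) || se <= 0) return(NA_real_)
  z <- fit$beta[["group"]] / se
  df <- fit$n_samples - length(fit$coefficients)
  if (df < 1) return(2 * stats::pnorm(-abs(z)))
  2 * stats::pt(-abs(z), df = df)
}

#' Likelihood-ratio test against a reduced model
#'
#' Optional cross-check to the Wald test: twice the log-likelihood gap
#' against a chi-squared with the difference in parameter count.
#'
#' @param fit_full,fit_reduced nested [fit_beta_binomial] objects.
#' @return p-value.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  df <- length(fit_full$beta) - length(fit_reduced$beta)
  if (df < 1) stop("models are not nested (df < 1)")
  stat <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; missing p-values are carried through as missing
#' and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in [0,1], `NA` allowed.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0,1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Per-taxon differential relative abundance for one contrast
#'
#' Fits [fit_beta_binomial] to every taxon of a count table against a 0/1
#' contrast with a pH covariate, and collects log2 fold changes, Wald
#' p-values and BH q-values. Taxa observed in fewer than `min_prevalence`
#' samples within the contrast are not tested (reported with missing
#' p/q and excluded from the number of tests).
#'
#' @param table a [count_table] restricted to the contrast's samples.
#' @param group 0/1 vector aligned to the table's sample columns.
#' @param pH per-sample pH covariate (centred internally), or `NULL`.
#' @param min_prevalence prevalence floor (samples with a nonzero count).
#' @return data.frame: taxon_id, log2fc, se_log2fc, p_value, q_value,
#'   converged, n_samples_used.
#' @export
diff_abundance <- function(table, group, pH = NULL, min_prevalence = 3L) {
  totals <- colSums(unclass(table))
  ids <- rownames(table)
  res <- data.frame(taxon_id = ids, log2fc = NA_real_, se_log2fc = NA_real_,
                    p_value = NA_real_, q_value = NA_real_, converged = FALSE,
                    n_samples_used = length(group), stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    y <- unclass(table)[i, ]
    if (sum(y > 0) < min_prevalence) next
    fit <- fit_beta_binomial(y, totals, group = group, covariates = pH)
    if (!fit$estimable) next
    fc <- log2_fold_change(fit)
    res$log2fc[i] <- fc$log2fc
    res$se_log2fc[i] <- fc$se
    res$p_value[i] <- wald_test(fit)
    res$converged[i] <- fit$converged
  }
  res$q_value <- bh_adjust(res$p_value)
  res
}
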