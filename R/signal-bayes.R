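# Bayesian disproportionality: BCPNN information component and the
# DuMouchel gamma-Poisson shrinker (MGPS / EBGM).

#' BCPNN information component with lower credibility bound
#'
#' Closed-form posterior moments of the information component
#' IC = log2 p(event, vaccine) / (p(event) p(vaccine)) under the Bayesian
#' confidence propagation neural network model with Beta/Dirichlet priors:
#'
#'   E(IC) = log2 [ (a + g11)(N + alpha)(N + beta) /
#'                  ((N + gamma)(a + b + alpha1)(a + c + beta1)) ]
#'
#' with gamma = g11 (N + alpha)(N + beta) /
#' ((a + b + alpha1)(a + c + beta1)) so the prior is centred on
#' independence, and V(IC) the three-term variance sum divided by
#' (ln 2)^2. The lower bound reported is E(IC) - 2 sqrt(V(IC)).
#' Values are finite for every valid table, including a = 0.
#'
#' @inheritParams rorStat
#' @param priors a \linkS4class{BcpnnPriors}; see [bcpnnPriors()].
#' @return data.frame(ic, ic_minus_2sd).
#' @examples
#' bcpnnIc(c(25, 75, 100, 900))
#' @export
bcpnnIc <- function(t, priors = bcpnnPriors()) {
  cc <- .cells(t)
  a <- cc$a; b <- cc$b; c <- cc$c; d <- cc$d
  N <- a + b + c + d
  if (any(N <= 0)) stop("N must be > 0")
  al <- priors@alpha; be <- priors@beta
  al1 <- priors@alpha1; be1 <- priors@beta1; g11 <- priors@gamma11
  g <- g11 * (N + al) * (N + be) / ((a + b + al1) * (a + c + be1))
  eic <- log2((a + g11) * (N + al) * (N + be) /
                ((N + g) * (a + b + al1) * (a + c + be1)))
  vic <- ((N - a + g - g11) / ((a + g11) * (1 + N + g)) +
            (N - a - b + al - al1) / ((a + b + al1) * (1 + N + al)) +
            (N - a - c + be - be1) / ((a + c + be1) * (1 + N + be))) /
    log(2)^2
  data.frame(ic = eic, ic_minus_2sd = eic - 2 * sqrt(vic))
}

# expected count per table under row/column independence, from the table's
# own margins
.expectedCount <- function(a, b, c, d) {
  N <- a + b + c + d
  (a + b) * (a + c) / N
}

# marginal log-likelihood of counts a with expectations E under the
# two-component negative-binomial mixture implied by the gamma prior
.mgpsNll <- function(theta, a, E) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  P <- stats::plogis(theta[5])
  # extreme parameter proposals can overflow dnbinom; treat as -Inf lik
  l1 <- suppressWarnings(
    log(P) + stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE))
  l2 <- suppressWarnings(
    log1p(-P) + stats::dnbinom(a, size = a2, prob = b2 / (b2 + E),
                               log = TRUE))
  m <- pmax(l1, l2)
  nll <- -sum(m + log(exp(l1 - m) + exp(l2 - m)))
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit the MGPS gamma-Poisson mixture prior
#'
#' Maximizes the DuMouchel marginal likelihood: each cell count a_i is
#' negative-binomially distributed given its expected count
#' E_i = (a+b)(a+c)/N, with the relative reporting rate lambda drawn from
#' the two-component gamma mixture
#' P Gamma(alpha1, beta1) + (1-P) Gamma(alpha2, beta2). Optimization is
#' quasi-Newton (BFGS) on log shapes/rates and logit P from the fixed
#' deterministic start (0.2, 0.1, 2, 4, 1/3), so the fit is reproducible.
#' On optimizer failure the start values are returned with
#' \code{converged = FALSE} and a warning.
#'
#' @param tables data.frame of 2x2 tables (columns a, b, c, d), or columns
#'   a and E (precomputed expected counts); at least 2 rows.
#' @param start numeric(5) starting point (alpha1, beta1, alpha2, beta2, P).
#' @return a \linkS4class{MgpsHyperparams}.
#' @export
mgpsFit <- function(tables, start = c(0.2, 0.1, 2, 4, 1 / 3)) {
  if (!is.data.frame(tables) || nrow(tables) < 2)
    stop("mgpsFit needs at least 2 tables")
  a <- as.numeric(tables$a)
  E <- if ("E" %in% names(tables)) as.numeric(tables$E)
       else .expectedCount(a, tables$b, tables$c, tables$d)
  keep <- is.finite(E) & E > 0
  if (sum(keep) < 2) stop("need at least 2 cells with expected count > 0")
  a <- a[keep]; E <- E[keep]

  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  fit <- tryCatch(
    stats::optim(theta0, .mgpsNll, a = a, E = E, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error") || !is.finite(fit$value)) {
    warning("MGPS optimizer failed; returning starting values: ",
            if (inherits(fit, "error")) conditionMessage(fit) else "")
    return(new("MgpsHyperparams", alpha1 = start[1], beta1 = start[2],
               alpha2 = start[3], beta2 = start[4], pMix = start[5],
               converged = FALSE,
               loglik = -.mgpsNll(theta0, a, E)))
  }
  th <- fit$par
  new("MgpsHyperparams",
      alpha1 = exp(th[1]), beta1 = exp(th[2]),
      alpha2 = exp(th[3]), beta2 = exp(th[4]),
      pMix = stats::plogis(th[5]),
      converged = fit$convergence == 0,
      loglik = -fit$value)
}

# posterior mixture weight on component 1, given a and E
.posteriorWeight <- function(a, E, h) {
  l1 <- log(h@pMix) +
    stats::dnbinom(a, size = h@alpha1, prob = h@beta1 / (h@beta1 + E),
                   log = TRUE)
  l2 <- log1p(-h@pMix) +
    stats::dnbinom(a, size = h@alpha2, prob = h@beta2 / (h@beta2 + E),
                   log = TRUE)
  1 / (1 + exp(l2 - l1))
}

.mixtureCdf <- function(q, a, E, h, Qn) {
  Qn * stats::pgamma(q, shape = h@alpha1 + a, rate = h@beta1 + E) +
    (1 - Qn) * stats::pgamma(q, shape = h@alpha2 + a, rate = h@beta2 + E)
}

#' Empirical Bayes geometric mean and its 5th posterior percentile
#'
#' Under the fitted gamma mixture prior, the posterior of the relative
#' reporting rate lambda given (a, E) is the mixture of
#' Gamma(alpha1 + a, beta1 + E) and Gamma(alpha2 + a, beta2 + E) with
#' count-dependent weights. EBGM = exp(E[ln lambda]) (via digamma);
#' EBGM05 is the 5th percentile of the posterior mixture, solved
#' numerically to |CDF(q) - 0.05| < 1e-6. a = 0 is allowed (the estimate
#' shrinks toward the prior).
#'
#' @inheritParams rorStat
#' @param h a \linkS4class{MgpsHyperparams} from [mgpsFit()].
#' @return data.frame(ebgm, ebgm05).
#' @export
ebgmStat <- function(t, h) {
  stopifnot(is(h, "MgpsHyperparams"))
  if ((is.data.frame(t) || is.list(t)) && !is.null(t[["E"]])) {
    a <- as.numeric(t[["a"]]); E <- as.numeric(t[["E"]])
  } else {
    cc <- .cells(t)
    a <- cc$a
    E <- .expectedCount(a, cc$b, cc$c, cc$d)
  }
  if (any(!is.finite(E) | E <= 0)) stop("expected counts must be > 0")
  Qn <- .posteriorWeight(a, E, h)
  elog <- Qn * (digamma(h@alpha1 + a) - log(h@beta1 + E)) +
    (1 - Qn) * (digamma(h@alpha2 + a) - log(h@beta2 + E))
  ebgm <- exp(elog)
  ebgm05 <- vapply(seq_along(a), function(i) {
    f <- function(q) .mixtureCdf(q, a[i], E[i], h, Qn[i]) - 0.05
    up <- max(stats::qgamma(0.95, shape = h@alpha1 + a[i],
                            rate = h@beta1 + E[i]),
              stats::qgamma(0.95, shape = h@alpha2 + a[i],
                            rate = h@beta2 + E[i]))
    lo <- min(stats::qgamma(1e-6, shape = h@alpha1 + a[i],
                            rate = h@beta1 + E[i]),
              stats::qgamma(1e-6, shape = h@alpha2 + a[i],
                            rate = h@beta2 + E[i]))
    stats::uniroot(f, lower = lo, upper = up, tol = 1e-12)$root
  }, numeric(1))
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}
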