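#' Fit transmission parameters to observed progeny-class counts
#'
#' Maximum-likelihood estimation of gametophytic transmission parameters
#' from a cross. The observed counts are multinomial over a subset of the
#' progeny classes of [progeny_distribution()] (seedling scoring on plates
#' never sees unfertilized ovules, and often not aborted seeds, so the
#' likelihood conditions on the scored classes: class probabilities are
#' renormalised over `names(observed)`).
#'
#' Free parameters are named `"tau_male[<gamete label>]"`,
#' `"tau_female[<gamete label>]"` or `"sac_failure[<gamete label>]"`, e.g.
#' `"tau_male[miro1:miro2-2]"`. Taus are optimised on `[0, Inf)`, sac-failure
#' probabilities on `[0, 1]`; estimates may lie on the boundary (a cross with
#' zero resistant seedlings gives tau-hat = 0). For a wild-type outcross with
#' a single free tau and resistant/sensitive counts the MLE has the closed
#' form `tau-hat = R / S`, the classical transmission-efficiency ratio.
#'
#' Identifiability is checked at the optimum through the observed-information
#' eigenvalues; a flat direction raises a warning rather than returning a
#' silently arbitrary estimate.
#'
#' @param cross a [cross_spec()].
#' @param observed named non-negative counts; names must be progeny-class
#'   labels of the cross (e.g. `"viable:BASTA+kanamycin"`).
#' @param free character vector naming the free parameters (see above).
#' @param params baseline [transmission_params()]; fixed values for
#'   everything not in `free`. Defaults to the neutral model over the
#'   cross's loci.
#' @param start optional named numeric starting values for `free`.
#' @return A `transfit` object with methods `print`, `summary`, `coef`,
#'   `logLik`, `vcov`, `confint`, `predict`, `simulate`, `residuals`,
#'   `fitted`, `nobs`.
#' @examples
#' loci <- miro_loci()
#' wt <- genotype(loci, "+/+ +/+")
#' dad <- genotype(loci, "+/- -/-")
#' fit <- fit_transmission(
#'   cross_spec(wt, dad),
#'   observed = c("viable:BASTA+kanamycin" = 161, "viable:kanamycin" = 464),
#'   free = "tau_male[miro1:miro2-2]")
#' coef(fit)   # 161/464 = 0.347
#' @export
fit_transmission <- function(cross, observed, free,
                             params = transmission_params(
                               attr(cross$mother, "loci")),
                             start = NULL) {
  stopifnot(inherits(cross, "cross_spec"),
            inherits(params, "transmission_params"))
  if (is.null(names(observed)) || any(!nzchar(names(observed)))) {
    stop("observed must be a named count vector over progeny classes",
         call. = FALSE)
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers", call. = FALSE)
  }
  loci <- params$loci
  parsed <- parse_free_params(free, loci)
  if (length(free) > length(observed) - 1L) {
    stop("more free parameters (", length(free),
         ") than observed degrees of freedom (", length(observed) - 1L, ")",
         call. = FALSE)
  }
  if (is.null(start)) {
    start <- ifelse(parsed$component == "sac_failure", 0.1, 0.5)
    names(start) <- free
  } else {
    start <- start[free]
  }
  # validate observed classes against the distribution at the starting
  # values, where every freed failure/lethality pathway is already open
  base_dist <- progeny_distribution(cross,
                                    set_free_params(params, parsed, start))
  unknown <- setdiff(names(observed), names(base_dist))
  if (length(unknown)) {
    stop("observed class(es) not produced by this cross: ",
         paste(unknown, collapse = ", "), "; available: ",
         paste(names(base_dist), collapse = ", "), call. = FALSE)
  }

  prob_fun <- function(theta) {
    p <- progeny_distribution(cross, set_free_params(params, parsed, theta))
    # a class can vanish at a parameter boundary (e.g. sac_failure = 0
    # removes the unfertilized class); its probability is then 0, not NA
    po <- as.numeric(p)[match(names(observed), names(p))]
    po[is.na(po)] <- 0
    names(po) <- names(observed)
    po / sum(po)
  }
  negll <- function(theta) {
    po <- prob_fun(theta)
    if (any(!is.finite(po)) || any(po <= 0 & observed > 0)) return(1e10)
    -sum(observed[observed > 0] * log(po[observed > 0]))
  }

  lower <- rep(0, length(free))
  upper <- ifelse(parsed$component == "sac_failure", 1, Inf)
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 10, pgtol = 1e-12))
  est <- opt$par
  if (length(est) == 1L) {
    # golden-section polish: L-BFGS-B's numerical gradient stalls a few
    # parts in 1e5 short of the analytic optimum on 1-d problems
    lo <- max(lower[1], est - 0.25 * (1 + abs(est)))
    hi <- min(upper[1], est + 0.25 * (1 + abs(est)))
    pol <- stats::optimize(negll, c(lo, hi), tol = 1e-10)
    if (pol$objective < opt$value) {
      est <- pol$minimum
      opt$value <- pol$objective
    }
  }
  names(est) <- free

  # multinomial log-likelihood (with combinatorial constant) at the optimum
  ll <- stats::dmultinom(observed, prob = prob_fun(est), log = TRUE)

  # observed information by central differences, respecting the bounds
  hess <- num_hessian(negll, est, lower, upper)
  vc <- matrix(NA_real_, length(est), length(est),
               dimnames = list(free, free))
  at_boundary <- est <= lower + 1e-7 | est >= upper - 1e-7
  identifiable <- TRUE
  if (!any(at_boundary)) {
    ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8 * max(abs(ev), 1)) {
      identifiable <- FALSE
      warning("flat likelihood: parameter set appears non-identifiable ",
              "(observed information is rank-deficient)", call. = FALSE)
    } else {
      vc <- solve(hess)
      dimnames(vc) <- list(free, free)
    }
  }

  structure(list(coefficients = est, logLik = ll, vcov = vc,
                 convergence = opt$convergence == 0,
                 identifiable = identifiable,
                 at_boundary = at_boundary,
                 lower = lower, upper = upper,
                 cross = cross, params = params, parsed = parsed,
                 observed = observed, free = free,
                 fitted_probs = prob_fun(est),
                 negll = negll, n = sum(observed)),
            class = "transfit")
}

# "tau_male[miro1:miro2-2]" -> component + gamete label, validated
parse_free_params <- function(free, loci) {
  if (!length(free) || !is.character(free)) {
    stop("free must name at least one parameter", call. = FALSE)
  }
  m <- regmatches(free,
                  regexec("^(tau_male|tau_female|sac_failure)\\[(.+)\\]$",
                          free))
  bad <- free[vapply(m, length, integer(1)) != 3L]
  if (length(bad)) {
    stop("malformed free parameter name(s): ", paste(bad, collapse = ", "),
         "; expected e.g. 'tau_male[miro1:miro2-2]'", call. = FALSE)
  }
  component <- vapply(m, `[`, character(1), 2L)
  label <- vapply(m, `[`, character(1), 3L)
  check_gamete_labels(label, loci, "free parameter")
  ref <- gamete_label(rep(0L, nrow(loci)), loci)
  if (any(component != "sac_failure" & label == ref)) {
    stop("the all-wild-type gamete's tau is the reference (fixed at 1) ",
         "and cannot be freed", call. = FALSE)
  }
  list(component = component, label = label)
}

set_free_params <- function(params, parsed, theta) {
  for (i in seq_along(theta)) {
    comp <- parsed$component[i]
    params[[comp]][parsed$label[i]] <- theta[i]
  }
  params
}

num_hessian <- function(f, x, lower, upper, eps = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1) * eps
  # keep evaluation points inside the feasible box
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      pp <- pm <- mp <- mm <- x
      pp[i] <- pp[i] + h[i]; pp[j] <- pp[j] + h[j]
      pm[i] <- pm[i] + h[i]; pm[j] <- pm[j] - h[j]
      mp[i] <- mp[i] - h[i]; mp[j] <- mp[j] + h[j]
      mm[i] <- mm[i] - h[i]; mm[j] <- mm[j] - h[j]
      ok <- function(v) all(v >= lower & v <= upper)
      if (!all(vapply(list(pp, pm, mp, mm), ok, logical(1)))) {
        H[i, j] <- H[j, i] <- NA_real_
        next
      }
      H[i, j] <- H[j, i] <-
        (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.transfit <- function(x, ...) {
  cat("Gametophytic transmission fit (maximum likelihood)\n")
  print(x$cross)
  cat("Observed classes (n =", x$n, "):",
      paste(names(x$observed), collapse = ", "), "\n")
  cat("Estimates:\n")
  print(round(x$coefficients, 6))
  if (!x$convergence) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.transfit <- function(object, ...) object$coefficients

#' @export
logLik.transfit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
vcov.transfit <- function(object, ...) object$vcov

#' @export
nobs.transfit <- function(object, ...) object$n

#' @export
fitted.transfit <- function(object, ...) object$fitted_probs

#' Confidence intervals for transmission-fit parameters
#'
#' Default is the profile-likelihood interval (inverting the likelihood-ratio
#' chi-square), which remains valid when an estimate sits on the `tau = 0`
#' boundary, where it degenerates to a one-sided interval. `method = "wald"`
#' uses the observed information instead.
#'
#' @param object a `transfit`.
#' @param parm parameters (names or indices); default all.
#' @param level confidence level.
#' @param method `"profile"` or `"wald"`.
#' @param ... unused.
#' @export
confint.transfit <- function(object, parm = object$free, level = 0.95,
                             method = c("profile", "wald"), ...) {
  method <- match.arg(method)
  if (is.numeric(parm)) parm <- object$free[parm]
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    for (p in parm) {
      se <- sqrt(object$vcov[p, p])
      est <- object$coefficients[[p]]
      i <- match(p, object$free)
      out[p, ] <- pmax(object$lower[i],
                       c(est - z * se, est + z * se))
      out[p, 2] <- min(object$upper[i], out[p, 2])
    }
    return(out)
  }
  crit <- stats::qchisq(level, df = 1)
  ll_hat <- -object$negll(object$coefficients)
  for (p in parm) {
    i <- match(p, object$free)
    out[p, ] <- profile_ci_one(object, i, ll_hat, crit)
  }
  out
}

# profile one free parameter; others re-optimised at each fixed value
profile_ci_one <- function(object, i, ll_hat, crit) {
  est <- object$coefficients
  k <- length(est)
  prof_dev <- function(v) {
    if (k == 1L) {
      th <- est; th[i] <- v
      return(2 * (object$negll(th) + ll_hat))
    }
    inner <- function(rest) {
      th <- est; th[i] <- v; th[-i] <- rest
      object$negll(th)
    }
    o <- stats::optim(est[-i], inner, method = "L-BFGS-B",
                      lower = object$lower[-i], upper = object$upper[-i])
    2 * (o$value + ll_hat)
  }
  root <- function(lo, hi) {
    tryCatch(stats::uniroot(function(v) prof_dev(v) - crit, c(lo, hi),
                            tol = 1e-8)$root,
             error = function(e) NA_real_)
  }
  e <- est[[i]]
  lb <- object$lower[i]; ub <- object$upper[i]
  # lower limit
  lower <- if (e <= lb + 1e-9 || prof_dev(lb) <= crit) lb else
    root(lb, e)
  # upper limit: expand until the deviance crosses the critical value
  hi <- max(2 * max(e, 0.1), e + 1)
  while (is.finite(ub) && hi > ub) hi <- ub
  tries <- 0
  while (prof_dev(min(hi, ub)) < crit && tries < 40 &&
         (!is.finite(ub) || hi < ub)) {
    hi <- hi * 2
    tries <- tries + 1
  }
  hi <- min(hi, ub)
  upper <- if (prof_dev(hi) < crit) hi else root(e, hi)
  c(lower, upper)
}

#' Predicted progeny-class probabilities or counts
#'
#' @param object a `transfit`.
#' @param type `"prob"` for class probabilities (over the scored classes,
#'   or all classes with `conditioned = FALSE`), `"counts"` for expected
#'   counts at total `n`.
#' @param n total count for `type = "counts"`; defaults to the fitted total.
#' @param conditioned restrict to the scored classes (default) or return the
#'   full progeny-class distribution.
#' @param ... unused.
#' @export
predict.transfit <- function(object, type = c("prob", "counts"),
                             n = object$n, conditioned = TRUE, ...) {
  type <- match.arg(type)
  if (conditioned) {
    p <- object$fitted_probs
  } else {
    full <- progeny_distribution(
      object$cross,
      set_free_params(object$params, object$parsed, object$coefficients))
    p <- stats::setNames(as.numeric(full), names(full))
  }
  if (type == "prob") p else p * n
}

#' Simulate progeny-class counts from a fitted transmission model
#'
#' @param object a `transfit`.
#' @param nsim number of replicate count vectors.
#' @param seed optional RNG seed.
#' @param n total progeny per replicate; defaults to the fitted total.
#' @param ... unused.
#' @return Matrix with one column per replicate, rows the scored classes.
#' @export
simulate.transfit <- function(object, nsim = 1, seed = NULL,
                              n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rmultinom(nsim, size = n, prob = object$fitted_probs)
}

#' @export
residuals.transfit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  e <- object$fitted_probs * object$n
  r <- object$observed - e
  if (type == "pearson") r / sqrt(e) else r
}

#' @export
summary.transfit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  ci <- confint(object, level = level)
  tab <- cbind(estimate = object$coefficients, se = se, ci)
  structure(list(fit = object, table = tab, level = level),
            class = "summary.transfit")
}

#' @export
print.summary.transfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nProfile %d%% confidence intervals:\n",
              round(100 * x$level)))
  print(round(x$table, 6))
  cat(sprintf("log-likelihood: %.4f\n", x$fit$logLik))
  if (any(x$fit$at_boundary)) {
    cat("note: estimate(s) on the parameter boundary; SE undefined there,",
        "profile interval is one-sided\n")
  }
  invisible(x)
}
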