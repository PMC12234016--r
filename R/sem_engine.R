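## Two-group structured-covariance ML core. Missing data are handled by
## full-information maximum likelihood: pairs are grouped by missingness
## pattern and each pattern contributes through its sufficient statistics
## (n, sum of observed vectors, raw cross-product), so the cost per
## likelihood evaluation is independent of sample size.

#' Define a structured-covariance model
#'
#' A model spec couples a free-parameter vector to a builder that maps it to
#' per-group mean vectors and covariance matrices. Fitting, likelihood
#' evaluation and standardization all operate on this object.
#'
#' @param name model label used in fit tables.
#' @param par_names character vector naming the free parameters.
#' @param start numeric vector of default starting values.
#' @param lower,upper box bounds for the optimizer (recycled).
#' @param builder function(theta) returning a named list of groups, each a
#'   list with `mu` (length p) and `sigma` (p x p symmetric).
#' @param summarize optional function(theta) returning a named numeric vector
#'   of derived quantities (standardized shares, correlations, ...) for which
#'   delta-method confidence intervals are reported.
#' @param meta free-form list (family, waves, ...).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name, par_names, start, builder, summarize = NULL,
                       lower = -Inf, upper = Inf, meta = list()) {
  k <- length(par_names)
  stopifnot(length(start) == k)
  structure(list(name = name, par_names = par_names,
                 start = stats::setNames(start, par_names),
                 lower = rep_len(lower, k), upper = rep_len(upper, k),
                 builder = builder, summarize = summarize,
                 n_par = k, meta = meta),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': %d free parameters\n", x$name, x$n_par))
  invisible(x)
}

## Sufficient statistics per missingness pattern for one group matrix.
fiml_stats <- function(Y) {
  Y <- as.matrix(Y)
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  pats <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    cols <- which(obs[idx[1], ])
    X <- Y[idx, cols, drop = FALSE]
    list(cols = cols, n = length(idx), sx = colSums(X), sxx = crossprod(X))
  })
  structure(list(patterns = pats, n = nrow(Y), p = ncol(Y),
                 n_cells = sum(obs)),
            class = "fiml_stats")
}

LOG2PI <- log(2 * pi)
FIML_PENALTY <- 1e10

## -2 log likelihood of one group given model mu/sigma and pattern stats.
n2ll_group <- function(mu, sigma, st) {
  total <- 0
  for (pt in st$patterns) {
    ms <- mu[pt$cols]
    Ss <- sigma[pt$cols, pt$cols, drop = FALSE]
    ch <- tryCatch(chol(Ss), error = function(e) NULL)
    if (is.null(ch)) return(FIML_PENALTY)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    Sc <- pt$sxx - tcrossprod(pt$sx, ms) - tcrossprod(ms, pt$sx) +
      pt$n * tcrossprod(ms)
    total <- total + pt$n * (length(pt$cols) * LOG2PI + logdet) + sum(Sinv * Sc)
  }
  total
}

as_group_stats <- function(data) {
  if (inherits(data, "twin_dataset")) data <- twin_matrices(data)
  if (is.matrix(data) || is.data.frame(data)) data <- list(all = as.matrix(data))
  if (inherits(data, "fiml_stats")) return(list(all = data))
  if (all(vapply(data, inherits, TRUE, "fiml_stats"))) return(data)
  lapply(data, fiml_stats)
}

#' FIML -2 log likelihood of a model at given parameter values
#'
#' Sums, over zygosity groups and missingness patterns, minus twice the log
#' multivariate-normal density of each pair's observed subvector. A
#' non-positive-definite observed submatrix yields a large penalty value
#' (keeping the optimizer inside the feasible region) rather than an error.
#'
#' @param spec a `model_spec`.
#' @param theta parameter vector.
#' @param data a `twin_dataset`, a named list of per-group score matrices, or
#'   precomputed `fiml_stats` (list thereof).
#' @return scalar -2 log likelihood.
#' @export
neg2_loglik <- function(spec, theta, data) {
  st <- as_group_stats(data)
  gm <- spec$builder(theta)
  total <- 0
  for (g in names(st)) {
    if (is.null(gm[[g]])) stop("model builder has no group '", g, "'")
    total <- total + n2ll_group(gm[[g]]$mu, gm[[g]]$sigma, st[[g]])
  }
  total
}

fingerprint_stats <- function(st) {
  list(groups = names(st),
       n = vapply(st, `[[`, 0, "n"),
       cells = vapply(st, `[[`, 0, "n_cells"),
       sum = vapply(st, function(s)
         sum(vapply(s$patterns, function(pt) sum(pt$sx), 0)), 0))
}

make_starts <- function(spec, n_starts, seed) {
  starts <- list(spec$start)
  if (n_starts > 1) {
    set.seed(seed)
    for (i in seq_len(n_starts - 1)) {
      s <- spec$start * (1 + 0.3 * stats::rnorm(spec$n_par)) +
        0.05 * stats::rnorm(spec$n_par)
      starts[[i + 1]] <- pmin(pmax(s, spec$lower + 1e-6), spec$upper - 1e-6)
    }
  }
  starts
}

#' Fit a structured-covariance model by FIML
#'
#' Quasi-Newton minimization (`nlminb`) of the FIML -2 log likelihood from
#' multiple jittered starting points; the best converged start wins, ties
#' (within 1e-6) broken in favour of the first. Standard errors come from the
#' numerical Hessian; confidence intervals for the derived quantities in
#' `spec$summarize` use the delta method.
#'
#' @param spec a `model_spec`.
#' @param data a `twin_dataset`, named list of group matrices, or `fiml_stats`.
#' @param n_starts number of starting points (first is `spec$start`).
#' @param seed RNG seed for start jitter.
#' @param se compute standard errors / delta-method CIs (default TRUE).
#' @param level confidence level for intervals.
#' @return an object of class `twin_fit` with elements `par`, `minus2LL`,
#'   `df`, `AIC`, `se`, `vcov`, `summary` (data.frame of derived quantities
#'   with CIs) and convergence diagnostics. `df` is the number of observed
#'   data cells minus the number of free parameters; AIC = -2LL + 2k.
#' @export
fit_model <- function(spec, data, n_starts = 5, seed = 1, se = TRUE,
                      level = 0.95) {
  st <- as_group_stats(data)
  obj <- function(theta) neg2_loglik(spec, theta, st)
  runs <- lapply(make_starts(spec, n_starts, seed), function(s0)
    tryCatch(stats::nlminb(s0, obj, lower = spec$lower, upper = spec$upper,
                           control = list(iter.max = 1000, eval.max = 4000)),
             error = function(e) list(objective = Inf, convergence = 99,
                                      message = conditionMessage(e))))
  objs <- vapply(runs, function(r) r$objective, 0)
  if (all(!is.finite(objs)) || min(objs) >= FIML_PENALTY / 2) {
    diag_tab <- data.frame(start = seq_along(runs), objective = objs,
                           code = vapply(runs, function(r) r$convergence %||% NA_integer_, 0L))
    stop("no start converged to a feasible optimum; per-start diagnostics:\n",
         paste(utils::capture.output(print(diag_tab)), collapse = "\n"))
  }
  best_i <- which(objs <= min(objs) + 1e-6)[1]
  best <- runs[[best_i]]
  theta <- stats::setNames(best$par, spec$par_names)
  m2ll <- best$objective
  n_cells <- sum(vapply(st, `[[`, 0, "n_cells"))
  k <- spec$n_par
  vcov <- se_vec <- NULL
  summ <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vcov)) {
        dv <- diag(vcov)
        se_vec <- stats::setNames(sqrt(pmax(dv, 0)), spec$par_names)
      }
    }
  }
  if (!is.null(spec$summarize)) {
    est <- spec$summarize(theta)
    qz <- stats::qnorm(1 - (1 - level) / 2)
    if (!is.null(vcov)) {
      J <- num_jacobian(spec$summarize, theta)
      vv <- diag(J %*% vcov %*% t(J))
      s <- sqrt(pmax(vv, 0))
    } else s <- rep(NA_real_, length(est))
    summ <- data.frame(quantity = names(est), estimate = unname(est),
                       se = unname(s), lo = unname(est - qz * s),
                       hi = unname(est + qz * s))
  }
  structure(list(name = spec$name, par = theta, minus2LL = m2ll,
                 k = k, df = n_cells - k, AIC = m2ll + 2 * k,
                 n_obs = vapply(st, `[[`, 0, "n"), n_cells = n_cells,
                 se = se_vec, vcov = vcov, summary = summ,
                 convergence = list(code = best$convergence,
                                    message = best$message %||% "",
                                    start_objectives = objs,
                                    best_start = best_i),
                 spec = spec, fingerprint = fingerprint_stats(st)),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s: -2LL = %.3f, df = %d, AIC = %.3f (k = %d)\n",
              x$name, x$minus2LL, x$df, x$AIC, x$k))
  if (!is.null(x$summary)) {
    s <- x$summary
    s[-1] <- lapply(s[-1], round, digits)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Standardized quantities of a fitted model
#'
#' Returns the derived-quantity table (variance-component shares, genetic and
#' environmental correlations, communalities, ...) computed by the model's
#' `summarize` mapping at the fitted parameters, with delta-method CIs.
#'
#' @param fit a `twin_fit`.
#' @return data.frame with columns quantity, estimate, se, lo, hi.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  if (is.null(fit$summary)) stop("model has no summarize mapping")
  fit$summary
}

## Pairwise-complete covariance with an eigenvalue floor, for starting values.
safe_cov <- function(Y, floor = 1e-3) {
  S <- suppressWarnings(stats::cov(Y, use = "pairwise.complete.obs"))
  S[is.na(S)] <- 0
  ev <- eigen(S, symmetric = TRUE)
  d <- pmax(ev$values, floor)
  ev$vectors %*% diag(d, length(d)) %*% t(ev$vectors)
}

sym_index <- function(p) which(lower.tri(matrix(0, p, p), diag = TRUE))

sym_vec2mat <- function(x, p) {
  M <- matrix(0, p, p)
  M[sym_index(p)] <- x
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

#' Saturated (unstructured) baseline fit
#'
#' Unstructured means and covariances per zygosity group. With
#' `constrained = TRUE`, means and within-twin covariance blocks are equated
#' across twins and zygosity groups and the cross-twin block of each group is
#' forced symmetric, the baseline used for twin-model fit comparison. With
#' complete data and no constraints the ML solution is the closed-form sample
#' moments; otherwise the model is optimized like any other spec.
#'
#' @param data a `twin_dataset` or named list of group score matrices.
#' @param constrained impose twin/zygosity equality and symmetry constraints.
#' @param ... passed to [fit_model()] when optimization is needed.
#' @return a `twin_fit`.
#' @export
saturated_fit <- function(data, constrained = FALSE, ...) {
  st <- as_group_stats(data)
  p <- st[[1]]$p
  complete <- all(vapply(st, function(s) length(s$patterns) == 1 &&
                           length(s$patterns[[1]]$cols) == p, TRUE))
  if (!constrained && complete) {
    m2ll <- 0; k <- 0
    for (s in st) {
      pt <- s$patterns[[1]]
      mu <- pt$sx / pt$n
      S <- pt$sxx / pt$n - tcrossprod(mu)
      m2ll <- m2ll + pt$n * (p * LOG2PI + determinant(S)$modulus[1] + p)
      k <- k + p + p * (p + 1) / 2
    }
    n_cells <- sum(vapply(st, `[[`, 0, "n_cells"))
    return(structure(list(name = "saturated", par = NULL, minus2LL = m2ll,
                          k = k, df = n_cells - k, AIC = m2ll + 2 * k,
                          n_obs = vapply(st, `[[`, 0, "n"), n_cells = n_cells,
                          se = NULL, vcov = NULL, summary = NULL,
                          convergence = list(code = 0, message = "closed form"),
                          spec = NULL, fingerprint = fingerprint_stats(st)),
                     class = "twin_fit"))
  }
  spec <- if (constrained) build_saturated_constrained(st)
          else build_saturated_free(st)
  fit_model(spec, st, ...)
}

## Free saturated model: per-group means + Cholesky-factor covariance.
build_saturated_free <- function(st) {
  p <- st[[1]]$p
  groups <- names(st)
  nlt <- p * (p + 1) / 2
  par_names <- start <- NULL
  for (g in groups) {
    pt_all <- st[[g]]$patterns
    Y_mu <- rep(0, p); cnt <- rep(0, p)
    for (pt in pt_all) { Y_mu[pt$cols] <- Y_mu[pt$cols] + pt$sx
                         cnt[pt$cols] <- cnt[pt$cols] + pt$n }
    mu0 <- ifelse(cnt > 0, Y_mu / pmax(cnt, 1), 0)
    S0 <- sat_start_cov(st[[g]], mu0)
    L0 <- t(chol(S0))
    par_names <- c(par_names, sprintf("%s_mu%d", g, 1:p),
                   sprintf("%s_L%d", g, seq_len(nlt)))
    start <- c(start, mu0, lt_mat2vec(L0))
  }
  idx <- split(seq_along(par_names), rep(groups, each = p + nlt))
  builder <- function(theta) {
    out <- list()
    for (g in groups) {
      th <- theta[idx[[g]]]
      L <- lt_vec2mat(th[(p + 1):(p + nlt)], p)
      out[[g]] <- list(mu = th[1:p], sigma = tcrossprod(L))
    }
    out
  }
  model_spec("saturated", par_names, start, builder,
             meta = list(structure = "saturated", constrained = FALSE))
}

sat_start_cov <- function(s, mu0) {
  p <- s$p
  S <- diag(1, p)
  acc <- matrix(0, p, p); cnt <- matrix(0, p, p)
  for (pt in s$patterns) {
    cs <- pt$cols
    Sc <- pt$sxx - tcrossprod(pt$sx, mu0[cs]) - tcrossprod(mu0[cs], pt$sx) +
      pt$n * tcrossprod(mu0[cs])
    acc[cs, cs] <- acc[cs, cs] + Sc
    cnt[cs, cs] <- cnt[cs, cs] + pt$n
  }
  S <- acc / pmax(cnt, 1)
  S[cnt == 0] <- 0
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(pmax(ev$values, 1e-3), p) %*% t(ev$vectors)
}

## Constrained saturated twin model: q phenotype means shared by both twins
## and groups, one within-twin covariance block, and a symmetric cross-twin
## block per zygosity group.
build_saturated_constrained <- function(st) {
  p <- st[[1]]$p
  stopifnot(p %% 2 == 0, all(c("MZ", "DZ") %in% names(st)))
  q <- p / 2
  nsym <- q * (q + 1) / 2
  mu_all <- rep(0, p); cnt <- rep(0, p)
  for (g in names(st)) for (pt in st[[g]]$patterns) {
    mu_all[pt$cols] <- mu_all[pt$cols] + pt$sx
    cnt[pt$cols] <- cnt[pt$cols] + pt$n
  }
  mu0 <- ifelse(cnt > 0, mu_all / pmax(cnt, 1), 0)
  mu_q <- (mu0[1:q] + mu0[(q + 1):p]) / 2
  S0 <- sat_start_cov(st[["MZ"]], mu0)
  W0 <- (S0[1:q, 1:q] + S0[(q + 1):p, (q + 1):p]) / 2
  C0 <- (S0[1:q, (q + 1):p] + t(S0[1:q, (q + 1):p])) / 2 * 0.5
  par_names <- c(sprintf("mu%d", 1:q), sprintf("W%d", seq_len(nsym)),
                 sprintf("Cmz%d", seq_len(nsym)), sprintf("Cdz%d", seq_len(nsym)))
  start <- c(mu_q, W0[sym_index(q)], C0[sym_index(q)], (0.5 * C0)[sym_index(q)])
  builder <- function(theta) {
    mu <- rep(theta[1:q], 2)
    Wm <- sym_vec2mat(theta[q + seq_len(nsym)], q)
    Cmz <- sym_vec2mat(theta[q + nsym + seq_len(nsym)], q)
    Cdz <- sym_vec2mat(theta[q + 2 * nsym + seq_len(nsym)], q)
    list(MZ = list(mu = mu, sigma = rbind(cbind(Wm, Cmz), cbind(Cmz, Wm))),
         DZ = list(mu = mu, sigma = rbind(cbind(Wm, Cdz), cbind(Cdz, Wm))))
  }
  model_spec("saturated (constrained)", par_names, start, builder,
             meta = list(structure = "saturated", constrained = TRUE))
}

#' Profile-likelihood confidence interval for one free parameter
#'
#' Finds the parameter values at which the profiled -2 log likelihood rises
#' by the chi-square(1) quantile, re-optimizing all other parameters.
#'
#' @param fit a converged `twin_fit` (fitted with `se = TRUE`).
#' @param data the data the model was fitted to.
#' @param par name of the free parameter.
#' @param level confidence level.
#' @return numeric vector c(lo, hi).
#' @export
profile_ci <- function(fit, data, par, level = 0.95) {
  spec <- fit$spec
  j <- match(par, spec$par_names)
  if (is.na(j)) stop("unknown parameter: ", par)
  st <- as_group_stats(data)
  crit <- fit$minus2LL + stats::qchisq(level, 1)
  prof <- function(val) {
    sp <- spec
    fix_builder <- sp$builder
    sp$builder <- function(th) {
      full <- numeric(spec$n_par)
      full[-j] <- th; full[j] <- val
      fix_builder(full)
    }
    sp$par_names <- spec$par_names[-j]
    sp$start <- fit$par[-j]
    sp$lower <- spec$lower[-j]; sp$upper <- spec$upper[-j]
    sp$n_par <- spec$n_par - 1
    r <- stats::nlminb(sp$start, function(th) neg2_loglik(sp, th, st),
                       lower = sp$lower, upper = sp$upper)
    r$objective
  }
  step <- max(fit$se[j], 0.05, na.rm = TRUE)
  root_side <- function(dir) {
    lo <- fit$par[j]; hi <- fit$par[j] + dir * step
    for (i in 1:30) {
      if (prof(hi) >= crit) break
      lo <- hi; hi <- hi + dir * step
    }
    if (prof(hi) < crit) return(dir * Inf)
    stats::uniroot(function(v) prof(v) - crit, sort(c(lo, hi)))$root
  }
  c(lo = root_side(-1), hi = root_side(1))
}
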