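#' MCMC chain settings
#'
#' Presets: `"full"` = 300000 samples, 250000 burn-in, thin 10 (the
#' full-scale analysis setting); `"test"` = 4000/1000/5 (desk-scale fits);
#' `"quick"` = 2000/500/5 (replicated validation schemes, where many fits
#' are averaged and short well-mixing chains suffice); `"oracle"` =
#' 20000/5000/5 (closed-form comparison runs).
#'
#' @param preset one of `"test"`, `"quick"`, `"oracle"`, `"full"`, or
#'   `NULL` to give the numbers directly.
#' @param n_iter,burn_in,thin chain length, discarded samples, keep-every.
#' @param seed integer seed for the chain.
#' @return object of class `chain_settings`.
#' @export
chain_settings <- function(preset = "test", n_iter = NULL, burn_in = NULL,
                           thin = NULL, seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("test", "quick", "oracle", "full"))
    p <- switch(preset,
                test = c(4000L, 1000L, 5L),
                quick = c(2000L, 500L, 5L),
                oracle = c(20000L, 5000L, 5L),
                full = c(300000L, 250000L, 10L))
    n_iter <- n_iter %||% p[1L]
    burn_in <- burn_in %||% p[2L]
    thin <- thin %||% p[3L]
  }
  stopifnot(is_count(n_iter), is_count(burn_in, 0), is_count(thin))
  if (burn_in >= n_iter) stop_config("burn_in must be smaller than n_iter")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_settings")
}

## Eigendecomposition of a relationship kernel with PSD repair: +1e-8
## diagonal jitter, eigenvalues below 1e-10 truncated.  Errors if the
## kernel is indefinite beyond jitter tolerance.
kernel_eigen <- function(K, jitter = 1e-8, tol = 1e-10) {
  n <- nrow(K)
  eig <- eigen(K + diag(jitter, n), symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop_config("kernel is not positive semi-definite beyond jitter tolerance")
  keep <- eig$values > tol
  list(U = eig$vectors[, keep, drop = FALSE], d = eig$values[keep])
}

## Batch-means effective sample size of one chain of draws.
ess_batch <- function(x) {
  n <- length(x)
  if (n < 16L || stats::var(x) < 1e-300) return(n)
  b <- max(floor(sqrt(n)), 2L)
  nb <- floor(n / b)
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  mcse2 <- stats::var(bm) / nb
  if (mcse2 <= 0) return(n)
  min(n, stats::var(x) / mcse2)
}

## Generic Gibbs sampler for y = mu + sum_t u_t + e, where each term is
## either an eigendecomposed Gaussian-process kernel (u = U a,
## a_k ~ N(0, d_k sigma2_t), so every coordinate update is diagonal) or an
## iid grouped effect.  Missing responses are data-augmented each sweep, so
## unphenotyped entries receive joint-kernel predictions.  Variances carry
## scaled-inverse-chi-square priors (df `prior_df`, scale set so each
## random term's prior mode takes an equal share of half the sample
## phenotypic variance); `fixed_var` pins any of them for oracle runs.
gibbs_sampler <- function(y, terms, chain, fixed_var = NULL, prior_df = 5) {
  n <- length(y)
  miss <- which(is.na(y))
  obs <- setdiff(seq_len(n), miss)
  set.seed(chain$seed)
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1
  y[miss] <- mean(y[obs])
  nt <- length(terms)
  r2_each <- 0.5 / nt
  df0 <- prior_df

  s2 <- numeric(nt)
  S0 <- numeric(nt)
  for (t in seq_len(nt)) {
    md <- if (terms[[t]]$type == "kernel")
      sum(terms[[t]]$d) / n else 1
    s2[t] <- vy * r2_each / md
    S0[t] <- s2[t] * (df0 + 2) / df0
  }
  se2 <- vy * 0.5
  Se0 <- se2 * (df0 + 2) / df0
  fix_t <- rep(NA_real_, nt)
  fix_e <- NA_real_
  if (!is.null(fixed_var)) {
    for (t in seq_len(nt)) {
      lb <- terms[[t]]$label
      if (!is.null(fixed_var[[lb]])) fix_t[t] <- s2[t] <- fixed_var[[lb]]
    }
    if (!is.null(fixed_var$sigma_e2)) fix_e <- se2 <- fixed_var$sigma_e2
  }

  u <- lapply(terms, function(t) numeric(n))
  coefs <- lapply(terms, function(t)
    numeric(if (t$type == "kernel") length(t$d) else t$n_levels))
  total_u <- numeric(n)
  mu <- mean(y)

  kept <- floor((chain$n_iter - chain$burn_in) / chain$thin)
  var_samp <- matrix(NA_real_, kept, nt + 1L,
                     dimnames = list(NULL, c(vapply(terms, `[[`, "", "label"),
                                             "sigma_e2")))
  mu_sum <- 0
  u_sum <- lapply(terms, function(t) numeric(n))
  eff_sum <- lapply(terms, function(t)
    if (t$type == "iid") numeric(t$n_levels) else NULL)
  ksave <- 0L

  for (it in seq_len(chain$n_iter)) {
    if (length(miss)) {
      y[miss] <- mu + total_u[miss] + stats::rnorm(length(miss), 0, sqrt(se2))
    }
    mu <- stats::rnorm(1L, mean(y - total_u), sqrt(se2 / n))
    for (t in seq_len(nt)) {
      tm <- terms[[t]]
      r <- y - mu - total_u + u[[t]]
      if (tm$type == "kernel") {
        tv <- tm$tmult(r)
        prec <- 1 / se2 + 1 / (tm$d * s2[t])
        a <- stats::rnorm(length(tv), (tv / se2) / prec, sqrt(1 / prec))
        coefs[[t]] <- a
        new_u <- tm$emult(a)
        ss <- sum(a * a / tm$d)
        k_t <- length(a)
      } else {
        sums <- rowsum(r, tm$index, reorder = TRUE)[, 1L]
        prec <- tm$level_n / se2 + 1 / s2[t]
        eff <- stats::rnorm(tm$n_levels, (sums / se2) / prec, sqrt(1 / prec))
        coefs[[t]] <- eff
        new_u <- eff[tm$index]
        ss <- sum(eff * eff)
        k_t <- tm$n_levels
      }
      total_u <- total_u - u[[t]] + new_u
      u[[t]] <- new_u
      if (is.na(fix_t[t])) {
        s2[t] <- (df0 * S0[t] + ss) / stats::rchisq(1L, df0 + k_t)
      }
    }
    if (is.na(fix_e)) {
      e <- y - mu - total_u
      se2 <- (df0 * Se0 + sum(e * e)) / stats::rchisq(1L, df0 + n)
    }
    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0L) {
      ksave <- ksave + 1L
      var_samp[ksave, ] <- c(s2, se2)
      mu_sum <- mu_sum + mu
      for (t in seq_len(nt)) {
        u_sum[[t]] <- u_sum[[t]] + u[[t]]
        if (terms[[t]]$type == "iid")
          eff_sum[[t]] <- eff_sum[[t]] + coefs[[t]]
      }
    }
  }
  list(mu = mu_sum / ksave,
       u_hat = lapply(u_sum, function(v) v / ksave),
       eff_hat = lapply(eff_sum, function(v) if (is.null(v)) NULL else v / ksave),
       var_hat = colMeans(var_samp),
       var_samples = var_samp,
       ess = apply(var_samp, 2, ess_batch),
       n_kept = ksave)
}

#' Fit the single-environment GBLUP model (SM) by Gibbs sampling
#'
#' Model: y_j = mu + g_j + e_j with g ~ MN(0, G sigma_g2) and independent
#' normal residuals; the response is the vector of stage-one line BLUPs of
#' one environment (or the across-location BLUPs of one year).  Lines whose
#' response is `NA` are carried as missing and receive GEBVs through the
#' joint relationship kernel.
#'
#' @param y named numeric vector of line responses (`NA` = genotyped but
#'   unphenotyped), or a data frame with columns `line_id`, `value`.
#' @param G a `genomic_relationship` object (or bare matrix) covering all
#'   lines in `y`.
#' @param chain a [chain_settings()] object.
#' @param fixed_var optional list pinning `sigma_g2` and/or `sigma_e2`
#'   (no variance sampling for the pinned components).
#' @param prior_df scaled-inverse-chi-square prior degrees of freedom.
#' @return object of class `sm_fit`: `mu`, `g_hat` (named, every line),
#'   `sigma_g2`, `sigma_e2`, `ess`, `var_samples`, `chain`.
#' @export
fit_sm <- function(y, G, chain = chain_settings("test"), fixed_var = NULL,
                   prior_df = 5) {
  if (is.data.frame(y)) y <- stats::setNames(y$value, y$line_id)
  if (is.null(names(y))) stop_config("y must be named by line id")
  if (sum(!is.na(y)) < 10L)
    stop_config("fewer than 10 phenotyped lines; refusing to fit")
  GM <- as_grm_matrix(G)
  missing_lines <- setdiff(names(y), rownames(GM))
  if (length(missing_lines))
    stop_config("line(s) absent from G: %s",
                paste(utils::head(missing_lines, 5), collapse = ", "))
  K <- GM[names(y), names(y)]
  eig <- kernel_eigen(K)
  term <- list(label = "sigma_g2", type = "kernel", d = eig$d,
               tmult = function(r) as.vector(crossprod(eig$U, r)),
               emult = function(a) as.vector(eig$U %*% a))
  out <- gibbs_sampler(unname(y), list(term), chain,
                       fixed_var = fixed_var, prior_df = prior_df)
  structure(list(line_ids = names(y), mu = out$mu,
                 g_hat = stats::setNames(out$u_hat[[1L]], names(y)),
                 sigma_g2 = out$var_hat[["sigma_g2"]],
                 sigma_e2 = out$var_hat[["sigma_e2"]],
                 ess = out$ess, var_samples = out$var_samples,
                 chain = chain, n_obs = sum(!is.na(y))),
            class = "sm_fit")
}

#' Dense reaction-norm interaction kernel (reference form)
#'
#' Builds \[Z_g G Z_g'\] Hadamard \[Z_E Z_E'\] explicitly for a set of
#' records: the genetic kernel expanded to record level, zeroed wherever
#' two records come from different environments.  [fit_mm()] uses an
#' equivalent structured eigendecomposition; this dense form is the
#' reference it is verified against.
#'
#' @param G genomic relationship (object or matrix).
#' @param line_idx character/integer vector mapping records to G rows.
#' @param env vector mapping records to environments.
#' @return dense records x records matrix.
#' @export
interaction_kernel <- function(G, line_idx, env) {
  GM <- as_grm_matrix(G)
  Kg <- GM[line_idx, line_idx, drop = FALSE]
  same_env <- outer(env, env, "==")
  Kg * same_env
}

#' Fit the multi-environment reaction-norm model (MM) by Gibbs sampling
#'
#' Model: y_ij = mu + E_i + g_j + gE_ij + e_ij with E ~ NIID(0, sigma_E2),
#' g ~ MN(0, Z_g G Z_g' sigma_g2) and gE ~ MN(0, \[Z_g G Z_g'\] Hadamard
#' \[Z_E Z_E'\] sigma_gE2).  Internally the sampler completes the
#' line-by-environment grid, carries unobserved cells as missing responses
#' (data augmentation), and uses the structured eigendecomposition of the
#' two kernels implied by eigen(G), so every update is diagonal.
#'
#' @param cells data frame with columns `line_id`, `env`, `value`
#'   (`NA` value = cell to predict; lines absent from `cells` but wanted in
#'   the output can be passed with `NA` values in any one environment).
#' @param G genomic relationship covering all lines.
#' @inheritParams fit_sm
#' @return object of class `mm_fit`: `mu`, `E_hat` (named by environment),
#'   `g_hat` (named by line), `gE_hat` (lines x environments), posterior
#'   mean variances (`sigma_E2`, `sigma_g2`, `sigma_gE2`, `sigma_e2`),
#'   `ess`, `var_samples`, `chain`.
#' @export
fit_mm <- function(cells, G, chain = chain_settings("test"),
                   fixed_var = NULL, prior_df = 5) {
  stopifnot(all(c("line_id", "env", "value") %in% names(cells)))
  envs <- sort(unique(as.character(cells$env)))
  if (length(envs) < 2L)
    stop_config("only one environment; use fit_sm() for a stratified analysis")
  lines <- sort(unique(as.character(cells$line_id)))
  if (anyDuplicated(paste(cells$line_id, cells$env)))
    stop_config("duplicate line-environment cell(s); supply one BLUP per cell")
  GM <- as_grm_matrix(G)
  missing_lines <- setdiff(lines, rownames(GM))
  if (length(missing_lines))
    stop_config("line(s) absent from G: %s",
                paste(utils::head(missing_lines, 5), collapse = ", "))
  L <- length(lines); E <- length(envs)
  ## complete grid, environment-major: record (i-1)*L + j  <->  env i, line j
  y <- rep(NA_real_, L * E)
  li <- match(as.character(cells$line_id), lines)
  ei <- match(as.character(cells$env), envs)
  y[(ei - 1L) * L + li] <- cells$value
  if (sum(!is.na(y)) < 10L)
    stop_config("fewer than 10 phenotyped cells; refusing to fit")

  eig <- kernel_eigen(GM[lines, lines])
  U <- eig$U; dG <- eig$d; kG <- length(dG)
  term_E <- list(label = "sigma_E2", type = "iid",
                 index = rep(seq_len(E), each = L),
                 n_levels = E, level_n = rep(L, E))
  term_g <- list(label = "sigma_g2", type = "kernel", d = E * dG,
                 tmult = function(r) as.vector(crossprod(U, rowSums(matrix(r, L, E)))) / sqrt(E),
                 emult = function(a) rep(as.vector(U %*% a), E) / sqrt(E))
  term_ge <- list(label = "sigma_gE2", type = "kernel", d = rep(dG, E),
                  tmult = function(r) as.vector(crossprod(U, matrix(r, L, E))),
                  emult = function(a) as.vector(U %*% matrix(a, kG, E)))
  out <- gibbs_sampler(y, list(term_E, term_g, term_ge), chain,
                       fixed_var = fixed_var, prior_df = prior_df)
  g_hat <- stats::setNames(out$u_hat[[2L]][seq_len(L)], lines)
  gE_hat <- matrix(out$u_hat[[3L]], L, E, dimnames = list(lines, envs))
  structure(list(lines = lines, envs = envs, mu = out$mu,
                 E_hat = stats::setNames(out$eff_hat[[1L]], envs),
                 g_hat = g_hat, gE_hat = gE_hat,
                 sigma_E2 = out$var_hat[["sigma_E2"]],
                 sigma_g2 = out$var_hat[["sigma_g2"]],
                 sigma_gE2 = out$var_hat[["sigma_gE2"]],
                 sigma_e2 = out$var_hat[["sigma_e2"]],
                 ess = out$ess, var_samples = out$var_samples,
                 chain = chain, n_obs = sum(!is.na(y))),
            class = "mm_fit")
}

#' @export
print.sm_fit <- function(x, ...) {
  cat("sm_fit:", length(x$g_hat), "lines (", x$n_obs, "phenotyped ), mu =",
      format(x$mu, digits = 4), "\n")
  cat("  sigma_g2 =", format(x$sigma_g2, digits = 4),
      " sigma_e2 =", format(x$sigma_e2, digits = 4), "\n")
  invisible(x)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("mm_fit:", length(x$g_hat), "lines x", length(x$envs), "environments (",
      x$n_obs, "cells observed )\n")
  cat("  sigma_E2 =", format(x$sigma_E2, digits = 4),
      " sigma_g2 =", format(x$sigma_g2, digits = 4),
      " sigma_gE2 =", format(x$sigma_gE2, digits = 4),
      " sigma_e2 =", format(x$sigma_e2, digits = 4), "\n")
  invisible(x)
}

#' Predicted values (GEBVs) from a fitted model
#'
#' For the SM: mu + g.  For the MM with an environment given:
#' mu + E_i + g + gE; without an environment (a line in a year whose
#' trials are absent from the training data) the main-effect prediction
#' mu + g is returned.
#'
#' @param fit an `sm_fit` or `mm_fit`.
#' @param lines line ids to predict (default: all lines in the fit).
#' @param environment optional environment label (MM only).
#' @return named numeric vector of predictions.
#' @export
predict_gebv <- function(fit, lines = NULL, environment = NULL) {
  if (inherits(fit, "sm_fit")) {
    lines <- lines %||% fit$line_ids
    unknown <- setdiff(lines, fit$line_ids)
    if (length(unknown)) stop_config("unknown line id(s): %s",
                                     paste(utils::head(unknown, 5), collapse = ", "))
    return(fit$mu + fit$g_hat[lines])
  }
  if (inherits(fit, "mm_fit")) {
    lines <- lines %||% fit$lines
    unknown <- setdiff(lines, fit$lines)
    if (length(unknown)) stop_config("unknown line id(s): %s",
                                     paste(utils::head(unknown, 5), collapse = ", "))
    if (is.null(environment)) return(fit$mu + fit$g_hat[lines])
    if (!environment %in% fit$envs)
      stop_config("unknown environment '%s'", environment)
    return(fit$mu + fit$E_hat[[environment]] + fit$g_hat[lines] +
             fit$gE_hat[lines, environment])
  }
  stop_config("fit must be an sm_fit or mm_fit")
}

#' Prediction accuracy r_MG
#'
#' Pearson correlation between observed and predicted phenotypes.  If both
#' vectors are named they are aligned by line id; pairs with a missing
#' entry are dropped with a message.
#'
#' @param observed,predicted numeric vectors (optionally named).
#' @return correlation, or `NA` with a warning when either vector has zero
#'   variance.
#' @export
pearson_accuracy <- function(observed, predicted) {
  if (!is.null(names(observed)) && !is.null(names(predicted))) {
    common <- intersect(names(observed), names(predicted))
    observed <- observed[common]
    predicted <- predicted[common]
  }
  if (length(observed) != length(predicted))
    stop_config("observed and predicted lengths differ")
  ok <- is.finite(observed) & is.finite(predicted)
  if (any(!ok)) message("dropping ", sum(!ok), " pair(s) with missing entries")
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3L) stop_config("need at least 3 paired finite values")
  if (stats::sd(observed) < 1e-12 || stats::sd(predicted) < 1e-12) {
    warning("zero variance in observed or predicted; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}
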