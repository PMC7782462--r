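#' Broad-sense heritability, within one environment
#'
#' Repeatability form H2 = sigma_g2 / (sigma_g2 + sigma_e2 / r), with r the
#' number of replicates per line in the environment.
#'
#' @param sigma_g2 genotypic variance.
#' @param sigma_e2 error variance.
#' @param r number of replications.
#' @return proportion in \[0, 1\].
#' @export
h2_within <- function(sigma_g2, sigma_e2, r) {
  stopifnot(r >= 1, sigma_g2 >= 0, sigma_e2 >= 0)
  den <- sigma_g2 + sigma_e2 / r
  if (den <= 0) stop_config("heritability undefined: zero total variance")
  sigma_g2 / den
}

#' Broad-sense heritability, across locations
#'
#' H2 = sigma_g2 / (sigma_g2 + sigma_gE2 / n + sigma_e2 / (n r)), with n the
#' number of environments and r the number of replications.  With n = 1 and
#' sigma_gE2 = 0 it reduces to [h2_within()].
#'
#' @param sigma_g2 genotypic variance.
#' @param sigma_gE2 genotype-by-environment variance.
#' @param sigma_e2 error variance.
#' @param n number of environments.
#' @param r number of replications.
#' @return proportion in \[0, 1\].
#' @export
h2_across <- function(sigma_g2, sigma_gE2, sigma_e2, n, r) {
  stopifnot(n >= 1, r >= 1, sigma_g2 >= 0, sigma_gE2 >= 0, sigma_e2 >= 0)
  den <- sigma_g2 + sigma_gE2 / n + sigma_e2 / (n * r)
  if (den <= 0) stop_config("heritability undefined: zero total variance")
  sigma_g2 / den
}

env_id <- function(year, location) paste(year, location, sep = "_")

## Degenerate (noise-free) data make REML ill-posed; detect exact replicate
## agreement and return centred line means directly.
noise_free_blup <- function(dat) {
  mns <- tapply(dat$value, dat$line_id, mean)
  data.frame(line_id = names(mns), blup = as.numeric(mns - mean(mns)),
             stringsAsFactors = FALSE)
}

#' Stage-one BLUP for one environment
#'
#' Fits the standard incomplete-block (alpha-lattice) analysis for a single
#' year-location trial by REML: replicate fixed, block nested in replicate
#' random, line random.  Returns shrunken (BLUP) line effects and the
#' variance components needed for [h2_within()].  Negative component
#' estimates are floored at zero by the REML fit itself.
#'
#' @param pheno plot-level phenotype table (`line_id`, `year`, `location`,
#'   `rep`, `block`, `value`).
#' @param environment environment label `"year_location"`.
#' @return list: `blups` (data frame `line_id`, `blup`), `vc` (list
#'   `sigma_g2`, `sigma_e2`, `n_env = 1`, `n_reps`), `H2`.
#' @export
fit_environment_blup <- function(pheno, environment) {
  dat <- pheno[env_id(pheno$year, pheno$location) == environment, , drop = FALSE]
  if (!nrow(dat)) stop_config("no records for environment %s", environment)
  if (length(unique(dat$line_id)) < 2L)
    stop_config("need >= 2 lines in environment %s", environment)
  r <- max(tapply(dat$rep, dat$line_id, function(x) length(unique(x))))
  rep_sd <- tapply(dat$value, dat$line_id, stats::sd)
  if (all(is.na(rep_sd) | rep_sd < 1e-12)) {
    blups <- noise_free_blup(dat)
    vc <- list(sigma_g2 = stats::var(blups$blup), sigma_e2 = 0,
               n_env = 1L, n_reps = r)
    return(list(blups = blups, vc = vc,
                H2 = h2_within(vc$sigma_g2, vc$sigma_e2, r)))
  }
  dat$line_f <- factor(dat$line_id)
  dat$rep_f <- factor(dat$rep)
  dat$blk_f <- factor(paste(dat$rep, dat$block, sep = ":"))
  has_blocks <- !is.null(dat$block) && length(unique(dat$blk_f)) > length(unique(dat$rep_f))
  form <- if (has_blocks)
    value ~ rep_f + (1 | blk_f) + (1 | line_f)
  else
    value ~ rep_f + (1 | line_f)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  sg2 <- vcs$vcov[vcs$grp == "line_f"]
  se2 <- vcs$vcov[vcs$grp == "Residual"]
  re <- lme4::ranef(fit)$line_f
  blups <- data.frame(line_id = rownames(re), blup = re[[1L]],
                      stringsAsFactors = FALSE)
  vc <- list(sigma_g2 = sg2, sigma_e2 = se2, n_env = 1L, n_reps = r)
  list(blups = blups, vc = vc, H2 = h2_within(sg2, se2, r))
}

#' Stage-one BLUP across the locations of one year
#'
#' Joint REML analysis of all environments (year-location combinations) of
#' one year: environment and replicate-within-environment fixed, block
#' random, line random, line-by-environment random.  Returns across-location
#' line BLUPs plus the components for [h2_across()].  With a single
#' environment it falls back to [fit_environment_blup()] with a notice.
#'
#' @param pheno plot-level phenotype table.
#' @param year year label.
#' @return list: `blups`, `vc` (`sigma_g2`, `sigma_gE2`, `sigma_e2`,
#'   `n_env`, `n_reps`), `H2`.
#' @export
fit_across_location_blup <- function(pheno, year) {
  dat <- pheno[pheno$year == year, , drop = FALSE]
  if (!nrow(dat)) stop_config("no records for year %s", year)
  envs <- unique(env_id(dat$year, dat$location))
  r <- max(tapply(dat$rep, dat$line_id, function(x) length(unique(x))))
  if (length(envs) < 2L) {
    message("single environment in ", year, "; falling back to fit_environment_blup()")
    one <- fit_environment_blup(pheno, envs)
    one$vc$sigma_gE2 <- 0
    return(one)
  }
  rep_sd <- tapply(dat$value, paste(dat$line_id, dat$location), stats::sd)
  dat$env_f <- factor(env_id(dat$year, dat$location))
  dat$line_f <- factor(dat$line_id)
  if (all(is.na(rep_sd) | rep_sd < 1e-12) &&
      isTRUE({
        lm0 <- tapply(dat$value, list(dat$line_f, dat$env_f), mean)
        !anyNA(lm0) && all(apply(lm0 - rowMeans(lm0), 2, stats::sd) < 1e-10)
      })) {
    ## noise-free, no G-by-E: centred line means are exact
    blups <- noise_free_blup(dat)
    vc <- list(sigma_g2 = stats::var(blups$blup), sigma_gE2 = 0, sigma_e2 = 0,
               n_env = length(envs), n_reps = r)
    return(list(blups = blups, vc = vc, H2 = 1))
  }
  dat$blk_f <- factor(paste(dat$env_f, dat$rep, dat$block, sep = ":"))
  has_blocks <- length(unique(dat$blk_f)) >
    length(unique(paste(dat$env_f, dat$rep)))
  form <- if (has_blocks)
    value ~ env_f + (1 | blk_f) + (1 | line_f) + (1 | line_f:env_f)
  else
    value ~ env_f + (1 | line_f) + (1 | line_f:env_f)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  sg2 <- vcs$vcov[vcs$grp == "line_f"]
  sge2 <- vcs$vcov[vcs$grp == "line_f:env_f"]
  se2 <- vcs$vcov[vcs$grp == "Residual"]
  re <- lme4::ranef(fit)$line_f
  blups <- data.frame(line_id = rownames(re), blup = re[[1L]],
                      stringsAsFactors = FALSE)
  vc <- list(sigma_g2 = sg2, sigma_gE2 = sge2, sigma_e2 = se2,
             n_env = length(envs), n_reps = r)
  list(blups = blups, vc = vc,
       H2 = h2_across(sg2, sge2, se2, length(envs), r))
}

#' Stage-one BLUPs for every environment and year
#'
#' Convenience wrapper running [fit_environment_blup()] on every
#' year-location combination and [fit_across_location_blup()] on every
#' year, the "observed phenotypes" that all validation schemes correlate
#' predictions against.
#'
#' @param pheno plot-level phenotype table.
#' @return list of class `blup_table`: `within` (data frame `line_id`,
#'   `year`, `location`, `env`, `blup`), `across` (`line_id`, `year`,
#'   `blup`), `h2` (per-environment and per-year heritability report).
#' @export
stage_one_blups <- function(pheno) {
  envs <- unique(data.frame(year = pheno$year, location = pheno$location))
  within <- list(); h2 <- list()
  for (i in seq_len(nrow(envs))) {
    e <- env_id(envs$year[i], envs$location[i])
    f <- fit_environment_blup(pheno, e)
    within[[i]] <- data.frame(line_id = f$blups$line_id, year = envs$year[i],
                              location = envs$location[i], env = e,
                              blup = f$blups$blup, stringsAsFactors = FALSE)
    h2[[length(h2) + 1L]] <- data.frame(
      level = "within", unit = e, sigma_g2 = f$vc$sigma_g2,
      sigma_gE2 = NA_real_, sigma_e2 = f$vc$sigma_e2, H2 = f$H2)
  }
  across <- list()
  for (y in unique(pheno$year)) {
    f <- fit_across_location_blup(pheno, y)
    across[[length(across) + 1L]] <- data.frame(
      line_id = f$blups$line_id, year = y, blup = f$blups$blup,
      stringsAsFactors = FALSE)
    h2[[length(h2) + 1L]] <- data.frame(
      level = "across", unit = y, sigma_g2 = f$vc$sigma_g2,
      sigma_gE2 = f$vc$sigma_gE2 %||% NA_real_,
      sigma_e2 = f$vc$sigma_e2, H2 = f$H2)
  }
  structure(list(within = do.call(rbind, within),
                 across = do.call(rbind, across),
                 h2 = do.call(rbind, h2)),
            class = "blup_table")
}
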