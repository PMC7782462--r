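#' Assemble the dataset all validation schemes operate on
#'
#' Applies the MAF filter to the program's dominant markers, builds the
#' genomic relationship matrix, and computes the stage-one BLUPs
#' (within-environment and across-location), which serve as the observed
#' phenotypes throughout.
#'
#' @param program a `dh_program` from [simulate_program()], or a list with
#'   elements `markers`, `pedigree`, `phenotypes`.
#' @param maf_threshold MAF cutoff for [maf_filter()].
#' @return object of class `gs_dataset`: `pedigree`, `G`, `within`,
#'   `across`, `h2`, `filter_report`.
#' @export
prepare_validation_data <- function(program, maf_threshold = 0.05) {
  M <- maf_filter(program$markers, maf_threshold)
  G <- grm(standardize_markers(M))
  bl <- stage_one_blups(program$phenotypes)
  structure(list(pedigree = program$pedigree, G = G,
                 within = bl$within, across = bl$across, h2 = bl$h2,
                 filter_report = attr(M, "filter_report")),
            class = "gs_dataset")
}

lines_of_year <- function(data, year) {
  data$pedigree$line_id[data$pedigree$year == year]
}

across_response <- function(data, lines) {
  v <- data$across$blup[match(lines, data$across$line_id)]
  stats::setNames(v, lines)
}

within_response <- function(data, lines, env) {
  sub <- data$within[data$within$env == env, ]
  stats::setNames(sub$blup[match(lines, sub$line_id)], lines)
}

new_validation_result <- function(kind, params, replicates, skipped = FALSE) {
  if (nrow(replicates)) {
    rep_means <- tapply(replicates$r, replicates$replicate,
                        function(x) mean(x, na.rm = TRUE))
    mean_acc <- mean(rep_means)
    se_acc <- if (length(rep_means) > 1L)
      stats::sd(rep_means) / sqrt(length(rep_means)) else NA_real_
  } else {
    mean_acc <- NA_real_; se_acc <- NA_real_
  }
  structure(list(scheme = c(list(kind = kind), params),
                 replicates = replicates, mean = mean_acc, se = se_acc,
                 skipped = skipped),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("validation_result [", x$scheme$kind, "]: r_MG =",
      format(x$mean, digits = 3),
      if (!is.na(x$se)) paste0("(SE ", format(x$se, digits = 2), ")"), "\n")
  invisible(x)
}

assert_disjoint <- function(trn, tst) {
  ov <- intersect(trn, tst)
  if (length(ov))
    stop_config("training and evaluation sets overlap (%d line(s))", length(ov))
}

## One SM fit + accuracy: train on named responses, predict tst, correlate
## against obs.
sm_accuracy <- function(y_trn, obs_tst, G, chain) {
  y <- c(y_trn, stats::setNames(rep(NA_real_, length(obs_tst)), names(obs_tst)))
  fit <- fit_sm(y, G, chain = chain)
  pearson_accuracy(obs_tst, predict_gebv(fit, names(obs_tst)))
}

#' Partition lines into cross-validation folds
#'
#' Random partition into `k` folds whose sizes differ by at most one
#' (e.g. 103 lines give folds of 21, 21, 21, 20, 20).
#'
#' @param ids line ids.
#' @param k number of folds.
#' @return integer fold assignment named by line id.
#' @export
cv_folds <- function(ids, k = 5L) {
  n <- length(ids)
  if (n < k) stop_config("fewer lines (%d) than folds (%d)", n, k)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  stats::setNames(sample(rep(seq_len(k), sizes)), ids)
}

#' Fivefold cross-validation (replicated)
#'
#' In every replication lines are randomly split into `folds` folds; each
#' fold in turn is the testing set (its lines' responses are masked in all
#' environments) while the remaining folds train the model.  The unit of
#' cross-validation is the DH line, so no record of a testing line leaks
#' into training.  A replicate's accuracy is the mean over folds (and over
#' environments within a fold); the result reports the mean and standard
#' error over replicates.
#'
#' @param data a `gs_dataset` from [prepare_validation_data()].
#' @param model `"sm"` or `"mm"`.
#' @param level `"across"` (across-location BLUPs; environments = years for
#'   the MM) or `"within"` (within-environment BLUPs; environments =
#'   year-location combinations).
#' @param n_reps number of replications (50 in the full-scale analysis).
#' @param seed master seed; each replicate gets its own spawned stream.
#' @param chain [chain_settings()] for every model fit.
#' @param years optional restriction to a subset of years.
#' @param folds number of folds.
#' @param unit `"line"` (all of a line's records move between folds
#'   together, so testing lines are entirely unphenotyped) or
#'   `"observation"` (response cells are assigned to folds independently,
#'   so a testing cell's line may be phenotyped in other environments --
#'   the situation in which the reaction-norm model borrows a line's own
#'   records across environments).
#' @return a `validation_result`.
#' @export
run_cv5 <- function(data, model = c("sm", "mm"), level = c("across", "within"),
                    n_reps = 50L, seed = 1L, chain = chain_settings("quick"),
                    years = NULL, folds = 5L, unit = c("line", "observation")) {
  model <- match.arg(model); level <- match.arg(level)
  unit <- match.arg(unit)
  ped <- data$pedigree
  if (!is.null(years)) ped <- ped[ped$year %in% years, ]
  ids <- ped$line_id
  if (length(ids) < 25L) stop_config("need at least 25 lines for fivefold CV")
  year_of <- stats::setNames(ped$year, ped$line_id)
  seeds <- spawn_seeds(seed, n_reps)
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    set.seed(seeds[rep_i])
    ch <- function(f) chain_settings(NULL, chain$n_iter, chain$burn_in,
                                     chain$thin,
                                     seed = seeds[rep_i] %% 100000L + f)
    if (unit == "line") {
      fold <- cv_folds(ids, folds)
      fold_r <- vapply(seq_len(folds), function(f) {
        tst <- ids[fold == f]
        trn <- ids[fold != f]
        assert_disjoint(trn, tst)
        cv_fold_accuracy(data, model, level, trn, tst, year_of, ch(f))
      }, numeric(1))
    } else {
      fold_r <- cv_observation_replicate(data, model, level, ids, folds, ch)
    }
    rows[[rep_i]] <- data.frame(replicate = rep_i, group = "all",
                                r = mean(fold_r, na.rm = TRUE))
  }
  new_validation_result("cv5",
                        list(model = model, level = level, n_reps = n_reps,
                             folds = folds, unit = unit, seed = seed),
                        do.call(rbind, rows))
}

## Observation-unit CV: response cells (line x environment at the within
## level, line x year at the across level) are split into folds.
cv_observation_replicate <- function(data, model, level, ids, folds, ch) {
  cells0 <- if (level == "within") {
    data.frame(line_id = data$within$line_id, env = data$within$env,
               value = data$within$blup)
  } else {
    data.frame(line_id = data$across$line_id, env = data$across$year,
               value = data$across$blup)
  }
  cells0 <- cells0[cells0$line_id %in% ids, ]
  fold <- cv_folds(seq_len(nrow(cells0)), folds)
  vapply(seq_len(folds), function(f) {
    masked <- fold == f
    rs <- c()
    if (model == "sm") {
      for (e in unique(cells0$env[masked])) {
        in_e <- cells0$env == e
        trn_c <- cells0[in_e & !masked, ]
        tst_c <- cells0[in_e & masked, ]
        if (nrow(tst_c) < 3L || nrow(trn_c) < 10L) next
        y <- c(stats::setNames(trn_c$value, trn_c$line_id),
               stats::setNames(rep(NA_real_, nrow(tst_c)), tst_c$line_id))
        fit <- fit_sm(y, data$G, chain = ch(f))
        rs <- c(rs, pearson_accuracy(stats::setNames(tst_c$value, tst_c$line_id),
                                     predict_gebv(fit, tst_c$line_id)))
      }
    } else {
      cells <- cells0
      cells$value[masked] <- NA_real_
      fit <- fit_mm(cells, data$G, chain = ch(f))
      for (e in unique(cells0$env[masked])) {
        tst_c <- cells0[cells0$env == e & masked, ]
        if (nrow(tst_c) < 3L) next
        rs <- c(rs, pearson_accuracy(
          stats::setNames(tst_c$value, tst_c$line_id),
          predict_gebv(fit, tst_c$line_id, environment = e)))
      }
    }
    mean(rs)
  }, numeric(1))
}

cv_fold_accuracy <- function(data, model, level, trn, tst, year_of, chain) {
  if (level == "across") {
    if (model == "sm") {
      rs <- c()
      for (y in unique(year_of[tst])) {
        trn_y <- trn[year_of[trn] == y]
        tst_y <- tst[year_of[tst] == y]
        if (length(tst_y) < 3L || length(trn_y) < 10L) next
        rs <- c(rs, sm_accuracy(across_response(data, trn_y),
                                across_response(data, tst_y), data$G, chain))
      }
      return(mean(rs))
    }
    ## MM with environments = years
    cells <- data.frame(line_id = data$across$line_id, env = data$across$year,
                        value = data$across$blup)
    cells$value[cells$line_id %in% tst] <- NA_real_
    fit <- fit_mm(cells, data$G, chain = chain)
    rs <- c()
    for (y in unique(year_of[tst])) {
      tst_y <- tst[year_of[tst] == y]
      if (length(tst_y) < 3L) next
      obs <- across_response(data, tst_y)
      rs <- c(rs, pearson_accuracy(obs, predict_gebv(fit, tst_y, environment = y)))
    }
    return(mean(rs))
  }
  ## within level
  if (model == "sm") {
    rs <- c()
    for (e in unique(data$within$env)) {
      sub <- data$within[data$within$env == e, ]
      trn_e <- intersect(trn, sub$line_id)
      tst_e <- intersect(tst, sub$line_id)
      if (length(tst_e) < 3L || length(trn_e) < 10L) next
      rs <- c(rs, sm_accuracy(within_response(data, trn_e, e),
                              within_response(data, tst_e, e), data$G, chain))
    }
    return(mean(rs))
  }
  cells <- data.frame(line_id = data$within$line_id, env = data$within$env,
                      value = data$within$blup)
  cells$value[cells$line_id %in% tst] <- NA_real_
  fit <- fit_mm(cells, data$G, chain = chain)
  rs <- c()
  for (e in unique(data$within$env)) {
    sub <- data$within[data$within$env == e, ]
    tst_e <- intersect(tst, sub$line_id)
    if (length(tst_e) < 3L) next
    obs <- within_response(data, tst_e, e)
    rs <- c(rs, pearson_accuracy(obs, predict_gebv(fit, tst_e, environment = e)))
  }
  mean(rs)
}

#' Across-year (independent) validation
#'
#' Trains on one or two whole years of breeding data and predicts the lines
#' of a different year, which are genotyped but treated as unphenotyped.
#' At the `"across"` level the response is the across-location BLUP and one
#' accuracy is reported; at the `"within"` level training and testing use
#' within-environment BLUPs of the same location and one accuracy per
#' location shared between the years is reported.  For the MM the testing
#' year's environments are absent from training, so its predictions are the
#' main-effect GEBVs mu + g.
#'
#' @inheritParams run_cv5
#' @param train_years one or more training years.
#' @param test_year the year predicted; must not be in `train_years`.
#' @param train_lines optional restriction of the training lines.
#' @param extra_train_lines test-year lines converted into training
#'   (partial-conversion scheme).
#' @param eval_lines optional explicit evaluation set (default: all
#'   test-year lines not converted).
#' @return a `validation_result` with one replicate (one row per location
#'   at the `"within"` level).
#' @export
run_across_year <- function(data, train_years, test_year,
                            model = c("sm", "mm"),
                            level = c("across", "within"),
                            chain = chain_settings("quick"),
                            train_lines = NULL, extra_train_lines = NULL,
                            eval_lines = NULL) {
  model <- match.arg(model); level <- match.arg(level)
  if (test_year %in% train_years)
    stop_config("test_year %s must not be among train_years", test_year)
  trn <- unlist(lapply(train_years, lines_of_year, data = data))
  if (!length(trn)) stop_config("no lines in training year(s)")
  if (!is.null(train_lines)) trn <- intersect(trn, train_lines)
  trn <- union(trn, extra_train_lines %||% character(0))
  tst <- setdiff(lines_of_year(data, test_year), extra_train_lines %||% character(0))
  if (!is.null(eval_lines)) tst <- intersect(tst, eval_lines)
  if (!length(tst)) stop_config("no lines to evaluate in %s", test_year)
  assert_disjoint(trn, tst)
  ped_year <- stats::setNames(data$pedigree$year, data$pedigree$line_id)

  if (level == "across") {
    obs_tst <- across_response(data, tst)
    if (model == "sm") {
      r <- sm_accuracy(across_response(data, trn), obs_tst, data$G, chain)
    } else {
      cells <- data.frame(line_id = trn, env = ped_year[trn],
                          value = across_response(data, trn))
      cells <- rbind(cells, data.frame(line_id = tst, env = test_year,
                                       value = NA_real_))
      fit <- fit_mm(cells, data$G, chain = chain)
      ## conversion lines make the test year partially observed; predict
      ## within that environment then, otherwise by genetic main effect
      pred <- if (test_year %in% ped_year[trn])
        predict_gebv(fit, tst, environment = test_year)
      else predict_gebv(fit, tst)
      r <- pearson_accuracy(obs_tst, pred)
    }
    reps <- data.frame(replicate = 1L, group = "across", r = r)
  } else {
    test_locs <- unique(data$within$location[data$within$year == test_year])
    train_locs <- unique(data$within$location[data$within$year %in% train_years])
    locs <- intersect(test_locs, train_locs)
    if (!length(locs)) stop_config("no shared locations between years")
    mm_fit_all <- NULL
    if (model == "mm") {
      w <- data$within[data$within$line_id %in% trn, ]
      cells <- data.frame(line_id = w$line_id, env = w$env, value = w$blup)
      cells <- rbind(cells, data.frame(line_id = tst,
                                       env = cells$env[1L], value = NA_real_))
      mm_fit_all <- fit_mm(cells, data$G, chain = chain)
    }
    reps <- list()
    for (loc in locs) {
      envs_trn <- unique(data$within$env[data$within$location == loc &
                                           data$within$year %in% train_years])
      env_tst <- env_id(test_year, loc)
      sub_tst <- data$within[data$within$env == env_tst, ]
      tst_l <- intersect(tst, sub_tst$line_id)
      if (length(tst_l) < 3L) next
      obs_tst <- within_response(data, tst_l, env_tst)
      if (model == "sm") {
        w <- data$within[data$within$env %in% envs_trn &
                           data$within$line_id %in% trn, ]
        y_trn <- stats::setNames(w$blup, w$line_id)
        r <- sm_accuracy(y_trn, obs_tst, data$G, chain)
      } else {
        r <- pearson_accuracy(obs_tst, predict_gebv(mm_fit_all, tst_l))
      }
      reps[[length(reps) + 1L]] <- data.frame(replicate = 1L, group = loc, r = r)
    }
    reps <- do.call(rbind, reps)
  }
  new_validation_result("across_year",
                        list(model = model, level = level,
                             train_years = paste(train_years, collapse = "+"),
                             test_year = test_year,
                             n_train = length(trn), n_test = length(tst)),
                        reps)
}

#' Size-adjusted two-year training sets
#'
#' Repeats the across-year prediction with the two-year training pool
#' randomly subsampled to `target_size` lines (typically the size of a
#' one-year training set), separating the effect of training-set size from
#' that of added environmental variation.
#'
#' @inheritParams run_across_year
#' @param target_size training-set size after subsampling.
#' @param n_reps number of random subsamples (30 in the full-scale
#'   analysis).
#' @param seed master seed.
#' @return a `validation_result` with `n_reps` replicates.
#' @export
run_size_adjusted <- function(data, train_years, test_year, target_size,
                              n_reps = 30L, seed = 1L,
                              model = "sm", level = "across",
                              chain = chain_settings("quick")) {
  pool <- unlist(lapply(train_years, lines_of_year, data = data))
  if (target_size > length(pool))
    stop_config("target_size %d exceeds the %d-line training pool",
                target_size, length(pool))
  seeds <- spawn_seeds(seed, n_reps)
  rows <- list()
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    subset_i <- sample(pool, target_size)
    res <- run_across_year(data, train_years, test_year, model = model,
                           level = level, chain = chain,
                           train_lines = subset_i)
    rr <- res$replicates
    rr$replicate <- i
    rows[[i]] <- rr
  }
  new_validation_result("size_adjusted",
                        list(model = model, level = level,
                             train_years = paste(train_years, collapse = "+"),
                             test_year = test_year, target_size = target_size,
                             n_reps = n_reps, seed = seed),
                        do.call(rbind, rows))
}

#' Classify the sibship of two DH lines
#'
#' Full-sibs share both parents (the parent sets are equal, order
#' ignored), half-sibs exactly one, unrelated lines none.
#'
#' @param pedigree data frame with `line_id`, `parent1`, `parent2`.
#' @param line_a,line_b line ids.
#' @return `"full_sib"`, `"half_sib"` or `"unrelated"`.
#' @export
classify_sibship <- function(pedigree, line_a, line_b) {
  ia <- match(line_a, pedigree$line_id)
  ib <- match(line_b, pedigree$line_id)
  if (is.na(ia) || is.na(ib))
    stop_config("unknown line id: %s", if (is.na(ia)) line_a else line_b)
  pa <- c(pedigree$parent1[ia], pedigree$parent2[ia])
  pb <- c(pedigree$parent1[ib], pedigree$parent2[ib])
  shared <- length(intersect(pa, pb))
  switch(shared + 1L, "unrelated", "half_sib", "full_sib")
}

#' Sibship-partitioned across-year validation
#'
#' Restricts training and testing lines before the across-year prediction:
#' `"all"` keeps every line; `"shared_sibs"` keeps only lines with at least
#' one full- or half-sib (a shared parent) on the other side;
#' `"no_shared_parents"` keeps only lines with no parental line in common
#' with the other year.  When a restricted subset has fewer than
#' `min_lines` lines on either side (e.g. distant years with no sib
#' overlap) the scheme is skipped with a warning, mirroring how such year
#' pairs cannot be evaluated.
#'
#' @inheritParams run_across_year
#' @param train_year single training year.
#' @param mode `"all"`, `"shared_sibs"` or `"no_shared_parents"`.
#' @param min_lines minimum subset size on each side.
#' @return a `validation_result` (with `skipped = TRUE` when the subset is
#'   too small).
#' @export
run_sibship_partition <- function(data, train_year, test_year,
                                  mode = c("all", "shared_sibs", "no_shared_parents"),
                                  model = "sm", level = "across",
                                  chain = chain_settings("quick"),
                                  min_lines = 10L) {
  mode <- match.arg(mode)
  ped <- data$pedigree
  trn_all <- lines_of_year(data, train_year)
  tst_all <- lines_of_year(data, test_year)
  parents_of <- function(ids) {
    i <- match(ids, ped$line_id)
    cbind(ped$parent1[i], ped$parent2[i])
  }
  shares_parent <- function(ids, other_ids) {
    other_parents <- unique(as.vector(parents_of(other_ids)))
    pm <- parents_of(ids)
    pm[, 1L] %in% other_parents | pm[, 2L] %in% other_parents
  }
  if (mode == "all") {
    trn <- trn_all; tst <- tst_all
  } else if (mode == "shared_sibs") {
    trn <- trn_all[shares_parent(trn_all, tst_all)]
    tst <- tst_all[shares_parent(tst_all, trn_all)]
  } else {
    trn <- trn_all[!shares_parent(trn_all, tst_all)]
    tst <- tst_all[!shares_parent(tst_all, trn_all)]
  }
  if (length(trn) < min_lines || length(tst) < min_lines) {
    warning(sprintf("sibship mode '%s' between %s and %s leaves %d training / %d testing lines; scheme skipped",
                    mode, train_year, test_year, length(trn), length(tst)))
    return(new_validation_result("sibship_partition",
                                 list(mode = mode, train_year = train_year,
                                      test_year = test_year, model = model,
                                      level = level),
                                 data.frame(replicate = integer(0),
                                            group = character(0),
                                            r = numeric(0)),
                                 skipped = TRUE))
  }
  res <- run_across_year(data, train_year, test_year, model = model,
                         level = level, chain = chain,
                         train_lines = trn, eval_lines = tst)
  new_validation_result("sibship_partition",
                        list(mode = mode, train_year = train_year,
                             test_year = test_year, model = model,
                             level = level, n_train = length(trn),
                             n_test = length(tst)),
                        res$replicates)
}

#' Partial conversion of the testing population
#'
#' Two whole years train the model together with a random `fraction` of the
#' third year's lines converted from testing to training; accuracy is
#' evaluated on the remaining (never-converted) test-year lines.  The
#' converted subset is resampled in every replication.
#'
#' @inheritParams run_across_year
#' @param fraction proportion of test-year lines converted, in (0, 1).
#' @param n_reps number of replications (50 in the full-scale analysis).
#' @param seed master seed.
#' @return a `validation_result` with `n_reps` replicates.
#' @export
run_partial_conversion <- function(data, train_years, test_year,
                                   fraction = 0.5, n_reps = 50L, seed = 1L,
                                   model = "sm", level = "across",
                                   chain = chain_settings("quick")) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_config("fraction must lie strictly between 0 and 1")
  tst_all <- lines_of_year(data, test_year)
  n_conv <- round(fraction * length(tst_all))
  if (n_conv < 10L)
    stop_config("converted fraction must cover at least 10 test-year lines")
  if (length(tst_all) - n_conv < 3L)
    stop_config("too few lines left for evaluation after conversion")
  seeds <- spawn_seeds(seed, n_reps)
  rows <- list()
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    converted <- sample(tst_all, n_conv)
    res <- run_across_year(data, train_years, test_year, model = model,
                           level = level, chain = chain,
                           extra_train_lines = converted,
                           eval_lines = setdiff(tst_all, converted))
    rr <- res$replicates
    rr$replicate <- i
    rows[[i]] <- rr
  }
  new_validation_result("partial_conversion",
                        list(model = model, level = level,
                             train_years = paste(train_years, collapse = "+"),
                             test_year = test_year, fraction = fraction,
                             n_reps = n_reps, seed = seed),
                        do.call(rbind, rows))
}
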