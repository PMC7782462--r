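#' Plan a multi-year DH crossing program
#'
#' Lays out the biparental crosses of each year.  Each new year reuses
#' `shared_parent_fraction` of the previous year's parent pool and
#' introduces fresh parents for the rest; a smaller fraction of crosses
#' (`shared_cross_fraction`, by default the square of the parent fraction
#' -- the chance that both parents of a cross were kept) is repeated
#' verbatim, producing the small number of across-year full-sib lines seen
#' in real programs, while the recycled parents inside new crosses produce
#' the much larger half-sib overlap.  With `shared_parent_fraction = 0`
#' years share no parents at all; with `1` every year repeats the same
#' plan.
#'
#' @param config a [sim_config()] object.
#' @return A list with `crosses` (data frame: `year`, `cross_id`, `parent1`,
#'   `parent2`, `n_lines`, `tester`), `parents_by_year`, and `parent_ids`.
#' @export
plan_multiyear_program <- function(config) {
  cfg <- validate_sim_config(config)
  n_pop <- cfg$n_populations_per_year
  n_carry <- round(cfg$shared_cross_fraction * n_pop)
  n_reuse <- round(cfg$shared_parent_fraction * cfg$n_parents)
  parent_counter <- 0L
  new_parents <- function(k) {
    ids <- sprintf("P%03d", parent_counter + seq_len(k))
    parent_counter <<- parent_counter + k
    ids
  }
  draw_pairs <- function(pool, k, taken) {
    ## distinct unordered pairs, also distinct from `taken`
    out <- character(0)
    pairs <- list()
    guard <- 0L
    while (length(pairs) < k) {
      pr <- sort(sample(pool, 2L))
      key <- paste(pr, collapse = "|")
      if (!(key %in% taken) && !(key %in% out)) {
        out <- c(out, key)
        pairs[[length(pairs) + 1L]] <- pr
      }
      guard <- guard + 1L
      if (guard > 10000L) stop_config("cannot draw %d distinct crosses from %d parents",
                                      k, length(pool))
    }
    pairs
  }

  crosses <- list()
  parents_by_year <- list()
  prev_pairs <- NULL
  prev_pool <- NULL
  for (y in seq_len(cfg$n_years)) {
    year <- sprintf("Y%d", y)
    if (y == 1L || is.null(prev_pool) || n_reuse == 0L) {
      reused <- character(0)
    } else {
      reused <- sample(prev_pool, min(n_reuse, length(prev_pool)))
    }
    if (y == 1L || n_carry == 0L || is.null(prev_pairs)) {
      carried <- list()
    } else {
      ## only crosses whose two parents were both kept can be repeated
      eligible <- Filter(function(p) all(p %in% reused), prev_pairs)
      if (length(eligible))
        carried <- eligible[sort(sample.int(length(eligible),
                                            min(n_carry, length(eligible))))]
      else carried <- list()
    }
    n_fresh <- max(cfg$n_parents - length(reused), 0L)
    pool <- c(reused, new_parents(n_fresh))
    taken <- vapply(carried, paste, "", collapse = "|")
    fresh_pairs <- draw_pairs(pool, n_pop - length(carried), taken)
    pairs <- c(carried, fresh_pairs)
    sizes <- sample_population_sizes(length(pairs), cfg$lines_per_population)
    n_testers <- cfg$n_testers_per_year[min(y, length(cfg$n_testers_per_year))]
    testers <- sprintf("T%d_%d", y, seq_len(n_testers))
    crosses[[y]] <- data.frame(
      year = year,
      cross_id = sprintf("%s_C%02d", year, seq_along(pairs)),
      parent1 = vapply(pairs, `[`, "", 1L),
      parent2 = vapply(pairs, `[`, "", 2L),
      n_lines = sizes,
      tester = testers[(seq_along(pairs) - 1L) %% n_testers + 1L],
      stringsAsFactors = FALSE
    )
    parents_by_year[[year]] <- pool
    prev_pairs <- pairs
    prev_pool <- pool
  }
  crosses <- do.call(rbind, crosses)
  list(crosses = crosses, parents_by_year = parents_by_year,
       parent_ids = sprintf("P%03d", seq_len(parent_counter)))
}

#' Simulate founder (parental line) genotypes
#'
#' Dominant presence/absence markers for the parental inbreds.  Presence
#' frequencies are drawn from a symmetric Beta spectrum (shape
#' `founder_beta_shape`, default 0.75) whose mass near the boundaries leaves
#' roughly 10-20 percent of markers below the 0.05 minor-allele-frequency
#' cutoff, so the MAF filter has realistic work to do.  Markers are placed
#' uniformly at random along `n_chromosomes` linkage groups of
#' `chrom_length_morgan` Morgans.
#'
#' Ancestral linkage disequilibrium between nearby markers is generated
#' with a Gaussian-copula AR(1) process along each chromosome whose
#' correlation decays as `exp(-distance / founder_ld_morgan)`; the copula
#' leaves every marker's marginal presence frequency exactly at its drawn
#' spectrum value.  Set `founder_ld_morgan = 0` for linkage-equilibrium
#' founders.
#'
#' @param config a [sim_config()] object.
#' @param parent_ids row identifiers; defaults to `P001 ...` of length
#'   `config$n_parents`.
#' @return binary matrix (parents x markers) with a `map` attribute
#'   (data frame: `marker`, `chrom`, `pos` in Morgans).
#' @export
simulate_founders <- function(config, parent_ids = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(parent_ids)) parent_ids <- sprintf("P%03d", seq_len(cfg$n_parents))
  n <- length(parent_ids)
  m <- cfg$n_markers
  if (n < 2L || m < 1L) stop_config("need at least 2 parents and 1 marker")
  freq <- if (!is.null(cfg$founder_freq)) {
    rep_len(cfg$founder_freq, m)
  } else {
    stats::rbeta(m, cfg$founder_beta_shape, cfg$founder_beta_shape)
  }
  map <- data.frame(
    marker = sprintf("M%04d", seq_len(m)),
    chrom = sample.int(cfg$n_chromosomes, m, replace = TRUE),
    pos = stats::runif(m, 0, cfg$chrom_length_morgan)
  )
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  freq <- freq[ord]
  d_ld <- cfg$founder_ld_morgan %||% 0
  geno <- matrix(0L, n, m, dimnames = list(parent_ids, map$marker))
  for (idx in split(seq_len(m), map$chrom)) {
    k <- length(idx)
    z <- matrix(stats::rnorm(n * k), n, k)
    if (d_ld > 0 && k > 1L) {
      a <- exp(-diff(map$pos[idx]) / d_ld)       # AR(1) along the chromosome
      for (j in 2L:k) z[, j] <- a[j - 1L] * z[, j - 1L] +
          sqrt(1 - a[j - 1L]^2) * z[, j]
    }
    ## copula threshold keeps each marker's marginal frequency exact
    geno[, idx] <- (z < rep(stats::qnorm(freq[idx]), each = n)) + 0L
  }
  attr(geno, "map") <- map
  geno
}

## One meiotic gamete of the F1 of two inbred parents; DH lines are fully
## homozygous so a single gamete defines the line.  Crossovers per
## chromosome are Poisson(length in Morgans) at uniform positions.
dh_gamete <- function(p1, p2, chrom_index, chrom_len) {
  out <- integer(length(p1))
  for (ci in seq_along(chrom_index)) {
    idx <- chrom_index[[ci]]$idx
    pos <- chrom_index[[ci]]$pos
    n_xo <- stats::rpois(1L, chrom_len)
    phase0 <- sample.int(2L, 1L) - 1L
    phase <- if (n_xo == 0L) {
      rep(phase0, length(idx))
    } else {
      xo <- sort(stats::runif(n_xo, 0, chrom_len))
      (phase0 + findInterval(pos, xo)) %% 2L
    }
    out[idx] <- ifelse(phase == 0L, p1[idx], p2[idx])
  }
  out
}

#' Derive DH lines from a cross plan
#'
#' Each DH line's marker vector is one recombinant gamete of its two
#' parents, so at every marker the line carries one of the two parental
#' alleles.
#'
#' @param founders founder genotype matrix from [simulate_founders()]
#'   (its `map` attribute supplies marker positions).
#' @param cross_plan data frame with columns `year`, `cross_id`, `parent1`,
#'   `parent2`, `n_lines`, `tester` (one row per biparental population).
#' @param config a [sim_config()] object.
#' @return list with `pedigree` (data frame: `line_id`, `parent1`,
#'   `parent2`, `year`, `tester`, `cross_id`) and `markers` (lines x
#'   markers binary matrix).
#' @export
make_dh_lines <- function(founders, cross_plan, config) {
  cfg <- validate_sim_config(config)
  map <- attr(founders, "map")
  if (is.null(map)) stop_config("founders must carry a 'map' attribute")
  missing_par <- setdiff(unique(c(cross_plan$parent1, cross_plan$parent2)),
                         rownames(founders))
  if (length(missing_par))
    stop_config("unknown parent id(s) in cross plan: %s",
                paste(missing_par, collapse = ", "))
  chrom_index <- lapply(split(seq_len(nrow(map)), map$chrom),
                        function(i) list(idx = i, pos = map$pos[i]))
  total <- sum(cross_plan$n_lines)
  geno <- matrix(0L, nrow = total, ncol = ncol(founders))
  colnames(geno) <- colnames(founders)
  ped <- vector("list", nrow(cross_plan))
  row <- 0L
  ids <- character(total)
  for (k in seq_len(nrow(cross_plan))) {
    cr <- cross_plan[k, ]
    p1 <- founders[cr$parent1, ]
    p2 <- founders[cr$parent2, ]
    line_ids <- sprintf("%s_L%02d", cr$cross_id, seq_len(cr$n_lines))
    for (j in seq_len(cr$n_lines)) {
      row <- row + 1L
      geno[row, ] <- dh_gamete(p1, p2, chrom_index, cfg$chrom_length_morgan)
      ids[row] <- line_ids[j]
    }
    ped[[k]] <- data.frame(line_id = line_ids, parent1 = cr$parent1,
                           parent2 = cr$parent2, year = cr$year,
                           tester = cr$tester, cross_id = cr$cross_id,
                           stringsAsFactors = FALSE)
  }
  rownames(geno) <- ids
  attr(geno, "map") <- map
  list(pedigree = do.call(rbind, ped), markers = geno)
}

#' Simulation ground truth: QTL effects, genetic values, G-by-E deviations
#'
#' `n_qtl` segregating markers carry additive effects drawn Normal(0, 1);
#' the resulting line values are rescaled so their sample variance equals
#' `sigma_g2` exactly.  Interaction deviations are built from per-environment
#' perturbations of the same QTL, double-centred (no line or environment
#' main effect leaks into them) and rescaled to `sigma_gE2`; a zero target
#' yields an exactly zero interaction.  Environment main effects are drawn
#' Normal(0, `sigma_E2`).
#'
#' @param markers line genotype matrix.
#' @param envs character vector of environment labels (year-location).
#' @param config a [sim_config()] object.
#' @return list of class `truth_set`: `qtl_indices`, `qtl_effects`,
#'   `true_g` (named), `true_gE` (lines x envs), `env_effects` (named).
#' @export
make_truth <- function(markers, envs, config) {
  cfg <- validate_sim_config(config)
  vt <- cfg$variance_targets
  n <- nrow(markers)
  seg <- which(apply(markers, 2, function(x) stats::var(x) > 0))
  if (length(seg) < cfg$n_qtl)
    stop_config("only %d segregating markers for %d QTL", length(seg), cfg$n_qtl)
  qtl <- sort(sample(seg, cfg$n_qtl))
  a <- stats::rnorm(cfg$n_qtl)
  raw_g <- as.vector(scale(markers[, qtl, drop = FALSE] %*% a, scale = FALSE))
  rescale_to <- function(x, target) {
    if (target == 0) return(x * 0)
    s <- stats::sd(x)
    if (s < 1e-12) stop_config("degenerate genetic values; increase n_qtl or diversity")
    x * sqrt(target) / s
  }
  true_g <- rescale_to(raw_g, vt$sigma_g2)
  names(true_g) <- rownames(markers)

  gE <- matrix(0, n, length(envs), dimnames = list(rownames(markers), envs))
  if (vt$sigma_gE2 > 0) {
    for (e in seq_along(envs)) {
      gE[, e] <- markers[, qtl, drop = FALSE] %*% stats::rnorm(cfg$n_qtl)
    }
    gE <- gE - rowMeans(gE)
    gE <- sweep(gE, 2, colMeans(gE))
    ## calibrate on the interaction degrees of freedom so an ANOVA
    ## interaction mean square (and the reaction-norm model) recover the
    ## target
    ss <- sum(gE^2)
    if (ss < 1e-12) stop_config("degenerate interaction deviations")
    gE <- gE * sqrt(vt$sigma_gE2 * (n - 1) * (length(envs) - 1) / ss)
  }
  env_effects <- stats::rnorm(length(envs), 0, sqrt(vt$sigma_E2))
  names(env_effects) <- envs
  structure(list(qtl_indices = qtl, qtl_effects = a, true_g = true_g,
                 true_gE = gE, env_effects = env_effects),
            class = "truth_set")
}

#' Simulate plot-level testcross phenotypes
#'
#' Generates the multi-location, replicated yield trial: plot value =
#' grand mean + environment effect + genetic value + G-by-E deviation +
#' incomplete-block effect + residual.  Each line is tested in every
#' location of its own year, in `n_reps` replicates, with blocks of
#' `block_size` plots nested in replicate (block variance
#' `block_var_ratio * sigma_e2`).  The tester assigned to a line's
#' population contributes only a constant absorbed in the environment mean
#' and is therefore not simulated as a separate effect.
#'
#' @param pedigree data frame from [make_dh_lines()].
#' @param truth a `truth_set` from [make_truth()].
#' @param config a [sim_config()] object.
#' @return data frame (`line_id`, `year`, `location`, `rep`, `block`,
#'   `value`) with attribute `h2_plot` (analytic within-environment
#'   plot-level broad-sense heritability implied by the variance targets).
#' @export
simulate_phenotypes <- function(pedigree, truth, config) {
  cfg <- validate_sim_config(config)
  vt <- cfg$variance_targets
  years <- sprintf("Y%d", seq_len(cfg$n_years))
  out <- list()
  for (y in seq_len(cfg$n_years)) {
    yr <- years[y]
    lines_y <- pedigree$line_id[pedigree$year == yr]
    if (!length(lines_y)) next
    for (loc in cfg$locations_per_year[[y]]) {
      env <- paste(yr, loc, sep = "_")
      if (!env %in% colnames(truth$true_gE))
        stop_config("no truth entry for environment %s", env)
      e_eff <- truth$env_effects[[env]]
      for (r in seq_len(cfg$n_reps)) {
        ord <- sample(lines_y)
        block <- ceiling(seq_along(ord) / cfg$block_size)
        b_eff <- stats::rnorm(max(block), 0,
                              sqrt(cfg$block_var_ratio * vt$sigma_e2))
        val <- cfg$grand_mean + e_eff +
          truth$true_g[ord] + truth$true_gE[ord, env] +
          b_eff[block] + stats::rnorm(length(ord), 0, sqrt(vt$sigma_e2))
        out[[length(out) + 1L]] <- data.frame(
          line_id = ord, year = yr, location = loc, rep = r,
          block = block, value = as.numeric(val), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  sig_w <- vt$sigma_g2 + vt$sigma_gE2      # line variance within one environment
  sig_e_eff <- vt$sigma_e2 * (1 + cfg$block_var_ratio)
  attr(res, "h2_plot") <- if (sig_w + sig_e_eff / cfg$n_reps > 0)
    sig_w / (sig_w + sig_e_eff / cfg$n_reps) else NA_real_
  res
}

#' Simulate a complete multi-year DH breeding program
#'
#' Runs the whole generator under one master seed: crossing plan, founder
#' genotypes, DH line derivation, trait truth, and plot phenotypes.
#' Identical `config` (including `seed`) gives byte-identical output.
#'
#' @param config a [sim_config()] object.
#' @return object of class `dh_program`: `config`, `plan`, `founders`,
#'   `pedigree`, `markers` (the observed panel; causal columns are masked
#'   unless `observe_qtl = TRUE`), `truth`, `phenotypes`, `sib_counts`.
#' @export
simulate_program <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  plan <- plan_multiyear_program(cfg)
  founders <- simulate_founders(cfg, parent_ids = plan$parent_ids)
  dh <- make_dh_lines(founders, plan$crosses, cfg)
  envs <- unlist(lapply(seq_len(cfg$n_years), function(y)
    paste(sprintf("Y%d", y), cfg$locations_per_year[[y]], sep = "_")))
  truth <- make_truth(dh$markers, envs, cfg)
  pheno <- simulate_phenotypes(dh$pedigree, truth, cfg)
  observed <- dh$markers
  if (!isTRUE(cfg$observe_qtl)) {
    ## causal loci are anonymous: the panel distributed to the analysis
    ## carries only the non-causal tags, so prediction must work through
    ## cosegregation and relatedness, as with real intergenic markers
    observed <- observed[, -truth$qtl_indices, drop = FALSE]
    map <- attr(dh$markers, "map")
    attr(observed, "map") <- map[map$marker %in% colnames(observed), ]
  }
  structure(list(config = cfg, plan = plan, founders = founders,
                 pedigree = dh$pedigree, markers = observed,
                 truth = truth, phenotypes = pheno,
                 sib_counts = sib_share_counts(dh$pedigree)),
            class = "dh_program")
}

#' @export
print.dh_program <- function(x, ...) {
  cat("dh_program:", nrow(x$pedigree), "DH lines,",
      ncol(x$markers), "markers,",
      length(unique(paste(x$phenotypes$year, x$phenotypes$location))),
      "environments\n")
  invisible(x)
}

#' Across-year sib sharing report
#'
#' For every ordered pair of distinct years, counts how many of year A's
#' lines have at least one full-sib (same biparental cross) and at least
#' one half-sib (exactly one shared parent) among year B's lines.
#'
#' @param pedigree data frame with `line_id`, `parent1`, `parent2`, `year`.
#' @return data frame (`year_a`, `year_b`, `n_full_sib`, `n_half_sib`).
#' @export
sib_share_counts <- function(pedigree) {
  years <- unique(pedigree$year)
  key <- function(p1, p2) paste(pmin(p1, p2), pmax(p1, p2), sep = "|")
  pedigree$cross_key <- key(pedigree$parent1, pedigree$parent2)
  out <- list()
  for (a in years) for (b in setdiff(years, a)) {
    pa <- pedigree[pedigree$year == a, ]
    pb <- pedigree[pedigree$year == b, ]
    full <- pa$cross_key %in% pb$cross_key
    pb_parents <- unique(c(pb$parent1, pb$parent2))
    half <- logical(nrow(pa))
    for (i in seq_len(nrow(pa))) {
      if (full[i]) next
      shared_b <- pb$parent1 %in% c(pa$parent1[i], pa$parent2[i]) |
        pb$parent2 %in% c(pa$parent1[i], pa$parent2[i])
      half[i] <- any(shared_b & !(pb$cross_key == pa$cross_key[i]))
    }
    ## half-sib here: shares >= 1 parent with some line of year b through a
    ## different cross (full-sibs counted separately)
    out[[length(out) + 1L]] <- data.frame(
      year_a = a, year_b = b,
      n_full_sib = sum(full), n_half_sib = sum(half),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
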