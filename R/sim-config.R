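#' Configuration for a simulated DH breeding program
#'
#' Assembles and validates the parameters of the synthetic multi-year
#' doubled-haploid (DH) testcross program: how many biparental populations
#' are made each year, how many parents are recycled between consecutive
#' years (which creates the full-sib/half-sib overlap the across-year
#' validation schemes exploit), the dominant-marker panel, the trait
#' architecture, and the multi-location trial layout.
#'
#' Variance targets are on the plot-value scale: `sigma_g2` (genotypic
#' main effect), `sigma_E2` (environment main effect), `sigma_gE2`
#' (genotype-by-environment interaction) and `sigma_e2` (plot residual).
#' Incomplete blocks of `block_size` plots nested in replicate carry an
#' additional variance of `block_var_ratio * sigma_e2`.
#'
#' Two presets are provided.  `"reference"` emulates a three-year tropical
#' maize DH program at desk scale: about 200 lines per year from 40 small
#' biparental populations (1 to 66 lines each, mean 5), 1000 dominant
#' markers on 10 chromosomes, three locations (AF, Cot, TL) with Cot
#' missing in the last year, two replicates, and adjacent-year parent
#' recycling that puts the line-level sib overlap between consecutive
#' years in the 30-50 percent band while years 1 and 3 share almost
#' nothing.  `"minimal"` is a small two-year, two-environment program for
#' smoke tests.
#'
#' @param preset `"reference"`, `"minimal"`, or `NULL` for bare defaults.
#' @param ... named overrides of any configuration field.
#' @param seed integer master seed for the whole simulation.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(preset = NULL, ..., seed = 1L) {
  base <- list(
    n_parents = 24L,
    n_populations_per_year = 20L,
    shared_cross_fraction = NULL,   # default: shared_parent_fraction^2
    lines_per_population = list(min = 1L, max = 66L, mean = 10),
    n_years = 3L,
    shared_parent_fraction = 0.5,
    n_markers = 1000L,
    n_chromosomes = 10L,
    chrom_length_morgan = 1.5,
    n_qtl = 200L,
    observe_qtl = FALSE,   # causal tags are masked from the observed panel
    variance_targets = list(sigma_g2 = 1, sigma_E2 = 2,
                            sigma_gE2 = 0.5, sigma_e2 = 1.5),
    locations_per_year = NULL,   # filled below
    n_reps = 2L,
    n_testers_per_year = c(2L, 4L, 6L),
    block_size = 20L,
    block_var_ratio = 0.25,
    grand_mean = 8,
    founder_beta_shape = 0.75,
    founder_freq = NULL,         # optional fixed presence frequency
    founder_ld_morgan = 0.05,    # ancestral-LD correlation length (Morgan)
    seed = as.integer(seed)
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("reference", "minimal"))
    if (preset == "reference") {
      base$locations_per_year <- list(c("AF", "Cot", "TL"),
                                      c("AF", "Cot", "TL"),
                                      c("AF", "TL"))
      ## many small biparental populations from a broad parent pool, with
      ## 25% pool reuse: adjacent-year line-level sib overlap lands in the
      ## 30-50% band of real programs (near zero between years 1 and 3),
      ## and sib-related subsets span many families
      base$n_parents <- 40L
      base$n_populations_per_year <- 40L
      base$lines_per_population <- list(min = 1L, max = 66L, mean = 5)
      base$shared_parent_fraction <- 0.25
    } else {
      base <- utils::modifyList(base, list(
        n_parents = 10L, n_populations_per_year = 10L,
        lines_per_population = list(min = 2L, max = 30L, mean = 10),
        n_years = 2L, n_markers = 500L, n_qtl = 100L,
        locations_per_year = list("L1", "L1"),
        n_testers_per_year = c(2L, 2L)
      ))
    }
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop_config("unknown sim_config field(s): %s",
                               paste(bad, collapse = ", "))
  cfg <- base
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]   # whole-field replacement
  if (is.null(cfg$locations_per_year)) {
    cfg$locations_per_year <- rep(list(c("AF", "Cot", "TL")), cfg$n_years)
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_parents, 2)) stop_config("n_parents must be a count >= 2")
  if (!is_count(cfg$n_populations_per_year)) stop_config("n_populations_per_year must be a positive count")
  if (!is_count(cfg$n_years)) stop_config("n_years must be >= 1")
  if (!is_count(cfg$n_markers)) stop_config("n_markers must be >= 1")
  if (!is_count(cfg$n_chromosomes)) stop_config("n_chromosomes must be >= 1")
  if (!is_count(cfg$n_qtl) || cfg$n_qtl > cfg$n_markers)
    stop_config("n_qtl must be a count <= n_markers")
  if (!is.numeric(cfg$shared_parent_fraction) ||
      cfg$shared_parent_fraction < 0 || cfg$shared_parent_fraction > 1)
    stop_config("shared_parent_fraction must lie in [0, 1]")
  if (is.null(cfg$shared_cross_fraction))
    cfg$shared_cross_fraction <- cfg$shared_parent_fraction^2
  if (!is.numeric(cfg$shared_cross_fraction) ||
      cfg$shared_cross_fraction < 0 || cfg$shared_cross_fraction > 1)
    stop_config("shared_cross_fraction must lie in [0, 1]")
  vt <- cfg$variance_targets
  need <- c("sigma_g2", "sigma_E2", "sigma_gE2", "sigma_e2")
  if (!all(need %in% names(vt))) stop_config("variance_targets needs %s",
                                             paste(need, collapse = ", "))
  if (any(unlist(vt[need]) < 0)) stop_config("variance targets must be >= 0")
  lp <- cfg$lines_per_population
  if (lp$min < 1 || lp$max < lp$min || lp$mean < lp$min || lp$mean > lp$max)
    stop_config("lines_per_population must satisfy min <= mean <= max")
  if (length(cfg$locations_per_year) != cfg$n_years)
    stop_config("locations_per_year must have one entry per year")
  if (!is_count(cfg$n_reps)) stop_config("n_reps must be >= 1")
  if (choose(cfg$n_parents, 2) < cfg$n_populations_per_year)
    stop_config("too few parents for %d distinct crosses per year",
                cfg$n_populations_per_year)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_years, "years,",
      x$n_populations_per_year, "populations/year,",
      x$n_markers, "markers,", x$n_qtl, "QTL\n")
  cat("  variance targets (g, E, gE, e):",
      unlist(x$variance_targets), "\n")
  invisible(x)
}

## Truncated-geometric population sizes: many small populations, a few
## large ones, mean solved to match the configured target.
sample_population_sizes <- function(n, lp) {
  if (lp$min == lp$max) return(rep(lp$min, n))
  ks <- lp$min:lp$max
  mean_of <- function(q) sum(ks * q^(ks - lp$min)) / sum(q^(ks - lp$min))
  if (lp$mean <= mean_of(1e-9)) {
    q <- 1e-9
  } else if (lp$mean >= mean_of(1 - 1e-9)) {
    q <- 1 - 1e-9
  } else {
    q <- stats::uniroot(function(q) mean_of(q) - lp$mean,
                        c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  }
  pr <- q^(ks - lp$min)
  sample(ks, n, replace = TRUE, prob = pr / sum(pr))
}
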