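# Breeding-program generator: founder spectrum, meiosis, multi-year
# structure, phenotype variance calibration.

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config("minimal", seed = 42)
  a <- simulate_program(cfg)
  b <- simulate_program(cfg)
  expect_identical(a$markers, b$markers)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$phenotypes, b$phenotypes)

  cfg2 <- sim_config("minimal", seed = 43)
  expect_false(identical(simulate_program(cfg2)$markers, a$markers))
})

test_that("founders are binary, reproducible, and handle a degenerate spectrum", {
  cfg <- sim_config(n_parents = 2L, n_markers = 4L, n_qtl = 2L,
                    n_populations_per_year = 1L, seed = 5)
  set.seed(5); f1 <- simulate_founders(cfg)
  set.seed(5); f2 <- simulate_founders(cfg)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(2L, 4L))
  expect_true(all(f1 %in% c(0L, 1L)))

  cfg_deg <- sim_config(n_markers = 10L, n_qtl = 1L,
                        n_populations_per_year = 1L, n_parents = 2L,
                        founder_freq = 1, seed = 1)
  set.seed(1)
  fd <- simulate_founders(cfg_deg)
  expect_true(all(fd == 1L))
  expect_true(all(pmin(colMeans(fd), 1 - colMeans(fd)) == 0))
})

test_that("fraction of rare markers matches the analytic spectrum expectation", {
  cfg <- sim_config(n_parents = 100L, n_markers = 7595L, seed = 99)
  set.seed(99)
  fd <- simulate_founders(cfg)
  f <- colMeans(fd)
  observed <- mean(pmin(f, 1 - f) < 0.05)
  ## oracle: Beta(s, s) spectrum pushed through binomial sampling of 100
  ## parents; MAF < 0.05 means a presence count of <= 4 or >= 96
  s <- cfg$founder_beta_shape
  expected <- integrate(function(p)
    dbeta(p, s, s) * (pbinom(4, 100, p) + pbinom(95, 100, p, lower.tail = FALSE)),
    0, 1, rel.tol = 1e-8)$value
  expect_gt(expected, 0.08)   # the filter has work to do
  expect_lt(expected, 0.25)
  expect_lt(abs(observed - expected), 0.05)
})

test_that("DH derivation respects parental alleles and Mendelian expectations", {
  cfg <- sim_config(n_parents = 2L, n_markers = 60L, n_chromosomes = 1L,
                    n_populations_per_year = 1L,
                    chrom_length_morgan = 50, n_qtl = 10L, seed = 3)
  set.seed(3)
  m <- cfg$n_markers
  founders <- simulate_founders(cfg, parent_ids = c("A", "B"))
  ## identical parents: no segregation at all
  founders_same <- founders
  founders_same["B", ] <- founders["A", ]
  plan <- data.frame(year = "Y1", cross_id = "Y1_C01", parent1 = "A",
                     parent2 = "B", n_lines = 50L, tester = "T1")
  same <- make_dh_lines(founders_same, plan, cfg)
  expect_true(all(same$markers == rep(founders["A", ], each = 50)))

  ## parents differing at every marker, effectively unlinked loci
  founders_diff <- founders
  founders_diff["A", ] <- 0L
  founders_diff["B", ] <- 1L
  plan$n_lines <- 1000L
  dh <- make_dh_lines(founders_diff, plan, cfg)
  expect_true(all(dh$markers %in% c(0L, 1L)))
  share_b <- colMeans(dh$markers)
  bound <- qnorm(0.9995) * sqrt(0.25 / 1000)
  expect_true(all(abs(share_b - 0.5) < bound + 0.02))
  expect_lt(abs(mean(share_b) - 0.5), 0.02)

  ## full-sib allele sharing at differing markers: brute force over the
  ## four equally likely gamete picks per unlinked marker gives 1/2
  sharing <- mean(dh$markers[seq(1, 999, 2), ] == dh$markers[seq(2, 1000, 2), ])
  expect_lt(abs(sharing - 0.5), 0.02)

  ## unknown parent is a pedigree error
  bad_plan <- transform(plan, parent2 = "NOPE")
  expect_error(make_dh_lines(founders_diff, bad_plan, cfg), "unknown parent")
})

test_that("multi-year plans control parent reuse and sib structure", {
  cfg0 <- sim_config("reference", shared_parent_fraction = 0, seed = 21,
                     n_populations_per_year = 8L,
                     lines_per_population = list(min = 2L, max = 10L, mean = 5),
                     n_markers = 100L, n_qtl = 20L)
  sim0 <- simulate_program(cfg0)
  expect_true(all(sim0$sib_counts$n_full_sib == 0))
  expect_true(all(sim0$sib_counts$n_half_sib == 0))

  cfg1 <- sim_config("reference", shared_parent_fraction = 1, seed = 22,
                     n_populations_per_year = 8L,
                     lines_per_population = list(min = 2L, max = 10L, mean = 5),
                     n_markers = 100L, n_qtl = 20L)
  sim1 <- simulate_program(cfg1)
  ped1 <- sim1$pedigree
  for (pair in list(c("Y1", "Y2"), c("Y2", "Y3"))) {
    na <- sum(ped1$year == pair[1])
    row <- sim1$sib_counts[sim1$sib_counts$year_a == pair[1] &
                             sim1$sib_counts$year_b == pair[2], ]
    expect_equal(row$n_full_sib, na)  # identical cross plans: all full-sibs
  }

  expect_error(sim_config("reference", shared_parent_fraction = 1.2),
               "shared_parent_fraction")
})

test_that("reference preset has large adjacent-year but small year1-year3 sib overlap", {
  sim <- test_program(seed = 11)
  sc <- sim$sib_counts
  get <- function(a, b) {
    row <- sc[sc$year_a == a & sc$year_b == b, ]
    row$n_full_sib + row$n_half_sib
  }
  expect_gt(get("Y1", "Y2"), get("Y1", "Y3"))
  expect_gt(get("Y2", "Y3"), get("Y1", "Y3"))

  ## exhaustive pedigree scan agrees with the generator's emitted counts
  ped <- sim$pedigree
  key <- paste(pmin(ped$parent1, ped$parent2), pmax(ped$parent1, ped$parent2))
  for (i in seq_len(nrow(sc))) {
    pa <- ped[ped$year == sc$year_a[i], ]; ka <- key[ped$year == sc$year_a[i]]
    pb <- ped[ped$year == sc$year_b[i], ]; kb <- key[ped$year == sc$year_b[i]]
    full <- ka %in% kb
    half <- vapply(seq_len(nrow(pa)), function(j) {
      if (full[j]) return(FALSE)
      shared <- pb$parent1 %in% c(pa$parent1[j], pa$parent2[j]) |
        pb$parent2 %in% c(pa$parent1[j], pa$parent2[j])
      any(shared & kb != ka[j])
    }, logical(1))
    expect_equal(sum(full), sc$n_full_sib[i])
    expect_equal(sum(half), sc$n_half_sib[i])
  }
})

test_that("phenotypes reduce to true genetic values in the noise-free limit", {
  cfg <- sim_config("minimal", seed = 9,
                    variance_targets = list(sigma_g2 = 1, sigma_E2 = 0,
                                            sigma_gE2 = 0, sigma_e2 = 0))
  sim <- simulate_program(cfg)
  ph <- sim$phenotypes
  expect_equal(ph$value,
               unname(cfg$grand_mean + sim$truth$true_g[ph$line_id]),
               tolerance = 1e-12)
  reps <- tapply(ph$value, paste(ph$line_id, ph$location), sd)
  expect_true(all(reps < 1e-12))
})

test_that("plot-level heritability metadata follows the repeatability formula", {
  cfg <- sim_config("minimal", seed = 2, block_var_ratio = 0,
                    variance_targets = list(sigma_g2 = 1, sigma_E2 = 0,
                                            sigma_gE2 = 0, sigma_e2 = 1))
  sim <- simulate_program(cfg)
  expect_equal(attr(sim$phenotypes, "h2_plot"), 2 / 3, tolerance = 1e-12)
})

test_that("true genetic values are calibrated to the variance targets", {
  for (s in 1:3) {
    sim <- test_program(seed = 30 + s)
    expect_lt(abs(var(sim$truth$true_g) - sim$config$variance_targets$sigma_g2),
              0.1 * sim$config$variance_targets$sigma_g2)
  }
  ## zero interaction target gives an exactly zero interaction surface
  cfg <- sim_config("minimal", seed = 4,
                    variance_targets = list(sigma_g2 = 1, sigma_E2 = 1,
                                            sigma_gE2 = 0, sigma_e2 = 1))
  sim0 <- simulate_program(cfg)
  expect_true(all(sim0$truth$true_gE == 0))
})

test_that("method-of-moments ANOVA recovers the generating variance components", {
  targets <- c(sigma_g2 = 1, sigma_E2 = 2, sigma_gE2 = 0.5, sigma_e2 = 1)
  est <- replicate(20, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(n_years = 1L, n_populations_per_year = 25L,
                      lines_per_population = list(min = 20L, max = 20L, mean = 20),
                      locations_per_year = list(c("E1", "E2", "E3", "E4")),
                      n_markers = 300L, n_qtl = 60L, block_var_ratio = 0,
                      variance_targets = as.list(targets), seed = seed)
    sim <- simulate_program(cfg)
    ph <- sim$phenotypes
    cell <- paste(ph$line_id, ph$location)
    se2 <- mean(tapply(ph$value, cell, var))
    cm <- tapply(ph$value, list(ph$line_id, ph$location), mean)
    r <- cfg$n_reps; E <- ncol(cm); n <- nrow(cm)
    int <- cm - rowMeans(cm) - rep(colMeans(cm), each = n) + mean(cm)
    ms_int <- sum(int^2) / ((n - 1) * (E - 1))
    sge2 <- ms_int - se2 / r
    sg2 <- var(rowMeans(cm)) - sge2 / E - se2 / (r * E)
    c(sg2 = sg2, sge2 = sge2, se2 = se2)
  })
  med <- apply(est, 1, median)
  expect_lt(abs(med["sg2"] - 1) / 1, 0.25)
  expect_lt(abs(med["sge2"] - 0.5) / 0.5, 0.25)
  expect_lt(abs(med["se2"] - 1) / 1, 0.25)
})

test_that("without G-by-E the interaction mean square matches the residual expectation", {
  cfg <- sim_config(n_years = 1L, n_populations_per_year = 25L,
                    lines_per_population = list(min = 20L, max = 20L, mean = 20),
                    locations_per_year = list(c("E1", "E2", "E3")),
                    n_markers = 300L, n_qtl = 60L, block_var_ratio = 0,
                    variance_targets = list(sigma_g2 = 1, sigma_E2 = 1,
                                            sigma_gE2 = 0, sigma_e2 = 1),
                    seed = 77)
  sim <- simulate_program(cfg)
  ph <- sim$phenotypes
  cell <- paste(ph$line_id, ph$location)
  se2 <- mean(tapply(ph$value, cell, var))
  cm <- tapply(ph$value, list(ph$line_id, ph$location), mean)
  n <- nrow(cm); E <- ncol(cm)
  int <- cm - rowMeans(cm) - rep(colMeans(cm), each = n) + mean(cm)
  ms_int <- sum(int^2) / ((n - 1) * (E - 1))
  expect_lt(abs(ms_int - se2 / cfg$n_reps), 0.15 * se2)
})
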