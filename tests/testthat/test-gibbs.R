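# Single-environment and reaction-norm GBLUP by Gibbs sampling, checked
# against closed-form mixed-model oracles.

test_that("fixed-variance SM posterior means match the closed-form GBLUP solution", {
  G <- cached("oracle_grm", toy_panel(50, 200, seed = 1))
  set.seed(10)
  g <- draw_gblup_truth(G$G)
  y <- setNames(5 + g + rnorm(50), rownames(G$G))
  fit <- fit_sm(y, G, chain_settings("oracle", seed = 3),
                fixed_var = list(sigma_g2 = 1, sigma_e2 = 1))
  cf <- closed_form_gblup(unname(y), G$G, 1, 1)
  expect_gt(cor(fit$g_hat, cf$g), 0.999)
  expect_lt(sqrt(mean((fit$g_hat - cf$g)^2)), 0.02)
  expect_lt(abs(fit$mu - cf$mu), 0.02)
})

test_that("a constant response yields essentially zero genetic effects", {
  G <- cached("oracle_grm", toy_panel(50, 200, seed = 1))
  y <- setNames(rep(3, 50), rownames(G$G))
  fit <- fit_sm(y, G, chain_settings("test", seed = 5))
  expect_lt(max(abs(fit$g_hat)), 0.05)
})

test_that("seeded chains are exactly reproducible and size guards hold", {
  G <- cached("oracle_grm", toy_panel(50, 200, seed = 1))
  set.seed(2)
  y <- setNames(rnorm(50), rownames(G$G))
  f1 <- fit_sm(y, G, chain_settings("quick", seed = 7))
  f2 <- fit_sm(y, G, chain_settings("quick", seed = 7))
  expect_identical(f1$g_hat, f2$g_hat)
  expect_identical(f1$var_samples, f2$var_samples)
  f3 <- fit_sm(y, G, chain_settings("quick", seed = 8))
  expect_false(identical(f1$g_hat, f3$g_hat))

  expect_error(fit_sm(y[1:5], G, chain_settings("quick")), "fewer than 10")
  expect_error(chain_settings(NULL, 100, 200, 5), "burn_in")
})

test_that("unphenotyped lines receive closed-form conditional-mean GEBVs", {
  G <- cached("oracle_grm", toy_panel(50, 200, seed = 1))
  set.seed(33)
  g <- draw_gblup_truth(G$G)
  y_full <- 2 + g + rnorm(50, 0, 1)
  obs <- 1:40; new <- 41:50
  y <- setNames(y_full, rownames(G$G))
  y[new] <- NA
  fit <- fit_sm(y, G, chain_settings("oracle", seed = 6),
                fixed_var = list(sigma_g2 = 1, sigma_e2 = 1))
  cf <- closed_form_prediction(y_full[obs], G$G, obs, new, 1, 1)
  expect_lt(sqrt(mean((fit$g_hat[new] - cf)^2)), 0.02)

  ## a training line's prediction is its fitted value
  expect_equal(predict_gebv(fit, rownames(G$G)[3]),
               fit$mu + fit$g_hat[3], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(predict_gebv(fit, "NOT_A_LINE"), "unknown line")
})

test_that("lines with identical marker rows get identical GEBVs", {
  set.seed(4)
  M <- matrix(rbinom(30 * 150, 1, rep(runif(150, 0.2, 0.8), each = 30)), 30,
              dimnames = list(sprintf("L%03d", 1:30), sprintf("M%03d", 1:150)))
  M[2, ] <- M[1, ]  # clones
  G <- grm(standardize_markers(maf_filter(M)))
  g <- draw_gblup_truth(G$G)
  y <- setNames(g + rnorm(30, 0, 0.5), rownames(G$G))
  y[1:2] <- NA  # predict both clones from the rest
  fit <- fit_sm(y, G, chain_settings("oracle", seed = 9))
  expect_lt(abs(fit$g_hat[1] - fit$g_hat[2]), 0.02)
})

test_that("the structured reaction-norm kernels equal their dense Hadamard forms", {
  ## 4 records x 2 environments, brute-force elementwise reference
  G4 <- toy_panel(4, 80, seed = 2)
  lines <- rownames(G4$G)[c(1, 2, 3, 4, 1, 3)]
  envs <- c("e1", "e1", "e1", "e1", "e2", "e2")
  K <- interaction_kernel(G4, lines, envs)
  Kg <- G4$G[lines, lines]
  ZE <- outer(envs, envs, "==")
  ref <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) ref[i, j] <- Kg[i, j] * ZE[i, j]
  expect_equal(unname(K), ref, tolerance = 1e-12)

  ## the sampler's eigen-operators reconstruct [Zg G Zg'] # [ZE ZE'] and
  ## the genetic main-effect kernel on the complete grid
  L <- 5; E <- 3
  G5 <- toy_panel(5, 80, seed = 3)
  eig <- dhgs:::kernel_eigen(G5$G)
  kG <- length(eig$d)
  grid_lines <- rep(rownames(G5$G), times = E)
  grid_envs <- rep(paste0("e", 1:E), each = L)
  gE_op <- function(a) as.vector(eig$U %*% matrix(a, kG, E))
  A <- vapply(seq_len(kG * E), function(j) {
    a <- numeric(kG * E); a[j] <- 1; gE_op(a)
  }, numeric(L * E))
  K_gE <- A %*% (rep(eig$d, E) * t(A))
  expect_lt(max(abs(K_gE - interaction_kernel(G5, grid_lines, grid_envs))), 1e-6)
  g_op <- function(a) rep(as.vector(eig$U %*% a), E) / sqrt(E)
  B <- vapply(seq_len(kG), function(j) {
    a <- numeric(kG); a[j] <- 1; g_op(a)
  }, numeric(L * E))
  K_g <- B %*% (E * eig$d * t(B))
  expect_lt(max(abs(K_g - G5$G[grid_lines, grid_lines])), 1e-6)
})

test_that("MM posterior keeps the interaction variance near zero when there is none", {
  ## family-structured relationship matrices (the generator's regime) are
  ## what identifies the interaction kernel against the residual
  ratios <- vapply(1:5, function(s) {
    d <- cached(paste0("mm_null_data_", s), {
      cfg <- sim_config(n_years = 1L, n_populations_per_year = 15L,
                        lines_per_population = list(min = 8L, max = 8L, mean = 8),
                        locations_per_year = list(c("E1", "E2", "E3")),
                        n_markers = 400L, n_qtl = 80L, seed = 100 + s,
                        variance_targets = list(sigma_g2 = 1, sigma_E2 = 1,
                                                sigma_gE2 = 0, sigma_e2 = 1))
      prepare_validation_data(simulate_program(cfg))
    })
    cells <- data.frame(line_id = d$within$line_id, env = d$within$env,
                        value = d$within$blup)
    fit <- fit_mm(cells, d$G, chain_settings("quick", seed = 300 + s))
    fit$sigma_gE2 / fit$sigma_g2
  }, numeric(1))
  expect_lt(median(ratios), 0.15)
})

test_that("MM recovers variance components from a structured simulation", {
  ## moderate size here; the full-scale recovery condition is exercised in
  ## the acceptance suite
  est <- vapply(1:5, function(s) {
    G <- cached(paste0("mm_rec_grm_", s), toy_panel(150, 300, seed = 400 + s))
    set.seed(500 + s)
    g <- draw_gblup_truth(G$G, 1)
    E <- 3
    gE <- vapply(1:E, function(e) draw_gblup_truth(G$G, 0.5), numeric(150))
    E_eff <- rnorm(E, 0, sqrt(2))
    cells <- expand.grid(line_id = rownames(G$G), env = paste0("e", 1:E),
                         stringsAsFactors = FALSE)
    ei <- as.integer(factor(cells$env))
    cells$value <- g[cells$line_id] + E_eff[ei] +
      gE[cbind(match(cells$line_id, rownames(G$G)), ei)] +
      rnorm(nrow(cells), 0, 1)
    fit <- fit_mm(cells, G, chain_settings("test", seed = 600 + s))
    c(fit$sigma_g2, fit$sigma_gE2, fit$sigma_e2)
  }, numeric(3))
  med <- apply(est, 1, median)
  expect_lt(abs(med[1] - 1) / 1, 0.3)
  expect_lt(abs(med[2] - 0.5) / 0.5, 0.3)
  expect_lt(abs(med[3] - 1) / 1, 0.3)
})

test_that("MM predictions use environment effects when available, main effects otherwise", {
  G <- toy_panel(40, 150, seed = 5)
  set.seed(6)
  g <- draw_gblup_truth(G$G)
  cells <- expand.grid(line_id = rownames(G$G), env = c("e1", "e2"),
                       stringsAsFactors = FALSE)
  cells$value <- g[cells$line_id] + c(e1 = -1, e2 = 1)[cells$env] +
    rnorm(nrow(cells), 0, 0.5)
  cells$value[cells$line_id %in% rownames(G$G)[1:5]] <- NA
  fit <- fit_mm(cells, G, chain_settings("test", seed = 7))
  tst <- rownames(G$G)[1:5]
  p_env <- predict_gebv(fit, tst, environment = "e2")
  p_main <- predict_gebv(fit, tst)
  expect_equal(unname(p_env - p_main),
               rep(fit$E_hat[["e2"]], 5) + unname(fit$gE_hat[tst, "e2"]),
               tolerance = 1e-12)
  expect_error(predict_gebv(fit, tst, environment = "e99"), "unknown environment")
  expect_error(fit_mm(cells[cells$env == "e1", ], G), "one environment")
})

test_that("prediction accuracy is the Pearson correlation with missing-pair handling", {
  expect_equal(pearson_accuracy(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_accuracy(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(8)
  x <- rnorm(100); z <- rnorm(100)
  ## independent two-pass formula
  ref <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  expect_equal(pearson_accuracy(x, z), ref, tolerance = 1e-12)
  expect_message(r <- pearson_accuracy(c(x, NA), c(z, 1)), "dropping 1")
  expect_equal(r, ref, tolerance = 1e-12)
  expect_error(pearson_accuracy(1:2, 1:2), "at least 3")
  expect_warning(r0 <- pearson_accuracy(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r0))
  ## named vectors align by line id
  a <- setNames(x[1:10], paste0("L", 1:10))
  b <- setNames(rev(x[1:10]), paste0("L", 10:1))
  expect_equal(pearson_accuracy(a, b), 1.0)
})

test_that("simulated-truth benchmark: SM reaches workable accuracy at h2 = 0.7", {
  accs <- vapply(1:10, function(s) {
    G <- cached(paste0("bench_grm_", s), {
      cfg <- sim_config(n_years = 1L, n_populations_per_year = 25L,
                        lines_per_population = list(min = 20L, max = 20L, mean = 20),
                        locations_per_year = list("E1"), n_markers = 400L,
                        n_qtl = 80L, seed = 700 + s,
                        variance_targets = list(sigma_g2 = 1, sigma_E2 = 0,
                                                sigma_gE2 = 0, sigma_e2 = 0.857))
      sim <- simulate_program(cfg)
      list(G = prepare_validation_data(sim)$G, truth = sim$truth$true_g)
    })
    set.seed(800 + s)
    ids <- rownames(G$G$G)
    ## plot h2 = 1/(1+0.857/2) = 0.7 at the line-mean level used here
    y_line <- G$truth[ids] + rnorm(length(ids), 0, sqrt(0.857 / 2))
    tst <- sample(ids, 100)
    y <- setNames(y_line, ids)
    y[tst] <- NA
    fit <- fit_sm(y, G$G, chain_settings("quick", seed = 900 + s))
    cor(G$truth[tst], fit$g_hat[tst])
  }, numeric(1))
  expect_gte(median(accs), 0.4)
})
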