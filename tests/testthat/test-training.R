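test_that("binning partitions sorted records into near-equal bins", {
  set.seed(14)
  d <- tibble::tibble(phi = runif(60, 1, 30), abraham_b = runif(60, 0.4, 3),
                      logs0_obs = rnorm(60))
  b <- bin_by_key(d, key = "phi_plus_b", n_bins = 20)
  expect_equal(nrow(b), 60)
  expect_equal(unname(table(b$bin)), rep(3L, 20), ignore_attr = TRUE)
  expect_false(is.unsorted(b$key_value))
  means <- tapply(b$key_value, b$bin, mean)
  expect_false(is.unsorted(means))
  # every record in exactly one bin
  expect_equal(sort(unique(b$bin)), 1:20)
  expect_error(bin_by_key(d, n_bins = 20, key = "phi"),
               NA)  # phi key works too
  expect_error(bin_by_key(d[1:10, ], n_bins = 20), "at least 60")
})

test_that("duplicate keys at a bin edge keep the partition exhaustive", {
  d <- tibble::tibble(phi = c(rep(5, 30), runif(30, 6, 20)),
                      abraham_b = 0.5, logs0_obs = rnorm(60))
  b <- bin_by_key(d, key = "phi", n_bins = 10)
  expect_equal(nrow(b), 60)
  expect_equal(sum(table(b$bin)), 60)
  expect_false(is.unsorted(b$key_value))
})

test_that("per-bin fits recover generating coefficients exactly at zero noise", {
  set.seed(11)
  d <- tibble::tibble(clogp = runif(50, -2, 6), mp_c = runif(50, 30, 300))
  d$logs0_obs <- 0.5 - 1.0 * d$clogp - 1.0 * (d$mp_c - 25) / 100
  co <- fit_bin_gse(d)
  expect_equal(unname(co), c(0.5, -1.0, -1.0), tolerance = 1e-8)
  # permutation invariance
  co2 <- fit_bin_gse(d[sample(50), ])
  expect_equal(co, co2, tolerance = 1e-10)
  # rank-deficient design is refused with a useful message
  expect_error(fit_bin_gse(tibble::tibble(clogp = 1, mp_c = c(100, 150, 200),
                                          logs0_obs = 1:3)),
               "rank deficient")
  expect_error(fit_bin_gse(d[1:2, ]), ">= 3")
})

test_that("per-bin lipophilicity slope is unbiased under noise (Monte Carlo)", {
  # 200 replicates at n = 1000, sigma = 0.5: the mean recovered slope must
  # sit within 0.05 of the generating -1.0
  set.seed(404)
  c1_hat <- replicate(200, {
    d <- tibble::tibble(clogp = runif(1000, -2, 6), mp_c = runif(1000, 30, 300))
    d$logs0_obs <- 0.5 - d$clogp - (d$mp_c - 25) / 100 + rnorm(1000, 0, 0.5)
    fit_bin_gse(d)["c1"]
  })
  expect_lt(abs(mean(c1_hat) + 1.0), 0.05)
})

test_that("coefficient-function fitting inverts noiseless published curves", {
  truth <- flex_acceptor_params()
  x <- 1:20
  cc <- c_coefficients(x, truth)
  fit <- fit_c_functions(tibble::tibble(key_mean = x, c0 = cc$c0,
                                        c1 = cc$c1, c2 = cc$c2))
  got <- unlist(fit$params)
  expect_equal(got, unlist(truth), tolerance = 1e-4)
  expect_true(all(fit$diagnostics$r2 > 1 - 1e-8))
  # invariance to bin ordering
  sh <- sample(20)
  fit2 <- fit_c_functions(tibble::tibble(key_mean = x, c0 = cc$c0,
                                         c1 = cc$c1, c2 = cc$c2)[sh, ])
  expect_equal(unlist(fit2$params), got, tolerance = 1e-8)
  # tidy/glance interfaces
  td <- generics::tidy(fit)
  expect_equal(td$term, paste0("b", 0:7))
  expect_equal(td$estimate, unname(got))
  expect_equal(generics::glance(fit)$n_bins, 20)
})

test_that("the linear crystal-lattice sub-fit equals ordinary least squares", {
  set.seed(6)
  x <- seq(0.5, 30, length.out = 12)
  c2pts <- -0.9 + 0.04 * x + rnorm(12, 0, 0.05)
  cc <- c_coefficients(x)
  fit <- fit_c_functions(tibble::tibble(key_mean = x, c0 = cc$c0, c1 = cc$c1,
                                        c2 = c2pts))
  ols <- stats::lm(c2pts ~ x)
  expect_equal(fit$params$b6, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$params$b7, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_error(fit_c_functions(tibble::tibble(key_mean = 1:5, c0 = 1:5,
                                              c1 = 1:5, c2 = 1:5)),
               "at least 8 bins")
})

test_that("coefficient functions are recoverable from noisy bins (Monte Carlo)", {
  truth <- flex_acceptor_params()
  x <- seq(1, 40, length.out = 20)
  cc <- c_coefficients(x, truth)
  set.seed(909)
  rel_err <- replicate(100, {
    fit <- fit_c_functions(tibble::tibble(
      key_mean = x,
      c0 = cc$c0 + rnorm(20, 0, 0.1),
      c1 = cc$c1 + rnorm(20, 0, 0.1),
      c2 = cc$c2 + rnorm(20, 0, 0.1)))
    abs(unlist(fit$params) - unlist(truth)) / abs(unlist(truth))
  })
  expect_lte(median(rel_err), 0.10)
})

test_that("grouped ABSOLV fits invert noiseless data and ignore record order", {
  set.seed(21)
  tab <- absolv_group_table()
  d <- tibble::tibble(
    abraham_a = runif(60, 0, 2), abraham_b = runif(60, 0.4, 6),
    abraham_s = runif(60, 0.5, 3.5), abraham_e = runif(60, 0.5, 4),
    abraham_v = runif(60, 0.5, 3), group = "neutral")
  d$logs0_obs <- absolv_grp(d$abraham_a, d$abraham_b, d$abraham_s,
                            d$abraham_e, d$abraham_v, d$group)
  fit <- fit_absolv_groups(d)
  neutral <- fit$table[fit$table$group == "neutral", paste0("a", 0:6)]
  expect_equal(unlist(neutral), unlist(tab[tab$group == "neutral", paste0("a", 0:6)]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # groups without data are reported unfit, not invented
  expect_true(all(is.na(fit$table[fit$table$group == "big", "a0"])))
  expect_equal(generics::glance(fit)$n[generics::glance(fit)$group == "neutral"], 60)
  # shuffle invariance
  fit2 <- fit_absolv_groups(d[sample(60), ])
  expect_equal(fit$table, fit2$table, tolerance = 1e-10)
  expect_error(fit_absolv_groups(d[1:4, ]), "floor")
})

test_that("grouped ABSOLV acceptor coefficient is unbiased under noise", {
  # 100 replicates, n = 500, sigma = 0.5: mean recovered a2 within 0.1
  tab <- absolv_group_table()
  truth_a2 <- tab$a2[tab$group == "neutral"]
  set.seed(515)
  a2_hat <- replicate(100, {
    d <- tibble::tibble(
      abraham_a = runif(500, 0, 2), abraham_b = runif(500, 0.4, 6),
      abraham_s = runif(500, 0.5, 3.5), abraham_e = runif(500, 0.5, 4),
      abraham_v = runif(500, 0.5, 3), group = "neutral")
    d$logs0_obs <- absolv_grp(d$abraham_a, d$abraham_b, d$abraham_s,
                              d$abraham_e, d$abraham_v, d$group) +
      rnorm(500, 0, 0.5)
    fit <- fit_absolv_groups(d)
    fit$table$a2[fit$table$group == "neutral"]
  })
  expect_lt(abs(mean(a2_hat) - truth_a2), 0.1)
})

test_that("two-step training recovers the generating constants end to end", {
  # stratified design: one Phi level per bin, constant B, so binning adds no
  # within-bin coefficient variation and zero-noise recovery is exact
  d <- simulate_compounds(4000, model = "gse_phib", noise_sd = 0, seed = 7,
                          phi_levels = 20, ranges = list(b = c(0.4, 0.4)))
  fit <- train_flex_acceptor(d, n_bins = 20, strategy = "equal_width")
  expect_equal(unlist(fit$params), unlist(flex_acceptor_params()),
               tolerance = 1e-6)
  expect_equal(sum(fit$bin_fits$n_entries), 4000)
})

test_that("bin profiling reproduces brute-force RMSE and crowns the generator", {
  d <- simulate_compounds(1500, model = "gse_phib", noise_sd = 0.1, seed = 12)
  prof <- suppressMessages(profile_bins(d, n_bins = 8))
  expect_equal(nrow(prof), 8)
  expect_equal(sum(prof$n_entries), 1500)
  expect_false(is.unsorted(prof$phi_avg))
  # the generating model wins every bin at small noise
  expect_true(all(prof$best_model == "gse_phib"))
  # RMSE equals a brute-force recomputation over the bin members
  preds <- predict_solubility(d, selector = "consensus")
  binned <- bin_by_key(preds, key = "phi", n_bins = 8)
  for (bi in c(1, 5, 8)) {
    members <- binned[binned$bin == bi, ]
    expect_equal(prof$rmse_gse[bi],
                 sqrt(mean((members$logs0_obs - members$logs0_gse)^2)),
                 tolerance = 1e-12)
    expect_equal(prof$rmse_gse_phib[bi],
                 sqrt(mean((members$logs0_obs - members$logs0_gse_phib)^2)),
                 tolerance = 1e-12)
  }
})
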