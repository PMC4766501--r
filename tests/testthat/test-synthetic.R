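test_that("generators are pure functions of their seed", {
  expect_identical(gen_trace(3.2, 25, 40, seed = 5),
                   gen_trace(3.2, 25, 40, seed = 5))
  expect_false(identical(gen_trace(3.2, 25, 40, seed = 5)$signal,
                         gen_trace(3.2, 25, 40, seed = 6)$signal))
  t1 <- gen_toy_complex(seed = 9)
  t2 <- gen_toy_complex(seed = 9)
  expect_identical(t1, t2)
  fx <- toy_fixture()
  expect_identical(gen_phi_set(fx$map, "B", 0.7, 0.1, seed = 4),
                   gen_phi_set(fx$map, "B", 0.7, 0.1, seed = 4))
  ## generator calls do not perturb the caller's RNG stream
  set.seed(123); a <- rnorm(1)
  set.seed(123); invisible(gen_trace(3.2, 25, 40, seed = 1)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("gen_trace embeds the pseudo-first-order rate and spans the decay", {
  tr <- gen_trace(3.2, 25, ligand_conc = 40, noise_sd_frac = 0, seed = 1)
  expect_equal(attr(tr, "k_obs_true"), 153)
  expect_gte(max(tr$time_s), 5 / 153)
  expect_error(gen_trace(-1, 25, 40), class = "domain_error")
  expect_error(gen_trace(3.2, 25, -4), class = "domain_error")
})

test_that("gen_trace_series reproduces the experimental design and manifests it", {
  rc <- rate_constants(3.2, 25)
  ser <- gen_trace_series(rc, replicates = 2L, seed = 1, n_points = 60L)
  expect_equal(length(ser$traces), 10L)          # 5 concentrations x 2
  expect_equal(sort(unique(ser$manifest$ligand_conc_uM)),
               c(8, 16, 32, 64, 80))
  expect_true(all(ser$manifest$probe_conc_uM == 3))
  expect_error(gen_trace_series(rc, concs = c(8, 16)),
               class = "insufficient_data")
})

test_that("toy complex honours its construction guarantees", {
  fx <- toy_fixture()
  rt <- residue_table(fx$toy)
  expect_equal(sum(rt$role == "receptor"), 30L)
  expect_equal(sum(rt$role == "ligand"), 10L)
  ## every ligand residue has >= 1 native inter-chain contact
  inter <- fx$map[fx$map$chain_i != fx$map$chain_j, ]
  lig_res <- sort(unique(c(inter$res_i[inter$chain_i == "B"],
                           inter$res_j[inter$chain_j == "B"])))
  expect_equal(lig_res, 1:10)
  ## no steric disaster: chains do not interpenetrate
  A <- as.matrix(fx$toy[fx$toy$chain == "A", c("x", "y", "z")])
  B <- as.matrix(fx$toy[fx$toy$chain == "B", c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  expect_gt(sqrt(min(d2)), 0.1)
  expect_error(gen_toy_complex(receptor_len = 3L), class = "domain_error")
})

test_that("gen_phi_set draws match the requested moments and support", {
  fx <- toy_fixture()
  ## zero spread: constant at the mean
  rs0 <- gen_phi_set(fx$map, "B", 1, 0, seed = 1)
  expect_true(all(rs0$phi == 1))
  ## only residues with native contacts are restrained
  in_map <- unique(c(paste(fx$map$chain_i, fx$map$res_i),
                     paste(fx$map$chain_j, fx$map$res_j)))
  expect_true(all(paste(rs0$chain, rs0$resid) %in% in_map))
  ## sample mean over many draws is within 3 sd of the target
  draws <- unlist(lapply(1:100, function(i)
    gen_phi_set(fx$map, "B", 0.55, 0.13, seed = i)$phi))
  expect_lt(abs(mean(draws) - 0.55), 3 * 0.13 / sqrt(length(draws) / 2))
  expect_true(all(draws >= 0 & draws <= 1.2))
  expect_error(gen_phi_set(fx$map, "B", 1.5, 0.1), class = "domain_error")
})

test_that("gen_lfer_dataset round-trips slope and intercept at zero noise", {
  lf <- lfer_fit(gen_lfer_dataset(0.89, 0.5, n = 10L, noise_sd = 0, seed = 2),
                 bootstrap = 0L, seed = 1)
  expect_equal(lf$alpha, 0.89, tolerance = 1e-10)
  expect_equal(lf$intercept, 0.5, tolerance = 1e-10)
  lf0 <- lfer_fit(gen_lfer_dataset(0, 0.2, n = 10L, noise_sd = 0, seed = 2),
                  bootstrap = 0L, seed = 1)
  expect_equal(lf0$alpha, 0, tolerance = 1e-10)
  ## records pass the energetics invariants unchanged
  recs <- gen_lfer_dataset(0.5, 0, n = 20L, ddg_range = c(0.1, 2), seed = 3)
  expect_true(all(is.na(recs$phi[abs(recs$ddG_eq) < 0.4])))
  expect_true(all(!recs$included_in_phi[abs(recs$ddG_eq) < 0.4]))
})

test_that("trace series round-trips through the CSV manifest format", {
  rc <- rate_constants(1.46, 6, variant_receptor = "I72V")
  ser <- gen_trace_series(rc, replicates = 1L, noise_sd_frac = 0, seed = 1,
                          n_points = 60L)
  dir <- withr::local_tempdir()
  manifest <- write_trace_series(ser, dir)
  back <- read_trace_manifest(manifest)
  expect_equal(length(back), length(ser$traces))
  expect_equal(back[[3]]$signal, ser$traces[[3]]$signal, tolerance = 1e-12)
  expect_equal(attr(back[[1]], "variant_receptor"), "I72V")
  f <- fit_trace_set(back)
  expect_equal(f$k_on, 1.46, tolerance = 1e-6)
})

test_that("rate and restraint CSV round trips preserve values", {
  rates <- list(rate_constants(3.2, 25, 0.3, 3),
                rate_constants(0.6, 16, 0.1, 2,
                               variant_receptor = "I72V/T11A"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rates_csv(rates, path)
  back <- read_rates_csv(path)
  expect_equal(back[[2]]$k_on, 0.6)
  expect_equal(back[[2]]$variant_receptor, "I72V/T11A")
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 0.8, 0.1, seed = 2)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_restraints_csv(rs, p2)
  rs2 <- read_restraints_csv(p2, ref = fx$map)
  expect_equal(rs2$phi, rs$phi, tolerance = 1e-12)
})

test_that("the packaged scenario carries the validation kinetics and alpha ladder", {
  scen <- scenario_paper_like(1L)
  expect_equal(scen$rates$WT$k_on, 3.2)
  expect_equal(scen$rates$`I72V/T11A`$k_off, 16)
  expect_equal(scen$ts_scenarios$alpha, c(0.89, 0.54, 0.51, 0.19))
  expect_equal(scen$ts_scenarios$mean_phi, c(0.9, 0.55, 0.5, 0.2))
  expect_equal(scen$concs, c(8, 16, 32, 64, 80))
})
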