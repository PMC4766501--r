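test_that("annealing schedule validates its parameters", {
  s <- annealing_schedule()
  expect_equal(s$n_cycles, 300L)
  expect_equal(s$T_high, 383)
  expect_equal(s$T_low, 283)
  expect_error(annealing_schedule(0L), class = "domain_error")
  expect_error(annealing_schedule(T_high = 200, T_low = 300),
               class = "domain_error")
})

test_that("identical seed and schedule give a bit-identical ensemble", {
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 0.7, 0.1, seed = 2)
  sched <- annealing_schedule(3L, 150L)
  e1 <- anneal(fx$model, rs, sched, seed = 42, burn_in = 1L)
  e2 <- anneal(fx$model, rs, sched, seed = 42, burn_in = 1L)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$phi_sim, e2$phi_sim)
  e3 <- anneal(fx$model, rs, sched, seed = 43, burn_in = 1L)
  expect_false(identical(e1$coords, e3$coords))
  expect_equal(n_conformations(e1), 3L)     # burn-in cycles not recorded
})

test_that("strong all-one restraints keep the ensemble native-like", {
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 1, 0, seed = 1)
  e <- anneal(fx$model, rs, annealing_schedule(8L, 500L), seed = 5)
  expect_gte(mean(mean_phi_sim(e, TRUE)), 0.9)
})

test_that("unrestrained annealing from native relaxes back to the native basin", {
  fx <- toy_fixture()
  empty <- phi_restraint_set(character(0), integer(0), numeric(0))
  e <- anneal(fx$model, empty, annealing_schedule(10L, 600L), seed = 5,
              k_phi = 0, random_pose = FALSE, burn_in = 0L)
  fq <- contact_frequency_map(e, fx$map)
  expect_gt(mean(fq$native$frequency), 0.8)
})

test_that("native reference is stationary, native-like and calm", {
  fx <- toy_fixture()
  nref <- native_reference(fx$model, sweeps = 4000L, seed = 3,
                           record_stride = 40L)
  expect_equal(n_conformations(nref), 100L)
  ## mean Phi_sim ~ 1 within 0.1
  expect_gt(mean(colMeans(nref$phi_sim), na.rm = TRUE), 0.9)
  ## no energy drift: second-half mean within 2 sd of first-half mean
  e <- nref$mechanical_energy
  h1 <- e[1:50]; h2 <- e[51:100]
  expect_lt(abs(mean(h2) - mean(h1)), 2 * sd(e))
})

test_that("native reference fluctuates less than a weakly restrained TS ensemble", {
  fx <- toy_fixture()
  nref <- native_reference(fx$model, sweeps = 4000L, seed = 9,
                           record_stride = 100L)
  rs <- gen_phi_set(fx$map, "B", 0.45, 0.1, seed = 4)
  e <- anneal(fx$model, rs, annealing_schedule(12L, 600L), seed = 9)
  expect_lt(ensemble_fluctuation(nref)$fluctuation,
            ensemble_fluctuation(e)$fluctuation)
})

test_that("Metropolis kernel reproduces exact Boltzmann statistics (detailed balance)", {
  ## two tethered, bonded glycine sites at identical native positions:
  ## the bond length r then follows a Maxwell distribution with
  ## scale^2 = kT / (2 (k_tether/2 + k_bond)) -- exactly integrable.
  atoms <- data.frame(
    chain = c("A", "A", "B"), resid = c(1L, 2L, 1L), restype = "GLY",
    atom = "CA", element = "C",
    x = c(0, 0, 5), y = c(0, 0, 5), z = c(0, 0, 5))
  s <- complex_structure(atoms, "A", "B")
  model <- build_cg_model(s, params = list(conf_k = 0))
  expect_equal(nrow(model$contacts), 0L)
  temperature <- 300
  run <- native_reference(model, temperature = temperature, sweeps = 60000L,
                          seed = 17, record_stride = 50L)
  d <- sqrt(colSums((run$coords[1, , ] - run$coords[2, , ])^2))
  kT <- gas_constant_kcal() * temperature
  cc <- cg_defaults()$k_tether_ca / 2 + cg_defaults()$k_bond
  a2 <- kT / (2 * cc)
  ## exact bin probabilities of p(r) dr ~ r^2 exp(-r^2 / (2 a2)) dr
  dens <- function(r) r^2 * exp(-r^2 / (2 * a2))
  norm <- integrate(dens, 0, Inf)$value
  qs <- seq(0, 0.999, length.out = 11)
  ## bin edges from the empirical range, probabilities from the density
  edges <- c(0, quantile(d, qs[-1]), Inf)
  probs <- vapply(seq_len(length(edges) - 1L), function(i)
    integrate(dens, edges[i], edges[i + 1L])$value / norm, numeric(1))
  counts <- table(cut(d, edges, include.lowest = TRUE))
  chi <- sum((as.numeric(counts) - length(d) * probs)^2 /
               (length(d) * probs))
  p <- pchisq(chi, df = length(probs) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.01)
  ## and the mean matches the analytic Maxwell mean 2 a sqrt(2/pi)
  expect_equal(mean(d), 2 * sqrt(a2) * sqrt(2 / pi), tolerance = 0.05)
})

test_that("subset control with the full set degenerates to a plain anneal", {
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 0.8, 0.1, seed = 6)
  sched <- annealing_schedule(3L, 150L)
  full <- anneal(fx$model, rs, sched, seed = 11)
  sub <- subset_restraint_control(fx$model, rs, rs$resid, sched, seed = 11,
                                  full_ensemble = full)
  expect_identical(sub$coords, full$coords)
  expect_equal(sub$subset_comparison$mean_abs_freq_diff, 0)
  expect_error(subset_restraint_control(fx$model, rs, integer(0), sched, 1),
               class = "domain_error")
  expect_error(subset_restraint_control(fx$model, rs, 999L, sched, 1),
               class = "domain_error")
})

test_that("subset control recovers its targets and reports the comparison", {
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 0.75, 0.1, seed = 8)
  rs$phi <- pmin(pmax(rs$phi, 0.2), 1)
  sched <- annealing_schedule(12L, 800L)
  subset <- rs$resid[c(1L, 3L, 5L, 7L)]
  full <- anneal(fx$model, rs, sched, seed = 13)
  sub <- subset_restraint_control(fx$model, rs, subset, sched, seed = 13,
                                  full_ensemble = full)
  got <- mean_phi_sim(sub)[paste0("B", subset)]
  want <- rs$phi[match(subset, rs$resid)]
  expect_lt(max(abs(got - want)), 0.15)
  expect_true(is.finite(sub$subset_comparison$native_fraction_subset))
})

test_that("ensemble round-trips through the multi-MODEL PDB writer", {
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 0.9, 0.05, seed = 2)
  e <- anneal(fx$model, rs, annealing_schedule(3L, 100L), seed = 1,
              burn_in = 0L)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(e, pdb, csv)
  txt <- readLines(pdb)
  expect_equal(sum(startsWith(txt, "MODEL")), 3L)
  back <- read_pdb(pdb, "A", "B", model = 2L)
  expect_equal(nrow(back), nrow(fx$model$coords0))
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) - e$coords[, , 2])),
            1e-3)
  df <- read.csv(csv)
  expect_equal(nrow(df), 3L)
  expect_true(all(c("mechanical_energy", "restraint_energy") %in% names(df)))
})
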