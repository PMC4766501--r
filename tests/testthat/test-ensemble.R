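## build a small ensemble object by hand around the toy model
manual_ensemble <- function(frames, model) {
  coords <- array(unlist(frames), dim = c(nrow(model$coords0), 3L,
                                          length(frames)))
  structure(list(coords = coords,
                 mechanical_energy = rep(0, length(frames)),
                 restraint_energy = rep(0, length(frames)),
                 temperature = rep(283, length(frames)),
                 phi_sim = matrix(NA_real_, length(frames), model$nres),
                 acceptance = c(site = NA_real_, rigid = NA_real_),
                 model = model,
                 provenance = list(kind = "manual", restraints = NULL)),
            class = "ts_ensemble")
}

test_that("identical members give zero fluctuation", {
  fx <- toy_fixture()
  e <- manual_ensemble(list(fx$model$coords0, fx$model$coords0,
                            fx$model$coords0), fx$model)
  expect_equal(ensemble_fluctuation(e)$fluctuation, 0, tolerance = 1e-9)
})

test_that("two-member displacement matches the closed form", {
  ## one ligand CA site displaced by d between the two members (with the
  ## receptor fixed, alignment is the identity): each member deviates
  ## d/2 at that site, so the RMS over the n_sel selected sites is
  ## sqrt(d^2 / (4 n_sel)) for both members.
  fx <- toy_fixture()
  m <- fx$model
  lig_ca <- which(m$chain == 1L & m$sites$type == "CA")
  f2 <- m$coords0
  d <- 0.8
  f2[lig_ca[3], 1] <- f2[lig_ca[3], 1] + d
  e <- manual_ensemble(list(m$coords0, f2), m)
  got <- ensemble_fluctuation(e, selection = "ligand_ca")
  expect_equal(got$fluctuation, sqrt(d^2 / (4 * length(lig_ca))),
               tolerance = 1e-6)
  expect_equal(got$per_member[1], got$per_member[2], tolerance = 1e-9)
})

test_that("fluctuation is invariant under a global rigid motion of every member", {
  fx <- toy_fixture()
  rs <- gen_phi_set(fx$map, "B", 0.7, 0.1, seed = 3)
  e <- anneal(fx$model, rs, annealing_schedule(4L, 200L), seed = 2,
              burn_in = 0L)
  f1 <- ensemble_fluctuation(e)$fluctuation
  e2 <- e
  for (k in seq_len(n_conformations(e)))
    e2$coords[, , k] <- rigid_transform(e$coords[, , k])
  expect_equal(ensemble_fluctuation(e2)$fluctuation, f1, tolerance = 1e-6)
  expect_error(ensemble_fluctuation(e, selection = "bogus"),
               class = "domain_error")
})

test_that("contact frequencies equal brute-force counts on a hand-built ensemble", {
  fx <- toy_fixture()
  m <- fx$model
  lig <- m$chain == 1L
  ## 4 members: native, native, ligand shifted out, ligand far away
  f_out <- m$coords0; f_out[lig, 2] <- f_out[lig, 2] + 0.45
  f_far <- m$coords0; f_far[lig, 2] <- f_far[lig, 2] + 8
  e <- manual_ensemble(list(m$coords0, m$coords0, f_out, f_far), m)
  fq <- contact_frequency_map(e, fx$map)
  ## brute force: count frames with centroid distance < 1.2 native
  sc <- m$sc_site
  rt <- m$residues
  ra <- match(paste(fx$map$chain_i, fx$map$res_i), paste(rt$chain, rt$resid))
  rb <- match(paste(fx$map$chain_j, fx$map$res_j), paste(rt$chain, rt$resid))
  for (k in seq_len(nrow(fx$map))) {
    rn <- sqrt(sum((m$coords0[sc[ra[k]], ] - m$coords0[sc[rb[k]], ])^2))
    cnt <- 0L
    for (fr in seq_len(4L)) {
      x <- e$coords[, , fr]
      if (sqrt(sum((x[sc[ra[k]], ] - x[sc[rb[k]], ])^2)) < 1.2 * rn)
        cnt <- cnt + 1L
    }
    expect_equal(fq$native$frequency[k], cnt / 4)
  }
  ## native-only ensemble: frequency 1 everywhere, no non-native pairs
  e_nat <- manual_ensemble(list(m$coords0, m$coords0), m)
  fq_nat <- contact_frequency_map(e_nat, fx$map)
  expect_true(all(fq_nat$native$frequency == 1))
  expect_equal(nrow(fq_nat$non_native), 0L)
  ## dissociated ensemble: all inter-chain frequencies are zero
  e_far <- manual_ensemble(list(f_far, f_far), m)
  fq_far <- contact_frequency_map(e_far, fx$map)
  inter <- fq_far$native$chain_i != fq_far$native$chain_j
  expect_true(all(fq_far$native$frequency[inter] == 0))
})

test_that("non-native contacts are reported above the frequency threshold", {
  fx <- toy_fixture()
  m <- fx$model
  lig <- m$chain == 1L
  ## slide the ligand along the groove axis: new residue pairings form
  f_slide <- m$coords0
  f_slide[lig, 3] <- f_slide[lig, 3] + 0.65
  e <- manual_ensemble(rep(list(f_slide), 3L), m)
  fq <- contact_frequency_map(e, fx$map)
  expect_gt(nrow(fq$non_native), 0L)
  expect_true(all(fq$non_native$frequency >= 0.1))
})

test_that("correlate matches the textbook formula and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  y <- 2 * x + 1
  cr <- correlate(x, y)
  expect_equal(cr$r, 1)
  expect_equal(cr$slope, 2)
  expect_equal(cr$intercept, 1)
  ## hand-computed sums for a 4-point set (independent formula)
  x2 <- c(0.3, 1.1, 2.0, 2.8); y2 <- c(1.2, 0.7, 2.5, 1.9)
  n <- 4
  r_hand <- (n * sum(x2 * y2) - sum(x2) * sum(y2)) /
    sqrt((n * sum(x2^2) - sum(x2)^2) * (n * sum(y2^2) - sum(y2)^2))
  expect_equal(correlate(x2, y2)$r, r_hand, tolerance = 1e-12)
  ## independent series: |r| small (seeded null case)
  set.seed(99)
  xn <- rnorm(1000); yn <- rnorm(1000)
  expect_lt(abs(correlate(xn, yn)$r), 0.1)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), class = "domain_error")
  expect_error(correlate(1:2, 1:2), class = "insufficient_data")
})

test_that("ensemble SASA drops when the ligand buries the groove", {
  fx <- toy_fixture()
  m <- fx$model
  inter <- fx$map[fx$map$chain_i != fx$map$chain_j, ]
  groove <- sort(unique(c(inter$res_i[inter$chain_i == "A"],
                          inter$res_j[inter$chain_j == "A"])))
  site <- binding_site("A", groove)
  e_nat <- manual_ensemble(list(m$coords0, m$coords0), m)
  lig <- m$chain == 1L
  f_far <- m$coords0; f_far[lig, 2] <- f_far[lig, 2] + 8
  e_apo <- manual_ensemble(list(f_far, f_far), m)
  s_nat <- ensemble_sasa(e_nat, site, n_points = 120L)
  s_apo <- ensemble_sasa(e_apo, site, n_points = 120L)
  expect_gt(s_apo$mean, s_nat$mean)
})
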