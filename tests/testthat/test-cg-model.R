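test_that("model bookkeeping: two sites per residue minus glycines", {
  fx <- toy_fixture()
  m <- fx$model
  rt <- residue_table(fx$toy)
  n_gly <- sum(rt$restype == "GLY")
  expect_gt(n_gly, 0L)                      # toy includes glycine
  expect_equal(nrow(m$coords0), 2L * nrow(rt) - n_gly)
  ## glycine side-chain proxy is its CA site
  gly <- which(rt$restype == "GLY")
  expect_equal(m$sc_site[gly], m$ca_site[gly])
  ## every restrainable residue has its native-contact count
  expect_equal(length(m$n_native), nrow(rt))
  expect_equal(sum(m$n_native), 2L * nrow(fx$map))
})

test_that("native conformation minimises the energy among decoys", {
  fx <- toy_fixture()
  m <- fx$model
  e_native <- cg_energy(m)$mechanical
  ## decoy 1: ligand shifted out of the groove
  shifted <- m$coords0
  lig <- m$chain == 1L
  shifted[lig, 2] <- shifted[lig, 2] + 1.5
  ## decoy 2: ligand residue order shuffled (sites permuted within chain)
  shuffled <- m$coords0
  set.seed(11)
  shuffled[lig, ] <- shuffled[sample(which(lig)), ]
  ## decoy 3: ligand extended along z
  extended <- m$coords0
  extended[lig, 3] <- extended[lig, 3] * 3
  for (decoy in list(shifted, shuffled, extended))
    expect_gt(cg_energy(m, decoy)$mechanical, e_native)
})

test_that("energy is invariant under rigid motion of the whole complex", {
  fx <- toy_fixture()
  m <- fx$model
  ## tethers and the confinement centre break frame invariance for the
  ## full model; the pair terms (Go + repulsion + bonds) must not.
  m0 <- build_cg_model(fx$toy, fx$map,
                       params = list(k_tether_ca = 0, k_tether_sc = 0,
                                     conf_k = 0))
  e1 <- cg_energy(m0)$mechanical
  e2 <- cg_energy(m0, rigid_transform(m0$coords0))$mechanical
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("restraint energy follows the squared-difference form", {
  fx <- toy_fixture()
  m <- fx$model
  ## native conformation: Phi_sim = 1 everywhere, so targets of 1 give 0
  rs1 <- gen_phi_set(fx$map, "B", mean_phi = 1, spread = 0, seed = 1)
  expect_equal(restraint_energy(m, m$coords0, rs1), 0)
  ## one restrained residue, ligand displaced rigidly: only its
  ## intra-chain contacts survive, so E = k_phi * (1 - f_intra)^2
  rs2 <- phi_restraint_set("B", 5L, 1.0)
  far <- m$coords0
  far[m$chain == 1L, 1] <- far[m$chain == 1L, 1] + 50
  r5 <- m$residues$ord[m$residues$chain == "B" & m$residues$resid == 5L]
  rows <- (m$contacts[, 5] == r5) | (m$contacts[, 6] == r5)
  f_intra <- sum(m$chain[m$contacts[rows, 1]] ==
                   m$chain[m$contacts[rows, 2]]) / sum(rows)
  expect_equal(restraint_energy(m, far, rs2, k_phi = 1), (1 - f_intra)^2)
  ## a residue whose contacts are all inter-chain scores the full k_phi
  all_inter <- which(vapply(seq_len(m$nres), function(r) {
    rws <- (m$contacts[, 5] == r) | (m$contacts[, 6] == r)
    sum(rws) > 0 && all(m$chain[m$contacts[rws, 1]] !=
                          m$chain[m$contacts[rws, 2]])
  }, logical(1)) & m$residues$role == "ligand")
  if (length(all_inter) > 0L) {
    rt <- m$residues
    rs3 <- phi_restraint_set(rt$chain[all_inter[1]], rt$resid[all_inter[1]], 1.0)
    expect_equal(restraint_energy(m, far, rs3, k_phi = 1), 1)
  }
  ## target 1, simulated 0.5 -> 0.25 (direct evaluation)
  expect_equal(1 * (1 - 0.5)^2, 0.25)
  ## non-negativity over random conformations
  set.seed(2)
  for (i in 1:5) {
    pert <- m$coords0 + matrix(rnorm(length(m$coords0), 0, 0.2),
                               ncol = 3)
    expect_gte(restraint_energy(m, pert, rs1), 0)
  }
})

test_that("restraints must reference residues with native contacts", {
  fx <- toy_fixture()
  expect_error(phi_restraint_set("B", 999L, 0.5, ref = fx$map),
               class = "domain_error")
  ## a receptor residue without any contact entry
  rt <- residue_table(fx$toy)
  in_map <- unique(c(paste(fx$map$chain_i, fx$map$res_i),
                     paste(fx$map$chain_j, fx$map$res_j)))
  lone <- rt[!(paste(rt$chain, rt$resid) %in% in_map), ]
  if (nrow(lone) > 0L)
    expect_error(phi_restraint_set(lone$chain[1], lone$resid[1], 0.5,
                                   ref = fx$map),
                 class = "domain_error")
})

test_that("phi_sim matches a brute-force pair count", {
  fx <- toy_fixture()
  m <- fx$model
  ## native: every contacted residue scores exactly 1
  ps <- phi_sim(m, m$coords0)
  expect_true(all(abs(ps[m$n_native > 0] - 1) < 1e-12))
  expect_true(all(is.na(ps[m$n_native == 0])))
  ## displaced ligand: all inter-chain contributions vanish, so every
  ## residue scores (intra contacts formed)/n_native
  far <- m$coords0
  far[m$chain == 1L, ] <- far[m$chain == 1L, ] + 5
  ps_far <- phi_sim(m, far)
  intra_count <- vapply(seq_len(m$nres), function(r) {
    rows <- which((m$contacts[, 5] == r) | (m$contacts[, 6] == r))
    sum(m$chain[m$contacts[rows, 1]] == m$chain[m$contacts[rows, 2]])
  }, numeric(1))
  has <- m$n_native > 0
  expect_equal(unname(ps_far[has]), (intra_count / m$n_native)[has])
  ## randomly perturbed conformation against an R-side brute force
  set.seed(7)
  pert <- m$coords0 + matrix(rnorm(length(m$coords0), 0, 0.1), ncol = 3)
  ps_p <- phi_sim(m, pert)
  rt <- m$residues
  d_pert <- function(i, j) sqrt(sum((pert[i, ] - pert[j, ])^2))
  d_nat <- function(i, j) sqrt(sum((m$coords0[i, ] - m$coords0[j, ])^2))
  for (r in which(m$n_native > 0)) {
    rows <- which((m$contacts[, 5] == r) | (m$contacts[, 6] == r))
    formed <- sum(vapply(rows, function(k) {
      i <- m$contacts[k, 1]; j <- m$contacts[k, 2]
      d_pert(i, j) < 1.2 * d_nat(i, j)
    }, logical(1)))
    expect_equal(unname(ps_p[r]), formed / m$n_native[r])
  }
  ## selector interface
  expect_equal(unname(phi_sim(m, m$coords0, "B", 5L)), 1)
  gly <- rt[rt$restype == "GLY" & m$n_native[rt$ord] == 0, ]
  expect_error(phi_sim(m, m$coords0, "Z", 1L), class = "missing_residue")
})

test_that("half-broken residue scores Phi_sim = 0.5", {
  fx <- toy_fixture()
  m <- fx$model
  ## pick a ligand residue with an even contact count and move the
  ## partners of half its contacts far away
  cand <- which(m$n_native %% 2L == 0L & m$n_native > 0L &
                  m$residues$role == "ligand")
  r <- cand[1]
  rows <- which((m$contacts[, 5] == r) | (m$contacts[, 6] == r))
  half <- rows[seq_len(length(rows) / 2L)]
  pert <- m$coords0
  for (k in half) {
    other <- setdiff(m$contacts[k, 1:2], m$sc_site[r])
    pert[other, ] <- pert[other, ] + 10   # break by displacement
  }
  ps <- phi_sim(m, pert)
  expect_equal(unname(ps[r]), 0.5)
})
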