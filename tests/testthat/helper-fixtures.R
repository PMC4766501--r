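# Shared fixtures, built once per test run.  Everything is generated
# in code; nothing is read from disk.

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- gen_toy_complex(seed = 1)
      map <- native_contacts(toy)
      cache <<- list(toy = toy, map = map,
                     model = build_cg_model(toy, map))
    }
    cache
  }
})

# Independent O(N^2) brute-force contact oracle: counts side-chain
# heavy-atom pairs (GLY: CA proxy) strictly within the cutoff for
# non-nearest-neighbour residue pairs.  Shares no code with
# native_contacts().
brute_force_contacts <- function(s, cutoff = 0.65) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  is_sc <- !(s$atom %in% backbone) | (s$restype == "GLY" & s$atom == "CA")
  a <- s[is_sc, ]
  res <- unique(a[, c("chain", "resid")])
  out <- NULL
  for (p in seq_len(nrow(res) - 1L)) for (q in (p + 1L):nrow(res)) {
    ci <- res$chain[p]; ri <- res$resid[p]
    cj <- res$chain[q]; rj <- res$resid[q]
    if (ci == cj && abs(ri - rj) <= 1L) next
    ai <- a[a$chain == ci & a$resid == ri, c("x", "y", "z")]
    aj <- a[a$chain == cj & a$resid == rj, c("x", "y", "z")]
    n <- 0L
    for (u in seq_len(nrow(ai))) for (v in seq_len(nrow(aj)))
      if (sqrt(sum((ai[u, ] - aj[v, ])^2)) < cutoff) n <- n + 1L
    if (n > 0L)
      out <- rbind(out, data.frame(chain_i = ci, res_i = ri, chain_j = cj,
                                   res_j = rj, n_atom_pairs = n))
  }
  out
}

# A tiny hand-built structure with side chains at controlled
# distances, used by the contact and mutation oracles.
tiny_structure <- function() {
  atoms <- rbind(
    data.frame(chain = "A", resid = 1L, restype = "ALA",
               atom = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
               x = c(0, 0.1, 0.2, 0.3, 0.1), y = c(0, 0, 0, 0, 0.15), z = 0),
    data.frame(chain = "A", resid = 2L, restype = "GLY",
               atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
               x = c(0.4, 0.5, 0.6, 0.7), y = 0, z = 0),
    data.frame(chain = "A", resid = 3L, restype = "LEU",
               atom = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
               element = c("N", "C", "C", "O", "C", "C", "C", "C"),
               x = c(0.8, 0.9, 1.0, 1.1, 0.9, 0.95, 1.0, 0.9),
               y = c(0, 0, 0, 0, 0.15, 0.28, 0.40, 0.42), z = 0),
    data.frame(chain = "B", resid = 1L, restype = "VAL",
               atom = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
               element = c("N", "C", "C", "O", "C", "C", "C"),
               x = c(0.0, 0.1, 0.2, 0.3, 0.1, 0.05, 0.2),
               y = c(0.6, 0.6, 0.6, 0.6, 0.45, 0.33, 0.32), z = 0))
  complex_structure(atoms, receptor_chain = "A", ligand_chain = "B")
}

# closed-form OLS via normal equations, independent of the package's
# fitting code
normal_eq_fit <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

rigid_transform <- function(xyz, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(0.5, -1, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  R <- matrix(c(
    c_ + axis[1]^2 * C, axis[1] * axis[2] * C - axis[3] * s_, axis[1] * axis[3] * C + axis[2] * s_,
    axis[2] * axis[1] * C + axis[3] * s_, c_ + axis[2]^2 * C, axis[2] * axis[3] * C - axis[1] * s_,
    axis[3] * axis[1] * C - axis[2] * s_, axis[3] * axis[2] * C + axis[1] * s_, c_ + axis[3]^2 * C),
    3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, shift, "+")
}
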