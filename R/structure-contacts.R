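## Structure module, part 2: native contact maps and deletion-type
## mutations.

## Logical mask of side-chain heavy atoms, with the glycine CA proxy:
## GLY has no side-chain heavy atom, so its CA stands in, letting it
## still form contacts.
.sidechain_mask <- function(s, gly_ca_proxy = TRUE) {
  sc <- !(s$atom %in% .BACKBONE_ATOMS)
  if (gly_ca_proxy)
    sc <- sc | (s$restype == "GLY" & s$atom == "CA")
  sc
}

#' Native side-chain heavy-atom contact map
#'
#' For every pair of residues that are not nearest neighbours
#' (different chains, or same chain with `|i - j| > 1`), counts the
#' pairs of heavy side-chain atoms lying strictly within the cutoff
#' (default 0.65 nm) in the native structure.  Pairs with zero count
#' are omitted.  Glycine contributes its CA as side-chain proxy.
#'
#' @param s A [complex_structure()] in its native conformation.
#' @param cutoff Distance cutoff in nm (strict `<`).
#' @return Object of class `native_contact_map`: a data frame with
#'   columns `chain_i`, `res_i`, `chain_j`, `res_j`, `n_atom_pairs`,
#'   ordered with `(chain_i, res_i) < (chain_j, res_j)`; the cutoff and
#'   the native side-chain centroid distance (`centroid_dist`, nm) of
#'   each pair are carried along for the coarse-grained analysis.
#' @export
native_contacts <- function(s, cutoff = 0.65) {
  stopifnot(inherits(s, "complex_structure"), is_num1(cutoff), cutoff > 0)
  sc <- .sidechain_mask(s)
  a <- s[sc, , drop = FALSE]
  if (nrow(a) == 0L) tf_stop("structure_invalid", "no side-chain heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ## residue id per atom
  rkey <- paste(a$chain, a$resid)
  rlev <- unique(rkey)
  ridx <- match(rkey, rlev)
  rchain <- a$chain[!duplicated(rkey)]
  rresid <- a$resid[!duplicated(rkey)]
  nres <- length(rlev)
  ## pairwise atom distances below cutoff (squared to avoid sqrt)
  d2 <- .pairwise_sq(xyz)
  within <- d2 < cutoff^2
  counts <- matrix(0L, nres, nres)
  idx <- which(within, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(idx) > 0L) {
    ri <- ridx[idx[, 1]]; rj <- ridx[idx[, 2]]
    keep <- ri != rj
    ri <- ri[keep]; rj <- rj[keep]
    for (k in seq_along(ri)) {
      counts[ri[k], rj[k]] <- counts[ri[k], rj[k]] + 1L
      counts[rj[k], ri[k]] <- counts[rj[k], ri[k]] + 1L
    }
  }
  ## centroids for the coarse-grained "formed" criterion
  cen <- rowsum(xyz, ridx) / as.vector(table(factor(ridx, seq_len(nres))))
  rows <- list()
  for (i in seq_len(nres - 1L)) for (j in (i + 1L):nres) {
    if (counts[i, j] == 0L) next
    same <- rchain[i] == rchain[j]
    if (same && abs(rresid[i] - rresid[j]) <= 1L) next  # nearest neighbours
    rows[[length(rows) + 1L]] <- data.frame(
      chain_i = rchain[i], res_i = rresid[i],
      chain_j = rchain[j], res_j = rresid[j],
      n_atom_pairs = counts[i, j],
      centroid_dist = sqrt(sum((cen[i, ] - cen[j, ])^2)))
  }
  map <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_i = character(0), res_i = integer(0),
               chain_j = character(0), res_j = integer(0),
               n_atom_pairs = integer(0), centroid_dist = numeric(0))
  structure(map, cutoff = cutoff,
            receptor_chain = attr(s, "receptor_chain"),
            ligand_chain = attr(s, "ligand_chain"),
            class = c("native_contact_map", "data.frame"))
}

.pairwise_sq <- function(xyz) {
  g <- tcrossprod(xyz)
  n2 <- rowSums(xyz^2)
  d2 <- outer(n2, n2, "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.native_contact_map <- function(x, ...) {
  inter <- sum(x$chain_i != x$chain_j)
  cat(sprintf("Native contact map: %d residue pairs (%d inter-chain), cutoff %.2f nm\n",
              nrow(x), inter, attr(x, "cutoff")))
  invisible(x)
}

#' Native contacts of one residue
#'
#' @param map A [native_contacts()] map.
#' @param chain,resid Residue selector.
#' @return The rows of `map` involving that residue.
#' @export
contacts_of <- function(map, chain, resid) {
  stopifnot(inherits(map, "native_contact_map"))
  map[(map$chain_i == chain & map$res_i == resid) |
      (map$chain_j == chain & map$res_j == resid), , drop = FALSE]
}

#' Apply a deletion-type point mutation to a structure
#'
#' Side chains are truncated, never grown: the mutated residue keeps
#' only the backbone plus the side-chain heavy atoms named in the new
#' type (I -> V drops CD1; L -> A keeps CB only).  Mutations whose new
#' side chain requires atoms the old residue does not carry (e.g.
#' A -> W) are unsupported: build such variants externally and read
#' them with [read_pdb()].
#'
#' @param s A [complex_structure()].
#' @param chain,index Residue to mutate.
#' @param new_type Three-letter code of the new residue type.
#' @return The mutated [complex_structure()].
#' @export
mutate_residue <- function(s, chain, index, new_type) {
  stopifnot(inherits(s, "complex_structure"))
  new_type <- toupper(new_type)
  want <- sidechain_atoms(new_type)   # validates the type
  sel <- s$chain == chain & s$resid == index
  if (!any(sel)) tf_stop("missing_residue", "no residue %s/%d", chain, index)
  have <- s$atom[sel]
  missing <- setdiff(want, have)
  if (length(missing) > 0L)
    tf_stop("unsupported_mutation",
            "%s%d%s -> %s needs atoms absent from the template (%s); supply a pre-built structure",
            s$restype[sel][1], index, chain, new_type,
            paste(missing, collapse = ", "))
  drop <- sel & !(s$atom %in% c(.BACKBONE_ATOMS, want))
  out <- s[!drop, , drop = FALSE]
  out$restype[out$chain == chain & out$resid == index] <- new_type
  rownames(out) <- NULL
  structure(out,
            receptor_chain = attr(s, "receptor_chain"),
            ligand_chain = attr(s, "ligand_chain"),
            class = class(s))
}
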