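## Structure module, part 3: Shrake-Rupley solvent-accessible surface
## area.  Test points are distributed on each expanded atomic sphere
## with a Fibonacci (golden-section) lattice; a point survives if it is
## outside every neighbouring expanded sphere.  Radii are Bondi van der
## Waals radii; unknown elements (including coarse-grained
## pseudo-atoms) default to carbon unless an explicit radius column is
## supplied.

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley SASA of every atom
#'
#' @param xyz Matrix of atom coordinates (n x 3, nm).
#' @param radii Vector of van der Waals radii (nm).
#' @param probe Probe radius in nm (water: 0.14 nm).
#' @param n_points Test points per sphere (default 960).
#' @return Numeric vector of per-atom areas in nm^2.
#' @export
shrake_rupley <- function(xyz, radii, probe = 0.14, n_points = 960L) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L, length(radii) == nrow(xyz))
  n <- nrow(xyz)
  pts <- .fibonacci_sphere(n_points)
  rexp <- radii + probe
  area <- numeric(n)
  ## neighbour lists once, from squared distances
  d2 <- .pairwise_sq(xyz)
  maxr <- max(rexp)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rexp[i] + maxr)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[i, nb] < (rexp[i] + rexp[nb])^2]
    sp <- sweep(pts * rexp[i], 2L, xyz[i, ], "+")
    if (length(nb) > 0L) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        free <- free & dj2 >= rexp[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    area[i] <- 4 * pi * rexp[i]^2 * frac
  }
  area
}

.atom_radii <- function(s) {
  if ("radius" %in% names(s)) return(s$radius)
  r <- .BONDI_NM[toupper(s$element)]
  r[is.na(r)] <- .BONDI_NM[["C"]]
  unname(r)
}

#' Define a binding site by residue selection
#'
#' @param chain Character vector of chain ids (recycled).
#' @param resid Integer vector of residue indices.
#' @return Data frame of class `binding_site`.
#' @export
binding_site <- function(chain, resid) {
  if (length(resid) == 0L) tf_stop("site_invalid", "empty binding site")
  structure(data.frame(chain = chain, resid = resid),
            class = c("binding_site", "data.frame"))
}

#' Hydrophobic SASA of a binding site
#'
#' Shrake-Rupley SASA computed on the full complex, then summed over
#' the side-chain heavy atoms of the site residues (the hydrophobic
#' residues lining the ligand groove).  This is the static
#' single-structure mode; [ensemble_sasa()] averages the same quantity
#' over a native-reference ensemble.
#'
#' @param s A [complex_structure()].
#' @param site A [binding_site()].
#' @param probe Probe radius (nm).
#' @param n_points Quadrature points per atom.
#' @return Site SASA in nm^2.
#' @export
hydrophobic_sasa <- function(s, site, probe = 0.14, n_points = 960L) {
  stopifnot(inherits(s, "complex_structure"), inherits(site, "binding_site"))
  key <- paste(s$chain, s$resid)
  want <- paste(site$chain, site$resid)
  if (!all(want %in% key))
    tf_stop("missing_residue", "site residues absent from structure: %s",
            paste(setdiff(want, key), collapse = ", "))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  area <- shrake_rupley(xyz, .atom_radii(s), probe = probe,
                        n_points = n_points)
  sel <- key %in% want & .sidechain_mask(s)
  sum(area[sel])
}
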