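# Solvent-accessible surface area (Shrake-Rupley with a deterministic
# spiral point set), interface burial, and crystal-contact burial.

# Van der Waals radii (A), Bondi-style set for protein heavy atoms plus
# common hetero elements; overridable via the `radii` argument.
.VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, D = 1.20,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 1.40, ZN = 1.39, MG = 1.73, MN = 1.39, "NA" = 2.27, K = 2.75, CU = 1.40
)

# Deterministic golden-section spiral point set on the unit sphere.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over van der Waals spheres using a fixed
#' deterministic spiral point set, so results are exactly reproducible for
#' a given `n_points`.
#'
#' @param atoms Atom data.frame (needs `elesy`, coordinates, residue ids).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @param subset Optional integer row indices: areas are computed only for
#'   these atoms, with all atoms acting as occluders (used for burial in a
#'   larger environment).
#' @param radii Named per-element radius table overriding the built-in set.
#' @return A `SasaResult`: list with `atom_area` (per selected atom),
#'   `residue_area` (named by `chain:resno|insert`), `total`, `probe`,
#'   `n_points`.
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960, subset = NULL,
                          radii = NULL) {
  if (nrow(atoms) == 0) stop("no atoms")
  tab <- .VDW_RADII
  if (!is.null(radii)) tab[names(radii)] <- radii
  el <- atoms$elesy
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown) > 0) {
    i <- which(el == unknown[1])[1]
    stop("unknown element '", unknown[1], "' for atom ", atoms$elety[i],
         " in residue ", atoms$resid[i], " ", atoms$resno[i])
  }
  r <- unname(tab[el]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(subset)) subset <- seq_len(nrow(atoms))
  pts <- .sphere_points(n_points)
  areas <- numeric(length(subset))
  r2 <- r^2
  for (k in seq_along(subset)) {
    i <- subset[k]
    # neighbours whose expanded spheres can clip atom i's shell
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r)^2 & d2 > 1e-12)
    if (length(nb) > 0) {
      p <- sweep(pts * r[i], 2, xyz[i, ], "+")
      nbx <- xyz[nb, , drop = FALSE]
      pd2 <- outer(rowSums(p^2), rowSums(nbx^2), "+") - 2 * p %*% t(nbx)
      occl <- pd2 < rep(r2[nb], each = n_points)
      frac <- sum(.rowSums(occl, n_points, length(nb)) == 0) / n_points
    } else {
      frac <- 1
    }
    areas[k] <- frac * 4 * pi * r[i]^2
  }
  keys <- paste0(atoms$chain[subset], ":", atoms$resno[subset], "|",
                 atoms$insert[subset])
  res_area <- tapply(areas, factor(keys, levels = unique(keys)), sum)
  structure(list(atom_area = areas, residue_area = res_area,
                 total = sum(areas), probe = probe, n_points = n_points),
            class = "SasaResult")
}

#' Fraction of a group's accessible surface buried by a partner
#'
#' `(SASA of A alone - SASA of A in the presence of B) / SASA of A alone`.
#'
#' @param atomsA,atomsB Disjoint atom data.frames.
#' @param probe,n_points See [shrake_rupley()].
#' @return List with `fraction`, `buried_area`, `isolated_total` and
#'   `residue_buried` (per-residue buried area of A, named).
#' @export
buried_fraction <- function(atomsA, atomsB, probe = 1.4, n_points = 960) {
  if (nrow(atomsA) == 0 || nrow(atomsB) == 0) stop("empty group")
  iso <- shrake_rupley(atomsA, probe, n_points)
  if (iso$total <= 0) stop("zero isolated accessible area: fraction undefined")
  both <- rbind(atomsA, atomsB)
  cplx <- shrake_rupley(both, probe, n_points, subset = seq_len(nrow(atomsA)))
  res_buried <- iso$residue_area - cplx$residue_area[names(iso$residue_area)]
  list(fraction = (iso$total - cplx$total) / iso$total,
       buried_area = iso$total - cplx$total,
       isolated_total = iso$total,
       residue_buried = res_buried)
}

#' Crystal-contact burial of a residue range
#'
#' Fraction of the range's isolated-chain accessible surface buried when
#' all other asymmetric-unit chains and all symmetry mates within `radius`
#' are present simultaneously. Both the stated-range fraction and the
#' whole-chain fraction are returned, since either reading of "total
#' solvent accessible area" may be wanted.
#'
#' @param s A `Structure` with crystal metadata.
#' @param chain Chain id.
#' @param resno_range Length-2 integer vector (author numbering, inclusive),
#'   or `NULL` for the whole chain.
#' @param radius Mate-inclusion radius in Angstrom (default 5).
#' @param probe,n_points See [shrake_rupley()].
#' @return List with `range_fraction`, `chain_fraction`, `n_mates`,
#'   and the underlying areas.
#' @export
crystal_contact_burial <- function(s, chain, resno_range = NULL, radius = 5,
                                   probe = 1.4, n_points = 960) {
  if (is.null(s$crystal)) stop("structure carries no crystal cell")
  a <- chain_atoms(s, chain)
  if (!is.null(resno_range)) {
    stopifnot(length(resno_range) == 2)
    in_range <- a$resno >= resno_range[1] & a$resno <= resno_range[2]
    if (!any(in_range)) stop("residue range outside chain")
  } else {
    in_range <- rep(TRUE, nrow(a))
  }
  others <- s$atoms[s$atoms$chain != chain, , drop = FALSE]
  mates <- expand_symmetry(s, radius)
  env <- do.call(rbind, c(list(others), lapply(mates, `[[`, "atoms")))
  iso <- shrake_rupley(a, probe, n_points)
  if (is.null(env) || nrow(env) == 0) {
    cplx_total <- iso$total
    cplx_range <- sum(iso$atom_area[in_range])
  } else {
    all_at <- rbind(a, env)
    cplx <- shrake_rupley(all_at, probe, n_points, subset = seq_len(nrow(a)))
    cplx_total <- cplx$total
    cplx_range <- sum(cplx$atom_area[in_range])
  }
  iso_range <- sum(iso$atom_area[in_range])
  list(
    range_fraction = if (iso_range > 0) (iso_range - cplx_range) / iso_range else NA,
    chain_fraction = (iso$total - cplx_total) / iso$total,
    n_mates = length(mates),
    isolated_range_area = iso_range,
    isolated_chain_area = iso$total
  )
}
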