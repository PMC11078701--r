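# Rigid-body mathematics: Kabsch superposition, iterative sequence-independent
# structural alignment, principal-axis fitting and inter-axis angles.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' RMSD between `P` and `R Q + t` over all rigid motions, via SVD of the
#' cross-covariance of the centered point sets.
#'
#' @param P,Q n x 3 coordinate matrices in identical row correspondence.
#' @return A `SuperpositionResult`: list with `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd`, `n_aligned`, `correspondence`
#'   (integer row pairing) and `degenerate` flag for collinear input.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in length")
  if (nrow(P) < 3) stop("at least 3 points required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cp - as.numeric(R %*% cq)
  Qal <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - Qal)^2)))
  # collinearity: rank of either centered set < 2 leaves the rotation free
  degen <- min(svd(Pc)$d[2], svd(Qc)$d[2]) < 1e-8
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_aligned = nrow(P),
                 correspondence = cbind(seq_len(nrow(P)), seq_len(nrow(P))),
                 degenerate = degen),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d aligned positions\n",
              x$rmsd, x$n_aligned))
  invisible(x)
}

# Apply a SuperpositionResult transform to an n x 3 matrix.
.apply_transform <- function(xyz, sp) {
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Sequence-independent structural alignment of two chains
#'
#' Seeds a residue correspondence by matching secondary-structure elements
#' of the same kind in N-to-C order, then iterates Kabsch superposition,
#' re-pairing of mutually nearest CA atoms within `pair_dist`, and rejection
#' of pairs beyond `drop_dist`, until the pair set is stable. This
#' reproduces the outlier-rejecting behaviour of common structure-alignment
#' tools; the reported RMSD is recomputed on the final correspondence.
#'
#' @param atomsA,atomsB Atom tables of the two chains (see [chain_atoms()]).
#' @param pair_dist Re-pairing distance cutoff in Angstrom (default 5).
#' @param drop_dist Outlier rejection cutoff in Angstrom (default 3.5).
#' @param max_cycles Iteration cap (default 50).
#' @return A `SuperpositionResult`; `correspondence` holds author residue
#'   numbers (columns `resnoA`, `resnoB`).
#' @export
structure_align <- function(atomsA, atomsB, pair_dist = 5, drop_dist = 3.5,
                            max_cycles = 50) {
  caA <- .ca_matrix(atomsA); caB <- .ca_matrix(atomsB)
  if (nrow(caA) < 20 || nrow(caB) < 20) {
    stop("each chain needs at least 20 CA atoms")
  }
  seed <- .seed_correspondence(atomsA, atomsB)
  if (is.null(seed) || nrow(seed) < 3) {
    stop("alignment failure: no seed correspondence from ",
         "secondary-structure element matching")
  }
  pairs <- seed
  prev_key <- ""
  sp <- NULL
  for (cycle in seq_len(max_cycles)) {
    sp <- kabsch_superpose(caA[pairs[, 1], , drop = FALSE],
                           caB[pairs[, 2], , drop = FALSE])
    Bt <- .apply_transform(caB, sp)
    d2 <- outer(rowSums(caA^2), rowSums(Bt^2), "+") - 2 * caA %*% t(Bt)
    d2[d2 < 0] <- 0
    nnB <- max.col(-d2)                 # nearest B for each A
    nnA <- max.col(-t(d2))              # nearest A for each B
    mutual <- which(nnA[nnB] == seq_len(nrow(caA)))
    d <- sqrt(d2[cbind(mutual, nnB[mutual])])
    keep <- d <= min(pair_dist, drop_dist)
    new_pairs <- cbind(mutual[keep], nnB[mutual][keep])
    if (nrow(new_pairs) < 3) break
    key <- paste(new_pairs[, 1], new_pairs[, 2], collapse = ";")
    pairs <- new_pairs
    if (key == prev_key) break
    prev_key <- key
  }
  sp <- kabsch_superpose(caA[pairs[, 1], , drop = FALSE],
                         caB[pairs[, 2], , drop = FALSE])
  keyA <- rownames(caA)[pairs[, 1]]; keyB <- rownames(caB)[pairs[, 2]]
  sp$correspondence <- data.frame(
    resnoA = as.integer(sub("\\|.*", "", keyA)),
    resnoB = as.integer(sub("\\|.*", "", keyB))
  )
  sp$n_aligned <- nrow(pairs)
  sp
}

# Pair residues of same-kind secondary-structure elements in N->C order.
.seed_correspondence <- function(atomsA, atomsB) {
  caA <- .ca_matrix(atomsA); caB <- .ca_matrix(atomsB)
  elA <- tryCatch(segment_elements(assign_secondary_structure(atomsA), atomsA),
                  error = function(e) NULL)
  elB <- tryCatch(segment_elements(assign_secondary_structure(atomsB), atomsB),
                  error = function(e) NULL)
  if (is.null(elA) || is.null(elB) || length(elA) == 0 || length(elB) == 0) {
    return(NULL)
  }
  pairs <- NULL
  for (kind in c("helix", "strand")) {
    ka <- Filter(function(e) e$kind == kind, elA)
    kb <- Filter(function(e) e$kind == kind, elB)
    for (i in seq_len(min(length(ka), length(kb)))) {
      ia <- match(ka[[i]]$residue_keys, rownames(caA))
      ib <- match(kb[[i]]$residue_keys, rownames(caB))
      ia <- ia[!is.na(ia)]; ib <- ib[!is.na(ib)]
      n <- min(length(ia), length(ib))
      if (n > 0) pairs <- rbind(pairs, cbind(ia[seq_len(n)], ib[seq_len(n)]))
    }
  }
  pairs
}

#' Fit a principal axis through CA coordinates
#'
#' The direction is the first principal component of the centered points,
#' with sign fixed N-terminus to C-terminus (first to last row).
#'
#' @param coords m x 3 matrix, m >= 4, rows in N-to-C order.
#' @return An `AxisFit`: list with unit `direction`, `centroid`, `length`
#'   (extent of the projection) and `linearity` (variance fraction on the
#'   first principal direction).
#' @export
fit_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("at least 4 points required for an axis fit")
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  sv <- svd(X)
  dir <- sv$v[, 1]
  ends <- coords[nrow(coords), ] - coords[1, ]
  if (sum(dir * ends) < 0) dir <- -dir
  proj <- X %*% dir
  structure(list(direction = dir, centroid = ctr,
                 length = diff(range(proj)),
                 linearity = sv$d[1]^2 / sum(sv$d^2)),
            class = "AxisFit")
}

#' Angle between two fitted axes
#'
#' @param a,b `AxisFit` objects.
#' @param directed If `TRUE`, the angle between the signed directions in
#'   [0, 180] degrees; if `FALSE`, folded to [0, 90] (line-line angle).
#' @return Angle in degrees.
#' @export
angle_between <- function(a, b, directed = TRUE) {
  ct <- sum(a$direction * b$direction)
  ct <- max(-1, min(1, ct))
  ang <- acos(ct) * 180 / pi
  if (!directed && ang > 90) ang <- 180 - ang
  ang
}
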