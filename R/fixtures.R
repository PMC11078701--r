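# Deterministic generators of ground-truth-labeled synthetic inputs:
# idealized backbones, PAS monomers (3 helices + 5-stranded antiparallel
# sheet in 2-5-1-4-3 spatial order), dimers of chosen interface element and
# orientation, and alignments with planted motif frequencies.

# Standard backbone geometry (A, degrees).
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ca_cb = 1.53, ang_n_ca_cb = 110.5, dih_cb = -122.6
)

#' Fixture specification
#'
#' Bundles the parameters of a synthetic fixture; identical spec + seed
#' yields bit-identical output.
#'
#' @param kind One of `"helix"`, `"hairpin"`, `"pas_monomer"`, `"pas_dimer"`,
#'   `"msa"`.
#' @param ... Kind-specific parameters (see [build_pas_monomer()],
#'   [build_pas_dimer()], [build_msa()]).
#' @param rng_seed Integer seed for any stochastic step.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(kind = c("pas_monomer", "pas_dimer", "helix",
                                  "hairpin", "msa"),
                         ..., rng_seed = 1L) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind, rng_seed = as.integer(rng_seed)), list(...)),
            class = "FixtureSpec")
}

# Place atom D given A-B-C positions, |C-D|, angle(B,C,D) and
# dihedral(A,B,C,D) in degrees (natural-extension reference frame).
.place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

.AA_321 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Build an idealized backbone chain from internal coordinates
#'
#' Extends a chain residue by residue from standard bond lengths/angles and
#' the per-segment phi/psi dihedrals (omega fixed at 180). Backbone N, CA,
#' C, O are placed for every residue; CB for all non-glycine residues.
#'
#' @param segments List of segments, each
#'   `list(kind, length, phi, psi, seq)`; `seq` (1-letter codes, optional)
#'   defaults to poly-Ala for helix/strand and poly-Gly for coil. `phi` and
#'   `psi` may be vectors of per-residue values.
#' @param chain Chain id (default "A").
#' @param start_resno First author residue number (default 1).
#' @return Atom data.frame in the package's atom-table layout.
#' @export
build_ideal_chain <- function(segments, chain = "A", start_resno = 1) {
  phis <- numeric(0); psis <- numeric(0); seq1 <- character(0)
  for (sg in segments) {
    n <- sg$length
    stopifnot(n >= 1)
    phis <- c(phis, rep_len(sg$phi, n))
    psis <- c(psis, rep_len(sg$psi, n))
    s <- if (!is.null(sg$seq)) strsplit(sg$seq, "")[[1]] else
      rep(if (identical(sg$kind, "coil")) "G" else "A", n)
    stopifnot(length(s) == n)
    seq1 <- c(seq1, s)
  }
  n <- length(phis)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$n_ca, 0, 0)
  # first C placed in the xy plane
  ang <- .BB$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BB$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            .BB$ca_c, .BB$ang_n_ca_c, phis[i])
    }
    if (i < n) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                                .BB$c_n, .BB$ang_ca_c_n, psis[i])
      CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                 .BB$n_ca, .BB$ang_c_n_ca, 180)
      O[i, ] <- .place_atom(N[i + 1, ], CA[i, ], C[i, ],
                            .BB$c_o, .BB$ang_ca_c_o, 180)
    } else {
      O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                            .BB$c_o, .BB$ang_ca_c_o, psis[i] + 180)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- .AA_321[[seq1[i]]]
    resno <- start_resno + i - 1
    add <- function(elety, elesy, xyz) {
      rows[[length(rows) + 1]] <<- data.frame(
        chain = chain, resno = resno, insert = "", resid = res3,
        elety = elety, elesy = elesy, alt = "",
        x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 30,
        is_het = FALSE, stringsAsFactors = FALSE)
    }
    add("N", "N", N[i, ]); add("CA", "C", CA[i, ])
    add("C", "C", C[i, ]); add("O", "O", O[i, ])
    if (seq1[i] != "G") {
      CB <- .place_atom(C[i, ], N[i, ], CA[i, ],
                        .BB$ca_cb, .BB$ang_n_ca_cb, .BB$dih_cb)
      add("CB", "C", CB)
    }
  }
  do.call(rbind, rows)
}

# Canonicalize a fragment: centroid at origin, CA principal axis along +x
# (N->C), first-residue offset toward +y.
.canonical_fragment <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- .ca_matrix(atoms)
  ax <- fit_axis(ca)
  R1 <- .rotation_onto(ax$direction, c(1, 0, 0))
  xyz <- sweep(xyz, 2, ax$centroid) %*% t(R1)
  ca1 <- (ca[1, ] - ax$centroid) %*% t(R1)
  perp <- c(0, ca1[2], ca1[3])
  np <- sqrt(sum(perp^2))
  if (np > 1e-6) {
    cth <- perp[2] / np; sth <- perp[3] / np
    R2 <- matrix(c(1, 0, 0, 0, cth, sth, 0, -sth, cth), 3, 3, byrow = TRUE)
    xyz <- xyz %*% t(R2)
  }
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# Rotation matrix taking unit vector a onto unit vector b.
.rotation_onto <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to a
    w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- w - sum(w * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

# Rigidly place a canonical fragment: optional 180-degree flip about the
# named axis, then translation.
.place_fragment <- function(atoms, translate = c(0, 0, 0), flip = NULL,
                            spin = 0) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (spin != 0) {
    th <- spin * pi / 180
    Rs <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                 3, 3, byrow = TRUE)
    xyz <- xyz %*% t(Rs)
  }
  if (!is.null(flip)) {
    Rf <- switch(flip,
      x = diag(c(1, -1, -1)), y = diag(c(-1, 1, -1)), z = diag(c(-1, -1, 1)))
    xyz <- xyz %*% t(Rf)
  }
  xyz <- sweep(xyz, 2, translate, "+")
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# Geometric connector between two backbone anchor points, optionally
# routed through waypoints (a polyline); chemistry is not modelled.
.loop_atoms <- function(from, to, chain, start_resno, via = NULL) {
  pts <- rbind(from, if (!is.null(via)) do.call(rbind, via), to)
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  total <- sum(seglen)
  n_res <- max(2L, ceiling((total - 2.8) / 3.2))
  cum <- c(0, cumsum(seglen))
  at_arc <- function(sarc) {
    k <- max(which(cum <= sarc + 1e-9)); k <- min(k, nrow(seg))
    frac <- (sarc - cum[k]) / seglen[k]
    list(p = pts[k, ] + seg[k, ] * frac, u = seg[k, ] / seglen[k])
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    t0 <- i / (n_res + 1)
    loc <- at_arc(t0 * total)
    u <- loc$u
    w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    p <- w - sum(w * u) * u; p <- p / sqrt(sum(p^2))
    q <- c(u[2] * p[3] - u[3] * p[2], u[3] * p[1] - u[1] * p[3],
           u[1] * p[2] - u[2] * p[1])
    CA <- loc$p
    N <- CA - u * 1.2 + q * 0.6
    C <- CA + u * 1.2 + q * 0.6
    O <- C + p * 1.23
    resno <- start_resno + i - 1
    add <- function(elety, elesy, xyz) data.frame(
      chain = chain, resno = resno, insert = "", resid = "GLY",
      elety = elety, elesy = elesy, alt = "",
      x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 30,
      is_het = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- add("N", "N", N)
    rows[[length(rows) + 1]] <- add("CA", "C", CA)
    rows[[length(rows) + 1]] <- add("C", "C", C)
    rows[[length(rows) + 1]] <- add("O", "O", O)
  }
  do.call(rbind, rows)
}

# Frozen layout constants of the synthetic PAS monomer (see the methods
# vignette for how the sheet registry offsets were calibrated).
.PAS_LAYOUT <- list(
  strand_len = 7, strand_phi = -139, strand_psi = 135,
  helix_phi = -57, helix_psi = -47,
  a1_len = 16, a2_len = 8, a3_len = 12,
  sheet_spacing = 4.5,           # inter-strand spacing (z axis of layout)
  reg_minus = 2.0,               # x registry shift, minus strand above plus
  reg_plus = -2.0,               # x registry shift, plus strand above minus
  flip_axis = "z",
  a1_pos = c(0, 11, 9.7),        # alpha1 centroid (x, y, z)
  a2_pos = c(0, 7.5, 17.5),
  a3_pos = c(0, -9, 9.7),
  # loop routing waypoints keyed by junction, so connectors go around the
  # sheet edges instead of through the sheet plane
  loop_via = list(
    "beta1-beta2"  = list(c(0, 6.5, 4.5)),
    "beta2-alpha2" = list(c(15, 4, 10)),
    "alpha2-alpha3" = list(c(16, 0, 13)),
    "alpha3-beta3" = list(c(0, -6.5, 14)),
    "beta4-beta5"  = list(c(-14.5, 2.5, 9))
  )
)

#' Build a synthetic PAS monomer with ground truth
#'
#' Assembles five antiparallel strands in spatial order 2-5-1-4-3, a long
#' N-terminal helix (alpha1) carrying a planted Ser N-cap preceded by Leu,
#' and two further helices (alpha2, alpha3), joined by straight geometric
#' connectors. Alpha1 and alpha3 sit on opposite outward faces so either
#' can be presented as a dimer interface.
#'
#' @param spec A [fixture_spec()] of kind `"pas_monomer"`. Optional fields:
#'   `n_strands` (default 5; 4 yields a non-PAS control), `chain`,
#'   `start_resno`.
#' @return List with `atoms` (chain atom table) and `truth` (`GroundTruth`:
#'   element residue ranges, sheet order, ncap class and positions).
#' @export
build_pas_monomer <- function(spec = fixture_spec("pas_monomer")) {
  stopifnot(spec$kind == "pas_monomer")
  L <- .PAS_LAYOUT
  n_strands <- if (!is.null(spec$n_strands)) spec$n_strands else 5L
  if (n_strands < 4 || n_strands > 5) stop("infeasible packing: n_strands")
  chain <- if (!is.null(spec$chain)) spec$chain else "A"
  start_resno <- if (!is.null(spec$start_resno)) spec$start_resno else 21L

  # canonical fragments
  strand_frag <- .canonical_fragment(build_ideal_chain(list(
    list(kind = "strand", length = L$strand_len,
         phi = L$strand_phi, psi = L$strand_psi))))
  helix_frag <- function(n, seq = NULL) .canonical_fragment(build_ideal_chain(
    list(list(kind = "helix", length = n, phi = L$helix_phi,
              psi = L$helix_psi, seq = seq))))

  # alpha1 with a two-residue extended tail: Leu (N''), Ser (N') preceding
  # the helical stretch
  a1 <- .canonical_fragment(build_ideal_chain(list(
    list(kind = "coil", length = 2, phi = -100, psi = 140, seq = "LS"),
    list(kind = "helix", length = L$a1_len, phi = L$helix_phi,
         psi = L$helix_psi)
  )))
  a2 <- helix_frag(L$a2_len)
  a3 <- helix_frag(L$a3_len)

  # spatial slots 0..4 hold sequence strands 2,5,1,4,3; even slots point +x
  slot_of_strand <- c(`1` = 2L, `2` = 0L, `3` = 4L, `4` = 3L, `5` = 1L)
  slot_x <- numeric(5)
  for (k in 2:5) {
    slot_x[k] <- slot_x[k - 1] +
      (if (k %% 2 == 0) L$reg_minus else L$reg_plus)
  }
  place_strand <- function(seq_idx) {
    slot <- slot_of_strand[[as.character(seq_idx)]]
    flip <- if (slot %% 2 == 1) L$flip_axis else NULL
    .place_fragment(strand_frag,
                    translate = c(slot_x[slot + 1], 0, slot * L$sheet_spacing),
                    flip = flip)
  }
  b <- lapply(1:5, place_strand)
  # spin alpha1 so its extended N-terminal tail points toward the sheet,
  # not into the prospective dimer interface
  a1p <- .place_fragment(a1, translate = L$a1_pos, spin = 180)
  a2p <- .place_fragment(a2, translate = L$a2_pos)
  a3p <- .place_fragment(a3, translate = L$a3_pos)

  # chain order: a1, b1, b2, a2, a3, b3, b4, b5 (b5 dropped for 4-strand
  # controls)
  frags <- list(a1p, b[[1]], b[[2]], a2p, a3p, b[[3]], b[[4]])
  kinds <- c("alpha1", "beta1", "beta2", "alpha2", "alpha3", "beta3", "beta4")
  if (n_strands == 5) {
    frags <- c(frags, list(b[[5]]))
    kinds <- c(kinds, "beta5")
  }
  atoms <- NULL
  resno <- start_resno
  ranges <- list()
  for (k in seq_along(frags)) {
    f <- frags[[k]]
    nres <- length(unique(f$resno))
    if (!is.null(atoms)) {
      prevC <- atoms[atoms$elety == "C", ][sum(atoms$elety == "C"), ]
      nextN <- f[f$elety == "N", ][1, ]
      via <- L$loop_via[[paste(kinds[k - 1], kinds[k], sep = "-")]]
      loop <- .loop_atoms(c(prevC$x, prevC$y, prevC$z),
                          c(nextN$x, nextN$y, nextN$z), chain, resno,
                          via = via)
      atoms <- rbind(atoms, loop)
      resno <- resno + length(unique(loop$resno))
    }
    f$chain <- chain
    f$resno <- f$resno - min(f$resno) + resno
    ranges[[kinds[k]]] <- c(min(f$resno), max(f$resno))
    atoms <- rbind(atoms, f)
    resno <- resno + nres
  }
  rownames(atoms) <- NULL

  # plant the Ser OG pointing at the backbone N three residues into the
  # helix (idealized capping-bond geometry)
  ser_resno <- ranges$alpha1[1] + 1L
  n3_resno <- ser_resno + 3L
  cb <- atoms[atoms$resno == ser_resno & atoms$elety == "CB", ]
  n3 <- atoms[atoms$resno == n3_resno & atoms$elety == "N", ]
  if (nrow(cb) == 1 && nrow(n3) == 1) {
    v <- c(n3$x - cb$x, n3$y - cb$y, n3$z - cb$z)
    d <- sqrt(sum(v^2))
    og <- c(cb$x, cb$y, cb$z) + v / d * min(1.42, max(0.8, d - 2.8))
    atoms <- rbind(atoms, data.frame(
      chain = chain, resno = ser_resno, insert = "", resid = "SER",
      elety = "OG", elesy = "O", alt = "", x = og[1], y = og[2], z = og[3],
      o = 1, b = 30, is_het = FALSE, stringsAsFactors = FALSE))
    atoms <- atoms[order(atoms$resno, atoms$insert), ]
  }
  truth <- list(
    element_ranges = ranges,
    sheet_order = if (n_strands == 5) "2-5-1-4-3" else NA_character_,
    is_pas = n_strands == 5,
    ncap = list(ncap_resno = ser_resno, ncap_class = "capping_box",
                preceding_class = "LI"),
    chain = chain
  )
  list(atoms = atoms, truth = truth)
}

#' Build a synthetic PAS dimer with ground truth
#'
#' Generates a second copy of the synthetic monomer by a two-fold rotation
#' chosen so the requested interface element (alpha1 or alpha3) faces its
#' counterpart, with the requested parallel or antiparallel relative chain
#' orientation, then translates the copy until the minimum inter-chain
#' heavy-atom distance equals `separation`. An optional global rigid
#' rotation (seeded) exercises orientation invariance.
#'
#' @param spec A [fixture_spec()] of kind `"pas_dimer"` with fields
#'   `interface_element` (`"alpha1"`/`"alpha3"`), `parallel` (flag),
#'   `separation` (A, >= 2.5), optional `rotate` (logical: apply a seeded
#'   global rotation).
#' @return List with `structure` (two-chain `Structure`), `truth`
#'   (`GroundTruth` incl. the expected dimer class under default screen
#'   thresholds) and `monomer_truth`.
#' @export
build_pas_dimer <- function(spec = fixture_spec("pas_dimer",
                                                interface_element = "alpha3",
                                                parallel = TRUE,
                                                separation = 3.8)) {
  stopifnot(spec$kind == "pas_dimer")
  iface <- match.arg(spec$interface_element, c("alpha1", "alpha3"))
  parallel <- isTRUE(spec$parallel)
  sep <- spec$separation
  if (sep < 2.5) stop("clashing separation: ", sep)
  mono <- build_pas_monomer(fixture_spec("pas_monomer"))
  A <- mono$atoms
  face_sign <- if (iface == "alpha1") 1 else -1    # alpha1 on +y, alpha3 on -y
  xyzA <- as.matrix(A[, c("x", "y", "z")])
  # two-fold operator: parallel -> C2 about x (through the element z),
  # antiparallel -> C2 about z
  zc <- .PAS_LAYOUT$a1_pos[3]
  B0 <- if (parallel) {
    # stagger the copy along the helix axis so the facing helices pack
    # ridge-into-groove instead of ridge-on-ridge; the offset is
    # calibrated per face to maximize interdigitation
    m <- xyzA %*% diag(c(1, -1, -1))
    m[, 3] <- m[, 3] + 2 * zc
    m[, 1] <- m[, 1] + if (iface == "alpha1") 2.0 else 2.75
    m
  } else {
    xyzA %*% diag(c(-1, -1, 1))
  }
  mind <- function(ty) {
    Bt <- B0; Bt[, 2] <- Bt[, 2] + ty
    sqrt(.min_cross_d2(xyzA, Bt))
  }
  # translate the copy along the facing direction until the minimum
  # inter-chain distance equals the requested separation
  lo <- 0; hi <- face_sign * 200
  f <- function(t) mind(t) - sep
  # ensure bracketing: at hi the chains are far apart
  root <- stats::uniroot(f, lower = min(0, hi), upper = max(0, hi),
                         tol = 1e-3)$root
  B <- A
  Bxyz <- B0; Bxyz[, 2] <- Bxyz[, 2] + root
  B[, c("x", "y", "z")] <- Bxyz
  B$chain <- "B"
  atoms <- rbind(A, B)
  if (isTRUE(spec$rotate)) {
    rot <- .seeded_rotation(spec$rng_seed)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
    atoms[, c("x", "y", "z")] <- xyz
  }
  s <- .new_structure(atoms, id = sprintf("dimer_%s_%s_sep%.1f", iface,
                                          if (parallel) "par" else "anti", sep))
  expected <- if (sep > 5) "not_dimer"
  else if (parallel) paste0(iface, "_interface")
  else "other_interface"
  truth <- list(interface_element = iface, parallel = parallel,
                separation = sep, expected_class = expected,
                rng_seed = spec$rng_seed)
  list(structure = s, truth = truth, monomer_truth = mono$truth)
}

.min_cross_d2 <- function(A, B) {
  best <- Inf
  step <- max(1L, floor(2e6 / max(1, nrow(B))))
  for (i0 in seq(1, nrow(A), by = step)) {
    idx <- i0:min(i0 + step - 1, nrow(A))
    d2 <- outer(rowSums(A[idx, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[idx, , drop = FALSE] %*% t(B)
    best <- min(best, min(d2))
  }
  max(best, 0)
}

# Deterministic rotation matrix from a seed (uniform axis, uniform angle).
.seeded_rotation <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Build a synthetic alignment with planted motif frequencies
#'
#' Records are mutated copies of a seeded random consensus; the per-column
#' mutation rate is solved so the expected mean pairwise identity matches
#' the target. The N-cap and preceding columns are then overwritten with
#' residues drawn from the requested class frequencies using
#' largest-remainder rounding, so planted counts are exact.
#'
#' @param spec A [fixture_spec()] of kind `"msa"` with fields `n` (records),
#'   `length` (columns, default 60), `identity` (target mean pairwise
#'   percent identity, default 80), `ncap_col`, `pre_col` (default
#'   length-10, length-12), `freq` (named: capping_box, non_traditional,
#'   pre_LI, pre_MV).
#' @return List with `msa` (an `Msa`) and `truth` (planted counts).
#' @export
build_msa <- function(spec = fixture_spec("msa", n = 100)) {
  stopifnot(spec$kind == "msa")
  n <- spec$n
  L <- if (!is.null(spec$length)) spec$length else 60L
  target <- if (!is.null(spec$identity)) spec$identity else 80
  ncap_col <- if (!is.null(spec$ncap_col)) spec$ncap_col else L - 10L
  pre_col <- if (!is.null(spec$pre_col)) spec$pre_col else L - 12L
  freq <- spec$freq
  if (is.null(freq)) freq <- c(capping_box = 0.9, non_traditional = 0.06,
                               pre_LI = 0.85, pre_MV = 0.1)
  stopifnot(all(freq >= 0), freq[["capping_box"]] + freq[["non_traditional"]] <= 1,
            freq[["pre_LI"]] + freq[["pre_MV"]] <= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$rng_seed)
  aas <- names(.AA_321)
  consensus <- sample(aas, L, replace = TRUE)
  # per-column mutation rate m with P(two records agree) = target/100:
  # (1-m)^2 + m^2/19 = t
  t0 <- target / 100
  disc <- 1 - (20 / 19) * (1 - t0)
  if (disc < 0) stop("contradictory constraints: identity target too low")
  m <- (1 - sqrt(disc)) * 19 / 20
  mat <- matrix(rep(consensus, each = n), n, L)
  mut <- matrix(stats::runif(n * L) < m, n, L)
  if (any(mut)) {
    idx <- which(mut)
    cur <- mat[idx]
    repl <- vapply(cur, function(a) sample(setdiff(aas, a), 1), character(1))
    mat[idx] <- repl
  }
  # exact planting at the motif columns (largest-remainder rounding)
  plant <- function(fracs, pools, n) {
    counts <- .largest_remainder(fracs, n)
    out <- character(0)
    for (k in seq_along(counts)) {
      pool <- pools[[k]]
      out <- c(out, pool[(seq_len(counts[k]) - 1) %% length(pool) + 1])
    }
    sample(out, n)   # seeded shuffle across records
  }
  rules <- .NCAP_RULES
  other_ncap <- setdiff(aas, c(rules$capping_box, rules$non_traditional))
  other_pre <- setdiff(aas, c(rules$preceding_LI, rules$preceding_MV))
  mat[, ncap_col] <- plant(
    c(freq[["capping_box"]], freq[["non_traditional"]],
      1 - freq[["capping_box"]] - freq[["non_traditional"]]),
    list(rules$capping_box, rules$non_traditional, other_ncap), n)
  mat[, pre_col] <- plant(
    c(freq[["pre_LI"]], freq[["pre_MV"]],
      1 - freq[["pre_LI"]] - freq[["pre_MV"]]),
    list(rules$preceding_LI, rules$preceding_MV, other_pre), n)
  seqs <- apply(mat, 1, paste, collapse = "")
  ids <- sprintf("rec%03d", seq_len(n))
  truth <- list(
    n = n, ncap_col = ncap_col, pre_col = pre_col,
    counts = list(
      capping_box = .largest_remainder(
        c(freq[["capping_box"]], freq[["non_traditional"]],
          1 - freq[["capping_box"]] - freq[["non_traditional"]]), n)[1],
      non_traditional = .largest_remainder(
        c(freq[["capping_box"]], freq[["non_traditional"]],
          1 - freq[["capping_box"]] - freq[["non_traditional"]]), n)[2],
      pre_LI = .largest_remainder(
        c(freq[["pre_LI"]], freq[["pre_MV"]],
          1 - freq[["pre_LI"]] - freq[["pre_MV"]]), n)[1],
      pre_MV = .largest_remainder(
        c(freq[["pre_LI"]], freq[["pre_MV"]],
          1 - freq[["pre_LI"]] - freq[["pre_MV"]]), n)[2]
    ),
    mutation_rate = m, identity_target = target, rng_seed = spec$rng_seed
  )
  list(msa = new_msa(ids, seqs), truth = truth)
}

# Integer apportionment of n by fractions (largest-remainder method).
.largest_remainder <- function(fracs, n) {
  raw <- fracs * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
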