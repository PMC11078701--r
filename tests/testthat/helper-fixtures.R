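# Shared fixtures and independent oracles, built in code at test time.

# cache expensive fixtures across tests within one run
.fx_env <- new.env(parent = emptyenv())

fx_monomer <- function() {
  if (is.null(.fx_env$mono)) .fx_env$mono <- build_pas_monomer()
  .fx_env$mono
}

fx_dimer <- function(iface = "alpha3", parallel = TRUE, sep = 3.8,
                     rotate = FALSE, seed = 1L) {
  key <- paste(iface, parallel, sep, rotate, seed)
  if (is.null(.fx_env[[key]])) {
    .fx_env[[key]] <- build_pas_dimer(fixture_spec(
      "pas_dimer", interface_element = iface, parallel = parallel,
      separation = sep, rotate = rotate, rng_seed = seed))
  }
  .fx_env[[key]]
}

# apply a rigid motion (rotation about an axis + translation) to an atom table
rigid_move <- function(atoms, angle = 37, axis = c(1, 2, 3),
                       shift = c(5, -3, 11)) {
  ax <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# independent RMSD oracle: dense grid over the first two Euler angles of
# R = Rz(a) Ry(b) Rz(g) with centroid pre-alignment, using the trace
# identity rmsd^2 = (|P|^2 + |Q|^2 - 2 tr(t(H) R)) / n, H = t(Qc) Pc.
# For fixed (a, b), tr(t(H) Rz1 Ry Rz2(g)) = u cos(g) + v sin(g) + w is
# maximized in closed form, so the search is exhaustive over rotations.
oracle_min_rmsd <- function(P, Q, coarse = 1, refine = 0.02) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Qc) %*% Pc
  sPQ <- sum(Pc^2) + sum(Qc^2)
  n <- nrow(P)
  eval_grid <- function(as, bs) {
    best <- list(gain = -Inf)
    for (a in as) {
      ca <- cos(a); sa <- sin(a)
      Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
      M <- t(H) %*% Rz1
      for (b in bs) {
        cb <- cos(b); sb <- sin(b)
        Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
        N <- M %*% Ry
        u <- N[1, 1] + N[2, 2]
        v <- N[1, 2] - N[2, 1]
        gain <- sqrt(u^2 + v^2) + N[3, 3]
        if (gain > best$gain) best <- list(gain = gain, a = a, b = b)
      }
    }
    best
  }
  d2r <- pi / 180
  step <- coarse * d2r
  best <- eval_grid(seq(0, 2 * pi, by = step), seq(0, pi, by = step))
  around <- function(x, w, s) seq(x - w, x + w, by = s)
  for (fine in c(step / 10, refine * d2r)) {
    b2 <- eval_grid(around(best$a, 12 * fine, fine),
                    around(best$b, 12 * fine, fine))
    if (b2$gain > best$gain) best <- b2
  }
  sqrt(max(0, (sPQ - 2 * best$gain) / n))
}

# independent SASA oracle for small atom sets: dense latitude-longitude
# quadrature of the exposed fraction of each expanded sphere
oracle_sasa <- function(xyz, radii, probe = 1.4, n_theta = 400) {
  r <- radii + probe
  total <- 0
  per_atom <- numeric(nrow(xyz))
  th <- (seq_len(n_theta) - 0.5) / n_theta * pi
  n_phi <- 2 * n_theta
  ph <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  for (i in seq_len(nrow(xyz))) {
    st <- sin(th); ct <- cos(th)
    area_acc <- 0
    # weight per band: r^2 sin(theta) dtheta dphi
    w <- r[i]^2 * st * (pi / n_theta) * (2 * pi / n_phi)
    for (k in seq_len(n_theta)) {
      px <- xyz[i, 1] + r[i] * st[k] * cos(ph)
      py <- xyz[i, 2] + r[i] * st[k] * sin(ph)
      pz <- xyz[i, 3] + r[i] * ct[k]
      acc <- rep(TRUE, n_phi)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        d2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
        acc <- acc & d2 >= r[j]^2
      }
      area_acc <- area_acc + sum(acc) * w[k]
    }
    per_atom[i] <- area_acc
    total <- total + area_acc
  }
  list(per_atom = per_atom, total = total)
}

# minimal one-residue PDB text (ALA, 4 backbone atoms)
minimal_pdb_text <- function() {
  c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "END"
  )
}

# the same residue as a minimal mmCIF atom_site loop
minimal_cif_text <- function() {
  c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 10.00 ? 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 1.251 2.390 0.000 1.00 10.00 ? 1 ALA A O 1"
  )
}

# write a Structure-like atom table to a temp PDB and return the path
write_tmp_pdb <- function(atoms, crystal = NULL) {
  s <- pascreen:::.new_structure(atoms, crystal = crystal)
  p <- tempfile(fileext = ".pdb")
  write_structure(s, p)
  p
}
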