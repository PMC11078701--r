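# Secondary structure from backbone hydrogen-bond energetics
# (Kabsch-Sander electrostatic model, reduced to 3 states), element
# segmentation, and polar-contact detection.

.HB_CUTOFF <- -0.5   # kcal/mol; bonds below this count

# Backbone coordinate frame of one chain: one row per residue, NA where absent.
.backbone_frame <- function(atoms) {
  keys <- .residue_keys(atoms)
  pick <- function(name) {
    m <- matrix(NA_real_, length(keys), 3)
    sel <- atoms[atoms$elety == name & !atoms$is_het, , drop = FALSE]
    idx <- match(paste(sel$resno, sel$insert, sep = "|"), keys)
    ok <- !is.na(idx)
    m[idx[ok], ] <- as.matrix(sel[ok, c("x", "y", "z")])
    m
  }
  resid <- atoms$resid[match(keys, paste(atoms$resno, atoms$insert, sep = "|"))]
  list(keys = keys, resid = resid,
       N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"))
}

# Amide H inferred at 1.0 A from N along the direction opposite the bisector
# of the C(prev)->N and CA->N bonds (crystal structures carry no hydrogens).
.infer_h <- function(N, CA, Cprev) {
  d1 <- N - Cprev; d1 <- d1 / sqrt(sum(d1^2))
  d2 <- N - CA; d2 <- d2 / sqrt(sum(d2^2))
  u <- d1 + d2
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) return(N + c(1, 0, 0))
  N + u / nu
}

#' Backbone hydrogen-bond energy (electrostatic model)
#'
#' Energy of the N-H(donor) ... O=C(acceptor) interaction:
#' `E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol, with
#' the amide H inferred from backbone geometry and E clamped at -9.9.
#'
#' @param donor_res Atom table of the donor residue (needs N and CA).
#' @param acceptor_res Atom table of the acceptor residue (needs C and O).
#' @param donor_prev Atom table of the residue preceding the donor (its C
#'   orients the inferred H); when `NULL` the H is placed along CA->N.
#' @return Energy in kcal/mol, or `NA` when a backbone atom is missing.
#' @export
hbond_energy <- function(donor_res, acceptor_res, donor_prev = NULL) {
  gx <- function(res, name) {
    r <- res[res$elety == name, c("x", "y", "z")]
    if (nrow(r) == 0) return(NULL)
    as.numeric(r[1, ])
  }
  N <- gx(donor_res, "N"); CA <- gx(donor_res, "CA")
  C <- gx(acceptor_res, "C"); O <- gx(acceptor_res, "O")
  if (is.null(N) || is.null(CA) || is.null(C) || is.null(O)) return(NA_real_)
  H <- if (!is.null(donor_prev)) {
    Cp <- gx(donor_prev, "C")
    if (is.null(Cp)) return(NA_real_)
    .infer_h(N, CA, Cp)
  } else {
    d <- N - CA
    N + d / sqrt(sum(d^2))
  }
  .ks_energy(N, H, C, O)
}

.ks_energy <- function(N, H, C, O) {
  dON <- sqrt(sum((O - N)^2)); dCH <- sqrt(sum((C - H)^2))
  dOH <- sqrt(sum((O - H)^2)); dCN <- sqrt(sum((C - N)^2))
  if (min(dON, dCH, dOH, dCN) < 0.5) return(-9.9)
  e <- 0.084 * 332 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
  max(e, -9.9)
}

# All backbone H-bonds of a chain with E < cutoff.
# Returns data.frame(donor, acceptor, energy) of residue indices.
.hbond_table <- function(frame, cutoff = .HB_CUTOFF) {
  n <- length(frame$keys)
  out <- list()
  if (n < 2) return(data.frame(donor = integer(0), acceptor = integer(0),
                               energy = numeric(0)))
  # H positions (donor side); first residue and prolines cannot donate
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (identical(frame$resid[i], "PRO")) next
    if (anyNA(frame$N[i, ]) || anyNA(frame$CA[i, ]) || anyNA(frame$C[i - 1, ]))
      next
    H[i, ] <- .infer_h(frame$N[i, ], frame$CA[i, ], frame$C[i - 1, ])
  }
  ca_ok <- !is.na(frame$CA[, 1])
  for (i in 2:n) {                       # donor
    if (anyNA(H[i, ])) next
    for (j in seq_len(n)) {              # acceptor
      if (abs(i - j) < 2) next
      if (anyNA(frame$C[j, ]) || anyNA(frame$O[j, ])) next
      if (ca_ok[i] && ca_ok[j] &&
          sum((frame$CA[i, ] - frame$CA[j, ])^2) > 81) next  # 9 A CA prefilter
      e <- .ks_energy(frame$N[i, ], H[i, ], frame$C[j, ], frame$O[j, ])
      if (e < cutoff) out[[length(out) + 1]] <- c(i, j, e)
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      energy = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(donor = as.integer(m[, 1]), acceptor = as.integer(m[, 2]),
             energy = m[, 3])
}

#' Assign 3-state secondary structure to a chain
#'
#' Kabsch-Sander hydrogen-bond energetics reduced to three states: `H`
#' where at least two consecutive helical turns (i -> i+4, with i -> i+3
#' accepted for 3-10 stretches) stack, `E` where inter-strand bridge
#' hydrogen bonds form a ladder, `C` otherwise.
#'
#' @param atoms Atom table of one chain (see [chain_atoms()]).
#' @param cutoff Hydrogen-bond energy cutoff in kcal/mol (default -0.5).
#' @return An `SSAssignment`: list with `labels` (named character vector,
#'   one of H/E/C per residue) and `hbonds` (donor/acceptor residue keys
#'   with energies).
#' @export
assign_secondary_structure <- function(atoms, cutoff = .HB_CUTOFF) {
  frame <- .backbone_frame(atoms)
  n <- length(frame$keys)
  labels <- rep("C", n)
  names(labels) <- frame$keys
  complete <- !is.na(frame$N[, 1]) & !is.na(frame$CA[, 1]) &
    !is.na(frame$C[, 1]) & !is.na(frame$O[, 1])
  if (sum(complete) < 5) {
    warning("fewer than 5 residues with complete backbone; all coil")
    return(structure(list(labels = labels,
                          hbonds = data.frame(donor = character(0),
                                              acceptor = character(0),
                                              energy = numeric(0))),
                     class = "SSAssignment"))
  }
  hb <- .hbond_table(frame, cutoff)
  has <- function(d, a) {
    any(hb$donor == d & hb$acceptor == a)
  }
  hbset <- paste(hb$donor, hb$acceptor)
  hasv <- function(d, a) paste(d, a) %in% hbset

  # helical turns
  turn4 <- vapply(seq_len(n), function(i) i + 4 <= n && hasv(i + 4, i), logical(1))
  turn3 <- vapply(seq_len(n), function(i) i + 3 <= n && hasv(i + 3, i), logical(1))
  for (i in seq_len(n - 1)) {
    if (turn4[i] && turn4[i + 1]) labels[(i + 1):(i + 4)] <- "H"
  }
  for (i in seq_len(n - 1)) {
    if (turn3[i] && turn3[i + 1]) {
      idx <- (i + 1):(i + 3)
      labels[idx][labels[idx] == "C"] <- "H"
    }
  }

  # beta bridges (Kabsch-Sander parallel and antiparallel rules)
  in_bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3 || j < 2 || j > n - 1) next
      anti <- (hasv(i, j) && hasv(j, i)) ||
        (hasv(i - 1, j + 1) && hasv(j - 1, i + 1))
      para <- (hasv(i + 1, j) && hasv(j, i - 1)) ||
        (hasv(j + 1, i) && hasv(i, j - 1))
      if (anti || para) { in_bridge[i] <- TRUE; in_bridge[j] <- TRUE }
    }
  }
  ladder <- in_bridge &
    (c(FALSE, in_bridge[-n]) | c(in_bridge[-1], FALSE))
  labels[ladder & labels == "C"] <- "E"

  hb_out <- data.frame(donor = frame$keys[hb$donor],
                       acceptor = frame$keys[hb$acceptor],
                       energy = hb$energy, stringsAsFactors = FALSE)
  structure(list(labels = labels, hbonds = hb_out), class = "SSAssignment")
}

#' Segment a secondary-structure assignment into elements
#'
#' Maximal runs of `H` of length >= 4 become helices, runs of `E` of length
#' >= 3 become strands; each element gets a fitted axis and a 1-based
#' `sequence_index` among elements of its kind, N- to C-terminal.
#'
#' @param a An `SSAssignment`.
#' @param atoms Atom table of the same chain.
#' @return List of `SSElement`: `kind`, `start`/`end` (author resno),
#'   `residue_keys`, `axis` ([fit_axis()] result), `sequence_index`.
#' @export
segment_elements <- function(a, atoms) {
  labels <- a$labels
  keys <- names(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  elements <- list()
  for (k in seq_along(r$values)) {
    kind <- switch(r$values[k], H = "helix", E = "strand", NULL)
    if (is.null(kind)) next
    minlen <- if (kind == "helix") 4 else 3
    if (r$lengths[k] < minlen) next
    idx <- starts[k]:ends[k]
    ca <- .ca_matrix(atoms)
    m <- ca[match(keys[idx], rownames(ca)), , drop = FALSE]
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    axis <- if (nrow(m) >= 4) fit_axis(m) else .two_point_axis(m)
    elements[[length(elements) + 1]] <- structure(list(
      kind = kind,
      start = as.integer(sub("\\|.*", "", keys[idx[1]])),
      end = as.integer(sub("\\|.*", "", keys[idx[length(idx)]])),
      residue_keys = keys[idx],
      axis = axis,
      sequence_index = NA_integer_
    ), class = "SSElement")
  }
  for (kind in c("helix", "strand")) {
    which_k <- which(vapply(elements, function(e) e$kind == kind, logical(1)))
    for (i in seq_along(which_k)) {
      elements[[which_k[i]]]$sequence_index <- i
    }
  }
  elements
}

.two_point_axis <- function(m) {
  d <- m[nrow(m), ] - m[1, ]
  len <- sqrt(sum(d^2))
  structure(list(direction = d / len, centroid = colMeans(m),
                 length = len, linearity = 1), class = "AxisFit")
}

#' Select atoms of a structure by chain, residue and scope
#'
#' @param s A `Structure`.
#' @param chain Chain id or `NULL` for all.
#' @param resno Author residue numbers or `NULL` for all.
#' @param scope `"all"`, `"sidechain"` or `"backbone"`.
#' @return Atom data.frame.
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL,
                         scope = c("all", "sidechain", "backbone")) {
  scope <- match.arg(scope)
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  bb <- c("N", "CA", "C", "O", "OXT")
  if (scope == "sidechain") a <- a[!(a$elety %in% bb), , drop = FALSE]
  if (scope == "backbone") a <- a[a$elety %in% bb, , drop = FALSE]
  a
}

#' Polar contacts between two atom selections
#'
#' All N/O atom pairs, one from each selection, within `d_max`. A pure
#' distance criterion (no angle term) identifies a qualitative
#' hydrogen-bond network. Same-residue pairs and backbone-backbone pairs of
#' adjacent residues in the same chain are excluded.
#'
#' @param selA,selB Atom data.frames (see [select_atoms()]).
#' @param d_max Distance cutoff in Angstrom (default 3.5).
#' @return data.frame of contacts with per-atom identity, `distance` and
#'   `inter_chain` flag.
#' @export
find_polar_contacts <- function(selA, selB, d_max = 3.5) {
  if (nrow(selA) == 0 || nrow(selB) == 0) stop("empty atom selection")
  pa <- selA[selA$elesy %in% c("N", "O"), , drop = FALSE]
  pb <- selB[selB$elesy %in% c("N", "O"), , drop = FALSE]
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    return(.empty_contacts())
  }
  A <- as.matrix(pa[, c("x", "y", "z")]); B <- as.matrix(pb[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(.empty_contacts())
  ia <- hit[, 1]; ib <- hit[, 2]
  same_res <- pa$chain[ia] == pb$chain[ib] & pa$resno[ia] == pb$resno[ib] &
    pa$insert[ia] == pb$insert[ib]
  bb <- c("N", "CA", "C", "O", "OXT")
  adj_bb <- pa$chain[ia] == pb$chain[ib] &
    abs(pa$resno[ia] - pb$resno[ib]) == 1 &
    pa$elety[ia] %in% bb & pb$elety[ib] %in% bb
  keep <- !(same_res | adj_bb)
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0) return(.empty_contacts())
  data.frame(
    chainA = pa$chain[ia], resnoA = pa$resno[ia], residA = pa$resid[ia],
    atomA = pa$elety[ia],
    chainB = pb$chain[ib], resnoB = pb$resno[ib], residB = pb$resid[ib],
    atomB = pb$elety[ib],
    distance = sqrt(d2[cbind(ia, ib)]),
    inter_chain = pa$chain[ia] != pb$chain[ib],
    stringsAsFactors = FALSE
  )
}

.empty_contacts <- function() {
  data.frame(chainA = character(0), resnoA = integer(0), residA = character(0),
             atomA = character(0), chainB = character(0), resnoB = integer(0),
             residB = character(0), atomB = character(0),
             distance = numeric(0), inter_chain = logical(0),
             stringsAsFactors = FALSE)
}
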