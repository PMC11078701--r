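# PAS-fold recognition: sheet-order computation, canonical element labelling
# (alpha1-alpha3, beta1-beta5), and helix N-cap motif detection.

.CANONICAL_SHEET <- "2-5-1-4-3"

# N-cap sequence rule tables. The capping set holds classic capping-box
# N' residues; the non-traditional set holds residues seen in known N-caps
# that are not capping boxes. Preceding-residue tiers: branched hydrophobes
# L/I, then M/V.
.NCAP_RULES <- list(
  capping_box = c("S", "T", "N", "D"),
  non_traditional = c("G", "P", "E", "Q", "H"),
  preceding_LI = c("L", "I"),
  preceding_MV = c("M", "V")
)

#' Spatial order of strands in a beta-sheet
#'
#' Clusters strands into a sheet by inter-strand distance and inter-strand
#' backbone hydrogen bonds, walks the unique linear adjacency path, and
#' reports the sequence indices of the strands along it. The string is
#' orientation-normalized: the lexicographically smaller of the path and
#' its reversal is returned, so "2-5-1-4-3" and "3-4-1-5-2" are the same
#' topology.
#'
#' @param strands List of strand `SSElement`s of one chain.
#' @param atoms Atom table of the chain.
#' @param assignment Optional `SSAssignment` (recomputed when missing) whose
#'   hydrogen bonds support adjacency calls.
#' @param d_adj Mean nearest-CA distance cutoff for adjacency (default 5.5).
#' @param min_hbonds Minimum inter-strand backbone H-bonds for adjacency
#'   (default 2).
#' @return Order string such as `"2-5-1-4-3"`.
#' @export
order_sheet_strands <- function(strands, atoms, assignment = NULL,
                                d_adj = 5.5, min_hbonds = 2) {
  ns <- length(strands)
  if (ns < 2) stop("need at least 2 strands")
  if (is.null(assignment)) assignment <- assign_secondary_structure(atoms)
  ca <- .ca_matrix(atoms)
  coords <- lapply(strands, function(e) {
    m <- ca[match(e$residue_keys, rownames(ca)), , drop = FALSE]
    m[!is.na(m[, 1]), , drop = FALSE]
  })
  hb <- assignment$hbonds
  strand_of <- rep(NA_integer_, 0)
  key2strand <- list()
  for (k in seq_len(ns)) for (key in strands[[k]]$residue_keys) {
    key2strand[[key]] <- k
  }
  hb_count <- matrix(0L, ns, ns)
  if (nrow(hb) > 0) {
    sd <- vapply(hb$donor, function(k) {
      v <- key2strand[[k]]; if (is.null(v)) NA_integer_ else v
    }, integer(1))
    sa <- vapply(hb$acceptor, function(k) {
      v <- key2strand[[k]]; if (is.null(v)) NA_integer_ else v
    }, integer(1))
    ok <- !is.na(sd) & !is.na(sa) & sd != sa
    for (i in which(ok)) {
      hb_count[sd[i], sa[i]] <- hb_count[sd[i], sa[i]] + 1L
      hb_count[sa[i], sd[i]] <- hb_count[sa[i], sd[i]] + 1L
    }
  }
  adj <- matrix(FALSE, ns, ns)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    di <- .mean_nearest_dist(coords[[i]], coords[[j]])
    if (di < d_adj && hb_count[i, j] / 2 >= min_hbonds) {
      adj[i, j] <- TRUE; adj[j, i] <- TRUE
    }
  }
  deg <- rowSums(adj)
  comp <- .components(adj)
  if (length(unique(comp)) > 1) {
    stop("strands do not form a single sheet; components: ",
         paste(tapply(seq_len(ns), comp, paste, collapse = ","),
               collapse = " | "))
  }
  if (any(deg > 2) || sum(deg == 1) != 2) {
    stop("sheet adjacency is branched or cyclic; no linear strand order")
  }
  path <- integer(ns)
  path[1] <- which(deg == 1)[1]
  visited <- rep(FALSE, ns); visited[path[1]] <- TRUE
  for (k in 2:ns) {
    nxt <- which(adj[path[k - 1], ] & !visited)
    path[k] <- nxt[1]; visited[nxt[1]] <- TRUE
  }
  idx <- vapply(strands, function(e) e$sequence_index, integer(1))
  .normalize_order(paste(idx[path], collapse = "-"))
}

.mean_nearest_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  mean(sqrt(apply(d2, 1, min)))
}

.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

.normalize_order <- function(order_string) {
  toks <- strsplit(order_string, "-")[[1]]
  rev_s <- paste(rev(toks), collapse = "-")
  if (order_string <= rev_s) order_string else rev_s
}

#' Detect the N-cap motif of a helix
#'
#' The N' residue is the residue immediately preceding the helix's first
#' residue. Its sequence class follows a two-tier rule table
#' (capping-box residues S/T/N/D; non-traditional G/P/E/Q/H; otherwise
#' absent), and a structural capping hydrogen bond is flagged when a
#' side-chain O/N of N' or N1 lies within `d_max` of the backbone N of
#' N2/N3. The residue preceding N' (the N'' position) is classed as L/I,
#' M/V, or other.
#'
#' @param atoms Atom table of the chain.
#' @param helix A helix `SSElement`.
#' @param d_max Capping hydrogen-bond distance cutoff (default 3.5).
#' @param rules Rule tables (see package default `.NCAP_RULES`).
#' @return An `NcapMotif`: list with `ncap_resno`, `ncap_class`,
#'   `capping_hbond` (TRUE/FALSE/NA when side-chain atoms are missing),
#'   `preceding_residue` (1-letter) and `preceding_class`.
#' @export
detect_ncap <- function(atoms, helix, d_max = 3.5, rules = .NCAP_RULES) {
  keys <- .residue_keys(atoms)
  h1 <- helix$residue_keys[1]
  pos <- match(h1, keys)
  if (is.na(pos) || pos == 1) {
    return(structure(list(ncap_resno = NA_integer_, ncap_class = "absent",
                          capping_hbond = FALSE,
                          preceding_residue = NA_character_,
                          preceding_class = "other",
                          reason = "terminal"), class = "NcapMotif"))
  }
  res_of <- function(key) {
    parts <- strsplit(key, "\\|")[[1]]
    atoms[atoms$resno == as.integer(parts[1]) &
            atoms$insert == ifelse(length(parts) > 1, parts[2], ""), ,
          drop = FALSE]
  }
  aa1 <- function(key) {
    r <- res_of(key)
    if (nrow(r) == 0) return(NA_character_)
    bio3d::aa321(r$resid[1])
  }
  nprime_key <- keys[pos - 1]
  nprime <- aa1(nprime_key)
  ncap_class <- if (nprime %in% rules$capping_box) {
    "capping_box"
  } else if (nprime %in% rules$non_traditional) {
    "non_traditional"
  } else {
    "absent"
  }
  # structural capping bond: side-chain O/N of N' or N1 to backbone N of N2/N3
  donors <- rbind(
    select_one_residue_sidechain(res_of(nprime_key)),
    select_one_residue_sidechain(res_of(helix$residue_keys[1]))
  )
  donors <- donors[donors$elesy %in% c("N", "O"), , drop = FALSE]
  targets <- NULL
  for (k in helix$residue_keys[c(2, 3)]) {
    if (is.na(k)) next
    r <- res_of(k)
    targets <- rbind(targets, r[r$elety == "N", , drop = FALSE])
  }
  capping <- if (nrow(donors) == 0 || is.null(targets) || nrow(targets) == 0) {
    NA
  } else {
    D <- as.matrix(donors[, c("x", "y", "z")])
    Tg <- as.matrix(targets[, c("x", "y", "z")])
    d2 <- outer(rowSums(D^2), rowSums(Tg^2), "+") - 2 * D %*% t(Tg)
    any(d2 <= d_max^2)
  }
  preceding <- if (pos >= 3) aa1(keys[pos - 2]) else NA_character_
  pre_class <- if (isTRUE(preceding %in% rules$preceding_LI)) {
    "LI"
  } else if (isTRUE(preceding %in% rules$preceding_MV)) {
    "MV"
  } else {
    "other"
  }
  structure(list(
    ncap_resno = as.integer(sub("\\|.*", "", nprime_key)),
    ncap_class = ncap_class,
    capping_hbond = capping,
    preceding_residue = preceding,
    preceding_class = pre_class
  ), class = "NcapMotif")
}

# Side-chain atoms of a single-residue atom table.
select_one_residue_sidechain <- function(res) {
  res[!(res$elety %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
}

#' Annotate the PAS fold of a chain
#'
#' A chain is called PAS (`is_pas`) when it has exactly one five-stranded
#' sheet whose normalized spatial order is the canonical 2-5-1-4-3 and at
#' least three helices. Canonical helix labels: alpha1 is the longest helix
#' (>= 10 residues) wholly N-terminal of beta1 — the long periplasmic
#' helix; alpha2 is the first helix between beta1 and beta3; alpha3 the
#' next helix before beta3. The alpha1 N-cap is characterized when alpha1
#' is present.
#'
#' @param atoms Atom table of one chain.
#' @return A `PasAnnotation`: list with `is_pas`, `sheet_order`, `alpha`
#'   (named list alpha1/alpha2/alpha3 of `SSElement`s), `beta` (beta1..beta5
#'   in sequence order), `ncap`, `elements` (all segmented elements) and
#'   `assignment`.
#' @export
annotate_pas <- function(atoms) {
  a <- assign_secondary_structure(atoms)
  elements <- segment_elements(a, atoms)
  helices <- Filter(function(e) e$kind == "helix", elements)
  strands <- Filter(function(e) e$kind == "strand", elements)
  sheet_order <- NA_character_
  is_pas <- FALSE
  if (length(strands) >= 2) {
    sheet_order <- tryCatch(
      order_sheet_strands(strands, atoms, assignment = a),
      error = function(e) NA_character_
    )
  }
  if (length(strands) == 5 && !is.na(sheet_order) &&
      sheet_order == .normalize_order(.CANONICAL_SHEET) &&
      length(helices) >= 3) {
    is_pas <- TRUE
  }
  beta <- stats::setNames(strands, paste0("beta", seq_along(strands)))
  alpha <- list(alpha1 = NULL, alpha2 = NULL, alpha3 = NULL)
  if (length(strands) >= 1 && length(helices) >= 1) {
    b1_start <- strands[[1]]$start
    b3_start <- if (length(strands) >= 3) strands[[3]]$start else Inf
    nterm <- Filter(function(h) h$end < b1_start, helices)
    long <- Filter(function(h) length(h$residue_keys) >= 10, nterm)
    if (length(long) > 0) {
      lens <- vapply(long, function(h) length(h$residue_keys), integer(1))
      alpha$alpha1 <- long[[which.max(lens)]]
    }
    mid <- Filter(function(h) h$start > b1_start && h$end < b3_start, helices)
    if (length(mid) >= 1) alpha$alpha2 <- mid[[1]]
    if (length(mid) >= 2) alpha$alpha3 <- mid[[2]]
  }
  ncap <- if (!is.null(alpha$alpha1)) detect_ncap(atoms, alpha$alpha1) else NULL
  structure(list(is_pas = is_pas, sheet_order = sheet_order,
                 alpha = alpha, beta = beta, ncap = ncap,
                 elements = elements, assignment = a),
            class = "PasAnnotation")
}

#' @export
print.PasAnnotation <- function(x, ...) {
  cat("PAS annotation: is_pas =", x$is_pas,
      "| sheet order:", x$sheet_order, "\n")
  for (nm in names(x$alpha)) {
    e <- x$alpha[[nm]]
    if (!is.null(e)) cat(sprintf("  %s: %d-%d\n", nm, e$start, e$end))
  }
  if (!is.null(x$ncap)) {
    cat("  alpha1 N-cap:", x$ncap$ncap_class,
        "| preceding:", x$ncap$preceding_class, "\n")
  }
  invisible(x)
}

# Map each residue key to its canonical element label, or NA.
.element_label_map <- function(pas) {
  out <- character(0)
  for (nm in names(pas$alpha)) {
    e <- pas$alpha[[nm]]
    if (!is.null(e)) out[e$residue_keys] <- nm
  }
  for (nm in names(pas$beta)) {
    e <- pas$beta[[nm]]
    out[e$residue_keys] <- nm
  }
  out
}
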