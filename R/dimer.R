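# Dimer-orientation classification: the core screen. For each pair of
# nearby chains, decide parallel vs antiparallel from chain reference axes
# and identify the interface element by per-element buried accessible area;
# a parallel pair burying alpha3 on both chains is an alpha3-interface
# dimer, the arrangement this screen was built to find.

#' Default screening parameters
#'
#' All thresholds of the dimer screen with documented defaults. The paper
#' trail for each: contact cutoff 5.0 A / 10 contacts operationalize
#' "nearby chains"; parallel threshold 45 degrees on the directed angle
#' between chain reference axes (alpha1 axis when present) operationalizes
#' "parallel dimers"; probe 1.4 A and 960 sphere points are the SASA
#' engine defaults; mate radius 5.0 A selects "close" crystal contacts.
#'
#' @param contact_cutoff Heavy-atom contact distance, Angstrom.
#' @param min_contacts Minimum inter-chain contacts for a dimer.
#' @param parallel_threshold Directed inter-axis angle below which a pair
#'   is parallel, degrees.
#' @param probe,n_points SASA parameters.
#' @param mate_radius Symmetry-mate inclusion radius, Angstrom.
#' @param hbond_cutoff Kabsch-Sander energy cutoff, kcal/mol.
#' @param polar_dmax Polar-contact distance cutoff, Angstrom.
#' @param identity_mode,identity_threshold MSA redundancy-filter settings.
#' @param seed Base RNG seed carried into any stochastic step.
#' @return Named list of parameters (class `screen_config`).
#' @export
screen_config <- function(contact_cutoff = 5, min_contacts = 10,
                          parallel_threshold = 45, probe = 1.4,
                          n_points = 960, mate_radius = 5,
                          hbond_cutoff = -0.5, polar_dmax = 3.5,
                          identity_mode = "longest", identity_threshold = 96,
                          seed = 1L) {
  structure(list(
    contact_cutoff = contact_cutoff, min_contacts = min_contacts,
    parallel_threshold = parallel_threshold, probe = probe,
    n_points = n_points, mate_radius = mate_radius,
    hbond_cutoff = hbond_cutoff, polar_dmax = polar_dmax,
    identity_mode = identity_mode, identity_threshold = identity_threshold,
    seed = as.integer(seed)
  ), class = "screen_config")
}

#' Round-trip a screen configuration through YAML
#' @param config A `screen_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(screen_config, vals)
}

# Count heavy-atom contacts between two atom tables.
.contact_count <- function(A, B, cutoff) {
  a <- as.matrix(A[, c("x", "y", "z")]); b <- as.matrix(B[, c("x", "y", "z")])
  n <- 0L
  step <- max(1L, floor(2e6 / max(1, nrow(b))))
  for (i0 in seq(1, nrow(a), by = step)) {
    idx <- i0:min(i0 + step - 1, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    n <- n + sum(d2 <= cutoff^2)
  }
  n
}

#' Find pairs of chains in contact
#'
#' @param s A `Structure` with at least one chain.
#' @param contact_cutoff Heavy-atom distance cutoff, Angstrom.
#' @param min_contacts Minimum number of atom pairs within the cutoff.
#' @return data.frame with `chainA`, `chainB`, `n_contacts` (one row per
#'   unordered pair meeting the threshold; empty for a single chain).
#' @export
find_chain_pairs <- function(s, contact_cutoff = 5, min_contacts = 10) {
  ch <- structure_chains(s)
  out <- data.frame(chainA = character(0), chainB = character(0),
                    n_contacts = integer(0), stringsAsFactors = FALSE)
  if (length(ch) < 2) return(out)
  for (i in seq_len(length(ch) - 1)) for (j in (i + 1):length(ch)) {
    n <- .contact_count(chain_atoms(s, ch[i]), chain_atoms(s, ch[j]),
                        contact_cutoff)
    if (n >= min_contacts) {
      out <- rbind(out, data.frame(chainA = ch[i], chainB = ch[j],
                                   n_contacts = as.integer(n),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Chain reference axis for the parallel test: alpha1 axis when the chain is
# PAS-annotated with an alpha1, else first principal axis of all CA atoms
# (sign N->C).
.reference_axis <- function(atoms, pas) {
  if (!is.null(pas$alpha$alpha1)) return(pas$alpha$alpha1$axis)
  fit_axis(.ca_matrix(atoms))
}

#' Classify the orientation of one chain pair
#'
#' A pair with fewer than `min_contacts` contacts is `not_dimer`. Otherwise
#' the pair is parallel when the directed angle between the chain reference
#' axes is below `parallel_threshold`; the interface element of each chain
#' is the canonical element with the largest buried accessible area upon
#' complex formation. `alpha3_interface` requires a parallel pair with
#' alpha3 as the interface element on both chains; `alpha1_interface` is
#' analogous; anything else (including chains that are not PAS folds) is
#' `other_interface`.
#'
#' @param s A `Structure`.
#' @param chainA,chainB Chain ids.
#' @param pasA,pasB `PasAnnotation`s of the chains (computed when missing).
#' @param params A [screen_config()].
#' @return A `DimerClassification`: list with `chain_pair`, `n_contacts`,
#'   `parallel`, `inter_axis_angle`, `interface_element_A/B`,
#'   `buried_area_by_element` (per chain), `class`.
#' @export
classify_dimer <- function(s, chainA, chainB, pasA = NULL, pasB = NULL,
                           params = screen_config()) {
  A <- chain_atoms(s, chainA); B <- chain_atoms(s, chainB)
  n_contacts <- .contact_count(A, B, params$contact_cutoff)
  base <- list(chain_pair = c(chainA, chainB), n_contacts = n_contacts,
               parallel = NA, inter_axis_angle = NA_real_,
               interface_element_A = "none", interface_element_B = "none",
               buried_area_by_element = NULL, class = "not_dimer")
  if (n_contacts < params$min_contacts) {
    return(structure(base, class = "DimerClassification"))
  }
  if (is.null(pasA)) pasA <- annotate_pas(A)
  if (is.null(pasB)) pasB <- annotate_pas(B)
  ang <- angle_between(.reference_axis(A, pasA), .reference_axis(B, pasB),
                       directed = TRUE)
  parallel <- ang < params$parallel_threshold
  burA <- .element_burial(A, B, pasA, params)
  burB <- .element_burial(B, A, pasB, params)
  elA <- .top_element(burA)
  elB <- .top_element(burB)
  cls <- if (!pasA$is_pas || !pasB$is_pas) {
    "other_interface"
  } else if (parallel && identical(elA, "alpha3") && identical(elB, "alpha3")) {
    "alpha3_interface"
  } else if (parallel && identical(elA, "alpha1") && identical(elB, "alpha1")) {
    "alpha1_interface"
  } else {
    "other_interface"
  }
  structure(list(chain_pair = c(chainA, chainB), n_contacts = n_contacts,
                 parallel = parallel, inter_axis_angle = ang,
                 interface_element_A = elA, interface_element_B = elB,
                 buried_area_by_element = list(A = burA, B = burB),
                 class = cls),
            class = "DimerClassification")
}

#' @export
print.DimerClassification <- function(x, ...) {
  cat(sprintf("Dimer %s-%s: %s (%d contacts, angle %.1f, interface %s/%s)\n",
              x$chain_pair[1], x$chain_pair[2], x$class, x$n_contacts,
              if (is.na(x$inter_axis_angle)) NaN else x$inter_axis_angle,
              x$interface_element_A, x$interface_element_B))
  invisible(x)
}

# Buried accessible area per canonical element of chain `A` against `B`.
.element_burial <- function(A, B, pas, params) {
  bf <- buried_fraction(A, B, probe = params$probe, n_points = params$n_points)
  labmap <- .element_label_map(pas)
  if (length(labmap) == 0) return(numeric(0))
  res_keys <- sub("^[^:]*:", "", names(bf$residue_buried))
  lab <- labmap[res_keys]
  ok <- !is.na(lab)
  if (!any(ok)) return(numeric(0))
  tapply(bf$residue_buried[ok], lab[ok], sum)
}

.top_element <- function(burial) {
  if (length(burial) == 0 || all(burial <= 0)) return("none")
  names(burial)[which.max(burial)]
}

#' Screen a collection of structure files for dimer orientations
#'
#' Reads each file, annotates every chain, evaluates every pair of nearby
#' chains, and tabulates the classification. Unreadable files produce an
#' error row and the screen continues.
#'
#' @param paths Character vector of structure file paths.
#' @param params A [screen_config()].
#' @return List with `table` (one row per evaluated pair, plus no-pair and
#'   error rows) and `summary` (named counts per class).
#' @export
screen_collection <- function(paths, params = screen_config()) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (p in paths) {
    res <- tryCatch({
      s <- read_structure(p)
      pairs <- find_chain_pairs(s, params$contact_cutoff, params$min_contacts)
      pas <- lapply(structure_chains(s), function(ch)
        annotate_pas(chain_atoms(s, ch)))
      names(pas) <- structure_chains(s)
      if (nrow(pairs) == 0) {
        add(file = basename(p), chainA = NA, chainB = NA, status = "no_pair",
            n_contacts = 0L, angle = NA_real_, interface_A = NA,
            interface_B = NA, class = "not_dimer")
      } else {
        for (k in seq_len(nrow(pairs))) {
          cl <- classify_dimer(s, pairs$chainA[k], pairs$chainB[k],
                               pas[[pairs$chainA[k]]], pas[[pairs$chainB[k]]],
                               params)
          add(file = basename(p), chainA = pairs$chainA[k],
              chainB = pairs$chainB[k], status = "ok",
              n_contacts = cl$n_contacts,
              angle = round(cl$inter_axis_angle, 2),
              interface_A = cl$interface_element_A,
              interface_B = cl$interface_element_B, class = cl$class)
        }
      }
      TRUE
    }, error = function(e) {
      add(file = basename(p), chainA = NA, chainB = NA, status = "error",
          n_contacts = NA_integer_, angle = NA_real_, interface_A = NA,
          interface_B = NA, class = NA)
      FALSE
    })
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(file = character(0), chainA = character(0),
               chainB = character(0), status = character(0),
               n_contacts = integer(0), angle = numeric(0),
               interface_A = character(0), interface_B = character(0),
               class = character(0), stringsAsFactors = FALSE)
  cls <- tab$class[tab$status == "ok"]
  summary <- table(factor(cls, levels = c("alpha1_interface",
                                          "alpha3_interface",
                                          "other_interface", "not_dimer")))
  list(table = tab, summary = as.list(summary))
}
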