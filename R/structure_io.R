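# Canonical amino-acid 3-letter codes treated as polymer residues.
.PROTEIN_RESID <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a structure file into a flat atom table with crystal metadata.
#' Alternate conformers are reduced to a single conformer per atom by
#' keeping the highest-occupancy altloc (ties broken alphabetically).
#' Hydrogens are dropped; waters and non-polymer heteroatoms are excluded
#' unless `include_hetero = TRUE`.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format One of `"pdb"`, `"mmcif"`, `"auto"` (by file extension).
#' @param include_hetero Keep non-polymer HETATM records (waters always
#'   dropped from geometric analyses are retained only with this flag).
#' @return A `Structure`: list with `id`, `atoms` (data.frame with columns
#'   chain, resno, insert, resid, elety, elesy, alt, x, y, z, o, b, is_het),
#'   `crystal` (list with `space_group`, `cell`, `operators`, or `NULL`)
#'   and `source_format`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           include_hetero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "mmcif", mmcif = "mmcif",
      stop("cannot infer structure format from extension '.", ext, "'")
    )
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("parse error in '", path, "': no ATOM/HETATM records", call. = FALSE)
  }
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    elesy = .resolve_element(at$elesy, at$elety),
    alt = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    is_het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$elesy != "H" & atoms$elesy != "D", , drop = FALSE]
  if (!include_hetero) {
    atoms <- atoms[atoms$resid %in% .PROTEIN_RESID, , drop = FALSE]
  } else {
    atoms <- atoms[atoms$resid != "HOH", , drop = FALSE]
  }
  if (nrow(atoms) == 0) {
    stop("no polymer atoms left after filtering in '", path, "'",
         call. = FALSE)
  }
  atoms <- .resolve_altloc(atoms)
  crystal <- if (format == "pdb") .parse_crystal_pdb(path) else .parse_crystal_cif(path)
  structure(
    list(id = sub("\\.[^.]*$", "", basename(path)), atoms = atoms,
         crystal = crystal, source_format = format),
    class = "Structure"
  )
}

.resolve_element <- function(elesy, elety) {
  out <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- out == ""
  if (any(miss)) {
    guess <- gsub("[0-9']", "", toupper(elety[miss]))
    # two-letter symbols only for common hetero elements; otherwise first char
    two <- substr(guess, 1, 2)
    one <- substr(guess, 1, 1)
    out[miss] <- ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA"),
                        two, one)
  }
  out
}

# Keep a single conformer per (chain, resno, insert, elety): highest occupancy,
# ties resolved to the alphabetically first altloc.
.resolve_altloc <- function(atoms) {
  if (nrow(atoms) == 0 || all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(match(paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                          sep = "\r"), unique(key))), , drop = FALSE]
}

.parse_crystal_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  cl <- cl[1]
  cell <- suppressWarnings(as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)
  )))
  if (anyNA(cell)) stop("malformed CRYST1 record in ", path)
  sg <- trimws(substr(cl, 56, 66))
  ops <- .parse_remark290(lines)
  if (is.null(ops)) ops <- space_group_operators(sg)
  list(space_group = sg, cell = cell, operators = ops)
}

# REMARK 290 SMTRY records carry the symmetry operators of deposited entries;
# prefer them over the built-in table when present.
.parse_remark290 <- function(lines) {
  sm <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  if (length(sm) < 3) return(NULL)
  f <- lapply(sm, function(l) {
    tok <- strsplit(trimws(sub("^REMARK 290\\s+SMTRY", "", l)), "\\s+")[[1]]
    suppressWarnings(as.numeric(tok))
  })
  row_of <- vapply(sm, function(l) as.integer(substr(sub(".*SMTRY", "", l), 1, 1)),
                   integer(1))
  nop <- length(sm) / 3
  if (nop != floor(nop)) return(NULL)
  ops <- vector("list", nop)
  for (k in seq_len(nop)) {
    idx <- (k - 1) * 3 + 1:3
    R <- matrix(0, 3, 3); t <- numeric(3)
    for (j in 1:3) {
      v <- f[[idx[j]]]
      # tokens: row-index, op-index, r1 r2 r3 t
      if (length(v) < 6 || anyNA(v[3:6])) return(NULL)
      R[row_of[idx[j]], ] <- v[3:5]
      t[row_of[idx[j]]] <- v[6]
    }
    ops[[k]] <- list(R = R, t = t, cartesian = TRUE)
  }
  ops
}

.parse_crystal_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getv <- function(tag) {
    l <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(l) == 0) return(NA)
    v <- trimws(sub(paste0("^", tag, "\\s+"), "", l[1]))
    gsub("^['\"]|['\"]$", "", v)
  }
  cell <- suppressWarnings(as.numeric(c(
    getv("_cell.length_a"), getv("_cell.length_b"), getv("_cell.length_c"),
    getv("_cell.angle_alpha"), getv("_cell.angle_beta"), getv("_cell.angle_gamma")
  )))
  sg <- getv("_symmetry.space_group_name_H-M")
  if (anyNA(cell) || is.na(sg)) return(NULL)
  list(space_group = sg, cell = cell, operators = space_group_operators(sg))
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure", x$id, "(", x$source_format, ")\n")
  ch <- structure_chains(x)
  for (c in ch) {
    a <- x$atoms[x$atoms$chain == c, ]
    cat("  chain", c, ":", length(unique(a$resno)), "residues,",
        nrow(a), "atoms\n")
  }
  if (!is.null(x$crystal)) {
    cat("  crystal:", x$crystal$space_group, "with",
        length(x$crystal$operators), "operators\n")
  }
  invisible(x)
}

#' Chain identifiers of a Structure
#' @param s A `Structure`.
#' @return Character vector of chain ids in order of appearance.
#' @export
structure_chains <- function(s) unique(s$atoms$chain)

#' Atom table of one chain
#' @param s A `Structure`.
#' @param chain Chain id.
#' @return Atom data.frame ordered by (resno, insert).
#' @export
chain_atoms <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no such chain: ", chain)
  a[order(a$resno, a$insert), , drop = FALSE]
}

# Unique residue keys "resno|insert" of an atom table, in chain order.
.residue_keys <- function(atoms) unique(paste(atoms$resno, atoms$insert, sep = "|"))

# CA coordinate matrix (n x 3) of an atom table, one row per residue with a CA.
.ca_matrix <- function(atoms) {
  ca <- atoms[atoms$elety == "CA" & !atoms$is_het, , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste(ca$resno, ca$insert, sep = "|")
  m
}

#' Write a Structure to a PDB file
#'
#' Round-trips coordinates to 1e-3 Angstrom (PDB fixed-point precision) and
#' author numbering exactly. A CRYST1 record is emitted when crystal
#' metadata is present.
#'
#' @param s A `Structure` with at least one atom.
#' @param path Output file path.
#' @param format Only `"pdb"` is supported.
#' @export
write_structure <- function(s, path, format = "pdb") {
  if (format != "pdb") stop("unsupported output dialect: ", format)
  a <- s$atoms
  if (is.null(a) || nrow(a) == 0) stop("cannot write an empty structure")
  if (any(nchar(a$chain) > 1)) {
    stop("PDB dialect error: chain id longer than one character")
  }
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(a$is_het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    elety = a$elety, elesy = a$elesy,
    o = a$o, b = a$b
  )
  if (!is.null(s$crystal)) {
    cr <- s$crystal
    cl <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                  cr$cell[1], cr$cell[2], cr$cell[3],
                  cr$cell[4], cr$cell[5], cr$cell[6],
                  cr$space_group, 1L)
    body <- readLines(path, warn = FALSE)
    writeLines(c(cl, body), path)
  }
  invisible(path)
}

#' Per-residue model-confidence (pLDDT) profile
#'
#' Predicted models store per-residue pLDDT (0-100) in the B-factor column;
#' this extracts the CA B-factor per residue and its mean. On experimental
#' structures the same accessor returns B-factors, with a warning when
#' values fall outside the pLDDT range.
#'
#' @param s A `Structure`.
#' @return List with `values` (named numeric, names `chain:resno`) and `mean`.
#' @export
extract_plddt_profile <- function(s) {
  ca <- s$atoms[s$atoms$elety == "CA" & !s$atoms$is_het, , drop = FALSE]
  n_res <- nrow(unique(s$atoms[!s$atoms$is_het, c("chain", "resno", "insert")]))
  if (nrow(ca) == 0) stop("no residues with CA atoms")
  if (nrow(ca) < n_res) {
    warning(n_res - nrow(ca), " residue(s) without CA skipped")
  }
  vals <- ca$b
  names(vals) <- paste(ca$chain, ca$resno, sep = ":")
  if (any(vals < 0 | vals > 100)) {
    warning("values outside [0, 100]: not a pLDDT-annotated model?")
  }
  list(values = vals, mean = mean(vals))
}

#' Parse a Dali hit list
#'
#' Reads a whitespace-separated text hit list and keeps hits with Z-score
#' strictly greater than `z_min`, preserving input order. Column positions
#' are configurable because the server's text layout varies by version.
#'
#' @param path Text file, one hit per line.
#' @param z_min Retain hits with `z_score > z_min` (strict).
#' @param id_col,z_col 1-based column positions of the chain id and Z-score.
#' @return data.frame with columns `pdb_chain_id`, `z_score`; attribute
#'   `n_malformed` counts skipped lines.
#' @export
parse_dali_hits <- function(path, z_min = 2, id_col = 1, z_col = 2) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); zs <- numeric(0); bad <- 0L
  for (l in lines) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < max(id_col, z_col)) { bad <- bad + 1L; next }
    z <- suppressWarnings(as.numeric(tok[z_col]))
    if (is.na(z)) { bad <- bad + 1L; next }
    ids <- c(ids, tok[id_col]); zs <- c(zs, z)
  }
  if (bad > 0) warning(bad, " malformed line(s) skipped")
  keep <- zs > z_min
  out <- data.frame(pdb_chain_id = ids[keep], z_score = zs[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- bad
  out
}

# Build a Structure from an atom data.frame (internal constructor used by
# the fixture generator and symmetry expansion).
.new_structure <- function(atoms, id = "synthetic", crystal = NULL,
                           source_format = "pdb") {
  structure(list(id = id, atoms = atoms, crystal = crystal,
                 source_format = source_format),
            class = "Structure")
}
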