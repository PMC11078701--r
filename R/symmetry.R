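# Crystallographic symmetry: general positions for the sohncke space groups
# that protein crystals commonly adopt, fractional<->cartesian conversion,
# and expansion of lattice neighbours around the asymmetric unit.

.SPACE_GROUPS <- list(
  "P 1"          = c("x,y,z"),
  "P 1 2 1"      = c("x,y,z", "-x,y,-z"),
  "P 1 21 1"     = c("x,y,z", "-x,y+1/2,-z"),
  "C 1 2 1"      = c("x,y,z", "-x,y,-z",
                     "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 2 2 2"      = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
  "P 2 2 21"     = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z"),
  "P 21 21 2"    = c("x,y,z", "-x,-y,z",
                     "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
  "P 21 21 21"   = c("x,y,z", "-x+1/2,-y,z+1/2",
                     "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "I 2 2 2"      = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z",
                     "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                     "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z+1/2"),
  "P 41 21 2"    = c("x,y,z", "-x,-y,z+1/2",
                     "-y+1/2,x+1/2,z+1/4", "y+1/2,-x+1/2,z+3/4",
                     "-x+1/2,y+1/2,-z+1/4", "x+1/2,-y+1/2,-z+3/4",
                     "y,x,-z", "-y,-x,-z+1/2"),
  "P 43 21 2"    = c("x,y,z", "-x,-y,z+1/2",
                     "-y+1/2,x+1/2,z+3/4", "y+1/2,-x+1/2,z+1/4",
                     "-x+1/2,y+1/2,-z+3/4", "x+1/2,-y+1/2,-z+1/4",
                     "y,x,-z", "-y,-x,-z+1/2")
)

# Parse one "x,y,z"-style triplet into a fractional (R, t) pair.
.parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry triplet: ", triplet)
  R <- matrix(0, 3, 3); t <- numeric(3)
  ax <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    # coordinate terms with sign
    for (m in regmatches(expr, gregexpr("[+-]?[xyz]", expr))[[1]]) {
      sgn <- if (startsWith(m, "-")) -1 else 1
      R[i, ax[substr(m, nchar(m), nchar(m))]] <- sgn
    }
    # fractional translation terms a/b
    fr <- regmatches(expr, gregexpr("[+-]?[0-9]+/[0-9]+", expr))[[1]]
    for (m in fr) {
      nm <- strsplit(sub("^\\+", "", m), "/")[[1]]
      t[i] <- t[i] + as.numeric(nm[1]) / as.numeric(nm[2])
    }
  }
  list(R = R, t = t, cartesian = FALSE)
}

#' Symmetry operators of a space group
#'
#' Returns the general positions of the named space group as fractional
#' rotation/translation pairs. Hermann-Mauguin symbols are matched with or
#' without spaces (e.g. `"P 21 21 21"` or `"P212121"`).
#'
#' @param symbol Hermann-Mauguin space-group symbol.
#' @return List of operators, each `list(R = 3x3, t = length-3,
#'   cartesian = FALSE)`.
#' @export
space_group_operators <- function(symbol) {
  key <- gsub(" ", "", toupper(symbol))
  tab <- gsub(" ", "", toupper(names(.SPACE_GROUPS)))
  # tolerate short monoclinic symbols P2, P21, C2
  alias <- c("P2" = "P121", "P21" = "P1211", "C2" = "C121")
  if (key %in% names(alias)) key <- alias[[key]]
  hit <- match(key, tab)
  if (is.na(hit)) {
    stop("space group '", symbol, "' not in the built-in table; ",
         "supply operators via REMARK 290 records")
  }
  lapply(.SPACE_GROUPS[[hit]], .parse_symop)
}

# Orthogonalization matrix (fractional -> cartesian), PDB convention:
# a along x, b in the xy plane.
.orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
            2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), c * cos(be),
    0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0,           c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

# Apply an operator (+ integer lattice shift) to cartesian coordinates.
.apply_symop <- function(xyz, op, shift, cell) {
  if (isTRUE(op$cartesian)) {
    M <- .orth_matrix(cell)
    out <- xyz %*% t(op$R)
    out <- sweep(out, 2, op$t + as.numeric(M %*% shift), "+")
    return(out)
  }
  M <- .orth_matrix(cell)
  Minv <- solve(M)
  frac <- xyz %*% t(Minv)
  frac <- frac %*% t(op$R)
  frac <- sweep(frac, 2, op$t + shift, "+")
  frac %*% t(M)
}

#' Expand crystallographic symmetry mates near the asymmetric unit
#'
#' Generates all symmetry-operator + lattice-translation copies of the
#' asymmetric unit that bring any atom within `radius` of it. The identity
#' copy at the origin is excluded.
#'
#' @param s A `Structure` with crystal metadata.
#' @param radius Contact radius in Angstrom (default 5).
#' @return List of mates: `list(op_index, shift, atoms)` where `atoms` is an
#'   atom table with chain ids suffixed by the mate label.
#' @export
expand_symmetry <- function(s, radius = 5) {
  if (is.null(s$crystal)) stop("structure carries no crystal cell")
  cr <- s$crystal
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  mates <- list()
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  rng <- apply(xyz, 2, range)
  for (k in seq_along(cr$operators)) {
    op <- cr$operators[[k]]
    for (si in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[si, ])
      ident <- !isTRUE(op$cartesian) &&
        all(op$R == diag(3)) && all(abs(op$t + sh) < 1e-9)
      ident_c <- isTRUE(op$cartesian) &&
        all(op$R == diag(3)) && all(abs(op$t) < 1e-9) && all(sh == 0)
      if (ident || ident_c) next
      m <- .apply_symop(xyz, op, sh, cr$cell)
      # bounding-box prefilter before the exact distance check
      mr <- apply(m, 2, range)
      if (any(mr[1, ] > rng[2, ] + radius) || any(mr[2, ] < rng[1, ] - radius)) next
      if (.min_crossdist_under(m, xyz, radius)) {
        a <- s$atoms
        a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
        a$chain <- paste0(a$chain, "*", k, ".", si)
        mates[[length(mates) + 1]] <- list(op_index = k, shift = sh, atoms = a)
      }
    }
  }
  mates
}

# TRUE when any cross pair of rows of A, B is closer than radius.
.min_crossdist_under <- function(A, B, radius) {
  # block over A to bound memory
  nb <- nrow(B)
  step <- max(1L, floor(2e6 / nb))
  for (i0 in seq(1, nrow(A), by = step)) {
    idx <- i0:min(i0 + step - 1, nrow(A))
    d2 <- outer(rowSums(A[idx, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[idx, , drop = FALSE] %*% t(B)
    if (min(d2) < radius^2) return(TRUE)
  }
  FALSE
}
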