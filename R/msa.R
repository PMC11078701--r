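# Multiple-sequence-alignment handling: ingestion, redundancy filtering,
# column-to-query mapping, conservation profiling and the N-cap census.

#' Construct an Msa object
#' @param ids Unique record identifiers.
#' @param seqs Aligned sequences (equal length, gaps as `-`).
#' @param query_id Optional id of the query record.
#' @return An `Msa`: list with `ids`, `seqs`, `n_columns`, `query_id`.
#' @export
new_msa <- function(ids, seqs, query_id = NULL) {
  seqs <- toupper(gsub("\\.", "-", seqs))
  if (anyDuplicated(ids)) stop("duplicate record ids")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- ids[which(lens != lens[1])[1]]
    stop("ragged alignment: record '", bad, "' differs in length")
  }
  if (!is.null(query_id) && !query_id %in% ids) {
    stop("query id not present: ", query_id)
  }
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 n_columns = unname(lens[1]), query_id = query_id),
            class = "Msa")
}

#' @export
print.Msa <- function(x, ...) {
  cat("Msa:", length(x$ids), "records x", x$n_columns, "columns\n")
  invisible(x)
}

# Alignment as a character matrix (records x columns).
.msa_matrix <- function(m) {
  do.call(rbind, strsplit(unname(m$seqs), ""))
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA is read through Biostrings; Stockholm is parsed directly
#' (sequence lines concatenated across blocks, `#` annotation lines and the
#' `//` terminator ignored).
#'
#' @param path Alignment file.
#' @param format `"fasta"`, `"stockholm"` or `"auto"` (by extension/content).
#' @param query_id Optional query record id.
#' @return An `Msa`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm"),
                     query_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    return(new_msa(names(ss), as.character(ss), query_id))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  ids <- character(0); seqs <- character(0)
  for (l in lines) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) != 2) stop("malformed Stockholm sequence line: ", l)
    i <- match(tok[1], ids)
    if (is.na(i)) { ids <- c(ids, tok[1]); seqs <- c(seqs, tok[2]) }
    else seqs[i] <- paste0(seqs[i], tok[2])
  }
  new_msa(ids, seqs, query_id)
}

#' Write an Msa as aligned FASTA
#' @param m An `Msa`.
#' @param path Output path.
#' @export
write_msa <- function(m, path) {
  out <- character(2 * length(m$ids))
  out[c(TRUE, FALSE)] <- paste0(">", m$ids)
  out[c(FALSE, TRUE)] <- unname(m$seqs)
  writeLines(out, path)
  invisible(path)
}

#' Pairwise percent identity of two aligned sequences
#'
#' Identities divided by the number of comparable columns, times 100.
#' Denominator modes: `"longest"` counts columns where at least one
#' sequence is non-gap (default), `"shortest"` uses the shorter ungapped
#' length, `"aligned"` counts only columns where both are non-gap.
#'
#' @param a,b Aligned sequences of equal length.
#' @param mode Denominator convention.
#' @return Percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b, mode = c("longest", "shortest", "aligned")) {
  mode <- match.arg(mode)
  va <- strsplit(toupper(a), "")[[1]]; vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) stop("sequences differ in aligned length")
  ga <- va == "-"; gb <- vb == "-"
  ident <- sum(!ga & !gb & va == vb)
  denom <- switch(mode,
    longest = sum(!(ga & gb)),
    shortest = min(sum(!ga), sum(!gb)),
    aligned = sum(!ga & !gb)
  )
  if (denom == 0) stop("no comparable columns")
  100 * ident / denom
}

#' Remove redundant sequences from an alignment
#'
#' Greedy filter: records are visited in descending ungapped length (ties
#' by input order; the query, when set, is always visited first and always
#' retained); a record is kept when its identity to every already-kept
#' record is below `threshold`. Every retained pair is therefore certified
#' below the threshold.
#'
#' @param m An `Msa`.
#' @param threshold Percent identity threshold in (0, 100].
#' @param mode Identity denominator mode (see [pairwise_identity()]).
#' @return Filtered `Msa`.
#' @export
remove_redundancy <- function(m, threshold,
                              mode = c("longest", "shortest", "aligned")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 100)
  lens <- nchar(gsub("-", "", m$seqs))
  ord <- order(-lens, seq_along(m$ids))
  if (!is.null(m$query_id)) {
    qi <- match(m$query_id, m$ids)
    ord <- c(qi, setdiff(ord, qi))
  }
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (pairwise_identity(m$seqs[i], m$seqs[j], mode) >= threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept <- sort(kept)
  new_msa(m$ids[kept], unname(m$seqs[kept]), m$query_id)
}

#' Map alignment columns to query residue numbers
#'
#' Columns where the query is non-gap map to successive residue numbers of
#' the ungapped query, starting at `offset`.
#'
#' @param m An `Msa` with `query_id` set.
#' @param offset Residue number of the query's first residue (default 1).
#' @return Integer vector of length `n_columns`; `NA` at query-gap columns.
#' @export
map_columns_to_query <- function(m, offset = 1) {
  if (is.null(m$query_id)) stop("alignment has no query record")
  q <- strsplit(m$seqs[[m$query_id]], "")[[1]]
  nongap <- q != "-"
  if (!any(nongap)) stop("query row is all gaps")
  out <- rep(NA_integer_, m$n_columns)
  out[nongap] <- seq_len(sum(nongap)) + offset - 1L
  out
}

#' Per-column conservation profile
#'
#' Non-gap residue frequencies per column; the conservation score is the
#' maximum frequency (an entropy-based score is available via
#' `score = "entropy"`). Columns with gap fraction above 0.5 are flagged
#' low-coverage.
#'
#' @param m An `Msa` with at least 2 records.
#' @param score `"max"` (default) or `"entropy"` (1 - normalized Shannon
#'   entropy).
#' @return A `ConservationProfile`: data.frame with `column`, `score`,
#'   `gap_fraction`, `low_coverage`, `consensus`; frequency matrix in
#'   attribute `"frequencies"`.
#' @export
conservation_profile <- function(m, score = c("max", "entropy")) {
  score <- match.arg(score)
  if (length(m$ids) < 2) stop("need at least 2 records")
  mat <- .msa_matrix(m)
  aas <- sort(setdiff(unique(as.vector(mat)), "-"))
  freq <- matrix(0, m$n_columns, length(aas), dimnames = list(NULL, aas))
  gapfrac <- numeric(m$n_columns)
  sc <- numeric(m$n_columns)
  cons <- character(m$n_columns)
  for (j in seq_len(m$n_columns)) {
    col <- mat[, j]
    gapfrac[j] <- mean(col == "-")
    col <- col[col != "-"]
    if (length(col) == 0) { sc[j] <- 0; cons[j] <- "-"; next }
    f <- table(col) / length(col)
    freq[j, names(f)] <- as.numeric(f)
    cons[j] <- names(f)[which.max(f)]
    sc[j] <- if (score == "max") max(f) else {
      h <- -sum(f * log(f))
      1 - h / log(20)
    }
  }
  out <- data.frame(column = seq_len(m$n_columns), score = sc,
                    gap_fraction = gapfrac, low_coverage = gapfrac > 0.5,
                    consensus = cons, stringsAsFactors = FALSE)
  attr(out, "frequencies") <- freq
  class(out) <- c("ConservationProfile", class(out))
  out
}

#' N-cap sequence census over an alignment
#'
#' Classifies each record's residue at the N-cap column with the two-tier
#' rule table (capping box vs non-traditional vs absent) and the residue at
#' the preceding column as L/I, M/V or other. Records gapped at the scored
#' column are tallied separately as unscored.
#'
#' @param m An `Msa`.
#' @param ncap_column,preceding_column 1-based alignment columns.
#' @param rules Rule table (default the package rule set, see
#'   [detect_ncap()]).
#' @return A `MotifCensus`: list of counts (`n_total`, `n_capping_box`,
#'   `n_non_traditional`, `n_absent`, `n_preceding_LI`, `n_preceding_MV`,
#'   `n_unscored`) and matching fractions over `n_total`.
#' @export
ncap_census <- function(m, ncap_column, preceding_column,
                        rules = .NCAP_RULES) {
  if (ncap_column < 1 || ncap_column > m$n_columns ||
      preceding_column < 1 || preceding_column > m$n_columns) {
    stop("column out of range")
  }
  mat <- .msa_matrix(m)
  nc <- mat[, ncap_column]
  pc <- mat[, preceding_column]
  scored <- nc != "-"
  n_total <- sum(scored)
  nc <- nc[scored]; pc <- pc[scored]
  n_cb <- sum(nc %in% rules$capping_box)
  n_nt <- sum(nc %in% rules$non_traditional)
  n_li <- sum(pc %in% rules$preceding_LI)
  n_mv <- sum(pc %in% rules$preceding_MV)
  frac <- function(x) if (n_total > 0) x / n_total else NA_real_
  structure(list(
    n_total = n_total, n_capping_box = n_cb, n_non_traditional = n_nt,
    n_absent = n_total - n_cb - n_nt,
    n_preceding_LI = n_li, n_preceding_MV = n_mv,
    n_unscored = sum(!scored),
    frac_capping_box = frac(n_cb), frac_non_traditional = frac(n_nt),
    frac_any_ncap = frac(n_cb + n_nt),
    frac_preceding_LI = frac(n_li), frac_preceding_MV = frac(n_mv)
  ), class = "MotifCensus")
}

#' @export
print.MotifCensus <- function(x, ...) {
  cat(sprintf("N-cap census over %d sequences:\n", x$n_total))
  cat(sprintf("  capping box      %d (%.1f%%)\n", x$n_capping_box,
              100 * x$frac_capping_box))
  cat(sprintf("  non-traditional  %d (%.1f%%)\n", x$n_non_traditional,
              100 * x$frac_non_traditional))
  cat(sprintf("  preceding L/I    %d (%.1f%%)\n", x$n_preceding_LI,
              100 * x$frac_preceding_LI))
  cat(sprintf("  preceding M/V    %d (%.1f%%)\n", x$n_preceding_MV,
              100 * x$frac_preceding_MV))
  invisible(x)
}
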