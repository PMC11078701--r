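# End-to-end orchestration: the full dimer-orientation screen over a
# structure collection, and the pairwise structure/sequence comparison.

#' Run the full dimer-orientation screen
#'
#' For every structure in `paths` (optionally restricted to entries named
#' in a Dali hit list): read, annotate every chain for the PAS fold, find
#' nearby chain pairs, classify each pair's dimer orientation, and report
#' the alpha1 N-cap class of every PAS chain. Per-file failures are logged
#' as error rows; the screen continues. Deterministic for fixed inputs and
#' config.
#'
#' @param paths Structure file paths (or a directory).
#' @param params A [screen_config()].
#' @param dali_hits Optional data.frame from [parse_dali_hits()]; when
#'   given, only files whose basename contains one of the hit ids (case
#'   insensitive, first 4 characters) are screened.
#' @return List with `table`, `summary` (class counts), `ncap` (per-chain
#'   N-cap table), `ncap_fractions`, `config`.
#' @export
run_screen <- function(paths, params = screen_config(), dali_hits = NULL) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif)$",
                        full.names = TRUE)
    paths <- sort(paths)
  }
  if (!is.null(dali_hits) && nrow(dali_hits) > 0) {
    keys <- tolower(substr(dali_hits$pdb_chain_id, 1, 4))
    keep <- vapply(paths, function(p) {
      any(vapply(keys, grepl, logical(1), x = tolower(basename(p)),
                 fixed = TRUE))
    }, logical(1))
    paths <- paths[keep]
  }
  scr <- screen_collection(paths, params)
  ncap_rows <- list()
  for (p in paths) {
    s <- tryCatch(read_structure(p), error = function(e) NULL)
    if (is.null(s)) next
    for (ch in structure_chains(s)) {
      pas <- tryCatch(annotate_pas(chain_atoms(s, ch)),
                      error = function(e) NULL)
      if (is.null(pas)) next
      ncap_rows[[length(ncap_rows) + 1]] <- data.frame(
        file = basename(p), chain = ch, is_pas = pas$is_pas,
        ncap_class = if (!is.null(pas$ncap)) pas$ncap$ncap_class else NA,
        preceding_class = if (!is.null(pas$ncap)) pas$ncap$preceding_class
        else NA,
        stringsAsFactors = FALSE)
    }
  }
  ncap <- if (length(ncap_rows) > 0) do.call(rbind, ncap_rows) else
    data.frame(file = character(0), chain = character(0),
               is_pas = logical(0), ncap_class = character(0),
               preceding_class = character(0))
  scored <- ncap[!is.na(ncap$ncap_class), , drop = FALSE]
  nf <- if (nrow(scored) > 0) {
    list(any_ncap = mean(scored$ncap_class %in%
                           c("capping_box", "non_traditional")),
         capping_box = mean(scored$ncap_class == "capping_box"),
         preceding_LI = mean(scored$preceding_class == "LI"))
  } else {
    list(any_ncap = NA, capping_box = NA, preceding_LI = NA)
  }
  list(table = scr$table, summary = scr$summary, ncap = ncap,
       ncap_fractions = nf, config = params)
}

#' Write screen results as provenance-stamped TSV + JSON
#'
#' @param res Result of [run_screen()].
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_screen_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_yaml <- yaml::as.yaml(unclass(res$config))
  tmp <- tempfile(); writeLines(cfg_yaml, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  hdr <- c(paste0("# pascreen ",
                  as.character(utils::packageVersion("pascreen"))),
           paste0("# config_md5 ", cfg_hash))
  tsv <- file.path(out_dir, "screen.tsv")
  con <- file(tsv, "w")
  writeLines(hdr, con)
  utils::write.table(res$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  js <- file.path(out_dir, "screen_summary.json")
  jsonlite::write_json(list(config_md5 = cfg_hash, summary = res$summary,
                            ncap_fractions = res$ncap_fractions),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Compare two chains: superposition and sequence identity
#'
#' Sequence-independent structural alignment of the two chains plus the
#' pairwise sequence identity over a residue window of the first chain
#' (global pairwise alignment of the window sequences, identity over
#' aligned columns).
#'
#' @param sA,sB `Structure`s.
#' @param chainA,chainB Chain ids.
#' @param window Length-2 author-numbering window on chain A (clipped with
#'   a warning when it extends beyond the chain), or `NULL` for the full
#'   chain.
#' @return List with `superposition` (a `SuperpositionResult`) and
#'   `identity` (percent).
#' @export
run_compare <- function(sA, chainA, sB, chainB, window = NULL) {
  A <- chain_atoms(sA, chainA); B <- chain_atoms(sB, chainB)
  sp <- structure_align(A, B)
  seq_of <- function(atoms, win) {
    ca <- atoms[atoms$elety == "CA" & !atoms$is_het, , drop = FALSE]
    if (!is.null(win)) {
      if (win[1] < min(ca$resno) || win[2] > max(ca$resno)) {
        warning("window clipped to chain extent")
        win <- c(max(win[1], min(ca$resno)), min(win[2], max(ca$resno)))
      }
      ca <- ca[ca$resno >= win[1] & ca$resno <= win[2], , drop = FALSE]
    }
    paste(bio3d::aa321(ca$resid), collapse = "")
  }
  # map the window onto chain B through the structural correspondence
  winB <- NULL
  if (!is.null(window)) {
    co <- sp$correspondence
    hit <- co[co$resnoA >= window[1] & co$resnoA <= window[2], , drop = FALSE]
    if (nrow(hit) >= 2) winB <- range(hit$resnoB)
  }
  qa <- seq_of(A, window); qb <- seq_of(B, winB)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa), Biostrings::AAString(qb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  list(superposition = sp, identity = Biostrings::pid(al, type = "PID1"))
}
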