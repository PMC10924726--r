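# Single-amino-acid-variant rescue of unmapped peptides, and allele counting
# across haplotype panels.

#' Explain an unmapped peptide as a single amino acid variant
#'
#' Scans every window of the protein equal in length to the peptide that
#' differs from it at exactly one residue. A window qualifies only if, after
#' substituting the observed residue into the protein, the window still has
#' tryptic boundaries and at most `max_missed` missed cleavages under the
#' substituted sequence (substitutions that create or destroy a K/R are
#' therefore evaluated in their new context).
#'
#' @param peptide peptide string with no exact tryptic match on the protein
#'   (use [map_peptide()] first; an exact match is a precondition error).
#' @param protein a single-row [protein_set] (or sequence string, in which
#'   case the protein id is reported as `""`).
#' @param max_missed maximum missed cleavages (default 2).
#' @param proline_rule see [cleavage_sites()].
#' @return A `data.frame` with one row per explaining window: `peptide`,
#'   `protein_id`, `protein_position` (1-based position of the substituted
#'   residue), `ref_residue`, `obs_residue`.
#' @export
rescue_single_substitution <- function(peptide, protein, max_missed = 2,
                                       proline_rule = TRUE) {
  stopifnot(length(peptide) == 1L, nzchar(peptide))
  seq <- protein_sequence(protein)
  id <- if (is.data.frame(protein)) protein$id else ""
  empty <- data.frame(peptide = character(0), protein_id = character(0),
                      protein_position = integer(0),
                      ref_residue = character(0), obs_residue = character(0),
                      stringsAsFactors = FALSE)
  if (grepl("X", peptide, fixed = TRUE)) return(empty)
  pset <- protein_set(if (nzchar(id)) id else "q", seq)
  if (nrow(map_peptide(peptide, pset, max_missed = max_missed,
                       proline_rule = proline_rule)))
    stop("peptide has an exact tryptic match; rescue applies only to unmapped peptides")
  L <- nchar(peptide)
  n <- nchar(seq)
  if (L > n) return(empty)
  pep_chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  seq_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (s in seq_len(n - L + 1L)) {
    win <- seq_chars[s:(s + L - 1L)]
    if (any(win == "X")) next
    diffs <- which(win != pep_chars)
    if (length(diffs) != 1L) next
    pos <- s + diffs - 1L
    sub_chars <- seq_chars
    sub_chars[pos] <- pep_chars[diffs]
    sub_seq <- paste(sub_chars, collapse = "")
    e <- s + L - 1L
    sites <- cleavage_sites(sub_seq, proline_rule)
    nterm <- s == 1L || (s - 1L) %in% sites
    cterm <- e == n || e %in% sites
    if (!nterm || !cterm) next
    if (sum(sites >= s & sites <= e - 1L) > max_missed) next
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = peptide, protein_id = id, protein_position = pos,
      ref_residue = seq_chars[pos], obs_residue = pep_chars[diffs],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition unmapped peptides into variant-explained and unexplained
#'
#' Each unmapped peptide is variant-explained iff
#' [rescue_single_substitution()] finds at least one qualifying window on the
#' target protein. When an evidence table is supplied, each explanation is
#' cross-checked for its exact-match counterpart (the unsubstituted protein
#' window as a peptide string); a counterpart found in the table is recorded
#' as corroboration, but its absence is not disqualifying. A peptide
#' explained by several windows contributes its observations once.
#'
#' @param unmapped data frame of unmapped peptides (`peptide`, `n_obs`).
#' @param protein single-row [protein_set]: the attribution target.
#' @param evidence optional full peptide table used for counterpart lookup.
#' @param max_missed,proline_rule passed to [rescue_single_substitution()].
#' @return A list with elements `explained` and `unexplained` (peptide
#'   tables), `explanations` (all windows, with a
#'   `supporting_exact_peptide` column, `NA` when no counterpart was found),
#'   and `variant_obs` (total observations of explained peptides).
#' @export
explain_unmapped <- function(unmapped, protein, evidence = NULL,
                             max_missed = 2, proline_rule = TRUE) {
  seq <- protein_sequence(protein)
  expl_rows <- list()
  explained_idx <- logical(nrow(unmapped))
  for (k in seq_len(nrow(unmapped))) {
    ex <- rescue_single_substitution(unmapped$peptide[k], protein,
                                     max_missed = max_missed,
                                     proline_rule = proline_rule)
    if (!nrow(ex)) next
    explained_idx[k] <- TRUE
    L <- nchar(unmapped$peptide[k])
    # window string = protein window that the peptide varies from
    win_start <- ex$protein_position -
      (regexpr_diff_offset(unmapped$peptide[k], seq, ex$protein_position) - 1L)
    ex$supporting_exact_peptide <- vapply(seq_len(nrow(ex)), function(j) {
      w <- substr(seq, win_start[j], win_start[j] + L - 1L)
      if (!is.null(evidence) && w %in% evidence$peptide) w else NA_character_
    }, character(1))
    expl_rows[[length(expl_rows) + 1L]] <- ex
  }
  explanations <- if (length(expl_rows)) do.call(rbind, expl_rows) else
    data.frame(peptide = character(0), protein_id = character(0),
               protein_position = integer(0), ref_residue = character(0),
               obs_residue = character(0),
               supporting_exact_peptide = character(0),
               stringsAsFactors = FALSE)
  rownames(explanations) <- NULL
  list(explained = unmapped[explained_idx, , drop = FALSE],
       unexplained = unmapped[!explained_idx, , drop = FALSE],
       explanations = explanations,
       variant_obs = sum(unmapped$n_obs[explained_idx]))
}

# Offset (1-based) of the substituted residue within its window, given the
# peptide, the protein sequence and the protein position of the substitution.
# The window start is protein_position - offset + 1; since the peptide and
# window agree everywhere except the substitution, the offset is the position
# within the peptide whose residue sits at protein_position.
regexpr_diff_offset <- function(peptide, seq, protein_position) {
  L <- nchar(peptide)
  n <- nchar(seq)
  vapply(protein_position, function(pos) {
    for (off in seq_len(L)) {
      s <- pos - off + 1L
      if (s < 1L || s + L - 1L > n) next
      win <- substr(seq, s, s + L - 1L)
      d <- which(strsplit(win, "")[[1]] != strsplit(peptide, "")[[1]])
      if (length(d) == 1L && d == off) return(off)
    }
    NA_integer_
  }, integer(1))
}

#' Residue histogram at one column of a haplotype panel
#'
#' @param panel aligned protein sequences (character vector or
#'   `Biostrings::AAStringSet`), all of equal length.
#' @param column 1-based alignment column.
#' @return An object of class `allele_count`: list with `column`, `counts`
#'   (named integer vector, gaps excluded, sorted by decreasing count then
#'   residue) and `n_gaps`.
#' @export
summarize_haplotype_alleles <- function(panel, column) {
  panel <- as.character(panel)
  if (!length(panel)) stop("empty panel")
  widths <- nchar(panel)
  if (length(unique(widths)) != 1L)
    stop("ragged panel: aligned sequences must have equal length")
  if (column < 1L || column > widths[1])
    stop("column out of range")
  res <- toupper(substr(panel, column, column))
  is_gap <- res %in% GAP_CHARS
  counts <- table(res[!is_gap])
  if (length(counts)) counts <- counts[order(-counts, names(counts))]
  out <- list(column = as.integer(column),
              counts = stats::setNames(as.integer(counts), names(counts)),
              n_gaps = sum(is_gap))
  class(out) <- "allele_count"
  out
}

#' @export
print.allele_count <- function(x, ...) {
  cat(sprintf("Alleles at alignment column %d:\n", x$column))
  if (length(x$counts))
    cat(paste(sprintf("  %s: %d", names(x$counts), x$counts), collapse = "\n"),
        "\n")
  if (x$n_gaps) cat(sprintf("  gaps: %d\n", x$n_gaps))
  invisible(x)
}
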