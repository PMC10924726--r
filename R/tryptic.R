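# Tryptic digestion, peptide filtering, mapping and attribution.
#
# Trypsin cleaves C-terminal to K or R; with the proline rule enabled
# (default), a K/R immediately followed by P is not cleavage-competent.
# All coordinates are 1-based and inclusive.

#' Cleavage-competent trypsin sites in a sequence
#'
#' @param sequence amino-acid string.
#' @param proline_rule if `TRUE`, K/R followed by P is not a site.
#' @return Integer positions `i` (1..n-1) such that trypsin cleaves between
#'   residues `i` and `i+1`.
#' @export
cleavage_sites <- function(sequence, proline_rule = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R"))
  if (proline_rule && length(idx))
    idx <- idx[chars[idx + 1L] != "P"]
  idx
}

#' Count missed cleavages within a peptide
#'
#' A missed cleavage is a cleavage-competent K/R among residues 1..len-1 of
#' the peptide (the C-terminal residue never counts). With the proline rule,
#' K/R immediately followed by P within the peptide does not count.
#'
#' @param peptide non-empty amino-acid string (vectorized).
#' @param proline_rule see [cleavage_sites()].
#' @return Integer vector of missed-cleavage counts.
#' @export
count_missed_cleavages <- function(peptide, proline_rule = TRUE) {
  if (any(!nzchar(peptide))) stop("empty peptide")
  vapply(peptide, function(p) length(cleavage_sites(p, proline_rule)),
         integer(1), USE.NAMES = FALSE)
}

#' Enumerate fully tryptic peptides of a protein
#'
#' Returns exactly the substrings whose N-boundary is the protein start or
#' follows a cleavage site, whose C-boundary is the protein end or a cleavage
#' site, with at most `max_missed` internal cleavage sites, within the length
#' window.
#'
#' @param protein a [protein_set] row, single-row protein set, or a plain
#'   sequence string.
#' @param max_missed maximum internal missed cleavages (default 2).
#' @param min_len,max_len peptide length window (defaults 7 and 50).
#' @param proline_rule see [cleavage_sites()].
#' @return A `data.frame` with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`.
#' @export
enumerate_tryptic_peptides <- function(protein, max_missed = 2, min_len = 7,
                                       max_len = 50, proline_rule = TRUE) {
  stopifnot(max_missed >= 0, min_len >= 1, min_len <= max_len)
  seq <- protein_sequence(protein)
  n <- nchar(seq)
  bounds <- c(0L, cleavage_sites(seq, proline_rule), n)
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    j <- (i + 1L):jmax
    start <- bounds[i] + 1L
    end <- bounds[j]
    len <- end - start + 1L
    keep <- len >= min_len & len <= max_len
    if (any(keep))
      out[[i]] <- data.frame(peptide = substring(seq, start, end[keep]),
                             start = start, end = end[keep],
                             missed_cleavages = (j - i - 1L)[keep],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0))
  rownames(out) <- NULL
  out
}

protein_sequence <- function(protein) {
  if (is.character(protein) && length(protein) == 1L && !grepl(">", protein))
    return(toupper(protein))
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    return(protein$sequence)
  }
  stop("cannot interpret 'protein' as a single sequence")
}

#' Filter a peptide evidence table
#'
#' Applies the evidence-quality filters: peptides must have at least
#' `min_obs` observations (singletons are removed at the default) and at most
#' `max_missed` internal K/R missed cleavages. The fully-tryptic requirement
#' is enforced at mapping time, because boundaries depend on the protein
#' context.
#'
#' @param peptides a peptide table (columns `peptide`, `n_obs`).
#' @param min_obs minimum observation count (default 2).
#' @param max_missed maximum missed cleavages (default 2).
#' @param proline_rule see [cleavage_sites()].
#' @return The filtered peptide table.
#' @export
filter_peptide_table <- function(peptides, min_obs = 2, max_missed = 2,
                                 proline_rule = TRUE) {
  if (!nrow(peptides)) return(peptides)
  keep <- peptides$n_obs >= min_obs &
    count_missed_cleavages(peptides$peptide, proline_rule) <= max_missed
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a peptide onto a panel of proteins
#'
#' Finds every occurrence of the peptide in any protein where both boundaries
#' are tryptic (N-boundary: protein start, or the preceding residue is a
#' cleavage-competent K/R; C-boundary: protein end, or the final residue is a
#' cleavage-competent K/R) and the number of internal missed cleavages, under
#' the protein's own context, is at most `max_missed`. A peptide containing
#' `X` never matches.
#'
#' @param peptide peptide string.
#' @param proteins a [protein_set].
#' @param max_missed maximum missed cleavages (default 2).
#' @param proline_rule see [cleavage_sites()].
#' @param il_equivalent if `TRUE`, isoleucine and leucine are treated as
#'   indistinguishable during matching (mass-spectrometry realism); default
#'   `FALSE`, so single-residue I/L differences discriminate paralogues.
#' @return A `data.frame` of matches sorted by (protein_id, start) with
#'   columns `peptide`, `protein_id`, `start`, `end`, `missed_cleavages`,
#'   `nterm_tryptic`, `cterm_tryptic`, `match_type`.
#' @export
map_peptide <- function(peptide, proteins, max_missed = 2,
                        proline_rule = TRUE, il_equivalent = FALSE) {
  stopifnot(length(peptide) == 1L, nzchar(peptide))
  empty <- data.frame(peptide = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0),
                      nterm_tryptic = logical(0), cterm_tryptic = logical(0),
                      match_type = character(0), stringsAsFactors = FALSE)
  if (grepl("X", peptide, fixed = TRUE)) return(empty)
  pep_q <- if (il_equivalent) chartr("L", "I", peptide) else peptide
  L <- nchar(peptide)
  # all occurrences, overlapping included (gregexpr alone skips overlaps)
  find_all <- function(pat, subj) {
    out <- integer(0)
    from <- 1L
    while (from <= nchar(subj)) {
      h <- regexpr(pat, substr(subj, from, nchar(subj)), fixed = TRUE)
      if (h == -1L) break
      pos <- from + as.integer(h) - 1L
      out <- c(out, pos)
      from <- pos + 1L
    }
    out
  }
  rows <- list()
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    seq_q <- if (il_equivalent) chartr("L", "I", seq) else seq
    hits <- find_all(pep_q, seq_q)
    if (!length(hits)) next
    n <- nchar(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    sites <- cleavage_sites(seq, proline_rule)
    for (s in as.integer(hits)) {
      e <- s + L - 1L
      if (any(chars[s:e] == "X")) next
      nterm <- s == 1L || (s - 1L) %in% sites
      cterm <- e == n || e %in% sites
      if (!nterm || !cterm) next
      missed <- sum(sites >= s & sites <= e - 1L)
      if (missed > max_missed) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = peptide, protein_id = proteins$id[i], start = s, end = e,
        missed_cleavages = missed, nterm_tryptic = nterm,
        cterm_tryptic = cterm, match_type = "exact",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the unique-peptide / observation-weighted attribution report
#'
#' For each paralogue, the capture set is the subset of filtered peptides
#' with at least one exact fully tryptic match to it; the unique set is the
#' subset captured by exactly one paralogue. Observation totals sum `n_obs`
#' over the respective sets. The explained-observation fraction is captured
#' observations divided by the total observations of all filtered peptides
#' (mapped or not). Paralogues are ranked by descending explained fraction,
#' ties broken by larger unique-observation total, then lexicographic id.
#'
#' @param peptides a filtered peptide table.
#' @param proteins a non-empty [protein_set].
#' @inheritParams map_peptide
#' @return An object of class `attribution_report`.
#' @export
build_attribution <- function(peptides, proteins, max_missed = 2,
                              proline_rule = TRUE, il_equivalent = FALSE) {
  if (!nrow(proteins)) stop("empty protein collection")
  ids <- proteins$id
  capture_sets <- stats::setNames(
    replicate(length(ids), character(0), simplify = FALSE), ids)
  unmapped <- character(0)
  hit_count <- stats::setNames(integer(nrow(peptides)), peptides$peptide)
  for (k in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[k]
    m <- map_peptide(pep, proteins, max_missed = max_missed,
                     proline_rule = proline_rule,
                     il_equivalent = il_equivalent)
    hit_ids <- unique(m$protein_id)
    hit_count[k] <- length(hit_ids)
    if (!length(hit_ids)) unmapped <- c(unmapped, pep)
    for (id in hit_ids) capture_sets[[id]] <- c(capture_sets[[id]], pep)
  }
  obs_of <- stats::setNames(peptides$n_obs, peptides$peptide)
  total_obs <- sum(peptides$n_obs)
  unique_sets <- lapply(capture_sets, function(set)
    set[hit_count[set] == 1L])
  captured_obs <- vapply(capture_sets, function(s) sum(obs_of[s]), numeric(1))
  unique_obs <- vapply(unique_sets, function(s) sum(obs_of[s]), numeric(1))
  explained <- if (total_obs > 0) captured_obs / total_obs else
    rep(0, length(ids))
  pp <- data.frame(
    protein_id = ids,
    n_captured = vapply(capture_sets, length, integer(1)),
    n_unique = vapply(unique_sets, length, integer(1)),
    captured_obs = as.integer(captured_obs),
    unique_obs = as.integer(unique_obs),
    explained_fraction = as.numeric(explained),
    stringsAsFactors = FALSE)
  ord <- order(-pp$explained_fraction, -pp$unique_obs, pp$protein_id)
  pp <- pp[ord, , drop = FALSE]
  pp$rank <- seq_len(nrow(pp))
  rownames(pp) <- NULL
  unmapped_df <- data.frame(peptide = unmapped,
                            n_obs = as.integer(obs_of[unmapped]),
                            stringsAsFactors = FALSE)
  rownames(unmapped_df) <- NULL
  report <- list(per_paralogue = pp,
                 capture_sets = capture_sets[pp$protein_id],
                 unique_sets = unique_sets[pp$protein_id],
                 unmapped = unmapped_df,
                 total_peptides = nrow(peptides),
                 total_obs = as.integer(total_obs))
  class(report) <- "attribution_report"
  report
}
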