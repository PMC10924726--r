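# Cross-species conservation profiling: conserved-column detection over
# nested clades, orthologue QC, conservative/radical substitution calls,
# per-paralogue variant profiles and shared derived variants.

#' Nested clade levels, shallowest first
#' @export
CLADE_LEVELS <- c("primates", "mammals", "tetrapods", "vertebrates")

# Physicochemical exchange groups used for the conservative/radical call.
# Pinned here as the package's fixed grouping.
EXCHANGE_GROUPS <- list(small = c("A", "G", "P", "S", "T"),
                        aliphatic = c("I", "L", "M", "V"),
                        acidic_amide = c("D", "E", "N", "Q"),
                        basic = c("K", "R", "H"),
                        aromatic = c("F", "W", "Y"),
                        cysteine = "C")

msa_matrix <- function(msa) {
  ids <- names(msa)
  msa <- stats::setNames(as.character(msa), ids)
  if (!length(msa)) stop("empty alignment")
  if (length(unique(nchar(msa))) != 1L)
    stop("unaligned input: rows have unequal length")
  m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Quality-control candidate orthologues against a reference
#'
#' Drops any candidate with an insertion or deletion run longer than
#' `max_indel` alignment columns relative to the reference row, or missing
#' the reference's first or last aligned residue (candidates must carry the
#' ancestral N- and C-terminal sequence).
#'
#' @param candidates named character vector (or `AAStringSet`) of sequences
#'   aligned to the reference (equal widths).
#' @param reference the aligned reference row (string of the same width).
#' @param max_indel longest tolerated gap run, in columns (default 7).
#' @return The retained subset of `candidates`, with the dropped ids in
#'   attribute `"dropped"`.
#' @export
qc_orthologues <- function(candidates, reference, max_indel = 7) {
  candidates <- stats::setNames(as.character(candidates), names(candidates))
  reference <- as.character(reference)
  if (any(nchar(candidates) != nchar(reference)))
    stop("unaligned input: candidate width differs from reference")
  ref_chars <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  ref_res <- !(ref_chars %in% GAP_CHARS)
  if (!any(ref_res)) stop("reference row is all gaps")
  first_ref <- which(ref_res)[1]
  last_ref <- which(ref_res)[sum(ref_res)]
  keep <- vapply(candidates, function(cand) {
    cc <- strsplit(toupper(cand), "", fixed = TRUE)[[1]]
    cand_res <- !(cc %in% GAP_CHARS)
    if (!cand_res[first_ref] || !cand_res[last_ref]) return(FALSE)
    del <- rle(!cand_res & ref_res)   # candidate gapped where reference isn't
    ins <- rle(cand_res & !ref_res)   # candidate residue where reference gapped
    if (any(del$lengths[del$values] > max_indel)) return(FALSE)
    if (any(ins$lengths[ins$values] > max_indel)) return(FALSE)
    TRUE
  }, logical(1))
  out <- candidates[keep]
  attr(out, "dropped") <- names(candidates)[!keep]
  out
}

#' Find alignment columns conserved across nested clades
#'
#' A column is conserved at clade level `L` iff, among the rows belonging to
#' `L` (rows whose clade tag is `L` or any shallower nested level), the
#' number of gaps is at most `gap_tolerance` and the modal residue's
#' frequency among non-gap rows is at least `min_fraction`. The reported
#' depth of a column is the deepest level such that the criterion holds at
#' that level and at every shallower level, which makes conservation monotone
#' by construction.
#'
#' @param msa named character vector (or `AAStringSet`) of aligned rows.
#' @param clades named character vector mapping every row id to a level in
#'   [CLADE_LEVELS].
#' @param min_fraction required modal-residue frequency (default 1.0: strict
#'   identity).
#' @param gap_tolerance maximum gaps tolerated per level (default 0).
#' @return An object of class `conserved_columns`: list with `depth`
#'   (integer vector per column: 0 = not conserved, k = index into
#'   [CLADE_LEVELS]), `consensus` (levels x columns character matrix of modal
#'   residues, `NA` where not conserved) and `levels`.
#' @export
conserved_columns <- function(msa, clades, min_fraction = 1.0,
                              gap_tolerance = 0) {
  m <- msa_matrix(msa)
  ids <- rownames(m)
  if (is.null(ids) || anyNA(match(ids, names(clades))))
    stop("every alignment row must have a clade level")
  lev <- match(clades[ids], CLADE_LEVELS)
  if (anyNA(lev)) stop("unknown clade level in clade map")
  ncol_aln <- ncol(m)
  ok <- matrix(FALSE, nrow = length(CLADE_LEVELS), ncol = ncol_aln)
  consensus <- matrix(NA_character_, nrow = length(CLADE_LEVELS),
                      ncol = ncol_aln,
                      dimnames = list(CLADE_LEVELS, NULL))
  for (k in seq_along(CLADE_LEVELS)) {
    rows <- which(lev <= k)
    for (j in seq_len(ncol_aln)) {
      col <- m[rows, j]
      gaps <- col %in% GAP_CHARS
      if (sum(gaps) > gap_tolerance) next
      res <- col[!gaps]
      if (!length(res)) next
      tab <- table(res)
      tab <- tab[order(-tab, names(tab))]  # deterministic modal tie-break
      if (tab[1] / length(res) >= min_fraction) {
        ok[k, j] <- TRUE
        consensus[k, j] <- names(tab)[1]
      }
    }
  }
  depth <- integer(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    run <- which(!ok[, j])
    depth[j] <- if (length(run)) run[1] - 1L else length(CLADE_LEVELS)
  }
  consensus[!ok] <- NA_character_
  out <- list(depth = depth, consensus = consensus, levels = CLADE_LEVELS)
  class(out) <- "conserved_columns"
  out
}

#' Classify an amino-acid substitution as conservative or not
#'
#' Conservative iff both residues lie in the same physicochemical exchange
#' group of the package's fixed grouping: \{A,G,P,S,T\}, \{I,L,M,V\},
#' \{D,E,N,Q\}, \{K,R,H\}, \{F,W,Y\}, \{C\}. Symmetric and deterministic.
#'
#' @param ref,alt standard amino-acid letters, `ref != alt` (vectorized).
#' @return Character vector: `"conservative"` or `"non_conservative"`.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% AA_STANDARD) || any(!alt %in% AA_STANDARD))
    stop("residues must be standard amino acids")
  if (any(ref == alt)) stop("ref and alt must differ")
  group_of <- function(x) {
    g <- vapply(x, function(a)
      which(vapply(EXCHANGE_GROUPS, function(grp) a %in% grp, logical(1))),
      integer(1))
    g
  }
  unname(ifelse(group_of(ref) == group_of(alt), "conservative",
                "non_conservative"))
}

# Global protein alignment of a paralogue against the ungapped reference.
# BLOSUM62, affine gaps; parameters pinned.
align_to_reference <- function(paralogue_seq, reference_seq,
                               gap_opening = 10, gap_extension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paralogue_seq), Biostrings::AAString(reference_seq),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  if (Biostrings::score(pa) <= 0)
    stop("no positive-scoring global alignment of paralogue to reference")
  list(pattern = as.character(Biostrings::pattern(pa)),
       subject = as.character(Biostrings::subject(pa)))
}

#' Profile a paralogue's variants against a conserved-column set
#'
#' Aligns the paralogue globally to the ungapped reference row, then lists
#' every position where the paralogue differs from the consensus of a
#' conserved column (a SAAV), and every deletion and insertion relative to
#' the reference. SAAVs carry the alignment column, the consensus (at the
#' column's deepest conserved level), the paralogue residue, the clade depth,
#' a conservative/radical flag and the paralogue's own 1-based residue
#' coordinate (the coordinate used for variant names such as G343S).
#'
#' @param paralogue single-row [protein_set] or plain sequence string.
#' @param reference_row the reference sequence as aligned in the orthologue
#'   MSA (may contain gaps; gaps map reference residues to MSA columns).
#' @param conserved a [conserved_columns()] result for the same MSA.
#' @return An object of class `paralog_profile`: list with `id`, `saavs`
#'   (data frame: `column`, `ref_residue`, `alt_residue`, `depth`, `level`,
#'   `conservative`, `paralogue_position`, `reference_position`),
#'   `deletions` (`column_start`, `column_end`, `length`), `insertions`
#'   (`column`, `length`) and `clade_totals` (named integer vector: SAAVs at
#'   columns conserved to at least each level).
#' @export
profile_paralogue_variants <- function(paralogue, reference_row, conserved) {
  stopifnot(inherits(conserved, "conserved_columns"))
  seq <- protein_sequence(paralogue)
  id <- if (is.data.frame(paralogue)) paralogue$id else ""
  ref_chars <- strsplit(toupper(as.character(reference_row)), "",
                        fixed = TRUE)[[1]]
  if (length(ref_chars) != length(conserved$depth))
    stop("reference row width differs from conserved-column set")
  ref_res_cols <- which(!(ref_chars %in% GAP_CHARS))
  ref_ungapped <- paste(ref_chars[ref_res_cols], collapse = "")
  aln <- align_to_reference(seq, ref_ungapped)
  p_chars <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  s_chars <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  saavs <- list()
  deletions <- list()
  insertions <- list()
  rpos <- 0L  # reference residue index (into ungapped reference)
  qpos <- 0L  # paralogue residue index
  i <- 1L
  while (i <= length(p_chars)) {
    p_gap <- p_chars[i] == "-"
    s_gap <- s_chars[i] == "-"
    if (!p_gap && !s_gap) {
      rpos <- rpos + 1L; qpos <- qpos + 1L
      col <- ref_res_cols[rpos]
      depth <- conserved$depth[col]
      if (depth >= 1L) {
        cons <- conserved$consensus[depth, col]
        if (!is.na(cons) && p_chars[i] != cons) {
          conservative <- if (p_chars[i] %in% AA_STANDARD &&
                              cons %in% AA_STANDARD)
            classify_substitution(cons, p_chars[i]) else NA_character_
          saavs[[length(saavs) + 1L]] <- data.frame(
            column = col, ref_residue = cons, alt_residue = p_chars[i],
            depth = depth, level = CLADE_LEVELS[depth],
            conservative = conservative,
            paralogue_position = qpos, reference_position = rpos,
            stringsAsFactors = FALSE)
        }
      }
      i <- i + 1L
    } else if (p_gap) {  # deletion in the paralogue
      len <- 0L
      start_r <- rpos + 1L
      while (i <= length(p_chars) && p_chars[i] == "-") {
        rpos <- rpos + 1L; len <- len + 1L; i <- i + 1L
      }
      deletions[[length(deletions) + 1L]] <- data.frame(
        column_start = ref_res_cols[start_r],
        column_end = ref_res_cols[rpos], length = len,
        stringsAsFactors = FALSE)
    } else {  # insertion in the paralogue
      len <- 0L
      while (i <= length(s_chars) && s_chars[i] == "-") {
        qpos <- qpos + 1L; len <- len + 1L; i <- i + 1L
      }
      insertions[[length(insertions) + 1L]] <- data.frame(
        column = if (rpos >= 1L) ref_res_cols[rpos] else 0L, length = len,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst, proto) {
    if (length(lst)) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else proto
  }
  saavs <- bind(saavs, data.frame(
    column = integer(0), ref_residue = character(0),
    alt_residue = character(0), depth = integer(0), level = character(0),
    conservative = character(0), paralogue_position = integer(0),
    reference_position = integer(0), stringsAsFactors = FALSE))
  totals <- vapply(seq_along(CLADE_LEVELS), function(k)
    sum(saavs$depth >= k), integer(1))
  names(totals) <- CLADE_LEVELS
  out <- list(id = id, saavs = saavs,
              deletions = bind(deletions, data.frame(
                column_start = integer(0), column_end = integer(0),
                length = integer(0))),
              insertions = bind(insertions, data.frame(
                column = integer(0), length = integer(0))),
              clade_totals = totals)
  class(out) <- "paralog_profile"
  out
}

#' Find derived variants shared across paralogue profiles
#'
#' Variants occupying the same alignment column and carrying the same
#' alternate residue (or, with `pool_alts = TRUE`, any alternate residue at
#' the same column, pooled in the style of "Y141D/E") that are present in at
#' least `min_share` profiles.
#'
#' @param profiles a list of `paralog_profile` objects (at least two).
#' @param min_share minimum number of sharing profiles (default 2).
#' @param pool_alts pool different alternate residues at one column.
#' @return A `data.frame` sorted by column: `column`, `ref_residue`,
#'   `alt_residue` (slash-pooled when `pool_alts`), `n_shared`, `ids`
#'   (comma-separated sharing paralogue ids).
#' @export
shared_derived_variants <- function(profiles, min_share = 2,
                                    pool_alts = FALSE) {
  if (length(profiles) < 2L) stop("need at least two profiles")
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$saavs)) return(NULL)
    cbind(p$saavs[, c("column", "ref_residue", "alt_residue")],
          id = p$id, stringsAsFactors = FALSE)
  })
  all_saavs <- do.call(rbind, rows)
  empty <- data.frame(column = integer(0), ref_residue = character(0),
                      alt_residue = character(0), n_shared = integer(0),
                      ids = character(0), stringsAsFactors = FALSE)
  if (is.null(all_saavs) || !nrow(all_saavs)) return(empty)
  key <- if (pool_alts) as.character(all_saavs$column) else
    paste(all_saavs$column, all_saavs$alt_residue, sep = ":")
  grp <- split(all_saavs, key)
  out <- lapply(grp, function(g) {
    ids <- sort(unique(g$id))
    if (length(ids) < min_share) return(NULL)
    data.frame(column = g$column[1],
               ref_residue = g$ref_residue[1],
               alt_residue = paste(sort(unique(g$alt_residue)),
                                   collapse = "/"),
               n_shared = length(ids),
               ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$column, out$alt_residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
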