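# Transcript coding-status assessment: classify a paralogue transcript's
# lesions (premature stops, frameshifts, 5'-truncation, fragmentary
# coverage) relative to a parent CDS, and combine lesion status with peptide
# evidence into coding/pseudogene verdicts.

CODING_STATUSES <- c("full_length_intact", "premature_stop", "frameshift",
                     "truncated_5prime", "fragment")
STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_dna <- function(x, what) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("non-DNA character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what))
  paste(chars, collapse = "")
}

#' Assess a transcript's coding status against a parent CDS
#'
#' Aligns the transcript to the parent CDS (global with free end gaps) and
#' reports, in order of precedence: `premature_stop` if an in-frame stop
#' codon precedes the parent's stop in the region upstream of any
#' frameshift; `frameshift` if any alignment indel has length not divisible
#' by 3; `truncated_5prime` if the alignment begins at least `trunc_codons`
#' codons into the parent; `fragment` if aligned parent coverage is below
#' `min_coverage`; otherwise `full_length_intact`. All detected lesions are
#' listed regardless of which one determines the status.
#'
#' Stops are sought on the "effective CDS" — the parent with the aligned
#' transcript region substituted in — scanning codons in the parent frame up
#' to the first frameshifting indel, so a stop downstream of a frameshift
#' (where the reading frame is already scrambled) is not reported.
#'
#' @param transcript_cds transcript nucleotide sequence (ACGTN).
#' @param parent_cds parent coding sequence; length must be divisible by 3
#'   and it must end in a stop codon.
#' @param trunc_codons codons of leading parent sequence whose absence calls
#'   a 5'-truncation (default 50, the length of the ancestral first coding
#'   exon).
#' @param min_coverage minimum aligned fraction of the parent below which the
#'   transcript is a fragment (default 0.5).
#' @return An object of class `coding_status`: list with `transcript_id`,
#'   `status`, `lesions` (data frame: `kind`, `coordinate` in parent-frame
#'   CDS bases, `detail`), `predicted_protein_length`, `coverage`.
#' @export
assess_transcript <- function(transcript_cds, parent_cds, trunc_codons = 50,
                              min_coverage = 0.5) {
  id <- if (is.data.frame(transcript_cds)) transcript_cds$id else ""
  if (is.data.frame(transcript_cds)) transcript_cds <- transcript_cds$sequence
  transcript_cds <- validate_dna(transcript_cds, "transcript_cds")
  parent_cds <- validate_dna(parent_cds, "parent_cds")
  if (nchar(parent_cds) %% 3 != 0)
    stop("parent_cds length must be divisible by 3")
  if (!substr(parent_cds, nchar(parent_cds) - 2, nchar(parent_cds)) %in%
      STOP_CODONS)
    stop("parent_cds must end in a stop codon")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(transcript_cds), Biostrings::DNAString(parent_cds),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 1)
  s_start <- Biostrings::start(Biostrings::subject(pa))
  s_end <- Biostrings::end(Biostrings::subject(pa))
  coverage <- (s_end - s_start + 1) / nchar(parent_cds)
  p_aln <- strsplit(as.character(Biostrings::pattern(pa)), "",
                    fixed = TRUE)[[1]]
  s_aln <- strsplit(as.character(Biostrings::subject(pa)), "",
                    fixed = TRUE)[[1]]

  # Effective CDS: parent prefix + aligned transcript bases + parent suffix.
  # Walk the alignment recording indel events at their effective coordinate.
  prefix <- if (s_start > 1) substr(parent_cds, 1, s_start - 1) else ""
  suffix <- if (s_end < nchar(parent_cds))
    substr(parent_cds, s_end + 1, nchar(parent_cds)) else ""
  eff <- strsplit(prefix, "", fixed = TRUE)[[1]]
  lesions <- list()
  first_fs_eff <- NA_integer_
  i <- 1L
  while (i <= length(p_aln)) {
    if (p_aln[i] != "-" && s_aln[i] != "-") {
      eff <- c(eff, p_aln[i])
      i <- i + 1L
    } else {
      gap_in <- if (p_aln[i] == "-") "deletion" else "insertion"
      len <- 0L
      at_eff <- length(eff) + 1L
      while (i <= length(p_aln) &&
             ((gap_in == "deletion" && p_aln[i] == "-") ||
              (gap_in == "insertion" && s_aln[i] == "-"))) {
        if (gap_in == "insertion") eff <- c(eff, p_aln[i])
        len <- len + 1L
        i <- i + 1L
      }
      if (len %% 3L != 0L) {
        lesions[[length(lesions) + 1L]] <- data.frame(
          kind = "frameshift", coordinate = at_eff,
          detail = sprintf("%s of %d nt (length mod 3 = %d)", gap_in, len,
                           len %% 3L),
          stringsAsFactors = FALSE)
        if (is.na(first_fs_eff)) first_fs_eff <- at_eff
      }
    }
  }
  eff <- c(eff, strsplit(suffix, "", fixed = TRUE)[[1]])
  eff_len <- length(eff)

  # In-frame stop scan (parent frame from base 1), stopping at the first
  # frameshift; the terminal codon position is the expected stop.
  n_codons <- eff_len %/% 3L
  terminal_codon_start <- 3L * (n_codons - 1L) + 1L
  scan_limit <- if (!is.na(first_fs_eff)) first_fs_eff - 1L else
    terminal_codon_start - 1L
  premature_at <- NA_integer_
  if (n_codons >= 1L) {
    for (c_idx in seq_len(n_codons)) {
      cs <- 3L * (c_idx - 1L) + 1L
      if (cs + 2L > scan_limit) break
      codon <- paste(eff[cs:(cs + 2L)], collapse = "")
      if (codon %in% STOP_CODONS) { premature_at <- cs; break }
    }
  }
  if (!is.na(premature_at))
    lesions <- c(list(data.frame(kind = "premature_stop",
                                 coordinate = premature_at,
                                 detail = paste(eff[premature_at:(premature_at + 2L)],
                                                collapse = ""),
                                 stringsAsFactors = FALSE)), lesions)
  truncated <- (s_start - 1L) >= trunc_codons * 3L
  if (truncated)
    lesions[[length(lesions) + 1L]] <- data.frame(
      kind = "truncated_5prime", coordinate = s_start,
      detail = sprintf("alignment starts %d nt (%d codons) into parent",
                       s_start - 1L, (s_start - 1L) %/% 3L),
      stringsAsFactors = FALSE)
  is_fragment <- coverage < min_coverage
  if (is_fragment)
    lesions[[length(lesions) + 1L]] <- data.frame(
      kind = "fragment", coordinate = s_start,
      detail = sprintf("aligned coverage %.1f%% of parent", 100 * coverage),
      stringsAsFactors = FALSE)

  status <- if (!is.na(premature_at)) "premature_stop"
  else if (!is.na(first_fs_eff)) "frameshift"
  else if (truncated) "truncated_5prime"
  else if (is_fragment) "fragment"
  else "full_length_intact"

  prot_len <- if (!is.na(premature_at)) (premature_at - 1L) %/% 3L
  else n_codons - 1L
  lesions <- if (length(lesions)) {
    out <- do.call(rbind, lesions); rownames(out) <- NULL; out
  } else data.frame(kind = character(0), coordinate = integer(0),
                    detail = character(0), stringsAsFactors = FALSE)
  out <- list(transcript_id = id, status = status, lesions = lesions,
              predicted_protein_length = prot_len, coverage = coverage)
  class(out) <- "coding_status"
  out
}

#' @export
print.coding_status <- function(x, ...) {
  cat(sprintf("Coding status%s: %s (coverage %.1f%%, predicted length %d aa)\n",
              if (nzchar(x$transcript_id)) paste0(" of ", x$transcript_id)
              else "", x$status, 100 * x$coverage,
              x$predicted_protein_length))
  if (nrow(x$lesions)) print(x$lesions, row.names = FALSE)
  invisible(x)
}

#' Combine lesion status and peptide evidence into a gene verdict
#'
#' A gene is a `pseudogene` when its transcript carries a disabling lesion
#' (premature stop, frameshift, or only fragmentary sequence). An intact
#' gene with at least one unique peptide is `coding`. An intact gene with no
#' unique peptides is `ambiguous` — unless a sibling paralogue's
#' variant-inclusive explained-observation fraction reaches
#' `comparative_threshold`, in which case essentially all evidence is
#' accounted for elsewhere and the verdict is `pseudogene`. A 5'-truncated
#' gene is a pseudogene unless unique peptides exist in its retained region.
#'
#' @param status a `coding_status` from [assess_transcript()], or one of the
#'   status strings.
#' @param n_unique number of peptides unique to this gene's protein.
#' @param n_captured number of peptides captured (shared or unique).
#' @param sibling_max_explained the largest variant-inclusive
#'   explained-observation fraction among the other paralogues (`NA` to skip
#'   the comparative rule).
#' @param comparative_threshold fraction at which a sibling is considered to
#'   explain essentially all observations (default 0.99).
#' @return One of `"coding"`, `"pseudogene"`, `"ambiguous"`.
#' @export
classify_gene <- function(status, n_unique, n_captured = n_unique,
                          sibling_max_explained = NA_real_,
                          comparative_threshold = 0.99) {
  st <- if (inherits(status, "coding_status")) status$status else status
  if (!st %in% CODING_STATUSES) stop("unknown coding status: ", st)
  if (st %in% c("premature_stop", "frameshift", "fragment"))
    return("pseudogene")
  if (st == "truncated_5prime")
    return(if (n_unique >= 1) "coding" else "pseudogene")
  # full_length_intact
  if (n_unique >= 1) return("coding")
  if (!is.na(sibling_max_explained) &&
      sibling_max_explained >= comparative_threshold)
    return("pseudogene")
  "ambiguous"
}
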