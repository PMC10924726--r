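#' @keywords internal
"_PACKAGE"

# Residue alphabets used throughout. 'X' (unknown residue) is tolerated in
# sequences but, by design, a peptide or window containing 'X' never matches
# anything.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_X <- c(AA_STANDARD, "X")
GAP_CHARS <- c("-", ".")
PROTEIN_SOURCES <- c("GRCh38", "CHM13", "UniProt", "RefSeq", "GenBank",
                     "synthetic")

#' Construct a protein record collection
#'
#' A protein set is the package's core container for paralogue and orthologue
#' sequences: a data frame with columns `id`, `description`, `sequence` and
#' `source`. Sequences are uppercased, a terminal `*` (stop) is stripped, and
#' residues are restricted to the 20 standard amino acids plus `X`.
#'
#' @param id character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences.
#' @param description free-text descriptions (recycled).
#' @param source provenance tag, one of `"GRCh38"`, `"CHM13"`, `"UniProt"`,
#'   `"RefSeq"`, `"GenBank"`, `"synthetic"` (recycled).
#' @return A `data.frame` of class `protein_set`.
#' @examples
#' protein_set(c("P1", "P2"), c("MKAAR", "MKAGR"))
#' @export
protein_set <- function(id, sequence, description = "", source = "synthetic") {
  stopifnot(length(id) == length(sequence))
  source <- rep_len(source, length(id))
  description <- rep_len(description, length(id))
  sequence <- toupper(sequence)
  sequence <- sub("\\*$", "", sequence)
  df <- data.frame(id = as.character(id),
                   description = as.character(description),
                   sequence = sequence,
                   source = source,
                   stringsAsFactors = FALSE)
  validate_protein_set(df)
  class(df) <- c("protein_set", "data.frame")
  df
}

validate_protein_set <- function(df) {
  if (anyDuplicated(df$id))
    stop("duplicate protein id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!nzchar(df$sequence)))
    stop("empty sequence for record(s): ",
         paste(df$id[!nzchar(df$sequence)], collapse = ", "))
  bad_src <- setdiff(unique(df$source), PROTEIN_SOURCES)
  if (length(bad_src))
    stop("unknown source tag(s): ", paste(bad_src, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    chars <- strsplit(df$sequence[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% AA_ALPHABET_X)
    if (length(bad))
      stop(sprintf("illegal residue '%s' at position %d in record '%s'",
                   chars[bad[1]], bad[1], df$id[i]))
  }
  invisible(df)
}

#' Read protein sequences from FASTA
#'
#' One record per FASTA entry. Sequences are uppercased and a terminal stop
#' (`*`) is removed; the record id is the first whitespace-delimited token of
#' the header, the remainder becomes the description. Duplicate ids and
#' residues outside the 20 standard amino acids plus `X` are errors.
#'
#' @param path path to a FASTA file.
#' @param source provenance tag applied to all records.
#' @return A [protein_set].
#' @export
read_protein_fasta <- function(path, source = "synthetic") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("malformed FASTA: no records in ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected '>' header", nonblank[1]))
  headers <- character(0)
  seqs <- character(0)
  for (i in nonblank) {
    line <- trimws(lines[i])
    if (startsWith(line, ">")) {
      hdr <- trimws(substring(line, 2))
      if (!nzchar(hdr))
        stop(sprintf("malformed FASTA at line %d: empty header", i))
      headers <- c(headers, hdr)
      seqs <- c(seqs, "")
    } else {
      seqs[length(seqs)] <- paste0(seqs[length(seqs)], gsub("\\s", "", line))
    }
  }
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(id, seqs, description = desc, source = source)
}

#' Write a protein set to FASTA
#'
#' @param proteins a [protein_set].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path, width = 60) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$id, proteins$description),
                proteins$id)
  out <- character(0)
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    out <- c(out, paste0(">", hdr[i]),
             substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a peptide observation table
#'
#' Parses a TSV with header columns `peptide` and `n_obs` (and optionally
#' `samples`, a comma-separated list of free-text tags). Rows with identical
#' peptide strings are aggregated by summing `n_obs` and uniting their sample
#' tags, so the result is order-independent.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with columns `peptide`, `n_obs` and, when present in
#'   the input, `samples`, sorted by peptide.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("peptide", "n_obs")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("peptide table is missing required column(s): ",
         paste(missing, collapse = ", "))
  n_obs <- suppressWarnings(as.numeric(df$n_obs))
  if (nrow(df) && (anyNA(n_obs) || any(n_obs < 0) || any(n_obs != floor(n_obs))))
    stop("n_obs must be a non-negative integer count")
  df$n_obs <- as.integer(n_obs)
  df$peptide <- toupper(df$peptide)
  if (any(!nzchar(df$peptide))) stop("empty peptide string in table")
  peptide_table(df$peptide, df$n_obs,
                samples = if ("samples" %in% names(df)) df$samples else NULL)
}

#' Construct (and aggregate) a peptide observation table
#'
#' @param peptide character vector of peptide sequences.
#' @param n_obs non-negative integer observation counts.
#' @param samples optional character vector of comma-separated sample tags.
#' @return A `data.frame` sorted by peptide with duplicates aggregated.
#' @export
peptide_table <- function(peptide, n_obs, samples = NULL) {
  stopifnot(length(peptide) == length(n_obs))
  if (any(n_obs < 0)) stop("n_obs must be non-negative")
  if (!length(peptide)) {
    out <- data.frame(peptide = character(0), n_obs = integer(0),
                      stringsAsFactors = FALSE)
    if (!is.null(samples)) out$samples <- character(0)
    return(out)
  }
  agg_n <- tapply(as.integer(n_obs), peptide, sum)
  out <- data.frame(peptide = names(agg_n),
                    n_obs = as.integer(agg_n),
                    stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    agg_s <- tapply(samples, peptide, function(s) {
      tags <- unlist(strsplit(s[nzchar(s)], ",", fixed = TRUE))
      paste(sort(unique(trimws(tags))), collapse = ",")
    })
    out$samples <- as.character(agg_s[out$peptide])
  }
  out <- out[order(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a peptide observation table
#'
#' @param peptides data frame with columns `peptide`, `n_obs` (and optionally
#'   `samples`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  cols <- intersect(c("peptide", "n_obs", "samples"), names(peptides))
  utils::write.table(peptides[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clade map
#'
#' A clade map assigns each orthologue sequence id to the shallowest clade
#' level that contains it, one of `"primates"`, `"mammals"`, `"tetrapods"`,
#' `"vertebrates"` (nested in that order). The file is a two-column TSV with
#' header `id`, `level`.
#'
#' @param path path to the TSV file.
#' @return A named character vector mapping id to clade level.
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "level") %in% names(df)))
    stop("clade map needs columns 'id' and 'level'")
  bad <- setdiff(unique(df$level), CLADE_LEVELS)
  if (length(bad)) stop("unknown clade level(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$level, df$id)
}

#' Write a clade map
#' @param clades named character vector (id to clade level).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(clades, path) {
  utils::write.table(
    data.frame(id = names(clades), level = unname(clades)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- attribution report serialization -------------------------------------

REPORT_SCHEMA <- "paralogid-attribution/1"

#' Write an attribution report
#'
#' Emits a machine-readable JSON file (stable key order, versioned schema tag)
#' and, alongside it, a flat TSV of per-paralogue counts (same path with a
#' `.tsv` extension). [read_attribution_report()] on the JSON reproduces the
#' report exactly.
#'
#' @param report an `attribution_report` from [build_attribution()].
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_attribution_report <- function(report, path) {
  stopifnot(inherits(report, "attribution_report"))
  payload <- list(
    schema = REPORT_SCHEMA,
    total_peptides = report$total_peptides,
    total_obs = report$total_obs,
    per_paralogue = report$per_paralogue,
    capture_sets = report$capture_sets,
    unique_sets = report$unique_sets,
    unmapped = report$unmapped
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  utils::write.table(report$per_paralogue, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an attribution report written by [write_attribution_report()]
#'
#' @param path path to the JSON file.
#' @return An `attribution_report` object.
#' @export
read_attribution_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, REPORT_SCHEMA))
    stop("unrecognized report schema: ", payload$schema)
  pp <- as.data.frame(payload$per_paralogue, stringsAsFactors = FALSE)
  unmapped <- as.data.frame(payload$unmapped, stringsAsFactors = FALSE)
  if (!nrow(unmapped))
    unmapped <- data.frame(peptide = character(0), n_obs = integer(0))
  unmapped$n_obs <- as.integer(unmapped$n_obs)
  as_chr <- function(x) if (is.null(x)) character(0) else as.character(x)
  report <- list(
    per_paralogue = pp,
    capture_sets = lapply(payload$capture_sets, as_chr)[pp$protein_id],
    unique_sets = lapply(payload$unique_sets, as_chr)[pp$protein_id],
    unmapped = unmapped,
    total_peptides = as.integer(payload$total_peptides),
    total_obs = as.integer(payload$total_obs)
  )
  class(report) <- "attribution_report"
  report
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("Attribution report: %d peptides, %d observations, %d paralogues\n",
              x$total_peptides, x$total_obs, nrow(x$per_paralogue)))
  print(x$per_paralogue, row.names = FALSE)
  cat(sprintf("unmapped: %d peptides (%d observations)\n",
              nrow(x$unmapped), sum(x$unmapped$n_obs)))
  invisible(x)
}
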