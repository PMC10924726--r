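# Seeded generators for paralogue families, peptide-evidence tables,
# orthologue alignments and divergent DNA families, with ground truth, so
# every pipeline stage is testable without downloads.

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

CODON_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

random_codon_for <- function(aa) {
  opts <- CODON_OF[[aa]]
  opts[sample.int(length(opts), 1L)]
}

translate_to_stop <- function(cds) {
  n <- (nchar(cds) %/% 3L) * 3L
  if (n < 3L) return("X")
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"
  stop_at <- which(aas == "*")
  if (length(stop_at)) aas <- aas[seq_len(stop_at[1] - 1L)]
  if (!length(aas)) return("X")  # degenerate: immediate stop
  paste(aas, collapse = "")
}

#' Specification of a synthetic paralogue family
#'
#' The defaults emulate a subtelomeric duplication family at the scale of
#' the human WASH1 paralogues: five copies of a 450-residue ancestor, one
#' designated coding copy kept intact, the others accumulating single
#' amino acid variants, occasional short indels, premature stops (probability
#' 0.6) and 5'-truncations of 50 codons; one heterozygous protein-level
#' allele on the coding copy at frequency ~0.49; singleton contaminant
#' peptides; and heavy-tailed log-normal observation counts spanning single
#' digits to thousands.
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_paralogues number of family members (default 5).
#' @param length ancestral protein length in residues (default 450).
#' @param saav_rate per-residue substitution probability per derived copy.
#' @param indel_mean expected number of short nucleotide indels per derived
#'   copy (lengths 1-6 nt, frameshifting when not a multiple of 3).
#' @param stop_prob probability a derived copy gains a premature stop.
#' @param trunc_prob probability a derived copy loses its 5' end.
#' @param trunc_codons truncation length in codons (default 50).
#' @param coding_index index of the designated coding copy.
#' @param het_freq population frequency of the alternate allele of the
#'   planted heterozygous variant on the coding copy (default 16/33).
#' @param n_contaminants number of random singleton contaminant peptides.
#' @param obs_meanlog,obs_sdlog log-normal observation-count parameters.
#' @param min_len,max_len tryptic peptide length window for the evidence
#'   table.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(seed = 1L, n_paralogues = 5L, length = 450L,
                        saav_rate = 0.01, indel_mean = 0.7, stop_prob = 0.6,
                        trunc_prob = 0.2, trunc_codons = 50L,
                        coding_index = 1L, het_freq = 16 / 33,
                        n_contaminants = 5L, obs_meanlog = 3.0,
                        obs_sdlog = 1.6, min_len = 7L, max_len = 50L) {
  stopifnot(n_paralogues >= 2L, length >= 30L,
            saav_rate >= 0, saav_rate <= 1,
            stop_prob >= 0, stop_prob <= 1,
            trunc_prob >= 0, trunc_prob <= 1,
            het_freq >= 0, het_freq <= 1,
            coding_index >= 1L, coding_index <= n_paralogues)
  spec <- list(seed = as.integer(seed), n_paralogues = as.integer(n_paralogues),
               length = as.integer(length), saav_rate = saav_rate,
               indel_mean = indel_mean, stop_prob = stop_prob,
               trunc_prob = trunc_prob, trunc_codons = as.integer(trunc_codons),
               coding_index = as.integer(coding_index), het_freq = het_freq,
               n_contaminants = as.integer(n_contaminants),
               obs_meanlog = obs_meanlog, obs_sdlog = obs_sdlog,
               min_len = as.integer(min_len), max_len = as.integer(max_len))
  class(spec) <- "family_spec"
  spec
}

#' Simulate a paralogue family with known ground truth
#'
#' Generates an ancestral CDS and derives the family: the designated coding
#' copy is kept intact while every other copy is mutated with sampled SAAVs,
#' indels, premature stops and 5'-truncations. Each copy's emitted protein is
#' the producible product of its CDS (translation to the first in-frame
#' stop), which models what a proteomics search database would hold for a
#' damaged copy. A heterozygous protein allele (at a residue where neither
#' allele touches K/R/P, so tryptic behaviour is unchanged) is planted on
#' the coding copy.
#'
#' @param spec a [family_spec()].
#' @return A list with `proteins` (a [protein_set]), `cds` (named character
#'   vector of nucleotide sequences), and `truth` (class `synthetic_truth`):
#'   `coding_id`, per-copy `lesions`, and the planted `het` allele
#'   (`position`, `ref`, `alt`, `freq`, given in coding-protein residue
#'   coordinates).
#' @export
simulate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    anc_aa <- c("M", sample(AA_STANDARD, spec$length - 1L, replace = TRUE))
    anc_codons <- vapply(anc_aa, random_codon_for, character(1))
    ids <- sprintf("PAR%02d", seq_len(spec$n_paralogues))
    coding_id <- ids[spec$coding_index]
    cds <- character(spec$n_paralogues)
    lesions <- vector("list", spec$n_paralogues)
    names(lesions) <- ids
    for (i in seq_len(spec$n_paralogues)) {
      les <- list()
      codons <- anc_codons
      if (i != spec$coding_index) {
        hit <- which(stats::runif(spec$length) < spec$saav_rate)
        hit <- hit[hit > 1L]  # keep the initiator methionine
        for (p in hit) {
          alt <- sample(setdiff(AA_STANDARD, anc_aa[p]), 1L)
          codons[p] <- random_codon_for(alt)
          les[[length(les) + 1L]] <- data.frame(
            kind = "saav", position = p,
            detail = paste0(anc_aa[p], p, alt), stringsAsFactors = FALSE)
        }
        if (stats::runif(1) < spec$stop_prob) {
          j <- sample(seq(max(2L, round(0.2 * spec$length)),
                          round(0.8 * spec$length)), 1L)
          codons[j] <- "TAA"
          les[[length(les) + 1L]] <- data.frame(
            kind = "premature_stop", position = j,
            detail = sprintf("codon %d -> TAA", j), stringsAsFactors = FALSE)
        }
      }
      nt <- paste(c(codons, "TAA"), collapse = "")
      if (i != spec$coding_index) {
        if (stats::runif(1) < spec$trunc_prob) {
          nt <- substr(nt, spec$trunc_codons * 3L + 1L, nchar(nt))
          les[[length(les) + 1L]] <- data.frame(
            kind = "truncated_5prime", position = 1L,
            detail = sprintf("first %d codons removed", spec$trunc_codons),
            stringsAsFactors = FALSE)
        }
        n_ind <- stats::rpois(1, spec$indel_mean)
        for (k in seq_len(n_ind)) {
          len <- sample(1:6, 1L)
          if (stats::runif(1) < 0.5 && nchar(nt) > len + 6L) {
            pos <- sample(seq(4L, nchar(nt) - len - 3L), 1L)
            nt <- paste0(substr(nt, 1L, pos - 1L),
                         substr(nt, pos + len, nchar(nt)))
            kind <- "deletion"
          } else {
            pos <- sample(seq(4L, nchar(nt) - 3L), 1L)
            ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
            nt <- paste0(substr(nt, 1L, pos - 1L), ins,
                         substr(nt, pos, nchar(nt)))
            kind <- "insertion"
          }
          les[[length(les) + 1L]] <- data.frame(
            kind = kind, position = pos,
            detail = sprintf("%d nt%s", len,
                             if (len %% 3L != 0L) " (frameshift)" else ""),
            stringsAsFactors = FALSE)
        }
      }
      cds[i] <- nt
      lesions[[i]] <- if (length(les)) do.call(rbind, les) else
        data.frame(kind = character(0), position = integer(0),
                   detail = character(0), stringsAsFactors = FALSE)
    }
    names(cds) <- ids
    prots <- vapply(cds, translate_to_stop, character(1))
    coding_prot <- prots[[coding_id]]
    # plant the heterozygous allele: ref and alt away from K/R/P so the
    # tryptic pattern is identical on both alleles
    cand <- which(!(strsplit(coding_prot, "")[[1]] %in% c("K", "R", "P")))
    cand <- cand[cand > 1L & cand < nchar(coding_prot)]
    het_pos <- sample(cand, 1L)
    het_ref <- substr(coding_prot, het_pos, het_pos)
    het_alt <- sample(setdiff(AA_STANDARD, c("K", "R", "P", het_ref)), 1L)
    truth <- list(coding_id = coding_id, lesions = lesions,
                  het = list(position = het_pos, ref = het_ref,
                             alt = het_alt, freq = spec$het_freq))
    class(truth) <- "synthetic_truth"
    list(proteins = protein_set(ids, prots, source = "synthetic"),
         cds = cds, truth = truth)
  })
}

#' Simulate a peptide-evidence table for a synthetic family
#'
#' Enumerates the coding copy's fully tryptic peptides (0-2 missed
#' cleavages, length window from the spec), samples observation counts from
#' the heavy-tailed log-normal model, splits peptides overlapping the planted
#' heterozygous position into reference/alternate versions by binomial
#' sampling at the allele frequency, and appends random singleton contaminant
#' peptides (which the default evidence filter removes). Every row is
#' labelled with its source.
#'
#' @param family output of [simulate_family()].
#' @param spec the same [family_spec()].
#' @return A `data.frame` with columns `peptide`, `n_obs`, `source`
#'   (`"coding"`, `"variant-allele"` or `"contaminant"`), aggregated over
#'   identical peptides.
#' @export
simulate_peptide_table <- function(family, spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  truth <- family$truth
  coding <- family$proteins[family$proteins$id == truth$coding_id, ]
  with_seed(spec$seed + 1L, {
    dig <- enumerate_tryptic_peptides(coding, max_missed = 2,
                                      min_len = spec$min_len,
                                      max_len = spec$max_len)
    dig <- dig[!duplicated(dig$peptide), , drop = FALSE]
    n_obs <- as.integer(round(stats::rlnorm(nrow(dig), spec$obs_meanlog,
                                            spec$obs_sdlog)))
    rows <- list()
    het <- truth$het
    for (k in seq_len(nrow(dig))) {
      if (n_obs[k] <= 0L) next
      covers <- dig$start[k] <= het$position & dig$end[k] >= het$position
      if (covers) {
        n_alt <- stats::rbinom(1L, n_obs[k], het$freq)
        off <- het$position - dig$start[k] + 1L
        alt_pep <- dig$peptide[k]
        substr(alt_pep, off, off) <- het$alt
        if (n_obs[k] - n_alt > 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = dig$peptide[k], n_obs = n_obs[k] - n_alt,
            source = "coding", stringsAsFactors = FALSE)
        if (n_alt > 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = alt_pep, n_obs = n_alt, source = "variant-allele",
            stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = dig$peptide[k], n_obs = n_obs[k], source = "coding",
          stringsAsFactors = FALSE)
      }
    }
    seqs <- family$proteins$sequence
    for (k in seq_len(spec$n_contaminants)) {
      repeat {
        len <- sample(8:15, 1L)
        pep <- paste(c(sample(setdiff(AA_STANDARD, c("K", "R")), len - 1L,
                              replace = TRUE),
                       sample(c("K", "R"), 1L)), collapse = "")
        if (!any(vapply(seqs, function(s) grepl(pep, s, fixed = TRUE),
                        logical(1)))) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, n_obs = 1L, source = "contaminant",
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    # aggregate identical peptides (ref/alt collisions are impossible by
    # construction, but contaminants are defensive-aggregated like real input)
    agg <- peptide_table(out$peptide, out$n_obs)
    src <- tapply(out$source, out$peptide, function(s)
      paste(sort(unique(s)), collapse = "+"))
    agg$source <- as.character(src[agg$peptide])
    agg
  })
}

#' Simulate an orthologue alignment with planted conserved columns
#'
#' Generates a gap-free protein alignment with rows at each nested clade
#' level. Each column is either non-conserved (the primate rows already
#' disagree) or conserved to a planted depth: rows within the planted clade
#' all carry the consensus residue and at least one row at the next deeper
#' level differs, so strict conservation scoring recovers the planted truth
#' exactly.
#'
#' @param clade_sizes named integer vector of row counts per level; the
#'   default (6 primates, 8 mammals, 7 tetrapods, 6 vertebrates) gives a
#'   27-row panel.
#' @param n_columns alignment width (default 450).
#' @param conserved_fraction fraction of columns that are conserved at some
#'   depth.
#' @param seed integer seed.
#' @param depth_weights sampling weights for the planted depth of conserved
#'   columns (shallowest first).
#' @return A list with `msa` (named character vector), `clades` (named level
#'   map), `reference_id` (the first primate row), and `truth` (list with
#'   per-column `depth` (0 = not conserved) and `consensus`).
#' @export
simulate_orthologue_msa <- function(clade_sizes = c(primates = 6, mammals = 8,
                                                    tetrapods = 7,
                                                    vertebrates = 6),
                                    n_columns = 450, conserved_fraction = 0.7,
                                    seed = 1L,
                                    depth_weights = c(0.35, 0.3, 0.2, 0.15)) {
  stopifnot(identical(names(clade_sizes), CLADE_LEVELS),
            all(clade_sizes >= 1), clade_sizes[["primates"]] >= 2,
            conserved_fraction >= 0, conserved_fraction <= 1)
  with_seed(seed, {
    lev_of_row <- rep(seq_along(CLADE_LEVELS), times = clade_sizes)
    ids <- unlist(lapply(seq_along(CLADE_LEVELS), function(k)
      sprintf("%s_%02d", CLADE_LEVELS[k], seq_len(clade_sizes[k]))))
    n_rows <- length(ids)
    m <- matrix("", nrow = n_rows, ncol = n_columns)
    depth <- integer(n_columns)
    consensus <- rep(NA_character_, n_columns)
    for (j in seq_len(n_columns)) {
      if (stats::runif(1) < conserved_fraction) {
        D <- sample.int(4L, 1L, prob = depth_weights)
        cons <- sample(AA_STANDARD, 1L)
        depth[j] <- D
        consensus[j] <- cons
        m[lev_of_row <= D, j] <- cons
        if (D < 4L) {
          deeper <- which(lev_of_row == D + 1L)
          m[deeper[1], j] <- sample(setdiff(AA_STANDARD, cons), 1L)
          rest <- c(deeper[-1], which(lev_of_row > D + 1L))
          if (length(rest))
            m[rest, j] <- sample(AA_STANDARD, length(rest), replace = TRUE)
        }
      } else {
        prim <- which(lev_of_row == 1L)
        a <- sample(AA_STANDARD, 1L)
        b <- sample(setdiff(AA_STANDARD, a), 1L)
        m[prim[1], j] <- a
        m[prim[2], j] <- b
        rest <- setdiff(seq_len(n_rows), prim[1:2])
        m[rest, j] <- sample(AA_STANDARD, length(rest), replace = TRUE)
      }
    }
    msa <- stats::setNames(apply(m, 1, paste, collapse = ""), ids)
    clades <- stats::setNames(CLADE_LEVELS[lev_of_row], ids)
    list(msa = msa, clades = clades, reference_id = ids[1],
         truth = list(depth = depth, consensus = consensus))
  })
}

#' Plant SAAVs on the reference row of a simulated orthologue alignment
#'
#' Builds a synthetic paralogue: the reference row with `n_saavs`
#' substitutions at conserved columns, returning both the sequence and the
#' planted truth for exact-recovery testing of
#' [profile_paralogue_variants()].
#'
#' @param sim output of [simulate_orthologue_msa()].
#' @param n_saavs number of substitutions to plant.
#' @param seed integer seed.
#' @return A list with `sequence` (the mutated paralogue) and `planted`
#'   (data frame: `column`, `ref_residue`, `alt_residue`, `depth`).
#' @export
plant_paralogue_saavs <- function(sim, n_saavs = 5, seed = 1L) {
  with_seed(seed, {
    ref <- strsplit(sim$msa[[sim$reference_id]], "", fixed = TRUE)[[1]]
    cols <- which(sim$truth$depth >= 1L)
    stopifnot(length(cols) >= n_saavs)
    pick <- sort(sample(cols, n_saavs))
    planted <- data.frame(column = pick,
                          ref_residue = sim$truth$consensus[pick],
                          alt_residue = NA_character_,
                          depth = sim$truth$depth[pick],
                          stringsAsFactors = FALSE)
    for (r in seq_len(n_saavs)) {
      alt <- sample(setdiff(AA_STANDARD, planted$ref_residue[r]), 1L)
      planted$alt_residue[r] <- alt
      ref[pick[r]] <- alt
    }
    list(sequence = paste(ref, collapse = ""), planted = planted)
  })
}

#' Simulate a DNA family with an already-diverged paralogue ancestor
#'
#' Emulates the scenario where derived paralogues duplicated from an
#' ancestor that had already drifted away from the coding gene: species
#' orthologues and the coding copy sit close to the root, while the derived
#' copies share a long internal branch. Substitution-only evolution keeps
#' the sequences aligned.
#'
#' @param seed integer seed.
#' @param n_sites alignment length in nucleotides.
#' @param n_derived number of derived paralogue copies.
#' @param n_species number of species orthologues (the first is the
#'   designated outgroup).
#' @param species_rate,coding_rate,derived_anc_rate,derived_tip_rate
#'   per-site substitution probabilities on the respective branches.
#' @return A list with `seqs` (named aligned DNA vector), `coding_id`,
#'   `derived_ids`, `species_ids`, `outgroup`.
#' @export
simulate_divergent_family_dna <- function(seed = 1L, n_sites = 900,
                                          n_derived = 4, n_species = 3,
                                          species_rate = 0.04,
                                          coding_rate = 0.03,
                                          derived_anc_rate = 0.12,
                                          derived_tip_rate = 0.02) {
  acgt <- c("A", "C", "G", "T")
  mutate <- function(x, rate) {
    hit <- which(stats::runif(length(x)) < rate)
    for (p in hit) x[p] <- sample(setdiff(acgt, x[p]), 1L)
    x
  }
  with_seed(seed, {
    anc <- sample(acgt, n_sites, replace = TRUE)
    human_anc <- mutate(anc, coding_rate / 2)
    coding <- mutate(human_anc, coding_rate / 2)
    derived_anc <- mutate(human_anc, derived_anc_rate)
    derived <- lapply(seq_len(n_derived), function(i)
      mutate(derived_anc, derived_tip_rate))
    species <- lapply(seq_len(n_species), function(i)
      mutate(anc, species_rate))
    ids <- c("coding", sprintf("derived_%02d", seq_len(n_derived)),
             sprintf("species_%02d", seq_len(n_species)))
    seqs <- stats::setNames(vapply(c(list(coding), derived, species),
                                   paste, character(1), collapse = ""), ids)
    list(seqs = seqs, coding_id = "coding",
         derived_ids = sprintf("derived_%02d", seq_len(n_derived)),
         species_ids = sprintf("species_%02d", seq_len(n_species)),
         outgroup = "species_01")
  })
}

#' Simulate a haplotype panel around a planted protein allele
#'
#' Builds an aligned panel of protein haplotypes: every sequence equals the
#' coding protein except at the planted heterozygous position, where
#' alternate-allele haplotypes carry the alternate residue in proportion to
#' the allele frequency (rounded).
#'
#' @param family output of [simulate_family()].
#' @param n_haplotypes panel size (default 33).
#' @return A list with `panel` (named character vector of aligned sequences)
#'   and `n_alt` (number of alternate-allele haplotypes).
#' @export
simulate_haplotype_panel <- function(family, n_haplotypes = 33) {
  truth <- family$truth
  coding <- family$proteins$sequence[family$proteins$id == truth$coding_id]
  n_alt <- round(n_haplotypes * truth$het$freq)
  panel <- rep(coding, n_haplotypes)
  for (i in seq_len(n_alt))
    substr(panel[i], truth$het$position, truth$het$position) <- truth$het$alt
  names(panel) <- sprintf("hap_%02d", seq_len(n_haplotypes))
  list(panel = panel, n_alt = n_alt)
}
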