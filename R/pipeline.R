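# End-to-end orchestration: filter -> map -> attribute -> rescue ->
# (optional) conservation profile -> (optional) coding status -> verdicts,
# with a manifest and per-stage logging.

#' Pipeline configuration
#'
#' Collects input paths and thresholds for [run_attribution_pipeline()].
#' Round-trips through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param proteins path to the paralogue protein FASTA.
#' @param peptides path to the peptide evidence TSV.
#' @param msa optional aligned orthologue FASTA (conservation stage).
#' @param clade_map optional clade-map TSV (conservation stage).
#' @param reference_id optional id of the reference row in `msa`; defaults
#'   to its first row.
#' @param cds optional transcript CDS FASTA (coding-status stage).
#' @param parent_cds optional path to the parent CDS FASTA (single record).
#' @param haplotype_panel optional aligned FASTA of protein haplotypes.
#' @param min_obs,max_missed evidence filters (defaults 2 and 2).
#' @param proline_rule,il_equivalent tryptic matching switches.
#' @param rescue run single-substitution variant rescue (default `TRUE`).
#' @param min_fraction conservation strictness (default 1.0).
#' @param comparative_threshold sibling explained-observation fraction at
#'   which an intact, unsupported paralogue is called a pseudogene (default
#'   0.99).
#' @param trunc_codons 5'-truncation threshold in codons (default 50).
#' @param seed integer seed recorded in the manifest (used by the simulate
#'   subcommand of the CLI).
#' @param out_dir output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, peptides, msa = NULL, clade_map = NULL,
                            reference_id = NULL, cds = NULL,
                            parent_cds = NULL, haplotype_panel = NULL,
                            min_obs = 2, max_missed = 2, proline_rule = TRUE,
                            il_equivalent = FALSE, rescue = TRUE,
                            min_fraction = 1.0, comparative_threshold = 0.99,
                            trunc_codons = 50, seed = NULL,
                            out_dir = tempfile("paralogid_run_")) {
  stopifnot(min_obs >= 0, max_missed >= 0,
            min_fraction > 0, min_fraction <= 1,
            comparative_threshold > 0, comparative_threshold <= 1)
  cfg <- list(proteins = proteins, peptides = peptides, msa = msa,
              clade_map = clade_map, reference_id = reference_id, cds = cds,
              parent_cds = parent_cds, haplotype_panel = haplotype_panel,
              min_obs = min_obs, max_missed = max_missed,
              proline_rule = proline_rule, il_equivalent = il_equivalent,
              rescue = rescue, min_fraction = min_fraction,
              comparative_threshold = comparative_threshold,
              trunc_codons = trunc_codons, seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))], path)
  invisible(path)
}

#' Run the paralogue-arbitration pipeline
#'
#' Executes filter, mapping, attribution, variant rescue and, when inputs
#' are configured, conservation profiling and coding-status assessment, then
#' combines them into per-gene verdicts. All artifacts are written under
#' `config$out_dir` together with a manifest recording the configuration
#' (and its md5), package version and per-stage counts.
#'
#' The per-paralogue table gains variant-inclusive columns: `variant_obs`
#' (observations of unmapped peptides explained as single-substitution
#' variants of that paralogue) and `variant_explained_fraction`. Verdicts
#' use the comparative rule: an intact paralogue with no unique peptides is
#' called a pseudogene when a sibling's variant-inclusive fraction reaches
#' `comparative_threshold`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `pipeline_result`: list with `report`,
#'   `profiles`, `statuses`, `verdicts`, `paths`. Invisibly.
#' @export
run_attribution_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    say("%s", line)
  }

  proteins <- if (is.data.frame(config$proteins)) config$proteins else
    read_protein_fasta(config$proteins)
  peptides <- if (is.data.frame(config$peptides)) config$peptides else
    read_peptide_table(config$peptides)
  log("inputs: %d proteins, %d peptides (%d observations)",
      nrow(proteins), nrow(peptides), sum(peptides$n_obs))

  filtered <- filter_peptide_table(peptides, min_obs = config$min_obs,
                                   max_missed = config$max_missed,
                                   proline_rule = config$proline_rule)
  log("filtered: %d peptides (%d observations) pass min_obs >= %d, missed <= %d",
      nrow(filtered), sum(filtered$n_obs), config$min_obs, config$max_missed)
  if (!nrow(filtered))
    warning("empty filtered peptide set; report will be zeroed")

  report <- build_attribution(filtered, proteins,
                              max_missed = config$max_missed,
                              proline_rule = config$proline_rule,
                              il_equivalent = config$il_equivalent)
  log("attribution: top-ranked %s (explained fraction %.4f), %d unmapped peptides",
      report$per_paralogue$protein_id[1],
      report$per_paralogue$explained_fraction[1], nrow(report$unmapped))

  rescues <- NULL
  pp <- report$per_paralogue
  pp$variant_obs <- 0L
  pp$variant_explained_fraction <- pp$explained_fraction
  if (isTRUE(config$rescue) && nrow(report$unmapped)) {
    rescues <- stats::setNames(vector("list", nrow(proteins)), proteins$id)
    for (id in proteins$id) {
      res <- explain_unmapped(report$unmapped,
                              proteins[proteins$id == id, ],
                              evidence = filtered,
                              max_missed = config$max_missed,
                              proline_rule = config$proline_rule)
      rescues[[id]] <- res
      k <- which(pp$protein_id == id)
      pp$variant_obs[k] <- as.integer(res$variant_obs)
      pp$variant_explained_fraction[k] <-
        if (report$total_obs > 0)
          (pp$captured_obs[k] + res$variant_obs) / report$total_obs else 0
    }
    log("rescue: variant-inclusive fraction of top paralogue %.4f",
        pp$variant_explained_fraction[pp$protein_id ==
                                        report$per_paralogue$protein_id[1]])
  }
  report$per_paralogue <- pp

  profiles <- NULL
  if (!is.null(config$msa) && !is.null(config$clade_map)) {
    msa_set <- Biostrings::readAAStringSet(config$msa)
    msa <- stats::setNames(as.character(msa_set),
                           sub("\\s.*$", "", names(msa_set)))
    clades <- read_clade_map(config$clade_map)
    ref_id <- if (!is.null(config$reference_id)) config$reference_id else
      names(msa)[1]
    conserved <- conserved_columns(msa, clades,
                                   min_fraction = config$min_fraction)
    profiles <- lapply(seq_len(nrow(proteins)), function(i)
      profile_paralogue_variants(proteins[i, ], msa[[ref_id]], conserved))
    names(profiles) <- proteins$id
    log("conservation: %d columns conserved at any depth",
        sum(conserved$depth >= 1))
  }

  statuses <- NULL
  verdicts <- NULL
  if (!is.null(config$cds) && !is.null(config$parent_cds)) {
    cds_set <- if (is.character(config$cds) && length(config$cds) == 1 &&
                   file.exists(config$cds)) {
      s <- Biostrings::readDNAStringSet(config$cds)
      stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
    } else config$cds
    parent <- if (is.character(config$parent_cds) &&
                  length(config$parent_cds) == 1 &&
                  file.exists(config$parent_cds)) {
      s <- Biostrings::readDNAStringSet(config$parent_cds)
      as.character(s)[[1]]
    } else config$parent_cds
    statuses <- lapply(names(cds_set), function(id) {
      st <- assess_transcript(cds_set[[id]], parent,
                              trunc_codons = config$trunc_codons)
      st$transcript_id <- id
      st
    })
    names(statuses) <- names(cds_set)
    verdicts <- data.frame(gene_id = names(statuses),
                           status = vapply(statuses, `[[`, character(1),
                                           "status"),
                           n_unique = NA_integer_, verdict = NA_character_,
                           stringsAsFactors = FALSE)
    for (i in seq_len(nrow(verdicts))) {
      id <- verdicts$gene_id[i]
      k <- which(pp$protein_id == id)
      n_uni <- if (length(k)) pp$n_unique[k] else 0L
      n_cap <- if (length(k)) pp$n_captured[k] else 0L
      # a sibling only counts as "explaining the evidence" if it is itself
      # distinguishable (has unique support); otherwise mutually shadowing
      # twins would argue each other into pseudogene status
      sibling <- pp$variant_explained_fraction[pp$protein_id != id &
                                                 pp$n_unique >= 1L]
      verdicts$n_unique[i] <- n_uni
      verdicts$verdict[i] <- classify_gene(
        statuses[[id]], n_uni, n_cap,
        sibling_max_explained = if (length(sibling)) max(sibling) else
          NA_real_,
        comparative_threshold = config$comparative_threshold)
    }
    log("verdicts: %s", paste(sprintf("%s=%s", verdicts$gene_id,
                                      verdicts$verdict), collapse = ", "))
    rownames(verdicts) <- NULL
  }

  paths <- list(report = file.path(config$out_dir, "attribution.json"),
                verdicts = file.path(config$out_dir, "verdicts.tsv"),
                config = file.path(config$out_dir, "config.yaml"),
                manifest = file.path(config$out_dir, "manifest.json"),
                log = file.path(config$out_dir, "run.log"))
  write_attribution_report(report, paths$report)
  if (!is.null(verdicts))
    utils::write.table(verdicts, paths$verdicts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cfg_for_file <- config
  cfg_for_file$proteins <- if (is.data.frame(config$proteins))
    "<in-memory>" else config$proteins
  cfg_for_file$peptides <- if (is.data.frame(config$peptides))
    "<in-memory>" else config$peptides
  write_pipeline_config(cfg_for_file, paths$config)
  manifest <- list(
    package = "paralogid",
    version = as.character(utils::packageVersion("paralogid")),
    config_md5 = unname(tools::md5sum(paths$config)),
    seed = config$seed,
    n_proteins = nrow(proteins),
    n_peptides_in = nrow(peptides),
    n_peptides_filtered = nrow(filtered),
    total_obs = report$total_obs,
    top_ranked = report$per_paralogue$protein_id[1])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeLines(log_lines, paths$log)

  out <- list(report = report, rescues = rescues, profiles = profiles,
              statuses = statuses, verdicts = verdicts, paths = paths)
  class(out) <- "pipeline_result"
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  if (!is.null(x$verdicts)) {
    cat("\nVerdicts:\n")
    print(x$verdicts, row.names = FALSE)
  }
  invisible(x)
}
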