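test_that("single-substitution rescue finds the variant window", {
  prot <- protein_set("W", "MKQDDGSSSASPSVQGAPRLL")
  ex <- rescue_single_substitution("QDDSSSSASPSVQGAPR", prot)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$ref_residue, "G")
  expect_equal(ex$obs_residue, "S")
  expect_equal(ex$protein_position, 6L)  # 4th residue of the window at 3

  # two mismatches from every window: nothing to rescue
  expect_equal(nrow(rescue_single_substitution("QDDSSSSASPSVQGAWC", prot)), 0L)

  # exact match is a precondition error
  expect_error(rescue_single_substitution("QDDGSSSASPSVQGAPR", prot),
               "exact")
})

test_that("rescue re-evaluates tryptic context on the substituted sequence", {
  # protein window AAAAAA with peptide AAKAAA: the A->K substitution creates
  # a cleavage site inside the window, breaking the C-boundary requirement
  # (K interior) -- but here it also adds an internal missed cleavage; build
  # a case with already 2 internal K/R so the extra site pushes it over
  prot <- protein_set("P", "MKAAKAAKAAADLR")
  # peptide matching window 3..14 with one substitution A->R at position 11
  pep <- "AAKAAKAARDLR"
  ex <- rescue_single_substitution(pep, prot)
  expect_equal(nrow(ex), 0L)  # 3 internal cleavage sites after substitution

  # same window with a harmless substitution is rescued
  ok <- rescue_single_substitution("AAKAAKAAWDLR", prot)
  expect_equal(ok$protein_position, 11L)
  expect_equal(ok$obs_residue, "W")
})

test_that("rescue never returns a window identical to the peptide", {
  set.seed(11)
  for (i in 1:25) {
    seq <- random_protein(60)
    prot <- protein_set("P", seq)
    dig <- enumerate_tryptic_peptides(prot, min_len = 6, max_len = 20)
    if (!nrow(dig)) next
    pep <- dig$peptide[1]
    sub <- pep
    pos <- sample(nchar(pep) - 1, 1)
    old <- substr(sub, pos, pos)
    new <- sample(setdiff(c("A", "D", "F", "W"), old), 1)
    substr(sub, pos, pos) <- new
    if (grepl(sub, seq, fixed = TRUE)) next
    if (nrow(map_peptide(sub, prot))) next
    ex <- rescue_single_substitution(sub, prot)
    if (nrow(ex)) {
      for (j in seq_len(nrow(ex)))
        expect_false(ex$ref_residue[j] == ex$obs_residue[j])
    }
  }
})

test_that("haplotype allele summaries count residues and gaps", {
  panel <- c(a = "MGA", b = "MSA", c = "MGA")
  ac <- summarize_haplotype_alleles(panel, 2)
  expect_equal(ac$counts, c(G = 2L, S = 1L))
  expect_equal(ac$n_gaps, 0L)

  same <- summarize_haplotype_alleles(rep("MAA", 5), 3)
  expect_equal(same$counts, c(A = 5L))

  gappy <- summarize_haplotype_alleles(c("M-A", "M-A"), 2)
  expect_equal(length(gappy$counts), 0L)
  expect_equal(gappy$n_gaps, 2L)

  expect_error(summarize_haplotype_alleles(c("MA", "MAA"), 1), "ragged")
  expect_error(summarize_haplotype_alleles(panel, 9), "range")
})

test_that("a simulated 33-haplotype panel reproduces the planted allele split", {
  spec <- family_spec(seed = 202)
  fam <- simulate_family(spec)
  hp <- simulate_haplotype_panel(fam, n_haplotypes = 33)
  ac <- summarize_haplotype_alleles(hp$panel, fam$truth$het$position)
  expect_equal(sum(ac$counts), 33L)
  expect_equal(unname(ac$counts[fam$truth$het$alt]), hp$n_alt)
  expect_equal(unname(ac$counts[fam$truth$het$ref]), 33L - hp$n_alt)
  expect_equal(hp$n_alt, 16)  # round(33 * 16/33)
})

test_that("explain_unmapped partitions and corroborates variants", {
  prot <- protein_set("W", "MKQDDGSSSASPSVQGAPRLL")
  evidence <- peptide_table(c("QDDGSSSASPSVQGAPR", "QDDSSSSASPSVQGAPR"),
                            c(1999L, 1239L))
  unmapped <- data.frame(peptide = c("QDDSSSSASPSVQGAPR", "WWWWHHHHFFFF"),
                         n_obs = c(1239L, 3L))
  res <- explain_unmapped(unmapped, prot, evidence = evidence)
  expect_equal(res$explained$peptide, "QDDSSSSASPSVQGAPR")
  expect_equal(res$unexplained$peptide, "WWWWHHHHFFFF")
  expect_equal(res$variant_obs, 1239L)
  expect_equal(res$explanations$supporting_exact_peptide,
               "QDDGSSSASPSVQGAPR")

  none <- explain_unmapped(unmapped[0, ], prot)
  expect_equal(nrow(none$explained), 0L)
  expect_equal(nrow(none$unexplained), 0L)
  expect_equal(none$variant_obs, 0L)
})

test_that("variant-inclusive fraction never falls below the exact fraction", {
  for (seed in 1:5) {
    spec <- family_spec(seed = seed)
    fam <- simulate_family(spec)
    tab <- simulate_peptide_table(fam, spec)
    cfg <- pipeline_config(proteins = fam$proteins,
                           peptides = tab[, c("peptide", "n_obs")],
                           out_dir = withr::local_tempdir())
    res <- run_attribution_pipeline(cfg, quiet = TRUE)
    pp <- res$report$per_paralogue
    expect_true(all(pp$variant_explained_fraction >=
                      pp$explained_fraction - 1e-12))
  }
})
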