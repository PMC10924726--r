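test_that("missed-cleavage counting follows the site rule", {
  expect_equal(count_missed_cleavages("ATSQGGDLMSDLFNK"), 0L)
  expect_equal(count_missed_cleavages("K"), 0L)
  expect_equal(count_missed_cleavages("AKRAK"), 2L)
  # proline suppression: K before P is not cleavage-competent
  expect_equal(count_missed_cleavages("AKPAAK"), 0L)
  expect_equal(count_missed_cleavages("AKPAAK", proline_rule = FALSE), 1L)
  expect_error(count_missed_cleavages(""), "empty")
})

test_that("tryptic enumeration matches the frozen examples", {
  dig0 <- enumerate_tryptic_peptides("MKAARGK", max_missed = 0,
                                     min_len = 1, max_len = 50)
  expect_setequal(paste(dig0$peptide, dig0$start), c("MK 1", "AAR 3", "GK 6"))
  dig1 <- enumerate_tryptic_peptides("MKAARGK", max_missed = 1,
                                     min_len = 1, max_len = 50)
  expect_setequal(paste(dig1$peptide, dig1$start),
                  c("MK 1", "AAR 3", "GK 6", "MKAAR 1", "AARGK 3"))
  # a protein without K/R digests to itself
  whole <- enumerate_tryptic_peptides("MAAA", max_missed = 0,
                                      min_len = 1, max_len = 50)
  expect_equal(whole$peptide, "MAAA")
  expect_equal(whole$start, 1L)
})

test_that("enumeration agrees with the all-substrings oracle", {
  set.seed(101)
  for (rep in 1:50) {
    seq <- random_protein(sample(10:60, 1))
    for (pr in c(TRUE, FALSE)) {
      got <- enumerate_tryptic_peptides(seq, max_missed = 2, min_len = 1,
                                        max_len = 60, proline_rule = pr)
      want <- brute_force_tryptic(seq, max_missed = 2, proline_rule = pr)
      got <- got[order(got$start, got$end), ]
      expect_equal(got$peptide, want$peptide)
      expect_equal(got$missed_cleavages, want$missed_cleavages)
    }
  }
})

test_that("peptide mapping enforces tryptic boundaries in protein context", {
  prot <- protein_set("T", "MKLLRGG")
  m <- map_peptide("LLR", prot)
  expect_equal(m$start, 3L)
  expect_equal(m$end, 5L)
  expect_equal(m$missed_cleavages, 0L)
  expect_true(m$nterm_tryptic && m$cterm_tryptic)

  expect_equal(nrow(map_peptide("LLRG", prot)), 0L)   # C-boundary not tryptic
  m2 <- map_peptide("MKLLR", prot)                    # N-terminus is a boundary
  expect_equal(m2$start, 1L)
  expect_equal(m2$missed_cleavages, 1L)

  # X never matches, neither in the peptide nor in the window
  expect_equal(nrow(map_peptide("LXR", protein_set("T", "MKLXRGG"))), 0L)
  expect_equal(nrow(map_peptide("LLR", protein_set("T", "MKLXRGG"))), 0L)
})

test_that("I/L equivalence mode collapses single I/L differences", {
  prots <- protein_set("T", "MKALIDKR")
  expect_equal(nrow(map_peptide("ALLDK", prots)), 0L)
  expect_equal(nrow(map_peptide("ALLDK", prots, il_equivalent = TRUE)), 1L)
})

test_that("evidence filtering removes singletons and over-cleaved peptides", {
  tab <- peptide_table(c("AAALDNK", "CCCDFNK", "DDDWEMK", "AKRKAAR"),
                       c(1L, 2L, 5L, 100L))
  kept <- filter_peptide_table(tab, min_obs = 2, max_missed = 2)
  expect_setequal(kept$peptide, c("CCCDFNK", "DDDWEMK"))
  expect_equal(nrow(filter_peptide_table(tab[0, ])), 0L)
})

test_that("attribution separates unique and shared evidence", {
  ps <- protein_set(c("P1", "P2"), c("MKAAADKR", "MKAAAEKR"))
  pt <- peptide_table(c("AAADK", "AAAEK"), c(10L, 4L))
  rep <- build_attribution(pt, ps)
  pp <- rep$per_paralogue
  expect_equal(rep$unique_sets$P1, "AAADK")
  expect_equal(rep$unique_sets$P2, "AAAEK")
  expect_equal(pp$explained_fraction[pp$protein_id == "P1"], 10 / 14)
  expect_equal(pp$rank[pp$protein_id == "P1"], 1L)

  # degenerate: no peptides
  rep0 <- build_attribution(peptide_table(character(0), integer(0)), ps)
  expect_equal(rep0$per_paralogue$explained_fraction, c(0, 0))
  expect_error(build_attribution(pt, ps[0, ]), "empty protein")

  # identical twins capture identically and uniquely nothing
  twins <- protein_set(c("T1", "T2"), c("MKAAADKR", "MKAAADKR"))
  rt <- build_attribution(pt, twins)
  expect_equal(rt$capture_sets$T1, rt$capture_sets$T2)
  expect_equal(lengths(rt$unique_sets), c(T1 = 0L, T2 = 0L))
})

test_that("attribution is invariant to input order", {
  set.seed(77)
  ps <- protein_set(paste0("P", 1:4),
                    vapply(1:4, function(i) random_protein(80), character(1)))
  dig <- enumerate_tryptic_peptides(ps[1, ], min_len = 4, max_len = 30)
  pt <- peptide_table(unique(dig$peptide),
                      sample(2:50, length(unique(dig$peptide)), replace = TRUE))
  rep1 <- build_attribution(pt, ps)
  perm_p <- sample(nrow(pt))
  perm_s <- sample(nrow(ps))
  rep2 <- build_attribution(pt[perm_p, ], ps[perm_s, ])
  expect_equal(rep1$per_paralogue, rep2$per_paralogue)
  expect_setequal(rep1$unmapped$peptide, rep2$unmapped$peptide)
})

test_that("captured peptides re-digest cleanly on their protein", {
  set.seed(5)
  seq <- random_protein(120)
  ps <- protein_set("P", seq)
  dig <- enumerate_tryptic_peptides(ps, min_len = 5, max_len = 40)
  pt <- peptide_table(unique(dig$peptide),
                      rep(3L, length(unique(dig$peptide))))
  rep <- build_attribution(pt, ps)
  for (pep in rep$capture_sets$P) {
    m <- map_peptide(pep, ps)
    expect_gt(nrow(m), 0)
    expect_true(all(m$missed_cleavages <= 2))
    expect_true(all(m$nterm_tryptic & m$cterm_tryptic))
  }
})
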