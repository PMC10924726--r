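# A clean 300-codon parent CDS used across the cases.
parent_cds <- function() {
  set.seed(42)
  aa <- c("M", sample(setdiff(c("A", "D", "E", "G", "L", "P", "S", "V", "W"),
                              NULL), 299, replace = TRUE))
  codons <- vapply(aa, function(a) paralogid:::random_codon_for(a),
                   character(1))
  paste(c(codons, "TAA"), collapse = "")
}

test_that("transcript assessment handles the forced lesion cases", {
  p <- parent_cds()

  expect_equal(assess_transcript(p, p)$status, "full_length_intact")
  expect_equal(assess_transcript(p, p)$predicted_protein_length, 300L)

  # in-frame TAA at codon 150
  mut <- p
  substr(mut, 448, 450) <- "TAA"
  st <- assess_transcript(mut, p)
  expect_equal(st$status, "premature_stop")
  expect_equal(st$lesions$coordinate[st$lesions$kind == "premature_stop"],
               448L)
  expect_equal(st$predicted_protein_length, 149L)

  # 4-base deletion: frameshift (4 mod 3 = 1)
  del4 <- paste0(substr(p, 1, 200), substr(p, 205, nchar(p)))
  st4 <- assess_transcript(del4, p)
  expect_equal(st4$status, "frameshift")
  expect_true(any(st4$lesions$kind == "frameshift"))

  # missing the first 150 bases (50 codons): 5'-truncated
  tr <- substr(p, 151, nchar(p))
  expect_equal(assess_transcript(tr, p)$status, "truncated_5prime")
  # a shorter truncation is not called
  expect_equal(assess_transcript(substr(p, 100, nchar(p)), p)$status,
               "full_length_intact")

  # fragment: less than half the parent aligns
  frag <- substr(p, 1, floor(nchar(p) * 0.4))
  expect_equal(assess_transcript(frag, p)$status, "fragment")
})

test_that("an upstream in-frame stop dominates a downstream frameshift", {
  p <- parent_cds()
  mut <- p
  substr(mut, 301, 303) <- "TAA"                       # stop at codon 101
  mut <- paste0(substr(mut, 1, 600), substr(mut, 603, nchar(mut)))  # 2-nt del
  st <- assess_transcript(mut, p)
  expect_equal(st$status, "premature_stop")
  expect_setequal(unique(st$lesions$kind), c("premature_stop", "frameshift"))
  expect_equal(st$lesions$coordinate[st$lesions$kind == "premature_stop"],
               301L)
})

test_that("stops downstream of a frameshift are not reported as lesions", {
  p <- parent_cds()
  # frameshift early; the scrambled downstream frame may contain stops that
  # are artefacts of the shifted reading
  fs <- paste0(substr(p, 1, 90), substr(p, 92, nchar(p)))
  st <- assess_transcript(fs, p)
  expect_equal(st$status, "frameshift")
  expect_false(any(st$lesions$kind == "premature_stop"))
})

test_that("transcript validation rejects malformed input", {
  p <- parent_cds()
  expect_error(assess_transcript("ACGU", p), "non-DNA")
  expect_error(assess_transcript(p, substr(p, 1, nchar(p) - 1)),
               "divisible")
  expect_error(assess_transcript(p, paste0(substr(p, 1, nchar(p) - 3), "AAA")),
               "stop codon")
})

test_that("gene verdicts combine lesions with peptide evidence", {
  expect_equal(classify_gene("full_length_intact", n_unique = 17), "coding")
  expect_equal(classify_gene("premature_stop", n_unique = 0), "pseudogene")
  expect_equal(classify_gene("frameshift", n_unique = 5), "pseudogene")
  expect_equal(classify_gene("fragment", n_unique = 0), "pseudogene")
  # intact but unsupported: ambiguous, unless a sibling explains ~everything
  expect_equal(classify_gene("full_length_intact", n_unique = 0,
                             n_captured = 20), "ambiguous")
  expect_equal(classify_gene("full_length_intact", n_unique = 0,
                             n_captured = 20,
                             sibling_max_explained = 0.9998), "pseudogene")
  expect_equal(classify_gene("full_length_intact", n_unique = 0,
                             n_captured = 20,
                             sibling_max_explained = 0.95), "ambiguous")
  # truncated copies need unique evidence in the retained region
  expect_equal(classify_gene("truncated_5prime", n_unique = 0), "pseudogene")
  expect_equal(classify_gene("truncated_5prime", n_unique = 2), "coding")
  expect_error(classify_gene("nonsense", 0), "unknown")
})
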