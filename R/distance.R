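# TN93 pairwise distances and neighbor-joining trees, used as a
# distance-based check that derived paralogues form their own clade apart
# from the coding copy and its species orthologues.

#' Tamura-Nei (1993) distance between two aligned DNA sequences
#'
#' Computed from the two transition proportions (A<->G and C<->T), the
#' transversion proportion, and the empirical base frequencies pooled over
#' the pair. Sites where either sequence carries a gap, `N`, or any other
#' ambiguity code are excluded pairwise. Returns `Inf` when a logarithm
#' argument is non-positive (saturation).
#'
#' @param a,b equal-length aligned DNA strings.
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  acgt <- c("A", "C", "G", "T")
  use <- ca %in% acgt & cb %in% acgt
  n <- sum(use)
  if (n == 0L) stop("zero comparable sites")
  ca <- ca[use]; cb <- cb[use]
  freq <- (table(factor(ca, levels = acgt)) +
           table(factor(cb, levels = acgt))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  pair <- paste0(pmin(ca, cb), pmax(ca, cb))
  P1 <- sum(diff & pair == "AG") / n          # purine transitions
  P2 <- sum(diff & pair == "CT") / n          # pyrimidine transitions
  Q <- sum(diff) / n - P1 - P2                # transversions
  safe_log <- function(x) if (x <= 0) -Inf else log(x)
  term <- 0
  if (gA * gG > 0) {
    w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
    term <- term - (2 * gA * gG / gR) * safe_log(w1)
  } else if (P1 > 0) return(Inf)
  if (gC * gT > 0) {
    w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
    term <- term - (2 * gC * gT / gY) * safe_log(w2)
  } else if (P2 > 0) return(Inf)
  if (gR * gY > 0) {
    w3 <- 1 - Q / (2 * gR * gY)
    c3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
    term <- term - c3 * safe_log(w3)
  } else if (Q > 0) return(Inf)
  if (!is.finite(term)) return(Inf)
  unname(term)
}

#' TN93 distance matrix for an aligned set of DNA sequences
#'
#' @param seqs named character vector (or `DNAStringSet`) of aligned
#'   sequences.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
tn93_matrix <- function(seqs) {
  ids <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), ids)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences need unique names")
  k <- length(seqs)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    d[i, j] <- d[j, i] <- tn93_distance(seqs[i], seqs[j])
  d
}

#' Write a distance matrix as a PHYLIP-style square TSV
#' @param d square matrix with taxa dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  lines <- c(as.character(nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i], format(d[i, ], digits = 10)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration (Q-criterion). When an outgroup
#' id is supplied the tree is rooted on its pendant edge.
#'
#' @param d symmetric distance matrix with at least three taxa (dimnames are
#'   the taxon ids), or a `dist` object.
#' @param outgroup optional taxon id to root on.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("non-finite distances (saturation?)")
  tree <- ape::nj(stats::as.dist(d))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) stop("outgroup not among taxa")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Test whether a set of taxa forms its own clade
#'
#' Roots the tree on `outgroup` and asks whether `taxa` are monophyletic —
#' the topological claim that a set of derived paralogues separates from the
#' coding copy and the species orthologues.
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa tip labels of the putative clade.
#' @param outgroup tip used to root the tree.
#' @return `TRUE` iff `taxa` form a clade in the rooted tree.
#' @export
is_separate_clade <- function(tree, taxa, outgroup) {
  if (outgroup %in% taxa) stop("outgroup cannot be inside the tested clade")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Serialize a tree to newick
#' @param tree an `ape::phylo` tree.
#' @param path optional output path; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
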