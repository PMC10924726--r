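# Independent oracles used to check the digestion/mapping code and the TN93
# distance. These deliberately re-derive everything from first principles
# (all-substrings scans, direct formula transcription) and share no code
# with the implementation.

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# All substrings of `seq` that are fully tryptic with <= max_missed missed
# cleavages, by brute force over every (start, end) pair.
brute_force_tryptic <- function(seq, max_missed = 2, min_len = 1,
                                max_len = nchar(seq), proline_rule = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cleaves_after <- function(i) {
    i >= 1 && i < n && chars[i] %in% c("K", "R") &&
      !(proline_rule && chars[i + 1] == "P")
  }
  out <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1
    if (len < min_len || len > max_len) next
    nterm <- s == 1 || cleaves_after(s - 1)
    cterm <- e == n || cleaves_after(e)
    if (!nterm || !cterm) next
    missed <- if (e > s) sum(vapply(s:(e - 1), cleaves_after, logical(1))) else 0L
    if (missed > max_missed) next
    out[[length(out) + 1]] <- data.frame(
      peptide = paste(chars[s:e], collapse = ""), start = s, end = e,
      missed_cleavages = missed, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Brute-force mapping: every start where the peptide occurs with tryptic
# boundaries and <= max_missed missed cleavages in the protein context.
brute_force_map <- function(peptide, seq, max_missed = 2,
                            proline_rule = TRUE) {
  bf <- brute_force_tryptic(seq, max_missed = max_missed,
                            proline_rule = proline_rule)
  hits <- bf[bf$peptide == peptide & !grepl("X", peptide, fixed = TRUE), ,
             drop = FALSE]
  hits[order(hits$start), , drop = FALSE]
}

# Direct transcription of the Tamura-Nei (1993) distance for two aligned
# gap-free ACGT strings: d = -k1 ln(w1) - k2 ln(w2) - k3 ln(w3) with
# k1 = 2 gA gG / gR, k2 = 2 gC gT / gY,
# k3 = 2 (gR gY - gA gG gY / gR - gC gT gR / gY),
# w1 = 1 - gR P1 / (2 gA gG) - Q / (2 gR),
# w2 = 1 - gY P2 / (2 gC gT) - Q / (2 gY),
# w3 = 1 - Q / (2 gR gY).
tn93_closed_form <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  counts <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
  g <- counts / (2 * n)
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- mean((x == "A" & y == "G") | (x == "G" & y == "A"))
  P2 <- mean((x == "C" & y == "T") | (x == "T" & y == "C"))
  Q <- mean(x != y) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a DNA string at a given per-site substitution rate.
mutate_dna <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (p in hit) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}
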