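# small deterministic fixtures shared across test files

# 100-base circular toy reference with one protein gene (10-30), a poly-C
# special region (40-45) and a wrapping control region (90-9)
toy_reference <- function() {
  gene_codons <- c("ATG", "GCT", "CCA", "TTC", "GGA", "ACA", "CTA")  # no stops
  base <- rep(c("A", "C", "G", "T"), length.out = 100)
  base[10:30] <- strsplit(paste(gene_codons, collapse = ""), "")[[1]]
  base[40:45] <- "C"
  reference_model(
    paste(base, collapse = ""),
    genes = tibble::tibble(
      gene = c("TOY1", "CRtoy"),
      start = c(10L, 90L), end = c(30L, 9L),
      strand = c("+", "+"),
      class = c("protein-coding", "control")),
    special_regions = tibble::tibble(label = "polyC", start = 40L, end = 45L),
    name = "toy circular reference")
}

# random pileup table over `n` positions with depths up to max_depth
rand_pileup <- function(n, seed, max_depth = 60) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  depth <- sample(0:max_depth, n, replace = TRUE)
  counts <- t(vapply(seq_len(n), function(i) {
    alt_reads <- rbinom(1, depth[i], runif(1, 0, 0.6))
    out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    out[ref[i]] <- depth[i] - alt_reads
    if (alt_reads > 0) {
      split <- rmultinom(1, alt_reads, rep(1/3, 3))[, 1]
      out[setdiff(names(out), ref[i])] <- as.integer(split)
    }
    out
  }, integer(4)))
  tibble::tibble(position = seq_len(n), ref = ref, depth = as.integer(depth),
                 A = counts[, "A"], C = counts[, "C"],
                 G = counts[, "G"], T = counts[, "T"])
}

# mutate/indel a sequence deterministically; returns the derived sequence
perturb_sequence <- function(seq, seed, n_sub = 5, n_del = 1, n_ins = 1) {
  set.seed(seed)
  b <- strsplit(seq, "")[[1]]
  for (p in sample(seq_along(b), n_sub)) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  }
  if (n_del > 0) {
    b <- b[-sample(seq_along(b), n_del)]
  }
  if (n_ins > 0) {
    at <- sample(seq_along(b), 1)
    b <- append(b, sample(c("A", "C", "G", "T"), n_ins, replace = TRUE), after = at)
  }
  paste(b, collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
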