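#' Synthetic rCRS-like mitochondrial reference
#'
#' Builds a synthetic 16,569-base circular mitochondrial reference on true
#' rCRS (NC_012920.1) coordinates. The gene and region map is the real
#' public annotation (packaged in `extdata/rcrs_genes.tsv`); the nucleotide
#' sequence is generated deterministically in code and is NOT the rCRS
#' sequence. The generated sequence honours the structural facts the
#' pipeline relies on: length 16,569; the historic placeholder base 'N' at
#' position 3107; the poly-C tract at 16184-16193 (with the interrupting T
#' at 16189); reference base A at 5009 (a third codon position of MTND2), A
#' at 2905 (MTRNR2), T at 250 (control region); and protein-coding genes
#' whose internal codons are free of stop codons under the vertebrate
#' mitochondrial genetic code, including in the frame-shifted overlaps
#' (MTATP8/MTATP6, MTND4L/MTND4) and the minus-strand gene MTND6.
#'
#' The result is cached within the session; repeated calls are cheap and the
#' sequence is identical across sessions and platforms.
#'
#' @return A [reference_model] named to mark it as synthetic.
#' @examples
#' ref <- synthetic_rcrs()
#' ref$length  # 16569
#' @export
synthetic_rcrs <- function() {
  if (!is.null(.synthetic_cache$rcrs)) return(.synthetic_cache$rcrs)
  tab <- rcrs_gene_table()
  L <- tab$decl_length

  with_preserved_rng({
    set.seed(16569L)
    # mtDNA-like base composition (heavy strand: A- and C-rich)
    seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.31, 0.31, 0.13, 0.25))
    anchored <- logical(L)
    set_anchor <- function(pos, base) {
      seq[pos] <<- base
      anchored[pos] <<- TRUE
    }
    set_anchor(250L, "T")
    set_anchor(2905L, "A")
    set_anchor(3107L, "N")
    set_anchor(5009L, "A")
    set_anchor(16184:16193, c("C","C","C","C","C","T","C","C","C","C"))

    code <- mito_code()
    genes <- tab$genes
    pg <- genes[genes$class == "protein-coding", ]
    pg <- pg[order(pg$start), ]

    codon_positions <- function(row, ci) {
      if (row$strand == "+") row$start + 3L * ci + 0:2 else row$end - 3L * ci - 0:2
    }
    coding_codon <- function(row, p) {
      b <- seq[p]
      if (row$strand == "-") b <- unname(.comp[b])
      paste(b, collapse = "")
    }
    is_stop <- function(cd) !is.na(code[cd]) && code[cd] == "*"

    locked <- anchored
    for (gi in seq_len(nrow(pg))) {
      row <- pg[gi, ]
      k <- region_width(row$start, row$end, L) %/% 3L
      for (ci in 0:(k - 1L)) {
        p <- codon_positions(row, ci)
        free <- !locked[p]
        if (any(free)) {
          for (try in 1:200) {
            seq[p[free]] <- sample(c("A", "C", "G", "T"), sum(free), replace = TRUE)
            if (!is_stop(coding_codon(row, p))) break
          }
        }
      }
      for (ci in 0:(k - 1L)) locked[codon_positions(row, ci)] <- TRUE
    }

    # repair pass: overlapping frames can still leave stops where all three
    # bases were locked by an earlier gene or an anchor
    genes_covering <- function(pos) {
      pg[in_region(pos, pg$start, pg$end, L), , drop = FALSE]
    }
    codon_ok_everywhere <- function(pos) {
      cov <- genes_covering(pos)
      for (j in seq_len(nrow(cov))) {
        row <- cov[j, ]
        cd <- codon_of(row, pos)
        if (!cd$complete) next
        if (is_stop(paste({
          b <- seq[cd$positions]
          if (row$strand == "-") b <- unname(.comp[b])
          b
        }, collapse = ""))) return(FALSE)
      }
      TRUE
    }
    for (pass in 1:25) {
      dirty <- FALSE
      for (gi in seq_len(nrow(pg))) {
        row <- pg[gi, ]
        k <- region_width(row$start, row$end, L) %/% 3L
        for (ci in 0:(k - 1L)) {
          p <- codon_positions(row, ci)
          if (!is_stop(coding_codon(row, p))) next
          fixed <- FALSE
          for (pos in p[!anchored[p]]) {
            orig <- seq[pos]
            for (b in setdiff(c("A", "C", "G", "T"), orig)) {
              seq[pos] <- b
              if (!is_stop(coding_codon(row, p)) && codon_ok_everywhere(pos)) {
                fixed <- TRUE; break
              }
              seq[pos] <- orig
            }
            if (fixed) break
          }
          if (!fixed) dirty <- TRUE
        }
      }
      if (!dirty) break
    }
    .synthetic_cache$rcrs <- reference_model(
      paste(seq, collapse = ""), tab$genes, tab$special,
      name = "synthetic rCRS-like (NC_012920.1 coordinates, synthetic sequence)")
  })
  .synthetic_cache$rcrs
}

#' Synthetic alternative mitochondrial reference
#'
#' Derives a synthetic non-rCRS mitochondrial reference from
#' [synthetic_rcrs()] by inserting two bases after position 3106 (so the
#' genome is 16,571 bases, mirroring the length difference between the hg19
#' mitochondrial record and rCRS) and applying 40 deterministic single-base
#' substitutions. Useful as the source reference in liftover examples and
#' tests.
#'
#' @return A list with `name` and `sequence` (character string).
#' @export
synthetic_alt_mt <- function() {
  if (!is.null(.synthetic_cache$alt)) return(.synthetic_cache$alt)
  ref <- synthetic_rcrs()
  base <- strsplit(ref$sequence, "")[[1]]
  with_preserved_rng({
    set.seed(1807L)
    subs <- sample(setdiff(seq_len(ref$length), 3050:3160), 40)
    for (p in subs) {
      base[p] <- sample(setdiff(c("A", "C", "G", "T"), base[p]), 1)
    }
    out <- c(base[1:3106], c("C", "C"), base[3107:ref$length])
    .synthetic_cache$alt <- list(
      name = "synthetic alternative mtDNA reference (16,571 bp)",
      sequence = paste(out, collapse = ""))
  })
  .synthetic_cache$alt
}

# packaged rCRS gene/region annotation (real NC_012920.1 coordinates)
rcrs_gene_table <- function() {
  path <- system.file("extdata", "rcrs_genes.tsv", package = "mitohet",
                      mustWork = TRUE)
  ann <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols())
  decl <- ann[ann$class == "genome", ]
  special <- ann[ann$class == "region", c("label", "start", "end")]
  g <- ann[!ann$class %in% c("region", "genome"), ]
  list(
    decl_length = as.integer(decl$end[1]),
    genes = tibble::tibble(gene = g$label, start = as.integer(g$start),
                           end = as.integer(g$end), strand = g$strand,
                           class = g$class),
    special = tibble::as_tibble(special)
  )
}

.synthetic_cache <- new.env(parent = emptyenv())

# run code with the caller's RNG state preserved
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}
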