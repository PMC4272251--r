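#' Reference model for a circular mitochondrial genome
#'
#' Bundles a mitochondrial reference sequence with its gene map and named
#' special regions (the poly-C tract, the light-strand replication origin)
#' into the coordinate ground truth used by every downstream module. All
#' coordinates are 1-based inclusive ("m." notation); a region with
#' `start > end` wraps the origin, as the control region does.
#'
#' @param sequence Single nucleotide string (A/C/G/T/N).
#' @param genes Tibble with columns `gene`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `class` (one of `"protein-coding"`, `"rRNA"`, `"tRNA"`,
#'   `"control"`).
#' @param special_regions Tibble with columns `label`, `start`, `end`. Must
#'   contain a region labelled `"polyC"`.
#' @param name Text identifier for the reference.
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(sequence, genes, special_regions,
                            name = "unnamed mtDNA reference") {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < 1) rlang::abort("empty reference sequence.")
  if (grepl("[^ACGTN]", sequence)) {
    rlang::abort("reference sequence contains characters outside ACGTN.")
  }
  genes <- tibble::as_tibble(genes)
  need <- c("gene", "start", "end", "strand", "class")
  if (!all(need %in% names(genes))) {
    rlang::abort(paste("gene table must have columns:", paste(need, collapse = ", ")))
  }
  classes <- c("protein-coding", "rRNA", "tRNA", "control")
  if (!all(genes$class %in% classes)) {
    rlang::abort("gene class must be one of protein-coding, rRNA, tRNA, control.")
  }
  if (any(genes$start < 1 | genes$start > L | genes$end < 1 | genes$end > L)) {
    rlang::abort("gene region out of bounds [1, genome length].")
  }
  special_regions <- tibble::as_tibble(special_regions)
  if (!all(c("label", "start", "end") %in% names(special_regions))) {
    rlang::abort("special_regions must have columns label, start, end.")
  }
  if (!"polyC" %in% special_regions$label) {
    rlang::abort("configuration error: mandatory special region 'polyC' missing.")
  }
  if (any(special_regions$start < 1 | special_regions$end > L)) {
    rlang::abort("special region out of bounds.")
  }
  structure(
    list(name = name, sequence = sequence, length = L,
         genes = genes, special_regions = special_regions),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %s: %d bp, %d genes, %d special regions\n",
              x$name, x$length, nrow(x$genes), nrow(x$special_regions)))
  invisible(x)
}

#' Width of a (possibly origin-wrapping) region on a circular genome
#'
#' @param start,end 1-based inclusive bounds; `start > end` means the region
#'   crosses the origin.
#' @param genome_length Total genome length L.
#' @return Integer width; for a wrapping region, `(L - start + 1) + end`.
#' @export
region_width <- function(start, end, genome_length) {
  ifelse(start <= end, end - start + 1L,
         (genome_length - start + 1L) + end)
}

# all positions of a region, honouring the wrap
region_positions <- function(start, end, genome_length) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, genome_length), seq.int(1L, end))
}

# is position p inside region [start, end] on a circle of length L;
# vectorized over p and over (start, end)
in_region <- function(p, start, end, genome_length) {
  k <- max(length(p), length(start), length(end))
  p <- rep_len(p, k); start <- rep_len(start, k); end <- rep_len(end, k)
  ifelse(start <= end, p >= start & p <= end, p >= start | p <= end)
}

#' Load a reference model from FASTA and an annotation table
#'
#' @param fasta_source Path to a single-record FASTA file.
#' @param annotation_source Path to a tab-separated annotation table with
#'   columns `start`, `end`, `label`, `class`, `strand`. Rows with
#'   `class == "region"` become special regions (a `polyC` row is mandatory);
#'   an optional row with `class == "genome"` declares the expected genome
#'   length in its `end` column and is checked against the FASTA.
#' @param name Optional reference name; defaults to the FASTA record name.
#' @return A validated [reference_model].
#' @export
load_reference <- function(fasta_source, annotation_source, name = NULL) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_source),
                   error = function(e) rlang::abort(paste("malformed FASTA:", conditionMessage(e))))
  if (length(seqs) != 1L) {
    rlang::abort(sprintf("FASTA must contain exactly one sequence (found %d).", length(seqs)))
  }
  seq <- as.character(seqs[[1]])
  ann <- readr::read_tsv(annotation_source, comment = "#",
                         col_types = readr::cols(
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           label = readr::col_character(),
                           class = readr::col_character(),
                           strand = readr::col_character()
                         ), progress = FALSE)
  if (!all(c("start", "end", "label", "class", "strand") %in% names(ann))) {
    rlang::abort("annotation table must have columns start, end, label, class, strand.")
  }
  decl <- ann[ann$class == "genome", ]
  if (nrow(decl) > 0 && any(decl$end != nchar(seq))) {
    rlang::abort(sprintf(
      "sequence length %d differs from the annotation's declared length %d.",
      nchar(seq), decl$end[1]))
  }
  special <- ann[ann$class == "region", c("label", "start", "end")]
  genes <- ann[!ann$class %in% c("region", "genome"), ]
  genes <- tibble::tibble(gene = genes$label, start = genes$start, end = genes$end,
                          strand = genes$strand, class = genes$class)
  reference_model(seq, genes, special,
                  name = name %||% names(seqs)[1])
}

# feature precedence when annotations overlap; smallest-feature-wins
# convention of mtDNA annotators
.feature_precedence <- c("tRNA" = 1L, "rRNA" = 2L, "protein-coding" = 3L, "control" = 4L)

#' Primary feature at a genome position
#'
#' Resolves overlapping annotations with the precedence
#' tRNA > rRNA > protein-coding > control; positions outside every annotated
#' feature are classified as noncoding control-class sequence.
#'
#' @param ref_model A [reference_model].
#' @param position Integer vector of 1-based positions.
#' @return Tibble with columns `position`, `gene`, `feature_class`.
#' @export
feature_at <- function(ref_model, position) {
  stopifnot(inherits(ref_model, "reference_model"))
  g <- ref_model$genes
  L <- ref_model$length
  res <- purrr::map(position, function(p) {
    hit <- g[in_region(p, g$start, g$end, L), , drop = FALSE]
    if (nrow(hit) == 0) {
      return(tibble::tibble(position = p, gene = "noncoding", feature_class = "control"))
    }
    hit <- hit[order(.feature_precedence[hit$class],
                     region_width(hit$start, hit$end, L)), ]
    tibble::tibble(position = p, gene = hit$gene[1], feature_class = hit$class[1])
  })
  dplyr::bind_rows(res)
}

# vertebrate mitochondrial genetic code (translation table 2)
mito_code <- function() {
  Biostrings::getGeneticCode("SGC1")
}

# reference base at a (vector of) position(s)
ref_base_at <- function(ref_model, position) {
  strsplit(ref_model$sequence, "")[[1]][position]
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# codon holding `position` within a protein-coding gene row; returns list
# (bases: plus-strand codon positions, offset: 0-based index of `position`
# within the coding-strand codon, complete: logical)
codon_of <- function(gene_row, position) {
  if (gene_row$strand == "+") {
    off <- position - gene_row$start
    ci <- off %/% 3L
    p <- gene_row$start + 3L * ci + 0:2
    list(positions = p, within = off %% 3L, complete = all(p <= gene_row$end))
  } else {
    off <- gene_row$end - position
    ci <- off %/% 3L
    p <- gene_row$end - 3L * ci - 0:2        # descending along coding strand
    list(positions = p, within = off %% 3L, complete = all(p >= gene_row$start))
  }
}

# translate the codon of a protein gene containing `position`, with base at
# `position` optionally substituted; NA for incomplete terminal codons
translate_at <- function(ref_model, gene_row, position, base = NULL) {
  cd <- codon_of(gene_row, position)
  if (!cd$complete) return(NA_character_)
  bases <- ref_base_at(ref_model, cd$positions)
  if (!is.null(base)) bases[cd$within + 1L] <- base
  if (gene_row$strand == "-") bases <- unname(.comp[bases])
  codon <- paste(bases, collapse = "")
  if (grepl("N", codon)) return(NA_character_)
  unname(mito_code()[codon])
}

#' Annotate single-nucleotide variants against the reference model
#'
#' Assigns each variant its gene and feature class by interval lookup, and
#' for protein-coding genes computes the coding consequence by translating
#' the containing codon before and after the substitution under the
#' vertebrate mitochondrial genetic code (translation table 2), honouring
#' gene strand. Variants in an incomplete terminal codon (genes ending in an
#' abbreviated stop completed by polyadenylation) are reported as synonymous,
#' since no encoded amino acid changes.
#'
#' @param ref_model A [reference_model].
#' @param position Integer vector of 1-based positions.
#' @param ref_allele,alt_allele Single-base alleles (A/C/G/T), recycled.
#' @return Tibble: `position`, `ref`, `alt`, `gene`, `feature_class`,
#'   `consequence` (`synonymous`, `nonsynonymous`, `stop-gain`, `stop-loss`
#'   or `noncoding`), `in_polyC`.
#' @examples
#' ref <- synthetic_rcrs()
#' annotate_variant(ref, 5009, "A", "G")   # synonymous, MTND2
#' @export
annotate_variant <- function(ref_model, position, ref_allele, alt_allele) {
  stopifnot(inherits(ref_model, "reference_model"))
  k <- max(length(position), length(ref_allele), length(alt_allele))
  position <- rep_len(as.integer(position), k)
  ref_allele <- rep_len(toupper(ref_allele), k)
  alt_allele <- rep_len(toupper(alt_allele), k)
  L <- ref_model$length
  if (any(position < 1 | position > L)) {
    rlang::abort(sprintf("position out of bounds [1, %d].", L))
  }
  if (!all(ref_allele %in% c("A", "C", "G", "T")) ||
      !all(alt_allele %in% c("A", "C", "G", "T"))) {
    rlang::abort("alleles must be single bases A/C/G/T.")
  }
  actual <- ref_base_at(ref_model, position)
  if (any(actual == "N")) {
    bad <- position[actual == "N"]
    rlang::abort(sprintf(
      "position %s is not a callable site (reference base 'N').", bad[1]))
  }
  if (any(actual != ref_allele)) {
    i <- which(actual != ref_allele)[1]
    rlang::abort(sprintf(
      "reference allele mismatch at position %d: supplied %s, reference has %s.",
      position[i], ref_allele[i], actual[i]))
  }
  feat <- feature_at(ref_model, position)
  pc <- ref_model$special_regions[ref_model$special_regions$label == "polyC", ]
  in_polyc <- in_region(position, pc$start[1], pc$end[1], L)
  consequence <- purrr::map_chr(seq_len(k), function(i) {
    if (feat$feature_class[i] != "protein-coding") return("noncoding")
    grow <- ref_model$genes[ref_model$genes$gene == feat$gene[i] &
                            ref_model$genes$class == "protein-coding", ][1, ]
    aa0 <- translate_at(ref_model, grow, position[i])
    aa1 <- translate_at(ref_model, grow, position[i], base = alt_allele[i])
    if (is.na(aa0) || is.na(aa1)) return("synonymous")  # incomplete terminal codon
    if (aa0 == aa1) "synonymous"
    else if (aa1 == "*") "stop-gain"
    else if (aa0 == "*") "stop-loss"
    else "nonsynonymous"
  })
  tibble::tibble(
    position = position, ref = ref_allele, alt = alt_allele,
    gene = feat$gene, feature_class = feat$feature_class,
    consequence = consequence, in_polyC = in_polyc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
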