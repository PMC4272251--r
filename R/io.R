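#' Read a samtools-style text pileup
#'
#' Parses the 6-column samtools mpileup text dialect (chrom, pos, ref,
#' depth, bases, quals) into per-position strand-collapsed allele counts.
#' Match symbols ('.', ',') count toward the reference base; ACGT (either
#' case) toward the alternate base; read-start markers ('^' plus the
#' following mapping-quality byte) and read-end markers ('$') are consumed
#' without counting; indel blocks ('+n...', '-n...') are skipped entirely
#' (the analysis is restricted to single-nucleotide variants); deletion
#' placeholders ('*') and 'N' calls are dropped. Base calls below
#' `min_base_quality` are removed from both the counts and the reported
#' depth, so the depth column is the denominator actually available for the
#' variant-read fraction.
#'
#' @param source Path to a pileup file, or a character vector of pileup
#'   lines.
#' @param min_base_quality Minimum phred base quality (default 20) for a
#'   call to be counted.
#' @param genome_length Optional; positions beyond it raise an error.
#' @return Tibble with columns `position`, `ref`, `depth`, `A`, `C`, `G`,
#'   `T`.
#' @export
read_pileup <- function(source, min_base_quality = 20, genome_length = NULL) {
  lines <- if (length(source) == 1L && !grepl("\t", source) && file.exists(source)) {
    readr::read_lines(source, progress = FALSE)
  } else {
    source
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(position = integer(), ref = character(),
                          depth = integer(), A = integer(), C = integer(),
                          G = integer(), T = integer()))
  }
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) {
      rlang::abort(sprintf("malformed pileup line %d: expected 6 columns, got %d.",
                           li, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1) {
      rlang::abort(sprintf("malformed pileup line %d: bad position '%s'.", li, f[2]))
    }
    if (!is.null(genome_length) && pos > genome_length) {
      rlang::abort(sprintf("pileup line %d: position %d beyond genome length %d.",
                           li, pos, genome_length))
    }
    ref <- toupper(f[3])
    cnt <- parse_pileup_bases(f[5], f[6], ref, min_base_quality, li)
    out[[li]] <- c(pos, cnt)
  }
  m <- do.call(rbind, out)
  tibble::tibble(
    position = as.integer(m[, 1]),
    ref = toupper(substr(sapply(strsplit(lines, "\t", fixed = TRUE), `[`, 3), 1, 1)),
    depth = as.integer(m[, 2] + m[, 3] + m[, 4] + m[, 5]),
    A = as.integer(m[, 2]), C = as.integer(m[, 3]),
    G = as.integer(m[, 4]), T = as.integer(m[, 5])
  )
}

# walk one bases/quals pair; returns c(A, C, G, T) counts
parse_pileup_bases <- function(bases, quals, ref, min_bq, line_no) {
  bs <- strsplit(bases, "")[[1]]
  qs <- strsplit(quals, "")[[1]]
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  i <- 1L; qi <- 1L; n <- length(bs)
  while (i <= n) {
    ch <- bs[i]
    if (ch == "^") {           # read start: next byte is mapping quality
      i <- i + 2L
    } else if (ch == "$") {    # read end marker
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {   # indel block: skip digits + bases
      j <- i + 1L
      while (j <= n && grepl("[0-9]", bs[j])) j <- j + 1L
      len <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(len)) {
        rlang::abort(sprintf("malformed indel block on pileup line %d.", line_no))
      }
      i <- j + len
    } else {
      if (qi > length(qs)) {
        rlang::abort(sprintf("pileup line %d: fewer qualities than base calls.", line_no))
      }
      q <- utf8ToInt(qs[qi]) - 33L
      qi <- qi + 1L
      base <- NA_character_
      if (ch == "." || ch == ",") base <- ref
      else if (toupper(ch) %in% c("A", "C", "G", "T")) base <- toupper(ch)
      # '*', 'N', '<', '>' consume a quality but are never counted
      if (!is.na(base) && base %in% names(counts) && q >= min_bq) {
        counts[base] <- counts[base] + 1L
      }
      i <- i + 1L
    }
  }
  counts
}

#' Write a pileup table in the samtools mpileup text dialect
#'
#' Inverse of [read_pileup()] for simulator output: every counted base is
#' emitted with quality 'I' (phred 40), reference-matching reads as '.'.
#'
#' @param pileup Tibble from [read_pileup()] or [simulate_cohort()].
#' @param path Output path; when `NULL`, the lines are returned invisibly.
#' @param chrom Chromosome label for column 1 (default `"MT"`).
#' @export
write_pileup <- function(pileup, path = NULL, chrom = "MT") {
  lines <- purrr::pmap_chr(
    pileup[, c("position", "ref", "A", "C", "G", "T")],
    function(position, ref, A, C, G, T) {
      counts <- c(A = A, C = C, G = G, T = T)
      nref <- if (ref %in% names(counts)) counts[[ref]] else 0L
      alts <- counts[setdiff(names(counts), ref)]
      calls <- paste0(strrep(".", nref),
                      paste(strrep(names(alts), alts), collapse = ""))
      depth <- sum(counts)
      if (depth == 0) calls <- "*"   # placeholder keeps the 6-column shape
      paste(chrom, position, ref, depth,
            calls, strrep("I", max(depth, 1L)), sep = "\t")
    })
  if (is.null(path)) return(invisible(lines))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write variant calls as VCF 4.2
#'
#' Emits one data line per call with INFO keys `V` (variant reads), `N`
#' (total depth), `VAF`, `CILOW`, `CIHIGH` and the filter flag set in the
#' FILTER column; the header records the reference name and tool version.
#'
#' @param records Tibble with columns `position`, `ref`, `alt`, `v`, `n`,
#'   `vaf`, `ci_low`, `ci_high` and optionally `filters` (`;`-joined flag
#'   string, empty or NA meaning PASS). Must be sorted by position.
#' @param ref_model A [reference_model] (its name goes in the header), or a
#'   character reference name.
#' @param path Output file path.
#' @param sample_id Sample name recorded in the header.
#' @export
write_vcf <- function(records, ref_model, path, sample_id = "sample") {
  if (nrow(records) > 1 && is.unsorted(records$position, strictly = FALSE)) {
    rlang::abort("records must be sorted by position before writing VCF.")
  }
  ref_name <- if (inherits(ref_model, "reference_model")) ref_model$name else as.character(ref_model)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mitohet-%s", as.character(utils::packageVersion("mitohet"))),
    sprintf("##reference=%s", ref_name),
    sprintf("##sample=%s", sample_id),
    "##INFO=<ID=V,Number=1,Type=Integer,Description=\"Variant read count\">",
    "##INFO=<ID=N,Number=1,Type=Integer,Description=\"Total usable read depth\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction v/n\">",
    "##INFO=<ID=CILOW,Number=1,Type=Float,Description=\"Exact binomial CI lower bound\">",
    "##INFO=<ID=CIHIGH,Number=1,Type=Float,Description=\"Exact binomial CI upper bound\">",
    "##FILTER=<ID=low_coverage,Description=\"Total depth below calling threshold\">",
    "##FILTER=<ID=polyC,Description=\"Inside the unstable poly-C tract\">",
    "##FILTER=<ID=recurrent_artifact,Description=\"Heteroplasmic at the same position in multiple samples\">",
    "##FILTER=<ID=background,Description=\"Variant reads within the background error band\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(records) > 0) {
    filt <- if ("filters" %in% names(records)) records$filters else rep(NA_character_, nrow(records))
    filt <- ifelse(is.na(filt) | filt == "", "PASS", filt)
    body <- sprintf(
      "MT\t%d\t.\t%s\t%s\t.\t%s\tV=%d;N=%d;VAF=%s;CILOW=%s;CIHIGH=%s",
      records$position, records$ref, records$alt, filt,
      records$v, records$n,
      formatC(records$vaf, digits = 10, format = "g"),
      formatC(records$ci_low, digits = 10, format = "g"),
      formatC(records$ci_high, digits = 10, format = "g"))
  }
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant call set from VCF or TSV
#'
#' Accepts either a VCF (format detected from the `##fileformat` header
#' line) or a whitespace/tab-separated table with columns
#' `position ref alt [v n]`. Non-SNV records (multi-base or symbolic
#' alleles, indels) are skipped and tallied in the `skipped` attribute with
#' a warning; duplicate (position, alt) entries are an error; records at
#' rCRS position 3107 (the historic placeholder base) are skipped.
#'
#' @param path Input file path.
#' @return Tibble `position`, `ref`, `alt`, `v`, `n`, `filters` (NA where
#'   unknown), with attribute `skipped` (count of skipped records).
#' @export
read_callset <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  is_vcf <- length(lines) > 0 && grepl("^##fileformat=VCF", lines[1])
  skipped <- 0L
  if (is_vcf) {
    data <- lines[!startsWith(lines, "#")]
    rows <- purrr::map(data, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 8) rlang::abort("malformed VCF data line (fewer than 8 fields).")
      info <- f[8]
      getk <- function(key) {
        m <- regmatches(info, regexpr(sprintf("(?:^|;)%s=([^;]+)", key), info, perl = TRUE))
        if (length(m) == 0) return(NA_real_)
        as.numeric(sub(sprintf(".*%s=", key), "", m))
      }
      tibble::tibble(position = as.integer(f[2]), ref = f[4], alt = f[5],
                     v = getk("V"), n = getk("N"),
                     filters = ifelse(f[7] %in% c("PASS", "."), NA_character_, f[7]))
    })
    calls <- dplyr::bind_rows(rows)
  } else {
    data <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(data) > 0 && !grepl("^[0-9]", strsplit(data[1], "[ \t]+")[[1]][1])) {
      data <- data[-1]   # header row
    }
    rows <- purrr::map(data, function(l) {
      f <- strsplit(trimws(l), "[ \t]+")[[1]]
      if (length(f) < 3) rlang::abort("malformed call table line: need position ref alt.")
      tibble::tibble(position = as.integer(f[1]), ref = toupper(f[2]),
                     alt = toupper(f[3]),
                     v = if (length(f) >= 4) as.numeric(f[4]) else NA_real_,
                     n = if (length(f) >= 5) as.numeric(f[5]) else NA_real_,
                     filters = NA_character_)
    })
    calls <- dplyr::bind_rows(rows)
  }
  if (nrow(calls) == 0) {
    return(structure(tibble::tibble(position = integer(), ref = character(),
                                    alt = character(), v = numeric(),
                                    n = numeric(), filters = character()),
                     skipped = 0L))
  }
  snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
    calls$ref %in% c("A", "C", "G", "T") & calls$alt %in% c("A", "C", "G", "T")
  placeholder <- calls$position == 3107L
  keep <- snv & !placeholder
  skipped <- sum(!keep)
  if (skipped > 0) {
    rlang::warn(sprintf("skipped %d non-SNV or placeholder-position record(s).", skipped))
  }
  calls <- calls[keep, ]
  key <- paste(calls$position, calls$alt)
  if (anyDuplicated(key)) {
    rlang::abort(sprintf("duplicate call at position %s.",
                         calls$position[duplicated(key)][1]))
  }
  structure(calls, skipped = skipped)
}

#' Read a BED mask as 1-based inclusive regions
#'
#' BED is 0-based half-open; this converts explicitly to the package's
#' 1-based inclusive convention.
#'
#' @param path BED file path (3+ columns).
#' @return Tibble `start`, `end`, `label`.
#' @export
read_bed_regions <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  rows <- purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) rlang::abort("malformed BED line: need chrom, start, end.")
    tibble::tibble(start = as.integer(f[2]) + 1L, end = as.integer(f[3]),
                   label = if (length(f) >= 4) f[4] else NA_character_)
  })
  dplyr::bind_rows(rows)
}
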