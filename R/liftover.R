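#' Build a coordinate block map between two mitochondrial references
#'
#' Derives a monotone position mapping from a global pairwise alignment of
#' the two sequences (Needleman-Wunsch; default scoring match +1, mismatch
#' -1, gap open 5, gap extend 1). Aligned runs become blocks of
#' `(source_start, target_start, length)`; gap columns become unmapped
#' positions on one side. The mapping is deterministic given the scoring.
#'
#' @param source_seq,target_seq Nucleotide strings (ACGTN), e.g. an hg19
#'   mitochondrial record and rCRS.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring; gap
#'   penalties are given as positive costs.
#' @param min_identity Identity floor (default 0.95) below which the
#'   sequences are declared not to be the same genome.
#' @param source_name,target_name Labels carried into the map.
#' @return An object of class `block_map`: `blocks` tibble
#'   (`source_start`, `target_start`, `length`), `unmapped_source`,
#'   `unmapped_target` integer vectors, names and lengths. `tidy()` returns
#'   the blocks tibble.
#' @export
build_block_map <- function(source_seq, target_seq,
                            match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 1,
                            min_identity = 0.95,
                            source_name = "source", target_name = "target") {
  source_seq <- toupper(as.character(source_seq))
  target_seq <- toupper(as.character(target_seq))
  if (nchar(source_seq) == 0 || nchar(target_seq) == 0) {
    rlang::abort("sequences must be non-empty.")
  }
  if (grepl("[^ACGTN]", source_seq) || grepl("[^ACGTN]", target_seq)) {
    rlang::abort("sequences must use the ACGTN alphabet.")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(source_seq), Biostrings::DNAString(target_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  s_al <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  t_al <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  aligned <- s_al != "-" & t_al != "-"
  identity <- sum(s_al == t_al & aligned) / max(nchar(source_seq), nchar(target_seq))
  if (identity < min_identity) {
    rlang::abort(sprintf(
      "alignment identity %.3f below the floor %.2f: these do not look like the same genome.",
      identity, min_identity))
  }
  s_pos <- cumsum(s_al != "-")
  t_pos <- cumsum(t_al != "-")
  sp <- s_pos[aligned]; tp <- t_pos[aligned]
  # break into maximal co-linear runs
  if (length(sp) == 0) rlang::abort("no aligned positions.")
  brk <- c(TRUE, diff(sp) != 1L | diff(tp) != 1L)
  grp <- cumsum(brk)
  blocks <- tibble::tibble(
    source_start = as.integer(tapply(sp, grp, min)),
    target_start = as.integer(tapply(tp, grp, min)),
    length = as.integer(tapply(sp, grp, length))
  )
  structure(
    list(source_name = source_name, target_name = target_name,
         blocks = blocks,
         unmapped_source = as.integer(s_pos[s_al != "-" & t_al == "-"]),
         unmapped_target = as.integer(t_pos[t_al != "-" & s_al == "-"]),
         source_length = nchar(source_seq),
         target_length = nchar(target_seq),
         identity = identity),
    class = "block_map"
  )
}

#' @export
print.block_map <- function(x, ...) {
  cat(sprintf("<block_map> %s (%d bp) -> %s (%d bp): %d blocks, %d/%d unmapped, identity %.4f\n",
              x$source_name, x$source_length, x$target_name, x$target_length,
              nrow(x$blocks), length(x$unmapped_source),
              length(x$unmapped_target), x$identity))
  invisible(x)
}

#' @rdname build_block_map
#' @param x A `block_map`.
#' @param ... Unused.
#' @method tidy block_map
#' @export
tidy.block_map <- function(x, ...) x$blocks

#' Map positions through a block map
#'
#' @param map A [build_block_map()] result.
#' @param position Integer vector of positions.
#' @param direction `"source_to_target"` (default) or `"target_to_source"`.
#' @return Integer vector of mapped positions, `NA` where unmapped.
#' @export
map_position <- function(map, position, direction = c("source_to_target",
                                                      "target_to_source")) {
  direction <- match.arg(direction)
  b <- map$blocks
  from <- if (direction == "source_to_target") b$source_start else b$target_start
  to <- if (direction == "source_to_target") b$target_start else b$source_start
  purrr::map_int(as.integer(position), function(p) {
    i <- which(p >= from & p <= from + b$length - 1L)
    if (length(i) == 0) return(NA_integer_)
    to[i[1]] + (p - from[i[1]])
  })
}

#' Lift SNV calls from a source reference onto a target reference
#'
#' Maps each single-nucleotide variant through the block map and
#' re-references its alleles. A mapped variant whose target reference base
#' equals the alternate allele vanishes (`dropped_ref_equals_alt`: the
#' "variant" was a strain difference between the references). When the
#' target reference base differs from both alleles, the call is emitted
#' against the target reference base with status `re_referenced`. Unmapped
#' source positions yield status `dropped_unmapped` and appear in the drop
#' log, never silently.
#'
#' @param map A [build_block_map()] result (source -> target).
#' @param source_seq,target_seq The two reference sequences.
#' @param variants Tibble with columns `position`, `ref`, `alt`
#'   (single-base alleles on the source reference).
#' @return Tibble: input columns plus `target_position`, `target_ref`,
#'   `target_alt`, `status` (one of `mapped`, `re_referenced`,
#'   `dropped_unmapped`, `dropped_ref_equals_alt`).
#' @export
lift_variants <- function(map, source_seq, target_seq, variants) {
  source_seq <- toupper(as.character(source_seq))
  target_seq <- toupper(as.character(target_seq))
  variants <- tibble::as_tibble(variants)
  if (!all(c("position", "ref", "alt") %in% names(variants))) {
    rlang::abort("variants must have columns position, ref, alt.")
  }
  if (any(nchar(variants$ref) != 1 | nchar(variants$alt) != 1)) {
    rlang::abort("only single-base SNV alleles can be lifted.")
  }
  s_bases <- strsplit(source_seq, "")[[1]]
  t_bases <- strsplit(target_seq, "")[[1]]
  actual <- s_bases[variants$position]
  if (any(actual != toupper(variants$ref))) {
    i <- which(actual != toupper(variants$ref))[1]
    rlang::abort(sprintf(
      "source reference mismatch at position %d: supplied %s, sequence has %s.",
      variants$position[i], variants$ref[i], actual[i]))
  }
  tpos <- map_position(map, variants$position, "source_to_target")
  tref <- ifelse(is.na(tpos), NA_character_, t_bases[tpos])
  alt <- toupper(variants$alt)
  status <- dplyr::case_when(
    is.na(tpos) ~ "dropped_unmapped",
    tref == alt ~ "dropped_ref_equals_alt",
    TRUE ~ ifelse(tref == toupper(variants$ref), "mapped", "re_referenced")
  )
  dplyr::mutate(variants,
                target_position = tpos,
                target_ref = ifelse(status %in% c("mapped", "re_referenced"), tref, NA_character_),
                target_alt = ifelse(status %in% c("mapped", "re_referenced"), alt, NA_character_),
                status = status)
}

#' Write / read a block map as a chain-like TSV
#'
#' Three columns: `source_start`, `target_start`, `length`; header comments
#' carry names and lengths so the map round-trips.
#'
#' @param map A `block_map`.
#' @param path File path.
#' @export
write_block_map <- function(map, path) {
  hdr <- c(
    sprintf("# source=%s length=%d", map$source_name, map$source_length),
    sprintf("# target=%s length=%d", map$target_name, map$target_length),
    "source_start\ttarget_start\tlength")
  body <- sprintf("%d\t%d\t%d", map$blocks$source_start,
                  map$blocks$target_start, map$blocks$length)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_block_map
#' @return `read_block_map()` returns a `block_map` (unmapped positions
#'   reconstructed from the gaps between blocks).
#' @export
read_block_map <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta <- lines[startsWith(lines, "#")]
  get_len <- function(which) {
    m <- meta[grepl(paste0("^# ", which, "="), meta)]
    as.integer(sub(".*length=", "", m[1]))
  }
  get_name <- function(which) {
    m <- meta[grepl(paste0("^# ", which, "="), meta)]
    sub(" length=.*", "", sub(paste0("^# ", which, "="), "", m[1]))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)][-1]  # drop column header
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  blocks <- tibble::tibble(source_start = as.integer(f[, 1]),
                           target_start = as.integer(f[, 2]),
                           length = as.integer(f[, 3]))
  sl <- get_len("source"); tl <- get_len("target")
  covered_s <- unlist(purrr::pmap(blocks, function(source_start, target_start, length)
    seq.int(source_start, source_start + length - 1L)))
  covered_t <- unlist(purrr::pmap(blocks, function(source_start, target_start, length)
    seq.int(target_start, target_start + length - 1L)))
  structure(
    list(source_name = get_name("source"), target_name = get_name("target"),
         blocks = blocks,
         unmapped_source = setdiff(seq_len(sl), covered_s),
         unmapped_target = setdiff(seq_len(tl), covered_t),
         source_length = sl, target_length = tl, identity = NA_real_),
    class = "block_map")
}
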