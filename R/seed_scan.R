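#' @name seed_scan
#' @title Canonical miRNA seed-site scanning of 3'UTR sequences
#'
#' @description
#' Scans a 3'UTR for perfect Watson-Crick matches to a miRNA seed
#' (nucleotides 2-8) and classifies each locus into the canonical TargetScan
#' site types. On the UTR sense strand (5'->3') a site is built from the
#' reverse complement of the seed:
#'
#' * `8mer`: match to seed nt 2-8 followed by an A opposite miRNA position 1
#' * `7mer-m8`: match to seed nt 2-8, no t1 A
#' * `7mer-A1`: match to seed nt 2-7 followed by a t1 A
#' * `6mer`: match to seed nt 2-7 only
#'
#' Coordinates are 1-based inclusive on the UTR sense strand (the convention
#' in which printed site positions such as "1887-1893" are expressed). Each
#' UTR position belongs to at most one reported site; where interpretations
#' overlap the strongest type wins (8mer > 7mer-m8 > 7mer-A1 > 6mer).
NULL

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

# normalize a miRNA sequence to RNA (A/C/G/U), uppercase; validate
norm_mirna <- function(mirna) {
  x <- chartr("T", "U", toupper(as.character(mirna)))
  if (nchar(x) < 8L) stopf("miRNA sequence must be at least 8 nt")
  if (grepl("[^ACGU]", x)) stopf("miRNA sequence contains invalid characters")
  x
}

# normalize a UTR sequence to DNA (A/C/G/T), uppercase; validate
norm_utr <- function(utr) {
  x <- chartr("U", "T", toupper(as.character(utr)))
  if (grepl("[^ACGT]", x)) stopf("UTR sequence contains invalid characters")
  x
}

# reverse complement of an RNA fragment, written in DNA letters
rc_dna <- function(rna) {
  comp <- chartr("ACGU", "TGCA", rna)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# seed-derived match strings: rc6 (seed nt 2-7) and the complement of nt 8
seed_patterns <- function(mirna) {
  m <- norm_mirna(mirna)
  seed27 <- substr(m, 2L, 7L)
  m8 <- substr(m, 8L, 8L)
  list(
    rc6 = rc_dna(seed27),
    m8c = chartr("ACGU", "TGCA", m8),
    seed28 = substr(m, 2L, 8L)
  )
}

# full site sequence (DNA letters) for a given type
site_sequence <- function(patterns, site_type) {
  switch(site_type,
    "8mer"    = paste0(patterns$m8c, patterns$rc6, "A"),
    "7mer-m8" = paste0(patterns$m8c, patterns$rc6),
    "7mer-A1" = paste0(patterns$rc6, "A"),
    "6mer"    = patterns$rc6,
    stopf("unknown site type '%s'", site_type)
  )
}

site_span <- function(site_type) {
  c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)[[site_type]]
}

empty_sites <- function() {
  data.frame(
    utr_id = character(), start = integer(), end = integer(),
    site_type = character(), site_seq = character(),
    stringsAsFactors = FALSE
  )
}

#' Scan a 3'UTR for canonical miRNA seed-match sites
#'
#' @param mirna miRNA sequence, 5'->3', RNA or DNA letters, length >= 8.
#' @param utr UTR sequence (sense strand, 5'->3'), RNA or DNA letters.
#' @param utr_id identifier reported in the output table.
#' @return A data frame with one row per site: `utr_id`, `start`, `end`
#'   (1-based inclusive), `site_type` and `site_seq` (DNA letters), sorted
#'   by `start`.
#' @examples
#' seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "AAACTACCTCAAA")
#' @export
seed_sites <- function(mirna, utr, utr_id = "UTR") {
  pat <- seed_patterns(mirna)
  u <- norm_utr(utr)
  L <- nchar(u)
  if (L < 6L) stopf("UTR must be at least 6 nt")

  hits <- Biostrings::matchPattern(pat$rc6, Biostrings::DNAString(u))
  if (length(hits) == 0L) return(empty_sites())
  core_starts <- Biostrings::start(hits)

  # classify every seed-core locus by its flanking context
  cand <- lapply(core_starts, function(p) {
    prev_m8 <- p > 1L && substr(u, p - 1L, p - 1L) == pat$m8c
    next_a <- p + 6L <= L && substr(u, p + 6L, p + 6L) == "A"
    if (prev_m8 && next_a) {
      list(start = p - 1L, type = "8mer")
    } else if (prev_m8) {
      list(start = p - 1L, type = "7mer-m8")
    } else if (next_a) {
      list(start = p, type = "7mer-A1")
    } else {
      list(start = p, type = "6mer")
    }
  })
  starts <- vapply(cand, `[[`, integer(1), "start")
  types <- vapply(cand, `[[`, character(1), "type")
  ends <- starts + vapply(types, site_span, integer(1)) - 1L

  # strongest type wins; then leftmost
  ord <- order(match(types, SITE_TYPES), starts)
  keep <- logical(length(ord))
  occupied <- logical(L)
  for (i in ord) {
    span <- starts[i]:ends[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- data.frame(
    utr_id = utr_id,
    start = starts[keep],
    end = ends[keep],
    site_type = types[keep],
    site_seq = substring(u, starts[keep], ends[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply point mutations to a UTR and rescan for seed sites
#'
#' Emulates the mutant-reporter comparison used to validate an interaction
#' site: point substitutions are applied to the UTR and the seed scan is
#' repeated, reporting which sites are lost and gained.
#'
#' @inheritParams seed_sites
#' @param edits data frame with columns `position` (1-based) and `base`
#'   (single A/C/G/U/T character).
#' @return list with elements `before`, `after` (site tables), `lost`,
#'   `gained` (rows of `before`/`after` absent from the other), and
#'   `mutated_utr`.
#' @export
mutate_and_rescan <- function(mirna, utr, edits, utr_id = "UTR") {
  u <- norm_utr(utr)
  if (!is.data.frame(edits)) stopf("'edits' must be a data frame")
  if (nrow(edits) > 0) {
    if (!all(c("position", "base") %in% names(edits))) {
      stopf("'edits' needs columns 'position' and 'base'")
    }
    pos <- as.integer(edits$position)
    if (any(pos < 1L | pos > nchar(u))) stopf("edit position out of range")
    base <- vapply(as.character(edits$base), function(b) {
      b <- chartr("U", "T", toupper(b))
      if (!b %in% c("A", "C", "G", "T")) stopf("invalid replacement base '%s'", b)
      b
    }, character(1))
    for (i in seq_along(pos)) substr(u, pos[i], pos[i]) <- base[i]
  }
  before <- seed_sites(mirna, utr, utr_id)
  after <- seed_sites(mirna, u, utr_id)
  key <- function(d) paste(d$start, d$end, d$site_type)
  list(
    before = before,
    after = after,
    lost = before[!key(before) %in% key(after), , drop = FALSE],
    gained = after[!key(after) %in% key(before), , drop = FALSE],
    mutated_utr = u
  )
}

#' Export a seed-site table as BED intervals
#'
#' Converts the 1-based inclusive site coordinates into BED's 0-based
#' half-open convention.
#'
#' @param sites site table from [seed_sites()].
#' @return data frame with `chrom`, `chromStart`, `chromEnd`, `name`.
#' @export
sites_to_bed <- function(sites) {
  data.frame(
    chrom = sites$utr_id,
    chromStart = sites$start - 1L,
    chromEnd = sites$end,
    name = sites$site_type,
    stringsAsFactors = FALSE
  )
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
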