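# Reference sequences, read records, quality filtering, and alignment-free
# variant calling for directly sequenced or barcoded libraries.

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

#' Wild-type reference sequence
#'
#' Defines the wild-type nucleotide sequence and coordinate frame that all
#' reads are compared against. Variant calling is alignment-free: reads must
#' have the same length and start point as this sequence.
#'
#' @param sequence Uppercase DNA string (A/C/G/T only).
#' @param is_coding Logical; if `TRUE`, amino-acid changes are derived per
#'   codon using the standard genetic code.
#' @param frame_offset Integer; 0-based offset (in nucleotides) of the first
#'   codon. Positions before the offset are treated as non-coding.
#' @param position_offset Integer added to reported nucleotide positions, so
#'   variant labels can use coordinates of a larger construct.
#' @return An object of class `reference_sequence`.
#' @examples
#' ref <- reference_sequence("ATGAAA", is_coding = TRUE)
#' @export
reference_sequence <- function(sequence, is_coding = FALSE, frame_offset = 0L,
                               position_offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("reference sequence must contain only A/C/G/T")
  }
  frame_offset <- as.integer(frame_offset)
  if (is_coding && (nchar(sequence) - frame_offset) %% 3L != 0L) {
    stop("coding reference length minus frame_offset must be a multiple of 3")
  }
  structure(
    list(
      sequence = sequence,
      is_coding = isTRUE(is_coding),
      frame_offset = frame_offset,
      position_offset = as.integer(position_offset)
    ),
    class = "reference_sequence"
  )
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(
    "reference_sequence:", nchar(x$sequence), "nt,",
    if (x$is_coding) "coding" else "non-coding", "\n"
  )
  invisible(x)
}

#' Sequencing read with per-base qualities
#'
#' @param bases DNA string, possibly containing `N`.
#' @param qualities Integer vector of Phred quality scores, one per base.
#' @return An object of class `read_record`.
#' @export
read_record <- function(bases, qualities) {
  stopifnot(is.character(bases), length(bases) == 1L)
  qualities <- as.integer(qualities)
  if (nchar(bases) != length(qualities)) {
    stop("read bases and qualities must have equal length")
  }
  if (any(is.na(qualities)) || any(qualities < 0L)) {
    stop("qualities must be nonnegative Phred integers")
  }
  structure(list(bases = toupper(bases), qualities = qualities),
            class = "read_record")
}

#' Quality filter for a single read
#'
#' A read is accepted only if every base quality is at least `min_quality`
#' and the read contains no `N` bases. Empty reads are rejected.
#'
#' @param read A [read_record()].
#' @param min_quality Minimum Phred score required at every position
#'   (default 20).
#' @return `TRUE` if the read passes, `FALSE` otherwise.
#' @export
filter_read <- function(read, min_quality = 20L) {
  stopifnot(inherits(read, "read_record"))
  if (nchar(read$bases) == 0L) return(FALSE)
  if (grepl("N", read$bases, fixed = TRUE)) return(FALSE)
  all(read$qualities >= min_quality)
}

rev_comp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""
  ))
}

#' Merge overlapping paired-end reads
#'
#' The reverse read is reverse-complemented (with qualities reversed) and the
#' two reads are merged position by position over the full variable region.
#' Where the reads disagree, the base with the higher quality wins; the merged
#' quality is the maximum of the two. Disagreements at equal quality become
#' `N`, so ambiguous positions are caught by the downstream `N` filter instead
#' of producing a silent base call.
#'
#' @param fwd,rev Forward and reverse [read_record()]s. Both must cover the
#'   variable region completely (equal lengths); anything else is an error.
#' @return A merged [read_record()].
#' @export
merge_paired_reads <- function(fwd, rev) {
  stopifnot(inherits(fwd, "read_record"), inherits(rev, "read_record"))
  if (nchar(fwd$bases) != nchar(rev$bases)) {
    stop("paired reads must fully overlap the variable region (equal lengths)")
  }
  if (nchar(fwd$bases) == 0L) stop("cannot merge empty reads")
  fb <- strsplit(fwd$bases, "")[[1]]
  rb <- strsplit(rev_comp(rev$bases), "")[[1]]
  fq <- fwd$qualities
  rq <- rev(rev$qualities)
  out_b <- ifelse(fq >= rq, fb, rb)
  out_q <- pmax(fq, rq)
  tie <- fb != rb & fq == rq
  out_b[tie] <- "N"
  read_record(paste(out_b, collapse = ""), out_q)
}

# Protein-level change labels for a set of nucleotide substitutions.
protein_changes <- function(positions, alt_bases, ref) {
  coding_pos <- positions[positions > ref$frame_offset]
  coding_alt <- alt_bases[positions > ref$frame_offset]
  if (length(coding_pos) == 0L) return(character(0))
  mut <- strsplit(ref$sequence, "")[[1]]
  mut[coding_pos] <- coding_alt
  codons <- sort(unique((coding_pos - ref$frame_offset - 1L) %/% 3L + 1L))
  vapply(codons, function(ci) {
    start <- ref$frame_offset + (ci - 1L) * 3L + 1L
    ref_codon <- substr(ref$sequence, start, start + 2L)
    alt_codon <- paste(mut[start:(start + 2L)], collapse = "")
    ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
    alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
    if (ref_aa == alt_aa) {
      sprintf("p.%s%d=", AA_THREE[[ref_aa]], ci)
    } else {
      sprintf("p.%s%d%s", AA_THREE[[ref_aa]], ci, AA_THREE[[alt_aa]])
    }
  }, "")
}

#' Call a variant against the reference (alignment-free)
#'
#' Compares a read to the wild-type sequence position by position and returns
#' the ordered list of nucleotide substitutions with an HGVS-like label
#' (e.g. `"c.5A>G (p.Lys2Arg)"` for coding references). Reads identical to the
#' reference return the wild-type sentinel `"_wt"`. Reads whose length differs
#' from the reference cannot be called in alignment-free mode and raise an
#' error (callers tally them as rejected).
#'
#' @param read A [read_record()] or a plain DNA string.
#' @param ref A [reference_sequence()].
#' @return An object of class `variant_key` with elements `substitutions`
#'   (data frame of `position`, `ref`, `alt`), `label`, and `is_wildtype`.
#' @export
call_variant <- function(read, ref) {
  stopifnot(inherits(ref, "reference_sequence"))
  bases <- if (inherits(read, "read_record")) read$bases else toupper(read)
  if (nchar(bases) != nchar(ref$sequence)) {
    stop("read length differs from reference; cannot call without alignment")
  }
  rb <- strsplit(bases, "")[[1]]
  sb <- strsplit(ref$sequence, "")[[1]]
  pos <- which(rb != sb)
  subs <- data.frame(
    position = pos,
    ref = sb[pos],
    alt = rb[pos],
    stringsAsFactors = FALSE
  )
  label <- if (length(pos) == 0L) {
    "_wt"
  } else {
    nt <- sprintf("c.%d%s>%s", pos + ref$position_offset, sb[pos], rb[pos])
    lab <- paste(nt, collapse = ", ")
    if (ref$is_coding) {
      paa <- protein_changes(pos, rb[pos], ref)
      if (length(paa)) lab <- paste0(lab, " (", paste(paa, collapse = ", "), ")")
    }
    lab
  }
  structure(
    list(substitutions = subs, label = label, is_wildtype = length(pos) == 0L),
    class = "variant_key"
  )
}

#' Apply a variant's substitutions to the reference
#'
#' Reconstructs the variant nucleotide sequence, the inverse of
#' [call_variant()].
#'
#' @param key A `variant_key`.
#' @param ref The [reference_sequence()] the key was called against.
#' @return A DNA string.
#' @export
apply_variant <- function(key, ref) {
  stopifnot(inherits(key, "variant_key"), inherits(ref, "reference_sequence"))
  s <- strsplit(ref$sequence, "")[[1]]
  s[key$substitutions$position] <- key$substitutions$alt
  paste(s, collapse = "")
}

#' Read a FASTQ file
#'
#' Reads single-end FASTQ (Sanger Phred+33 qualities, optionally gzipped) into
#' a compact reads object used by [count_reads()].
#'
#' @param path Path to a FASTQ file.
#' @return An object of class `fastq_reads`: a list with character vector
#'   `bases` and list of integer vectors `qualities`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- unname(as.character(S4Vectors::mcols(x)$qualities))
  structure(
    list(
      bases = unname(as.character(x)),
      qualities = lapply(quals, function(q) utf8ToInt(q) - 33L)
    ),
    class = "fastq_reads"
  )
}

#' @export
length.fastq_reads <- function(x) length(x$bases)

as_reads <- function(reads) {
  if (inherits(reads, "fastq_reads")) return(reads)
  if (inherits(reads, "read_record")) reads <- list(reads)
  if (is.list(reads)) {
    stopifnot(all(vapply(reads, inherits, TRUE, "read_record")))
    return(structure(
      list(
        bases = vapply(reads, `[[`, "", "bases"),
        qualities = lapply(reads, `[[`, "qualities")
      ),
      class = "fastq_reads"
    ))
  }
  stop("reads must be a fastq_reads object or a list of read_record objects")
}

#' Read a barcode-to-variant map
#'
#' Two-column tab-separated file (barcode, variant label); many barcodes may
#' map to one variant, each barcode to exactly one.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: `names` are barcodes, values variant labels.
#' @export
read_barcode_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("barcode", "variant"))
  if (anyDuplicated(df$barcode)) {
    stop("barcode map contains duplicated barcodes")
  }
  stats::setNames(df$variant, df$barcode)
}

#' Count variants in a read stream
#'
#' Applies the quality filter, calls variants alignment-free (or resolves
#' barcodes through `barcode_map`), and tallies counts per variant. Every read
#' is accounted for: accepted counts plus rejection tallies (low quality /
#' contains `N`, wrong length, unmapped barcode) always sum to the input total.
#'
#' @param reads A `fastq_reads` object (see [read_fastq()]) or list of
#'   [read_record()]s.
#' @param ref A [reference_sequence()]; ignored in barcode mode.
#' @param barcode_map Optional named character vector from
#'   [read_barcode_map()]. When supplied, reads are treated as barcodes;
#'   unmapped barcodes are tallied and excluded.
#' @param min_quality Minimum Phred score at every position (default 20).
#' @return A data frame with columns `variant` and `count`, with an attribute
#'   `tallies` (named integer vector: `total`, `counted`, `low_quality`,
#'   `wrong_length`, `unmapped_barcode`).
#' @export
count_reads <- function(reads, ref = NULL, barcode_map = NULL,
                        min_quality = 20L) {
  reads <- as_reads(reads)
  n <- length(reads$bases)
  tallies <- c(total = n, counted = 0L, low_quality = 0L,
               wrong_length = 0L, unmapped_barcode = 0L)
  empty <- data.frame(variant = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "tallies") <- tallies
    return(empty)
  }
  min_q <- vapply(reads$qualities, function(q) {
    if (length(q) == 0L) -1L else min(q)
  }, 0L)
  ok <- min_q >= min_quality & !grepl("N", reads$bases, fixed = TRUE) &
    nchar(reads$bases) > 0L
  tallies["low_quality"] <- sum(!ok)
  bases <- reads$bases[ok]

  if (!is.null(barcode_map)) {
    hit <- bases %in% names(barcode_map)
    tallies["unmapped_barcode"] <- sum(!hit)
    labels <- unname(barcode_map[bases[hit]])
  } else {
    stopifnot(inherits(ref, "reference_sequence"))
    good_len <- nchar(bases) == nchar(ref$sequence)
    tallies["wrong_length"] <- sum(!good_len)
    bases <- bases[good_len]
    uniq <- unique(bases)
    uniq_label <- vapply(uniq, function(b) call_variant(b, ref)$label, "")
    labels <- unname(uniq_label[match(bases, uniq)])
  }
  tallies["counted"] <- length(labels)
  if (length(labels) == 0L) {
    attr(empty, "tallies") <- tallies
    return(empty)
  }
  tab <- table(labels)
  out <- data.frame(variant = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tallies") <- tallies
  out
}
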