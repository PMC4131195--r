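#' Genome objects
#'
#' A `genome` is a set of named contig sequences (uppercase A/C/G/T/N)
#' together with a per-contig topology flag (`"linear"` or `"circular"`).
#' All interval arithmetic in the package uses 0-based half-open
#' coordinates on the forward strand of these contigs.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences.
#' @param topology character vector of `"linear"`/`"circular"`, recycled
#'   or named by contig. Defaults to linear.
#' @return an object of class `genome`.
#' @export
genome <- function(seqs, topology = "linear") {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop_format("all contigs must be named")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop_format("duplicate contig id: ",
                                      ids[duplicated(ids)][1])
  if (length(seqs) == 0L) stop_format("genome has no contigs")
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) stop_format("contig ", ids[bad][1],
                            " contains characters outside {A,C,G,T,N}")
  if (is.null(names(topology))) {
    topology <- rep_len(topology, length(ids))
    names(topology) <- ids
  } else {
    topology <- topology[ids]
    topology[is.na(topology)] <- "linear"
    names(topology) <- ids
  }
  if (!all(topology %in% c("linear", "circular")))
    stop_usage("topology must be 'linear' or 'circular'")
  structure(list(seq = Biostrings::DNAStringSet(chr), topology = topology),
            class = "genome")
}

#' Read genome sequences from FASTA
#'
#' Lowercase input is uppercased and U (RNA) is mapped to T. IUPAC
#' ambiguity codes other than N are mapped to N with a warning; any other
#' character is an error. A contig is flagged circular when its FASTA
#' header contains the token `circular`.
#'
#' @param path path to a FASTA file.
#' @return a [genome] object.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop_format("malformed FASTA: ",
                                                   conditionMessage(e)))
  if (length(seqs) == 0L) stop_format("empty FASTA file: ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) stop_format("duplicate contig id: ",
                                      ids[duplicated(ids)][1])
  chr <- toupper(as.character(seqs))
  chr <- gsub("U", "T", chr, fixed = TRUE)
  if (any(grepl("[^A-Z]", chr))) stop_format("non-IUPAC character in ", path)
  iupac <- "RYSWKMBDHV"
  if (any(grepl(sprintf("[%s]", iupac), chr))) {
    warning("IUPAC ambiguity codes other than N mapped to N")
    chr <- chartr(iupac, strrep("N", nchar(iupac)), chr)
  }
  if (any(grepl("[^ACGTN]", chr)))
    stop_format("non-IUPAC character in ", path)
  names(chr) <- ids
  circ <- grepl("(^|\\s)circular(\\s|$)", headers, ignore.case = TRUE)
  genome(chr, topology = ifelse(circ, "circular", "linear"))
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x$seq), "contig(s)\n")
  for (id in names(x$seq))
    cat(sprintf("  %s: %d bp (%s)\n", id, Biostrings::width(x$seq)[
      match(id, names(x$seq))], x$topology[[id]]))
  invisible(x)
}

#' Contig lengths of a genome
#' @param g a [genome].
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(g) {
  stats::setNames(Biostrings::width(g$seq), names(g$seq))
}

#' Construct a sequence region
#'
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param contig contig id.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return a `seq_region` list.
#' @export
seq_region <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop_usage("invalid region: need 0 <= start < end")
  if (!strand %in% c("+", "-", ".")) stop_usage("invalid strand: ", strand)
  structure(list(contig = as.character(contig), start = start, end = end,
                 strand = strand), class = "seq_region")
}

## forward-strand sequence of [start, end) on a contig
contig_subseq <- function(g, contig, start, end) {
  len <- contig_lengths(g)[[contig]]
  if (is.null(len)) stop_usage("unknown contig: ", contig)
  if (start < 0L || end > len) stop_usage("region outside contig ", contig)
  as.character(Biostrings::subseq(g$seq[[contig]], start + 1L, end))
}

#' Extract the strand-sense sequence of a region
#'
#' @param g a [genome].
#' @param region a [seq_region] (or list with contig/start/end/strand).
#' @return character scalar, reverse-complemented for minus-strand regions.
#' @export
region_seq <- function(g, region) {
  s <- contig_subseq(g, region$contig, region$start, region$end)
  if (identical(region$strand, "-")) revcomp_chr(s) else s
}

genetic_code_table <- function(table_id) {
  if (identical(table_id, "uag_trp")) {
    code <- Biostrings::getGeneticCode("1")
    code[["TAG"]] <- "W"
    return(code)
  }
  id <- as.character(table_id)
  code <- tryCatch(Biostrings::getGeneticCode(id),
                   error = function(e) NULL)
  if (is.null(code)) stop_usage("unknown translation table id: ", table_id)
  code
}

## translate an uppercase ACGTN string; stops as "*", N-codons as "X"
translate_chr <- function(nt, table_id = 1) {
  code <- genetic_code_table(table_id)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a genomic region
#'
#' Minus-strand regions are reverse-complemented before translation.
#' A trailing partial codon is dropped with a warning; codons containing
#' N translate to `X` and stop codons render as `*`.
#'
#' @param g a [genome].
#' @param region a [seq_region].
#' @param table_id an NCBI genetic-code table id (e.g. `1`, `4`), or
#'   `"uag_trp"` for the standard code with UAG read as Trp (as in the
#'   reassigned code of some highly reduced endosymbiont genomes).
#' @return amino-acid string.
#' @export
translate_region <- function(g, region, table_id = 1) {
  nt <- region_seq(g, region)
  if (nchar(nt) %% 3L != 0L) {
    warning("region length not divisible by 3; trailing partial codon dropped")
    nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
  }
  translate_chr(nt, table_id)
}

#' Reverse-complement a whole genome
#'
#' Utility for strand-symmetry checks: every contig is reverse
#' complemented, so a feature at `[start, end)` maps to
#' `[L - end, L - start)` with flipped strand.
#'
#' @param g a [genome].
#' @return a [genome] with every contig reverse-complemented.
#' @export
reverse_complement_genome <- function(g) {
  seqs <- as.character(Biostrings::reverseComplement(g$seq))
  names(seqs) <- names(g$seq)
  genome(seqs, topology = g$topology)
}

#' Write a genome to FASTA
#' @param g a [genome].
#' @param path output path.
#' @return `path`, invisibly. Circular contigs carry a `circular` token in
#'   their header.
#' @export
write_genome <- function(g, path) {
  hdr <- ifelse(g$topology == "circular",
                paste(names(g$seq), "circular"), names(g$seq))
  x <- g$seq
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
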