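#' Acceptor-stem pairing map
#'
#' Pair positions are 0-based within the tmRNA sequence. The default map
#' for a one-piece tmRNA of length `L` ending in `NCCA` (discriminator
#' at `L - 4`) pairs stem position `i` (`i = 0..6` from the 5' end) with
#' `L - 5 - i`.
#'
#' @param five_prime_index,three_prime_index paired 0-based positions,
#'   `five_prime_index < three_prime_index` pairwise.
#' @return a `stem_map` data.frame.
#' @export
stem_map <- function(five_prime_index, three_prime_index) {
  df <- data.frame(five_prime_index = as.integer(five_prime_index),
                   three_prime_index = as.integer(three_prime_index))
  if (any(df$five_prime_index < 0L) ||
      any(df$five_prime_index >= df$three_prime_index))
    stop_usage("stem map needs 0 <= five_prime_index < three_prime_index")
  structure(df, class = c("stem_map", "data.frame"))
}

default_stem_map <- function(L) {
  stem_map(0:6, L - 5L - 0:6)
}

classify_pair <- function(b5, b3) {
  p <- paste0(b5, b3)
  if (p == "GC") "canonical_GC"
  else if (p %in% c("CG", "AT", "TA")) "watson_crick"
  else if (p %in% c("GT", "TG")) "wobble_GU"
  else "non_pairing"
}

#' Check acceptor-stem base pairing of a tmRNA sequence
#'
#' Classifies each stem pair: the canonical closing pair is exactly G:C;
#' other Watson-Crick pairs (A:U, U:A, C:G) and G:U wobbles are reported
#' as such, anything else as non-pairing. The alanylation determinant
#' check (by analogy to the tRNA-Ala G3:U70 identity element) asks
#' whether the pair at stem index 2 is G:U in that order.
#'
#' @param seq tmRNA nucleotide sequence (DNA or RNA letters).
#' @param stem a [stem_map()]; when omitted the sequence must end in CCA
#'   and the default map for a one-piece tmRNA is applied.
#' @return a `pair_report`: list with `pairs` (per-pair data.frame of
#'   bases and class, U shown as T) and `determinant_3_70`.
#' @export
check_acceptor_pairs <- function(seq, stem = NULL) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  L <- nchar(s)
  if (is.null(stem)) {
    if (!endsWith(s, "CCA"))
      stop_usage("sequence does not end in CCA; supply an explicit ",
                 "stem_map")
    stem <- default_stem_map(L)
  }
  if (max(stem$three_prime_index) >= L)
    stop_usage("stem map index beyond sequence length")
  ch <- strsplit(s, "")[[1]]
  b5 <- ch[stem$five_prime_index + 1L]
  b3 <- ch[stem$three_prime_index + 1L]
  pairs <- data.frame(stem_index = seq_len(nrow(stem)) - 1L,
                      five_prime_index = stem$five_prime_index,
                      three_prime_index = stem$three_prime_index,
                      five_base = b5, three_base = b3,
                      class = mapply(classify_pair, b5, b3,
                                     USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  det <- nrow(pairs) >= 3L && pairs$five_base[3] == "G" &&
    pairs$three_base[3] == "T"
  structure(list(pairs = pairs, determinant_3_70 = det),
            class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat("acceptor-stem pair report\n")
  print.data.frame(x$pairs)
  cat("3:70-style G:U determinant:", x$determinant_3_70, "\n")
  invisible(x)
}

#' Read a gapped multiple alignment from aligned FASTA
#' @param path aligned FASTA (rows of equal gapped length).
#' @return named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(x))
  names(rows) <- sub("\\s.*$", "", names(x))
  if (length(unique(nchar(rows))) != 1L)
    stop_format("alignment rows differ in length")
  rows
}

## per-frame codon-by-sequence amino-acid matrices projected through
## the alignment onto the reference row's ungapped coordinates
project_codons <- function(alnmat, ref_cols, frame, code) {
  n_codons <- (length(ref_cols) - frame) %/% 3L
  if (n_codons < 1L) return(NULL)
  aa <- matrix(NA_character_, nrow = nrow(alnmat), ncol = n_codons)
  for (j in seq_len(n_codons)) {
    cols <- ref_cols[frame + (j - 1L) * 3L + 1:3]
    tri <- alnmat[, cols, drop = FALSE]
    cod <- paste0(tri[, 1], tri[, 2], tri[, 3])
    ok <- !grepl("-", cod, fixed = TRUE)
    aa[ok, j] <- unname(code[cod[ok]])
    aa[ok, j][is.na(aa[ok, j])] <- "X"
  }
  aa
}

modal_score <- function(col) {
  col <- col[!is.na(col)]
  if (!length(col)) return(c(NA_real_, NA))
  tab <- sort(table(col), decreasing = TRUE)
  c(tab[[1]] / length(col), names(tab)[1])
}

#' Identify the tag reading frame by cross-strain conservation
#'
#' Scans every frame offset and window position on the reference row's
#' ungapped coordinates, projecting codon columns through the alignment
#' and translating each sequence (codons touching a gap are scored
#' missing). A codon column scores the fraction of non-missing
#' sequences agreeing with the modal amino acid; a window scores the
#' mean over its codon columns. The maximizing (frame, window) is
#' returned, ties broken by smaller frame offset then leftmost window.
#'
#' @param alignment gapped nucleotide alignment: named character vector
#'   of equal-length rows (>= 3 sequences).
#' @param reference_row index of the reference sequence.
#' @param window_codons window width in codons.
#' @param table_id genetic-code table (see [translate_region()]).
#' @return a `frame_result`: list with `frame` (0/1/2), `start`/`end`
#'   (0-based ungapped reference nt bounds of the best window), `score`,
#'   `frame_scores` (best score per frame), and `stop_codons`
#'   (window codon indices whose modal residue is a stop).
#' @export
find_tag_frame <- function(alignment, reference_row = 1L,
                           window_codons = 20L, table_id = 1) {
  rows <- toupper(unlist(alignment))
  if (length(rows) < 3L)
    stop_usage("conservation is undefined with fewer than 3 sequences")
  rows <- gsub("U", "T", rows, fixed = TRUE)
  if (length(unique(nchar(rows))) != 1L)
    stop_format("alignment rows differ in length")
  alnmat <- do.call(rbind, strsplit(rows, ""))
  ref_cols <- which(alnmat[reference_row, ] != "-")
  if (length(ref_cols) < 3L * window_codons)
    stop_usage("reference row shorter than one window")
  code <- genetic_code_table(table_id)
  best <- NULL
  frame_scores <- stats::setNames(rep(NA_real_, 3L), paste0("frame", 0:2))
  for (frame in 0:2) {
    aa <- project_codons(alnmat, ref_cols, frame, code)
    if (is.null(aa) || ncol(aa) < window_codons) next
    ms <- apply(aa, 2L, modal_score)
    cod_score <- as.numeric(ms[1L, ])
    modal <- ms[2L, ]
    n_win <- ncol(aa) - window_codons + 1L
    for (w in seq_len(n_win)) {
      sc <- cod_score[w:(w + window_codons - 1L)]
      if (all(is.na(sc))) next    # all-gap projection: window skipped
      s <- mean(sc, na.rm = TRUE)
      if (!is.na(frame_scores[frame + 1L]) &&
          s <= frame_scores[frame + 1L]) { } else
        frame_scores[frame + 1L] <- s
      if (is.null(best) || s > best$score + 1e-12) {
        stops <- which(!is.na(modal[w:(w + window_codons - 1L)]) &
                         modal[w:(w + window_codons - 1L)] == "*")
        best <- list(frame = frame,
                     start = frame + (w - 1L) * 3L,
                     end = frame + (w - 1L + window_codons) * 3L,
                     score = s, stop_codons = stops)
      }
    }
  }
  if (is.null(best)) stop_format("no scorable window in alignment")
  best$frame_scores <- frame_scores
  structure(best, class = "frame_result")
}

#' @export
print.frame_result <- function(x, ...) {
  cat(sprintf("tag frame %d, window [%d, %d), conservation %.3f\n",
              x$frame, x$start, x$end, x$score))
  if (length(x$stop_codons))
    cat("modal stop codon(s) at window codon(s):",
        paste(x$stop_codons, collapse = ", "), "\n")
  invisible(x)
}

## per-reference-position identity indicator from a global alignment of
## one frame's translation against the reference protein
ref_match_profile <- function(trans, ref) {
  chars <- unique(strsplit(paste0(trans, ref, "X*"), "")[[1]])
  sm <- matrix(-1, length(chars), length(chars),
               dimnames = list(chars, chars))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BString(trans),
    subject = Biostrings::BString(ref), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  m <- logical(nchar(ref))
  pat_pos <- integer(nchar(ref))  # pattern (translation) residue index
  r <- 0L; q <- 0L
  for (i in seq_along(s)) {
    if (p[i] != "-") q <- q + 1L
    if (s[i] != "-") {
      r <- r + 1L
      m[r] <- p[i] == s[i]
      pat_pos[r] <- if (p[i] != "-") q else NA_integer_
    }
  }
  list(match = m, pat_pos = pat_pos)
}

#' Assess the integrity of a candidate protein-coding gene
#'
#' Translates the region in all three frames, aligns each translation
#' globally to a reference protein and classifies the gene:
#' `intact` when a single frame covers at least `min_cover` of the
#' reference with no internal stop; `pseudogene_stops` when the
#' covering frame contains internal stop codons; `frameshifted` when no
#' single frame covers but an ordered pair of frames jointly does, with
#' a single breakpoint; otherwise `truncated`, reporting the reference
#' residues left uncovered at each end.
#'
#' @param nt_seq nucleotide sequence of the candidate gene region
#'   (reading sense).
#' @param ref_protein reference amino-acid sequence.
#' @param table_id genetic-code table id.
#' @param min_cover fraction of reference residues that must be matched.
#' @return an `integrity_report`: list with `verdict`,
#'   `internal_stops` (codon indices in the covering frame),
#'   `frameshift` (list of `breakpoint` in reference codon units,
#'   `frame_before`, `frame_after`, or NULL), `n_truncation`,
#'   `c_truncation` and per-frame `coverage`.
#' @export
orf_integrity <- function(nt_seq, ref_protein, table_id = 1,
                          min_cover = 0.9) {
  nt <- gsub("U", "T", toupper(nt_seq), fixed = TRUE)
  ref <- toupper(ref_protein)
  R <- nchar(ref)
  trans <- lapply(0:2, function(f) {
    sub <- substr(nt, f + 1L, nchar(nt))
    translate_chr(substr(sub, 1L, (nchar(sub) %/% 3L) * 3L), table_id)
  })
  prof <- lapply(trans, function(tr)
    if (nchar(tr) == 0L) list(match = logical(R),
                              pat_pos = rep(NA_integer_, R))
    else ref_match_profile(tr, ref))
  coverage <- vapply(prof, function(p) mean(p$match), 0)
  names(coverage) <- paste0("frame", 0:2)
  report <- function(verdict, stops = integer(), fs = NULL,
                     ntr = 0L, ctr = 0L)
    structure(list(verdict = verdict, internal_stops = stops,
                   frameshift = fs, n_truncation = ntr,
                   c_truncation = ctr, coverage = coverage),
              class = "integrity_report")
  fbest <- which.max(coverage)
  if (coverage[fbest] >= min_cover) {
    p <- prof[[fbest]]
    hits <- which(p$match)
    span <- range(p$pat_pos[hits], na.rm = TRUE)
    stops <- which(strsplit(trans[[fbest]], "")[[1]] == "*")
    stops <- stops[stops >= span[1] & stops < span[2]]
    if (length(stops)) return(report("pseudogene_stops", stops = stops))
    return(report("intact"))
  }
  ## frameshift scan: prefix of one frame + suffix of another
  best_fs <- NULL
  for (f1 in 1:3) for (f2 in 1:3) {
    if (f1 == f2) next
    s1 <- cumsum(prof[[f1]]$match)
    s2 <- cumsum(prof[[f2]]$match)
    tot2 <- s2[R]
    sc <- s1[1:(R - 1L)] + tot2 - s2[1:(R - 1L)]
    b <- which.max(sc)
    if (is.null(best_fs) || sc[b] > best_fs$score)
      best_fs <- list(score = sc[b], breakpoint = b,
                      frame_before = f1 - 1L, frame_after = f2 - 1L)
  }
  if (!is.null(best_fs) && best_fs$score / R >= min_cover)
    return(report("frameshifted",
                  fs = best_fs[c("breakpoint", "frame_before",
                                 "frame_after")]))
  hits <- which(prof[[fbest]]$match)
  if (!length(hits)) return(report("truncated", ntr = R, ctr = 0L))
  report("truncated", ntr = hits[1] - 1L, ctr = R - hits[length(hits)])
}

#' @export
print.integrity_report <- function(x, ...) {
  cat("ORF integrity verdict:", x$verdict, "\n")
  if (length(x$internal_stops))
    cat("internal stop codon(s) at:",
        paste(x$internal_stops, collapse = ", "), "\n")
  if (!is.null(x$frameshift))
    cat(sprintf("frameshift near reference codon %d (frame %d -> %d)\n",
                x$frameshift$breakpoint, x$frameshift$frame_before,
                x$frameshift$frame_after))
  if (x$verdict == "truncated")
    cat(sprintf("uncovered: %d N-terminal, %d C-terminal residue(s)\n",
                x$n_truncation, x$c_truncation))
  invisible(x)
}

#' Score presence of alignment regions per sequence
#'
#' A named region (column range) is absent for a sequence when its gap
#' fraction over those columns reaches `gap_threshold`. Also reports,
#' per sequence, the residue count beyond the last region column
#' (C-terminal extensions).
#'
#' @param alignment gapped amino-acid alignment (named character vector
#'   of equal-length rows).
#' @param regions named list of `c(start, end)` 1-based column ranges.
#' @param gap_threshold gap fraction at or above which a region is
#'   absent.
#' @param reference_row index of a reference sequence that must be
#'   ungapped over every region.
#' @return a `region_report`: list with `presence` (sequence x region
#'   matrix of `"present"`/`"absent"`) and `extensions` (named integer).
#' @export
region_presence <- function(alignment, regions, gap_threshold = 0.8,
                            reference_row = 1L) {
  rows <- toupper(unlist(alignment))
  if (length(unique(nchar(rows))) != 1L)
    stop_format("alignment rows differ in length")
  width <- nchar(rows[1])
  alnmat <- do.call(rbind, strsplit(rows, ""))
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop_usage("regions must be named")
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (r[1] < 1L || r[2] > width || r[1] > r[2])
      stop_usage("region ", nm, " outside alignment columns")
    if (any(alnmat[reference_row, r[1]:r[2]] == "-"))
      stop_usage("reference row is gapped over region ", nm)
  }
  presence <- matrix("present", nrow = nrow(alnmat),
                     ncol = length(regions),
                     dimnames = list(names(rows), names(regions)))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    gapfrac <- rowMeans(alnmat[, r[1]:r[2], drop = FALSE] == "-")
    presence[gapfrac >= gap_threshold, nm] <- "absent"
  }
  last_col <- max(vapply(regions, `[`, 0, 2L))
  ext <- if (last_col < width)
    rowSums(alnmat[, (last_col + 1L):width, drop = FALSE] != "-")
  else rep(0L, nrow(alnmat))
  structure(list(presence = presence,
                 extensions = stats::setNames(as.integer(ext),
                                              names(rows)),
                 gap_threshold = gap_threshold),
            class = "region_report")
}
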