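#' Merge overlapping gene calls into union hits
#'
#' Collapses the transitive closure of >= 1 bp overlap among call regions
#' into union intervals, the unit at which raw predictor output is
#' evaluated. Merging is strand-blind by default; two-piece tmRNA calls
#' contribute each region separately.
#'
#' @param calls a [gene_calls] table.
#' @param strand_mode `"ignore"` (default): calls on opposite strands may
#'   merge; `"require_same"`: merging is done per strand.
#' @return a `merged_hits` data.frame with columns `contig`, `start`,
#'   `end`, `strand` (`.` under `"ignore"`), `n_members`, `members`
#'   (list column of member call ids) and `source_family` (sorted unique
#'   member sources joined with `+`), sorted by position.
#' @export
merge_calls <- function(calls, strand_mode = c("ignore", "require_same")) {
  strand_mode <- match.arg(strand_mode)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_members = integer(), source_family = character(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (is.null(calls) || nrow(calls) == 0L)
    return(structure(empty, class = c("merged_hits", "data.frame")))
  key <- if (strand_mode == "ignore") calls$contig
         else paste(calls$contig, calls$strand)
  out <- lapply(split(seq_len(nrow(calls)), key), function(ix) {
    ir <- IRanges::IRanges(calls$start[ix] + 1L, calls$end[ix])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    mem <- split(calls$id[ix][S4Vectors::queryHits(hit)],
                 S4Vectors::subjectHits(hit))
    src <- split(calls$source[ix][S4Vectors::queryHits(hit)],
                 S4Vectors::subjectHits(hit))
    d <- data.frame(contig = calls$contig[ix[1]],
                    start = BiocGenerics::start(red) - 1L,
                    end = BiocGenerics::end(red),
                    strand = if (strand_mode == "ignore") "."
                             else calls$strand[ix[1]],
                    n_members = vapply(mem, function(m)
                      length(unique(m)), 0L),
                    source_family = vapply(src, function(s)
                      paste(sort(unique(s)), collapse = "+"), ""),
                    stringsAsFactors = FALSE)
    d$members <- lapply(mem, unique)
    d
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("merged_hits", "data.frame"))
}

#' @export
`[.merged_hits` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "members" %in% names(out))
    class(out) <- c("merged_hits", "data.frame")
  out
}

as_reconciled <- function(calls, status, reason = NA_character_) {
  calls <- as.data.frame(calls)
  calls$status <- status
  calls$rejection_reason <- reason
  structure(calls, class = c("reconciled_calls", "data.frame"))
}

bind_reconciled <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
  if (!length(parts)) {
    out <- as.data.frame(gene_calls())
    out$status <- character()
    out$rejection_reason <- character()
    return(structure(out, class = c("reconciled_calls", "data.frame")))
  }
  cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(d) {
    for (col in setdiff(cols, names(d))) d[[col]] <- NA
    as.data.frame(d)[, cols, drop = FALSE]
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$contig, out$start, out$end, out$id, out$part), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("reconciled_calls", "data.frame"))
}

## same-strand >= 1 bp overlap with any row of `others`; optional
## anticodon agreement when both sides report one
corroborated <- function(row, others, check_anticodon = TRUE) {
  if (nrow(others) == 0L) return(FALSE)
  cand <- others$contig == row$contig & others$strand == row$strand &
    pmin(row$end, others$end) - pmax(row$start, others$start) >= 1L
  if (check_anticodon && !is.na(row$anticodon)) {
    ac <- others$anticodon
    cand <- cand & (is.na(ac) | ac == row$anticodon)
  }
  any(cand)
}

#' Classify tRNA calls as valid or questionable
#'
#' A tRNAscan-SE call is *valid* when its Cove score is strictly above
#' `cove_min`, it is not flagged Pseudo or Undetermined, and a second
#' predictor corroborates it with a >= 1 bp same-strand overlap (with
#' anticodon agreement when both callers report one). Every remaining
#' tRNA call from either source is *questionable*; corroborating calls
#' absorbed by a valid gene are dropped and identical intervals are
#' deduplicated so each questionable interval appears once.
#'
#' @param trnascan_calls [gene_calls] carrying Cove scores (and
#'   Pseudo/Undetermined flags) from tRNAscan-SE.
#' @param corroborating_calls tRNA-type [gene_calls] from a second
#'   predictor (e.g. ARAGORN).
#' @param cove_min Cove score cutoff; the comparison is strict (`>`).
#' @param check_anticodon require anticodon agreement when both callers
#'   report one.
#' @return a `reconciled_calls` data.frame with `status`
#'   (`tRNA_valid`/`tRNA_questionable`) and `rejection_reason` columns.
#' @export
classify_trnas <- function(trnascan_calls, corroborating_calls,
                           cove_min = 50, check_anticodon = TRUE) {
  ts <- trnascan_calls[trnascan_calls$type == "tRNA", , drop = FALSE]
  co <- corroborating_calls[corroborating_calls$type == "tRNA", ,
                            drop = FALSE]
  if (nrow(ts) && anyNA(ts$score))
    warning(sum(is.na(ts$score)),
            " tRNAscan call(s) without Cove score classified questionable")
  valid <- logical(nrow(ts))
  for (i in seq_len(nrow(ts))) {
    row <- ts[i, ]
    valid[i] <- !is.na(row$score) && row$score > cove_min &&
      !row$pseudo && !row$undetermined &&
      corroborated(row, co, check_anticodon)
  }
  vt <- ts[valid, , drop = FALSE]
  quest_ts <- ts[!valid, , drop = FALSE]
  ## corroborating calls absorbed by a valid gene are the same gene
  absorbed <- logical(nrow(co))
  for (i in seq_len(nrow(co)))
    absorbed[i] <- corroborated(co[i, ], vt, check_anticodon = FALSE)
  quest_co <- co[!absorbed, , drop = FALSE]
  quest <- rbind(as.data.frame(quest_ts), as.data.frame(quest_co))
  if (nrow(quest))
    quest <- quest[!duplicated(quest[, c("contig", "start", "end",
                                         "strand")]), , drop = FALSE]
  bind_reconciled(
    if (nrow(vt)) as_reconciled(vt, "tRNA_valid"),
    if (nrow(quest)) as_reconciled(quest, "tRNA_questionable"))
}

## sliding-window Hamming distances of motif over a character vector
hamming_scan <- function(win_chars, motif_chars) {
  n <- length(win_chars); m <- length(motif_chars)
  if (n < m) return(integer(0))
  k <- n - m + 1L
  mm <- integer(k)
  for (j in seq_len(m))
    mm <- mm + (win_chars[j:(j + k - 1L)] != motif_chars[j])
  mm
}

best_motif_match <- function(win_chars, motifs, max_mismatch, anchor,
                             boundary = c("start", "end")) {
  boundary <- match.arg(boundary)
  best <- NULL
  for (i in seq_len(nrow(motifs))) {
    mc <- strsplit(motifs$seq[i], "")[[1]]
    mm <- hamming_scan(win_chars, mc)
    ok <- which(mm <= max_mismatch)
    if (!length(ok)) next
    bnd <- if (boundary == "start") ok - 1L else ok - 1L + length(mc)
    for (j in order(mm[ok], abs(bnd - anchor))[1]) {
      cand <- list(pos = ok[j] - 1L, mismatches = mm[ok[j]],
                   motif = motifs$label[i], len = length(mc),
                   boundary = bnd[j])
      if (is.null(best) || cand$mismatches < best$mismatches ||
          (cand$mismatches == best$mismatches &&
             abs(cand$boundary - anchor) < abs(best$boundary - anchor)))
        best <- cand
    }
  }
  best
}

#' Refine tmRNA gene termini against a terminus-motif database
#'
#' Searches the candidate region extended by `flank` nt on each side for
#' the best occurrence (sliding-window Hamming distance, at most
#' `max_mismatch` mismatches) of any 5' motif and any 3' motif, in the
#' reading sense dictated by the candidate strand. The region is trimmed
#' or extended to the outermost matched motif boundaries; ties are broken
#' by fewer mismatches, then by proximity to the original boundary. A
#' terminus class with no acceptable match leaves that boundary
#' unchanged and is reported as unrefined.
#'
#' @param genome a [genome].
#' @param candidate a [seq_region] for the candidate gene.
#' @param terminus_db data.frame with columns `label`
#'   (`five_prime`/`three_prime`) and `seq` (10-40 nt motifs); see
#'   [read_terminus_db()].
#' @param max_mismatch maximum Hamming mismatches per motif.
#' @param flank nt searched beyond each candidate boundary.
#' @return list with `region` (the refined [seq_region]) and `report`
#'   (one row per terminus class: `refined`, `motif`, `mismatches`,
#'   `shift` = signed boundary movement in reading-sense nt).
#' @export
refine_termini <- function(genome, candidate, terminus_db,
                           max_mismatch = 2L, flank = 100L) {
  check_terminus_db(terminus_db)
  len <- contig_lengths(genome)[[candidate$contig]]
  ws <- max(0L, candidate$start - as.integer(flank))
  we <- min(len, candidate$end + as.integer(flank))
  win <- contig_subseq(genome, candidate$contig, ws, we)
  minus <- identical(candidate$strand, "-")
  if (minus) win <- revcomp_chr(win)
  wc <- strsplit(win, "")[[1]]
  ## candidate boundaries in reading-sense window offsets
  off5 <- if (minus) we - candidate$end else candidate$start - ws
  off3 <- off5 + (candidate$end - candidate$start)
  five <- terminus_db[terminus_db$label == "five_prime", , drop = FALSE]
  three <- terminus_db[terminus_db$label == "three_prime", , drop = FALSE]
  b5 <- best_motif_match(wc, five, max_mismatch, off5, "start")
  b3 <- best_motif_match(wc, three, max_mismatch, off3, "end")
  new5 <- if (!is.null(b5)) b5$boundary else off5
  new3 <- if (!is.null(b3)) b3$boundary else off3
  if (new5 >= new3) { # degenerate refinement: keep the original extent
    new5 <- off5; new3 <- off3; b5 <- NULL; b3 <- NULL
  }
  gs <- if (minus) we - new3 else ws + new5
  ge <- if (minus) we - new5 else ws + new3
  report <- data.frame(
    class = c("five_prime", "three_prime"),
    refined = c(!is.null(b5), !is.null(b3)),
    motif = c(if (is.null(b5)) NA_character_ else b5$motif,
              if (is.null(b3)) NA_character_ else b3$motif),
    mismatches = c(if (is.null(b5)) NA_integer_ else b5$mismatches,
                   if (is.null(b3)) NA_integer_ else b3$mismatches),
    shift = c(new5 - off5, new3 - off3),
    stringsAsFactors = FALSE)
  list(region = seq_region(candidate$contig, gs, ge, candidate$strand),
       report = report)
}

check_terminus_db <- function(db) {
  if (!is.data.frame(db) || !all(c("label", "seq") %in% names(db)))
    stop_usage("terminus_db needs columns label, seq")
  if (!all(db$label %in% c("five_prime", "three_prime")))
    stop_usage("terminus labels must be five_prime/three_prime")
  n <- nchar(db$seq)
  if (any(n < 10L | n > 40L))
    stop_usage("terminus motifs must be 10-40 nt")
  invisible(db)
}

#' Read a terminus-motif database from FASTA
#'
#' Headers must carry a `five_prime` or `three_prime` token.
#'
#' @param path FASTA file of terminus motifs (10-40 nt).
#' @return data.frame with columns `label`, `seq`.
#' @export
read_terminus_db <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  label <- ifelse(grepl("five_prime", hdr), "five_prime",
                  ifelse(grepl("three_prime", hdr), "three_prime",
                         NA_character_))
  if (anyNA(label))
    stop_format("terminus FASTA headers must contain five_prime or ",
                "three_prime")
  db <- data.frame(label = label,
                   seq = gsub("U", "T", toupper(as.character(x)),
                              fixed = TRUE),
                   stringsAsFactors = FALSE)
  check_terminus_db(db)
}

## does the region set contain both terminus classes (<= max_mismatch)?
terminus_classes_found <- function(genome, rows, terminus_db,
                                   max_mismatch) {
  found <- c(five_prime = FALSE, three_prime = FALSE)
  for (i in seq_len(nrow(rows))) {
    s <- region_seq(genome, list(contig = rows$contig[i],
                                 start = rows$start[i], end = rows$end[i],
                                 strand = rows$strand[i]))
    sc <- strsplit(s, "")[[1]]
    for (lab in c("five_prime", "three_prime")) {
      if (found[[lab]]) next
      motifs <- terminus_db[terminus_db$label == lab, , drop = FALSE]
      for (j in seq_len(nrow(motifs))) {
        mm <- hamming_scan(sc, strsplit(motifs$seq[j], "")[[1]])
        if (length(mm) && min(mm) <= max_mismatch) {
          found[[lab]] <- TRUE
          break
        }
      }
    }
  }
  sum(found)
}

#' Resolve duplicate and conflicting tmRNA calls
#'
#' A tmRNA call is rejected with reason `overlaps_valid_trna` when it
#' overlaps a valid tRNA by >= 1 bp on either strand (questionable tRNAs
#' never cause rejection), and with reason `missing_terminus` when fewer
#' than two terminus-motif classes are found within its extent (the
#' pseudogene signature of a gene missing one end). Remaining calls are
#' accepted; when one replicon carries more than one accepted tmRNA all
#' are kept and flagged `multi_allele`.
#'
#' @param tmrna_calls tmRNA-type [gene_calls] (one- or two-piece).
#' @param valid_trnas a `reconciled_calls` table from [classify_trnas()]
#'   (only rows with status `tRNA_valid` are used) or a plain
#'   [gene_calls] table of trusted tRNAs.
#' @param terminus_db optional terminus database (see
#'   [read_terminus_db()]); with `genome`, enables the missing-terminus
#'   check.
#' @param genome the [genome], required for the terminus check.
#' @param max_mismatch Hamming tolerance for terminus motifs.
#' @return a `reconciled_calls` data.frame with `status`
#'   (`tmRNA_accepted`/`rejected`), `rejection_reason` and a logical
#'   `multi_allele` column.
#' @export
resolve_tmrna_duplicates <- function(tmrna_calls, valid_trnas,
                                     terminus_db = NULL, genome = NULL,
                                     max_mismatch = 2L) {
  vt <- valid_trnas
  if (!is.null(vt$status))
    vt <- vt[vt$status == "tRNA_valid", , drop = FALSE]
  tm <- tmrna_calls[tmrna_calls$type %in% c("tmRNA", "tmRNA_two_piece"), ,
                    drop = FALSE]
  check_term <- !is.null(terminus_db) && !is.null(genome)
  if (!is.null(terminus_db) && is.null(genome))
    stop_usage("terminus check requires a genome")
  ids <- unique(tm$id)
  status <- character(length(ids))
  reason <- rep(NA_character_, length(ids))
  for (k in seq_along(ids)) {
    rows <- tm[tm$id == ids[k], , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(rows)))
      hit <- hit || overlaps_any0(
        rows$start[i], rows$end[i],
        vt$start[vt$contig == rows$contig[i]],
        vt$end[vt$contig == rows$contig[i]])
    if (hit) {
      status[k] <- "rejected"; reason[k] <- "overlaps_valid_trna"
    } else if (check_term &&
               terminus_classes_found(genome, rows, terminus_db,
                                      max_mismatch) < 2L) {
      status[k] <- "rejected"; reason[k] <- "missing_terminus"
    } else status[k] <- "tmRNA_accepted"
  }
  out <- as.data.frame(tm)
  out$status <- status[match(out$id, ids)]
  out$rejection_reason <- reason[match(out$id, ids)]
  acc <- out[out$status == "tmRNA_accepted", , drop = FALSE]
  per_contig <- table(unique(acc[, c("id", "contig")])$contig)
  out$multi_allele <- out$status == "tmRNA_accepted" &
    out$contig %in% names(per_contig)[per_contig > 1L]
  out <- out[order(out$contig, out$start, out$end, out$id, out$part), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("reconciled_calls", "data.frame"))
}

#' Calibrate profile-score thresholds from decoy hits
#'
#' For each profile, the acceptance threshold is `factor` times the
#' highest score attained by a decoy (known non-target) hit. With
#' `factor > 1` every decoy is strictly sub-threshold. Target hits
#' scoring at or above the threshold are above-threshold; the rest are
#' sub-threshold fallbacks.
#'
#' @param hits data.frame with columns `query_id`, `profile_id`, `score`
#'   (finite, higher is better) and `label` (`target`/`decoy`).
#' @param factor multiplier applied to the best decoy score.
#' @return named numeric vector of per-profile thresholds.
#' @export
calibrate_profile_threshold <- function(hits, factor = 1.4) {
  if (!all(c("query_id", "profile_id", "score", "label") %in% names(hits)))
    stop_usage("hits needs columns query_id, profile_id, score, label")
  if (!all(is.finite(hits$score))) stop_format("scores must be finite")
  if (!all(hits$label %in% c("target", "decoy")))
    stop_format("labels must be target/decoy")
  profiles <- unique(hits$profile_id)
  th <- vapply(profiles, function(p) {
    d <- hits$score[hits$profile_id == p & hits$label == "decoy"]
    if (!length(d))
      stop_format("profile ", p,
                  " has no decoy hits; cannot calibrate a threshold")
    factor * max(d)
  }, 0)
  names(th) <- profiles
  th
}

#' Classify profile hits against calibrated thresholds
#'
#' @param hits as in [calibrate_profile_threshold()].
#' @param thresholds named per-profile thresholds.
#' @return `hits` with an added `category` column:
#'   `above_threshold` (score >= threshold) or `sub_threshold`.
#' @export
classify_profile_hits <- function(hits, thresholds) {
  th <- thresholds[hits$profile_id]
  if (anyNA(th)) stop_usage("missing threshold for some profile(s)")
  hits$category <- ifelse(hits$score >= th, "above_threshold",
                          "sub_threshold")
  hits
}

#' Read a profile hit table (TSV)
#' @param path TSV with header query_id, profile_id, score, label.
#' @return validated data.frame.
#' @export
read_profile_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "profile_id", "score", "label")
  if (!all(need %in% names(df)))
    stop_format("profile hit table needs columns: ",
                paste(need, collapse = ", "))
  df$score <- as.numeric(df$score)
  if (!all(is.finite(df$score))) stop_format("scores must be finite")
  if (!all(df$label %in% c("target", "decoy")))
    stop_format("labels must be target/decoy")
  df
}
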