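ORIENTATIONS <- c("same", "opposite")
POSITION_CLASSES <- c("cds_upstream", "cds_downstream", "cds_internal",
                      "cds_spanning")

## scalar geometry; upstream/downstream are relative to the RNA gene's
## reading direction, so the classes read directly as "where does the
## CDS stick out of the RNA gene"
classify_overlap_geom <- function(cs, ce, cstrand, rs, re, rstrand) {
  orientation <- if (cstrand == rstrand) "same" else "opposite"
  cls <- if (cs >= rs && ce <= re) {
    "cds_internal"                      # includes identical extents
  } else if (cs <= rs && ce >= re) {
    "cds_spanning"
  } else if (cs < rs) {                 # CDS exceeds the RNA's left edge
    if (rstrand == "-") "cds_downstream" else "cds_upstream"
  } else {                              # CDS exceeds the RNA's right edge
    if (rstrand == "-") "cds_upstream" else "cds_downstream"
  }
  list(orientation = orientation, position_class = cls)
}

#' Classify one CDS x RNA-gene overlap
#'
#' Orientation is `same` iff the strands agree. The positional class is
#' relative to the RNA gene's reading direction: `cds_internal` when the
#' CDS lies within the RNA gene (identical extents included),
#' `cds_spanning` when the CDS contains it, otherwise `cds_upstream` or
#' `cds_downstream` according to which RNA boundary (5' or 3') the CDS
#' extends beyond.
#'
#' @param cds,rna one-row [gene_calls] (or one region of a two-piece
#'   tmRNA). The pair must overlap by >= 1 bp.
#' @return list with `orientation` and `position_class`.
#' @export
classify_overlap <- function(cds, rna) {
  cds <- as.data.frame(cds); rna <- as.data.frame(rna)
  if (nrow(cds) != 1L || nrow(rna) != 1L)
    stop_usage("classify_overlap takes single regions")
  if (min(cds$end, rna$end) - max(cds$start, rna$start) < 1L)
    stop_usage("classify_overlap requires an overlapping pair")
  classify_overlap_geom(cds$start, cds$end, cds$strand,
                        rna$start, rna$end, rna$strand)
}

#' Find and classify CDS x RNA-gene overlaps
#'
#' One record per (CDS, RNA region) pair sharing at least `min_bp`
#' intersection on either strand; each piece of a two-piece tmRNA is
#' classified independently and records carry the piece index. Non-stop
#' flags are populated via [flag_nonstop()].
#'
#' @param cds_calls CDS-type [gene_calls].
#' @param rna_calls tmRNA/tRNA [gene_calls].
#' @param min_bp minimum intersection width.
#' @return an `overlap_records` data.frame.
#' @export
find_overlaps <- function(cds_calls, rna_calls, min_bp = 1L) {
  cds <- as.data.frame(cds_calls[cds_calls$type == "CDS", , drop = FALSE])
  rna <- as.data.frame(rna_calls[rna_calls$type %in%
    c("tmRNA", "tmRNA_two_piece", "tRNA"), , drop = FALSE])
  rows <- list()
  for (ctg in intersect(unique(cds$contig), unique(rna$contig))) {
    ci <- which(cds$contig == ctg)
    ri <- which(rna$contig == ctg)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(cds$start[ci] + 1L, cds$end[ci]),
      IRanges::IRanges(rna$start[ri] + 1L, rna$end[ri]),
      minoverlap = as.integer(min_bp))
    if (length(hits) == 0L) next
    i <- ci[S4Vectors::queryHits(hits)]
    j <- ri[S4Vectors::subjectHits(hits)]
    geom <- lapply(seq_along(i), function(k)
      classify_overlap_geom(cds$start[i[k]], cds$end[i[k]],
                            cds$strand[i[k]], rna$start[j[k]],
                            rna$end[j[k]], rna$strand[j[k]]))
    rows[[length(rows) + 1L]] <- data.frame(
      cds_id = cds$id[i], rna_id = rna$id[j], rna_part = rna$part[j],
      rna_type = rna$type[j], contig = ctg,
      cds_start = cds$start[i], cds_end = cds$end[i],
      cds_strand = cds$strand[i],
      rna_start = rna$start[j], rna_end = rna$end[j],
      rna_strand = rna$strand[j],
      overlap_bp = overlap_width0(cds$start[i], cds$end[i],
                                  rna$start[j], rna$end[j]),
      orientation = vapply(geom, `[[`, "", "orientation"),
      position_class = vapply(geom, `[[`, "", "position_class"),
      family = cds$family[i],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(cds_id = character(), rna_id = character(),
                      rna_part = integer(), rna_type = character(),
                      contig = character(), cds_start = integer(),
                      cds_end = integer(), cds_strand = character(),
                      rna_start = integer(), rna_end = integer(),
                      rna_strand = character(), overlap_bp = integer(),
                      orientation = character(),
                      position_class = character(), family = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$contig, out$cds_start, out$rna_start), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  flag_nonstop(structure(out, class = c("overlap_records", "data.frame")))
}

#' Flag candidate non-stop mRNA overlaps
#'
#' Maturation of a same-orientation overlapping RNA gene cleaves the
#' mRNA, so every same-orientation record is a non-stop candidate;
#' records with the CDS downstream of the RNA gene are additionally
#' marked suspicious (they may reflect a start codon called too far
#' upstream). Opposite-orientation records are never flagged.
#'
#' @param records an `overlap_records` table with classification fields
#'   populated.
#' @return the same table with `nonstop_candidate` and `suspicious`
#'   logical columns (re)computed.
#' @export
flag_nonstop <- function(records) {
  records$nonstop_candidate <- records$orientation == "same"
  records$suspicious <- records$orientation == "same" &
    records$position_class == "cds_downstream"
  records
}

#' Summarize overlap records into an orientation x class x validity table
#'
#' @param records an `overlap_records` table.
#' @param validity named character map from RNA call id to `"valid"` or
#'   `"questionable"`; every RNA id in `records` must be present.
#' @return an [overlap_summary()] with per-cell counts, the top CDS
#'   family per cell (when records carry families), per-orientation
#'   totals and the grand total, per validity class.
#' @export
summarize_overlaps <- function(records, validity) {
  miss <- setdiff(unique(records$rna_id), names(validity))
  if (length(miss))
    stop_usage("validity entry missing for RNA id(s): ",
               paste(miss, collapse = ", "))
  if (!all(validity %in% c("valid", "questionable")))
    stop_usage("validity values must be valid/questionable")
  v <- unname(validity[records$rna_id])
  counts <- array(0L, dim = c(2L, 4L, 2L),
                  dimnames = list(ORIENTATIONS, POSITION_CLASSES,
                                  c("valid", "questionable")))
  top_family <- array(NA_character_, dim = dim(counts),
                      dimnames = dimnames(counts))
  if (nrow(records)) {
    tab <- table(factor(records$orientation, ORIENTATIONS),
                 factor(records$position_class, POSITION_CLASSES),
                 factor(v, c("valid", "questionable")))
    counts[] <- as.integer(tab)
    for (o in ORIENTATIONS) for (p in POSITION_CLASSES)
      for (val in c("valid", "questionable")) {
        fam <- records$family[records$orientation == o &
                                records$position_class == p & v == val]
        fam <- fam[!is.na(fam)]
        if (length(fam))
          top_family[o, p, val] <- names(sort(table(fam),
                                              decreasing = TRUE))[1]
      }
  }
  overlap_summary(counts, top_family)
}

#' Construct an overlap summary from per-cell counts
#'
#' The totals are recomputed from the cells, so the partition arithmetic
#' (per-orientation total = sum of its four positional classes; grand
#' total = same + opposite) holds by construction for any record set.
#'
#' @param counts 2 x 4 matrix (orientation x positional class) or
#'   2 x 4 x 2 array (x validity class) of cell counts.
#' @param top_family optional array of top CDS family labels per cell.
#' @return an `overlap_summary` object with `counts`,
#'   `orientation_totals`, `grand_total` (per validity class) and
#'   `top_family`.
#' @export
overlap_summary <- function(counts, top_family = NULL) {
  if (length(dim(counts)) == 2L)
    counts <- array(counts, dim = c(dim(counts), 1L),
                    dimnames = c(dimnames(counts), list("valid")))
  stopifnot(dim(counts)[1] == 2L, dim(counts)[2] == 4L)
  dimnames(counts)[[1]] <- ORIENTATIONS
  dimnames(counts)[[2]] <- POSITION_CLASSES
  ot <- apply(counts, c(1, 3), sum)
  gt <- apply(counts, 3, sum)
  structure(list(counts = counts, orientation_totals = ot,
                 grand_total = gt, top_family = top_family),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  vals <- dimnames(x$counts)[[3]]
  hdr <- c("", vals)
  rows <- list(c("Overlapping CDS", x$grand_total))
  for (o in ORIENTATIONS) {
    rows[[length(rows) + 1L]] <-
      c(sprintf("%s orientation", tools::toTitleCase(o)),
        x$orientation_totals[o, ])
    for (p in POSITION_CLASSES)
      rows[[length(rows) + 1L]] <- c(paste0("  ", p), x$counts[o, p, ])
  }
  m <- rbind(hdr, do.call(rbind, lapply(rows, as.character)))
  cat(align_columns(m), sep = "\n")
  invisible(x)
}

#' Write overlap records and summary as TSV
#' @param records an `overlap_records` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_overlap_records
#' @param summary an `overlap_summary`.
#' @export
write_overlap_summary <- function(summary, path) {
  vals <- dimnames(summary$counts)[[3]]
  df <- data.frame(row = c("total", paste0(rep(ORIENTATIONS, each = 5L),
    c("_total", paste0("_", POSITION_CLASSES)))),
    stringsAsFactors = FALSE)
  for (val in vals)
    df[[val]] <- c(summary$grand_total[[val]],
                   unlist(lapply(ORIENTATIONS, function(o)
                     c(summary$orientation_totals[o, val],
                       summary$counts[o, , val]))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
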