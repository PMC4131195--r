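#' Ordered reference sets for sequential hit evaluation
#'
#' @param ... named interval sets, each a [gene_calls] table, a
#'   `merged_hits` table, or any data.frame with `contig`, `start`,
#'   `end` (0-based half-open). Order is significant: a hit is assigned
#'   to the first set it overlaps. The conventional order is
#'   `final_tmRNA`, `valid_tRNA`, `questionable_tRNA`, `pfam_cds`.
#' @return a `reference_sets` object (named ordered list).
#' @export
reference_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.null(names(sets)) && is.list(sets[[1]]) &&
      !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_usage("every reference set must be named")
  if (anyDuplicated(nm)) stop_usage("reference set names must be unique")
  sets <- lapply(sets, function(s) {
    s <- as.data.frame(s)
    if (!all(c("contig", "start", "end") %in% names(s)))
      stop_usage("each reference set needs contig/start/end columns")
    s[, c("contig", "start", "end")]
  })
  structure(sets, class = "reference_sets")
}

#' Remove hits that overlap a higher-tier hit set
#'
#' Whole-hit exclusion: a below-threshold hit sharing >= 1 bp with any
#' above-threshold hit is dropped entirely (no coordinate clipping), so
#' only intervals unique to the lower tier remain.
#'
#' @param below,above `merged_hits` tables (each internally
#'   non-overlapping, see [merge_calls()]).
#' @return the retained rows of `below`.
#' @export
subtract_hits <- function(below, above) {
  if (nrow(below) == 0L) return(below)
  keep <- vapply(seq_len(nrow(below)), function(i) {
    ax <- above$contig == below$contig[i]
    !overlaps_any0(below$start[i], below$end[i],
                   above$start[ax], above$end[ax])
  }, TRUE)
  out <- below[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each hit to the first overlapping reference category
#'
#' Hits are tested against the reference sets in order and assigned to
#' the first category they overlap by >= 1 bp (strand-blind); hits
#' overlapping no set are `unhit`. Every hit is assigned exactly once.
#'
#' @param raw a `merged_hits` table of raw predictor hits.
#' @param refsets a [reference_sets] object.
#' @return `raw` with an added `category` factor (levels = category
#'   names plus `unhit`).
#' @export
sequential_assign <- function(raw, refsets) {
  stopifnot(inherits(refsets, "reference_sets"))
  cats <- names(refsets)
  assign1 <- function(i) {
    for (nm in cats) {
      s <- refsets[[nm]]
      sx <- s$contig == raw$contig[i]
      if (overlaps_any0(raw$start[i], raw$end[i], s$start[sx], s$end[sx]))
        return(nm)
    }
    "unhit"
  }
  raw$category <- factor(vapply(seq_len(nrow(raw)), assign1, ""),
                         levels = c(cats, "unhit"))
  raw
}

#' Build an evaluation report from per-category counts
#'
#' Validates the partition invariant (raw = sum of category counts plus
#' unhit) and computes the true-positive rate as the percentage of raw
#' hits falling in the first (tmRNA) category, rounded half-up to one
#' decimal. With zero raw hits the rate is undefined (`NA`), not 0.
#'
#' @param label dataset label (e.g. domain x source family).
#' @param counts named integer vector of per-category counts, in
#'   reference-set order with the tmRNA category first.
#' @param unhit count of hits overlapping no reference set.
#' @param raw total raw hit count; defaults to `sum(counts) + unhit` and
#'   is checked against it when supplied.
#' @return an `evaluation_report` object.
#' @export
evaluation_report <- function(label, counts, unhit, raw = NULL) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_usage("counts must be named by category")
  unhit <- as.integer(unhit)
  total <- sum(counts) + unhit
  if (is.null(raw)) raw <- total
  if (as.integer(raw) != total)
    stop_format("partition violated: raw (", raw,
                ") != sum of categories + unhit (", total, ")")
  tp <- if (raw > 0L) round_half_up(100 * counts[[1]] / raw, 1)
        else NA_real_
  structure(list(label = label, raw = as.integer(raw), counts = counts,
                 unhit = unhit, tp_rate = tp),
            class = "evaluation_report")
}

#' Tally sequential assignments into an evaluation report
#'
#' @param assignments output of [sequential_assign()].
#' @param dataset_label report label.
#' @return an [evaluation_report()].
#' @export
build_report <- function(assignments, dataset_label = "dataset") {
  if (is.null(assignments$category))
    stop_usage("assignments must come from sequential_assign()")
  tab <- table(assignments$category)
  cats <- setdiff(names(tab), "unhit")
  evaluation_report(dataset_label,
                    counts = stats::setNames(as.integer(tab[cats]), cats),
                    unhit = as.integer(tab[["unhit"]]))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

#' Render one or more evaluation reports as aligned text
#' @param x an `evaluation_report` or list of them.
#' @return character vector of lines.
#' @export
format_report_text <- function(x) {
  reports <- if (inherits(x, "evaluation_report")) list(x) else x
  cats <- names(reports[[1]]$counts)
  hdr <- c("Dataset", "Raw", cats, "Unhit", "TP rate")
  rows <- lapply(reports, function(r)
    c(r$label, r$raw, unname(r$counts), r$unhit,
      if (is.na(r$tp_rate)) "NA" else sprintf("%.1f%%", r$tp_rate)))
  m <- rbind(hdr, do.call(rbind, lapply(rows, as.character)))
  align_columns(m)
}

#' Write evaluation reports as TSV
#'
#' One row per report with columns label, raw, one per category, unhit,
#' tp_rate.
#'
#' @param reports an `evaluation_report` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(reports, path) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    d <- data.frame(label = r$label, raw = r$raw,
                    stringsAsFactors = FALSE)
    for (nm in names(r$counts)) d[[nm]] <- r$counts[[nm]]
    d$unhit <- r$unhit
    d$tp_rate <- r$tp_rate
    d
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
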