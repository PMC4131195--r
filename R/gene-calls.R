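CALL_COLS <- c("id", "contig", "start", "end", "strand", "part", "type",
               "source", "score", "pseudo", "undetermined", "isotype",
               "anticodon", "family")

GENE_TYPES <- c("tmRNA", "tmRNA_two_piece", "tRNA", "CDS", "other")

#' Gene-call tables
#'
#' The universal currency of the toolkit: one row per genomic region of a
#' predicted or annotated gene. Coordinates are 0-based half-open.
#' A two-piece (circularly permuted) tmRNA is the one gene type allowed
#' two regions; its two rows share an `id` and carry `part` 1 and 2.
#'
#' Columns: `id`, `contig`, `start`, `end`, `strand` (+/-/.), `part`,
#' `type` (tmRNA, tmRNA_two_piece, tRNA, CDS, other), `source`, `score`,
#' `pseudo`, `undetermined`, `isotype`, `anticodon`, `family`.
#'
#' @param df data.frame with at least `id`, `contig`, `start`, `end`,
#'   `strand`, `type`; missing optional columns are filled with defaults
#'   (`pseudo`/`undetermined` default FALSE).
#' @return a `gene_calls` data.frame sorted by (contig, start, end).
#' @export
gene_calls <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(id = character(), contig = character(),
                     start = integer(), end = integer(),
                     strand = character(), part = integer(),
                     type = character(), source = character(),
                     score = numeric(), pseudo = logical(),
                     undetermined = logical(), isotype = character(),
                     anticodon = character(), family = character(),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("gene_calls", "data.frame")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "contig", "start", "end", "strand", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_usage("gene_calls missing column(s): ",
                               paste(miss, collapse = ", "))
  if (is.null(df$part)) df$part <- 1L
  if (is.null(df$source)) df$source <- "unknown"
  if (is.null(df$score)) df$score <- NA_real_
  if (is.null(df$pseudo)) df$pseudo <- FALSE
  if (is.null(df$undetermined)) df$undetermined <- FALSE
  if (is.null(df$isotype)) df$isotype <- NA_character_
  if (is.null(df$anticodon)) df$anticodon <- NA_character_
  if (is.null(df$family)) df$family <- NA_character_
  df$pseudo[is.na(df$pseudo)] <- FALSE
  df$undetermined[is.na(df$undetermined)] <- FALSE
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$part <- as.integer(df$part); df$score <- as.numeric(df$score)
  for (col in c("id", "contig", "strand", "type", "source", "isotype",
                "anticodon", "family"))
    df[[col]] <- as.character(df[[col]])
  extra <- setdiff(names(df), CALL_COLS)
  df <- df[, c(CALL_COLS, extra)]
  validate_gene_calls(df)
  df <- df[order(df$contig, df$start, df$end, df$id, df$part), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_calls", "data.frame"))
}

validate_gene_calls <- function(df) {
  if (any(is.na(df$start) | is.na(df$end) | df$start < 0L |
            df$start >= df$end))
    stop_format("invalid coordinates: need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop_format("invalid strand value")
  if (!all(df$type %in% GENE_TYPES))
    stop_format("unknown gene type: ",
                paste(setdiff(df$type, GENE_TYPES), collapse = ", "))
  sp <- split(seq_len(nrow(df)), df$id)
  for (ix in sp) {
    if (length(unique(df$contig[ix])) != 1L ||
        length(unique(df$strand[ix])) != 1L)
      stop_format("call ", df$id[ix[1]],
                  ": all regions must share one contig and one strand")
    if (length(unique(df$type[ix])) != 1L)
      stop_format("call ", df$id[ix[1]], ": inconsistent type")
    two <- identical(df$type[ix[1]], "tmRNA_two_piece")
    if (two && (length(ix) != 2L || !setequal(df$part[ix], 1:2)))
      stop_format("call ", df$id[ix[1]],
                  ": two-piece tmRNA needs exactly parts 1 and 2")
    if (!two && length(ix) != 1L)
      stop_format("call ", df$id[ix[1]],
                  ": only two-piece tmRNA may have 2 regions")
  }
  invisible(df)
}

#' Construct a single gene call
#'
#' @param id call id. @param contig contig id.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param type one of tmRNA, tmRNA_two_piece, tRNA, CDS, other.
#' @param source predictor or annotation name.
#' @param score optional numeric score (predictor-specific scale).
#' @param ... further attribute columns (pseudo, undetermined, isotype,
#'   anticodon, family) or, for `type = "tmRNA_two_piece"`, vectors of
#'   length 2 for `start`/`end` (plus `part = 1:2`).
#' @return a one-gene `gene_calls` table.
#' @export
gene_call <- function(id, contig, start, end, strand = "+", type = "other",
                      source = "unknown", score = NA_real_, ...) {
  n <- length(start)
  gene_calls(data.frame(id = id, contig = contig, start = start, end = end,
                        strand = strand,
                        part = if (n > 1L) seq_len(n) else 1L,
                        type = type, source = source, score = score,
                        ..., stringsAsFactors = FALSE))
}

#' @export
print.gene_calls <- function(x, ...) {
  cat("gene_calls:", length(unique(x$id)), "call(s),", nrow(x),
      "region(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L))
  if (nrow(x) > 20L) cat("... and", nrow(x) - 20L, "more region(s)\n")
  invisible(x)
}

#' @export
`[.gene_calls` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(CALL_COLS %in% names(out)))
    class(out) <- c("gene_calls", "data.frame")
  out
}

#' Combine gene-call tables
#'
#' Row-binds any number of `gene_calls` tables (missing optional
#' columns are filled) and re-validates and sorts the result.
#'
#' @param ... `gene_calls` tables (NULL and empty tables are ignored).
#' @return a [gene_calls] table.
#' @export
bind_calls <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
  if (!length(parts)) return(gene_calls())
  cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(d) {
    for (col in setdiff(cols, names(d))) d[[col]] <- NA
    as.data.frame(d)[, cols, drop = FALSE]
  })
  gene_calls(do.call(rbind, parts))
}

#' Reverse-complement coordinates of gene calls
#'
#' Maps every region `[start, end)` on a contig of length `L` to
#' `[L - end, L - start)` and flips strands, matching
#' [reverse_complement_genome()]. Used for strand-symmetry checks.
#'
#' @param calls a `gene_calls` table.
#' @param lens named contig lengths (see [contig_lengths()]).
#' @return the transformed `gene_calls`.
#' @export
reverse_complement_calls <- function(calls, lens) {
  if (nrow(calls) == 0L) return(calls)
  L <- unname(lens[calls$contig])
  if (anyNA(L)) stop_usage("contig length missing for some calls")
  s <- L - calls$end
  e <- L - calls$start
  calls$start <- s
  calls$end <- e
  calls$strand <- chartr("+-", "-+", calls$strand)
  gene_calls(as.data.frame(calls))
}
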