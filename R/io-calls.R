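#' Read gene calls from predictor and annotation files
#'
#' Supported dialects:
#' \describe{
#'   \item{gff3}{1-based inclusive coordinates (converted to the internal
#'     0-based half-open convention); two features sharing a `Parent`
#'     attribute are joined into one two-piece tmRNA call.}
#'   \item{bed6}{0-based half-open; two rows sharing a name are joined
#'     into a two-piece tmRNA. BED carries no gene type or attributes, so
#'     other rows read back with type `other`.}
#'   \item{trnascan_tabular}{the tabular output of tRNAscan-SE: an
#'     optional 3-line header, then whitespace-separated columns
#'     name, tRNA#, begin, end, isotype, anticodon, intron begin/end,
#'     Cove score and an optional note. `begin > end` encodes the minus
#'     strand; Pseudo/Undetermined notes land in the call attributes.}
#'   \item{aragorn_batch}{the ARAGORN batch listing: `>contig` headers
#'     followed by numbered gene lines with `[x,y]` coordinates
#'     (`c[x,y]` for the complement strand) and, for tRNAs, the
#'     anticodon in parentheses.}
#'   \item{generic_tsv}{tab-separated with header columns
#'     contig, start, end, strand, type, source, score, attrs
#'     (0-based half-open; `attrs` is `key=value` pairs separated by
#'     `;`, including `id` and `part` for two-piece tmRNAs).}
#' }
#'
#' @param path input file.
#' @param dialect one of `"gff3"`, `"bed6"`, `"trnascan_tabular"`,
#'   `"aragorn_batch"`, `"generic_tsv"`.
#' @param strict if `TRUE` (default) an unparseable row is an error with
#'   its line number; if `FALSE` such rows are skipped with a warning.
#' @return a [gene_calls] table, sorted.
#' @export
read_calls <- function(path,
                       dialect = c("gff3", "bed6", "trnascan_tabular",
                                   "aragorn_batch", "generic_tsv"),
                       strict = TRUE) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop_usage("unknown dialect"))
  if (!file.exists(path)) stop_format("no such file: ", path)
  switch(dialect,
         gff3 = read_calls_gff3(path),
         bed6 = read_calls_bed6(path),
         trnascan_tabular = read_calls_trnascan(path, strict),
         aragorn_batch = read_calls_aragorn(path, strict),
         generic_tsv = read_calls_tsv(path, strict))
}

first_nonna <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[1] else NA
}

as_flag <- function(x) {
  !is.na(x) & tolower(as.character(x)) %in% c("true", "1", "yes")
}

read_calls_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(gene_calls())
  mc <- S4Vectors::mcols(gr)
  get <- function(col) if (col %in% names(mc)) as.character(mc[[col]])
         else rep(NA_character_, length(gr))
  parent <- get("Parent")
  if ("Parent" %in% names(mc) && methods::is(mc$Parent, "List"))
    parent <- vapply(mc$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, "")
  id <- get("ID")
  id <- ifelse(is.na(parent), ifelse(is.na(id), paste0("call", seq_along(gr)),
                                     id), parent)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(id = id,
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = strand,
                   type = get("type"),
                   source = get("source"),
                   score = if ("score" %in% names(mc))
                             as.numeric(mc$score) else NA_real_,
                   pseudo = as_flag(get("pseudo")),
                   undetermined = as_flag(get("undetermined")),
                   isotype = get("isotype"),
                   anticodon = get("anticodon"),
                   family = get("family"),
                   stringsAsFactors = FALSE)
  df$type[!df$type %in% GENE_TYPES] <- "other"
  ## assign part numbers within each id by coordinate order
  df <- df[order(df$id, df$start), , drop = FALSE]
  df$part <- stats::ave(df$start, df$id, FUN = seq_along)
  gene_calls(df)
}

read_calls_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(gene_calls())
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) as.character(mc$name)
        else paste0("call", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(id = nm,
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = strand,
                   type = "other",
                   source = "bed",
                   score = if ("score" %in% names(mc))
                             as.numeric(mc$score) else NA_real_,
                   stringsAsFactors = FALSE)
  dup <- nm %in% nm[duplicated(nm)]
  df$type[dup] <- "tmRNA_two_piece"
  df <- df[order(df$id, df$start), , drop = FALSE]
  df$part <- stats::ave(df$start, df$id, FUN = seq_along)
  gene_calls(df)
}

row_problem <- function(strict, lineno, msg) {
  full <- sprintf("line %d: %s", lineno, msg)
  if (strict) stop_format(full)
  warning(full, "; row skipped")
  NULL
}

read_calls_trnascan <- function(path, strict) {
  lines <- readLines(path)
  ## skip the canonical 3-line header (and any line of dashes)
  body <- grepl("^\\S", lines) & !grepl("^(Sequence|Name\\b|--)", lines)
  rows <- list()
  for (i in which(body & nzchar(lines))) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 9L) {
      row_problem(strict, i, "expected >= 9 whitespace-separated fields")
      next
    }
    b <- suppressWarnings(as.integer(f[3])); e <- suppressWarnings(as.integer(f[4]))
    if (is.na(b) || is.na(e)) { row_problem(strict, i, "bad coordinates"); next }
    strand <- if (b > e) "-" else "+"
    lo <- min(b, e); hi <- max(b, e)
    note <- if (length(f) > 9L) paste(f[-(1:9)], collapse = " ") else ""
    score <- suppressWarnings(as.numeric(f[9]))
    if (is.na(score)) { row_problem(strict, i, "bad Cove score"); next }
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s.trna%s", f[1], f[2]), contig = f[1],
      start = lo - 1L, end = hi, strand = strand, part = 1L,
      type = "tRNA", source = "tRNAscan-SE", score = score,
      pseudo = grepl("pseudo", note, ignore.case = TRUE),
      undetermined = grepl("undet", note, ignore.case = TRUE) ||
        grepl("^undet", f[5], ignore.case = TRUE),
      isotype = f[5], anticodon = f[6], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(gene_calls())
  gene_calls(do.call(rbind, rows))
}

read_calls_aragorn <- function(path, strict) {
  lines <- readLines(path)
  contig <- NA_character_
  pat <- "^\\s*(\\d+)\\s+(tmRNA|tRNA-\\S+)\\s+(c?)\\[(\\d+),(\\d+)\\]\\s*(.*)$"
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      contig <- sub("\\s.*$", "", sub("^>", "", ln))
      next
    }
    if (!grepl(pat, ln)) next
    if (is.na(contig)) { row_problem(strict, i, "gene line before any >contig header"); next }
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    b <- as.integer(m[5]); e <- as.integer(m[6])
    if (is.na(b) || is.na(e) || e < b) { row_problem(strict, i, "end < start"); next }
    isot <- if (m[3] == "tmRNA") NA_character_ else sub("^tRNA-", "", m[3])
    anti <- NA_character_
    am <- regmatches(m[7], regexec("\\(([acgtu]{3})\\)", m[7]))[[1]]
    if (length(am) == 2L) anti <- toupper(chartr("u", "t", am[2]))
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s.aragorn%s", contig, m[2]), contig = contig,
      start = b - 1L, end = e, strand = if (m[4] == "c") "-" else "+",
      part = 1L, type = if (m[3] == "tmRNA") "tmRNA" else "tRNA",
      source = "ARAGORN", score = NA_real_, isotype = isot,
      anticodon = anti, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(gene_calls())
  gene_calls(do.call(rbind, rows))
}

parse_attrs <- function(s) {
  if (is.na(s) || !nzchar(s) || s == ".") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) == 2L) p[2] else NA_character_)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

read_calls_tsv <- function(path, strict) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("contig", "start", "end", "strand", "type", "source", "score",
            "attrs")
  if (!all(need %in% names(df)))
    stop_format("generic_tsv needs header columns: ",
                paste(need, collapse = ","))
  rows <- list()
  for (i in seq_len(nrow(df))) {
    s <- suppressWarnings(as.integer(df$start[i]))
    e <- suppressWarnings(as.integer(df$end[i]))
    if (is.na(s) || is.na(e) || e <= s) {
      row_problem(strict, i + 1L, "bad coordinates (need start < end)")
      next
    }
    at <- parse_attrs(df$attrs[i])
    rows[[length(rows) + 1L]] <- data.frame(
      id = at$id %||% sprintf("%s.row%d", df$contig[i], i),
      contig = df$contig[i], start = s, end = e, strand = df$strand[i],
      part = as.integer(at$part %||% 1L), type = df$type[i],
      source = df$source[i],
      score = suppressWarnings(as.numeric(df$score[i])),
      pseudo = as_flag(at$pseudo %||% NA),
      undetermined = as_flag(at$undetermined %||% NA),
      isotype = at$isotype %||% NA_character_,
      anticodon = at$anticodon %||% NA_character_,
      family = at$family %||% NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(gene_calls())
  gene_calls(do.call(rbind, rows))
}

#' Write gene calls to GFF3 or BED6
#'
#' GFF3 restores 1-based inclusive coordinates and writes gene type,
#' source, score and attributes; a two-piece tmRNA becomes two features
#' sharing a `Parent`. BED6 writes 0-based half-open rows (two rows
#' sharing a name for a two-piece tmRNA); type and attributes are not
#' representable in BED.
#'
#' @param calls a [gene_calls] table.
#' @param path output path.
#' @param format `"gff3"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("gff3", "bed6")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_usage("unknown format"))
  if (nrow(calls) == 0L) {
    writeLines(if (format == "gff3") "##gff-version 3" else character(),
               path)
    return(invisible(path))
  }
  strand <- calls$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    calls$contig,
    IRanges::IRanges(calls$start + 1L, calls$end),
    strand = strand)
  if (format == "bed6") {
    S4Vectors::mcols(gr)$name <- calls$id
    S4Vectors::mcols(gr)$score <- ifelse(is.na(calls$score), 0, calls$score)
    rtracklayer::export(gr, path, format = "bed")
    return(invisible(path))
  }
  two <- calls$type == "tmRNA_two_piece"
  mc <- S4Vectors::DataFrame(
    source = calls$source,
    type = calls$type,
    score = calls$score,
    phase = ifelse(calls$type == "CDS", 0L, NA_integer_),
    ID = ifelse(two, sprintf("%s.p%d", calls$id, calls$part), calls$id))
  mc$Parent <- ifelse(two, calls$id, NA_character_)
  opt <- function(x, true_only = FALSE) {
    if (true_only) ifelse(calls[[x]], "true", NA_character_)
    else calls[[x]]
  }
  mc$pseudo <- opt("pseudo", TRUE)
  mc$undetermined <- opt("undetermined", TRUE)
  mc$isotype <- calls$isotype
  mc$anticodon <- calls$anticodon
  mc$family <- calls$family
  for (extra in intersect(c("status", "rejection_reason", "multi_allele"),
                          names(calls)))
    mc[[extra]] <- as.character(calls[[extra]])
  ## drop all-NA attribute columns so the output stays clean
  keep <- vapply(names(mc), function(n)
    n %in% c("source", "type", "score", "ID") || !all(is.na(mc[[n]])),
    TRUE)
  S4Vectors::mcols(gr) <- mc[, keep, drop = FALSE]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
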