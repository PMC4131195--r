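#' Build gene-rank windows centered on a gene family
#'
#' For every gene of `center_family`, the window is the `2k + 1`-gene
#' run centered on it in gene order (rank, not bp distance). Circular
#' replicons wrap; linear replicon edges truncate the window and set
#' `truncated`. When the center gene lies on the minus strand the window
#' is reversed and all strands flipped, so that windows read in the
#' center gene's own direction and left/right mean upstream/downstream
#' of it.
#'
#' @param table a [gene_calls] table with `family` labels (one gene per
#'   id; only part-1 regions of two-piece genes anchor the rank order).
#' @param center_family family label of the window centers.
#' @param k half-width in genes (default 5 gives the 11-gene window).
#' @param topology named per-contig `"linear"`/`"circular"` vector;
#'   defaults to linear.
#' @return a `neighborhoods` data.frame with `center_id`, `contig`,
#'   `truncated`, `k` and a `tokens` list column of
#'   `data.frame(family, strand)` in window order.
#' @export
build_windows <- function(table, center_family = "smpB", k = 5L,
                          topology = NULL) {
  k <- as.integer(k)
  genes <- as.data.frame(table[table$part == 1L, , drop = FALSE])
  out <- list()
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    circular <- !is.null(topology) &&
      identical(unname(topology[ctg]), "circular")
    centers <- which(!is.na(g$family) & g$family == center_family)
    for (ci in centers) {
      if (circular) {
        span <- min(k, (n - 1L) %/% 2L)
        idx <- ((ci - 1L + seq(-span, span)) %% n) + 1L
        truncated <- FALSE
      } else {
        idx <- max(1L, ci - k):min(n, ci + k)
        truncated <- length(idx) < 2L * k + 1L
      }
      tok <- data.frame(family = g$family[idx], strand = g$strand[idx],
                        stringsAsFactors = FALSE)
      if (g$strand[ci] == "-") {
        tok <- tok[rev(seq_len(nrow(tok))), , drop = FALSE]
        tok$strand <- chartr("+-", "-+", tok$strand)
        rownames(tok) <- NULL
      }
      out[[length(out) + 1L]] <- list(center_id = g$id[ci], contig = ctg,
                                      truncated = truncated, tokens = tok)
    }
  }
  if (!length(out))
    warning("no gene of family '", center_family, "' found")
  nb <- data.frame(
    center_id = vapply(out, `[[`, "", "center_id"),
    contig = vapply(out, `[[`, "", "contig"),
    truncated = vapply(out, `[[`, TRUE, "truncated"),
    k = k, stringsAsFactors = FALSE)
  nb$tokens <- lapply(out, `[[`, "tokens")
  structure(nb, class = c("neighborhoods", "data.frame"),
            center_family = center_family)
}

#' Families present in more than `min_count` windows
#'
#' Presence is counted once per window regardless of copy number; the
#' center family itself is excluded, but any other token (including RNA
#' genes such as the tmRNA gene) counts. The cutoff is strict
#' (`count > min_count`).
#'
#' @param windows a `neighborhoods` table from [build_windows()].
#' @param min_count presence cutoff (strict `>`).
#' @param min_frac optional fraction of windows; when given,
#'   `min_count = min_frac * nrow(windows)` (still strict `>`), for
#'   datasets of other sizes.
#' @return character vector of family labels.
#' @export
frequent_families <- function(windows, min_count = 200L,
                              min_frac = NULL) {
  center <- attr(windows, "center_family") %||% "smpB"
  if (!is.null(min_frac)) min_count <- min_frac * nrow(windows)
  fams <- unlist(lapply(windows$tokens, function(t)
    unique(t$family[!is.na(t$family) & t$family != center])))
  tab <- table(fams)
  sort(names(tab)[tab > min_count])
}

signature_one <- function(tokens, keep, with_strand = TRUE) {
  t <- tokens[!is.na(tokens$family) & tokens$family %in% keep, ,
              drop = FALSE]
  if (with_strand) paste(sprintf("%s(%s)", t$family, t$strand),
                         collapse = "|")
  else paste(t$family, collapse = "|")
}

#' Summarize windows as cluster signatures
#'
#' Tokens outside `families` (plus the center family, always kept) are
#' dropped and the remainder joined in window order as
#' `family(strand)` separated by `|`. A window with no frequent
#' neighbors yields the center-only signature.
#'
#' @param windows a `neighborhoods` table.
#' @param families set of frequent family labels (see
#'   [frequent_families()]); must be non-empty.
#' @param with_strand include relative strands in the signature.
#' @return character vector of signatures, one per window.
#' @export
cluster_signature <- function(windows, families, with_strand = TRUE) {
  if (!length(families)) stop_usage("families must be non-empty")
  center <- attr(windows, "center_family") %||% "smpB"
  keep <- union(families, center)
  vapply(windows$tokens, signature_one, "", keep = keep,
         with_strand = with_strand)
}

#' Rank cluster signatures by frequency
#'
#' @param signatures character vector of signatures (one per window).
#' @param center_ids optional parallel vector of window center ids,
#'   recorded per cluster.
#' @return a `cluster_signatures` data.frame with `signature`, `count`
#'   (and a `members` list column when ids are given), sorted by count
#'   descending then signature.
#' @export
rank_clusters <- function(signatures, center_ids = NULL) {
  if (!length(signatures)) {
    out <- data.frame(signature = character(), count = integer(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("cluster_signatures", "data.frame")))
  }
  tab <- table(signatures)
  out <- data.frame(signature = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(center_ids))
    out$members <- lapply(out$signature, function(s)
      center_ids[signatures == s])
  structure(out, class = c("cluster_signatures", "data.frame"))
}

#' Write a cluster ranking as TSV
#' @param clusters a `cluster_signatures` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- as.data.frame(clusters)[, c("signature", "count")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
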