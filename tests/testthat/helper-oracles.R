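# Independent brute-force oracles and small fixture builders used
# across the suite. The oracles deliberately avoid the package's
# interval machinery: plain O(n^2) pairwise arithmetic only.

# pairwise >= 1 bp overlap of 0-based half-open intervals
ov1 <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2) >= 1L

# transitive closure of pairwise overlap -> union intervals + members
brute_merge <- function(calls, strand_mode = "ignore") {
  df <- as.data.frame(calls)
  key <- if (strand_mode == "ignore") df$contig
         else paste(df$contig, df$strand)
  out <- list()
  for (k in unique(key)) {
    d <- df[key == k, , drop = FALSE]
    n <- nrow(d)
    # O(n^2) pairwise adjacency, then label propagation to convergence
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
      ov1(d$start[i], d$end[i], d$start[j], d$end[j]))
    comp <- seq_len(n)
    repeat {
      nc <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0L)
      if (identical(nc, comp)) break
      comp <- nc
    }
    for (cc in unique(comp)) {
      ix <- which(comp == cc)
      row <- data.frame(contig = d$contig[1], start = min(d$start[ix]),
                        end = max(d$end[ix]), stringsAsFactors = FALSE)
      row$members <- list(sort(unique(d$id[ix])))
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    empty <- data.frame(contig = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    empty$members <- list()
    return(empty)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$members <- unname(out$members)
  out
}

brute_subtract <- function(below, above) {
  keep <- vapply(seq_len(nrow(below)), function(i) {
    drop <- FALSE
    for (j in seq_len(nrow(above)))
      if (above$contig[j] == below$contig[i] &&
          ov1(below$start[i], below$end[i], above$start[j],
              above$end[j]))
        drop <- TRUE
    !drop
  }, TRUE)
  below[keep, , drop = FALSE]
}

brute_sequential <- function(raw, refsets) {
  vapply(seq_len(nrow(raw)), function(i) {
    for (nm in names(refsets)) {
      s <- refsets[[nm]]
      for (j in seq_len(nrow(s)))
        if (s$contig[j] == raw$contig[i] &&
            ov1(raw$start[i], raw$end[i], s$start[j], s$end[j]))
          return(nm)
    }
    "unhit"
  }, "")
}

# random gene_calls table for interval-oracle tests
random_calls <- function(n, n_contigs = 2L, max_pos = 1000L,
                         max_width = 100L) {
  if (n == 0L) return(gene_calls())
  start <- sample.int(max_pos, n, replace = TRUE)
  gene_calls(data.frame(
    id = sprintf("r%d", seq_len(n)),
    contig = sample(paste0("c", seq_len(n_contigs)), n, replace = TRUE),
    start = start, end = start + sample.int(max_width, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    type = "other", source = sample(c("A", "B"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

merged_as_plain <- function(m) {
  out <- data.frame(contig = m$contig, start = m$start, end = m$end,
                    stringsAsFactors = FALSE)
  out$members <- unname(lapply(m$members, sort))
  out
}

# exact back-translation of a protein using the standard code
back_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(protein, "")[[1]], function(a)
    sample(names(code)[code == a], 1L), ""), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# no coordinate jitter, no misses, no false positives, degenerate
# score distribution: every error-model knob at zero
zero_noise_spec <- function(seed = 11L, ...) {
  fixture_spec(seed = seed, jitter_sd = 0, miss_rate = 0,
               n_false_positive = 0L, score_sd = 0, ...)
}
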