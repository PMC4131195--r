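## run expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## fixed template pieces; the terminus motifs are distinct 15-mers and
## the template acceptor stem satisfies the default pairing map
## (positions 0..6 pair with L-5-i, terminal ACCA)
TMRNA_FIVE_MOTIF <- "GGGGCTGATTCTGGA"
TMRNA_THREE_MOTIF <- "GCTACAGCCCCACCA"
TMRNA_TAG_ORF <- "ATGGCTGCAAATGATGAAAATTACGCTCTGGCTTAA"  # 12 codons
TMRNA_LINKER1 <- "TTCGACTCATCAGGACTCATCGATCAGGTC"
TMRNA_LINKER2 <- "GATCCTGACGGTTTAGACGTCCTGAAGCTA"
TRNA_TEMPLATE <- paste0("GGGGCTATAGCTCAGCTGGGAGAGCGCCTGCTTNNNGACGCAG",
                        "GAGGTCTGCGGTTCGATCCCGCATAGCTCCACCA")

#' The terminus-motif database of the synthetic tmRNA template
#' @return data.frame with columns `label`, `seq` usable as a
#'   `terminus_db` (see [refine_termini()]).
#' @export
fixture_terminus_db <- function() {
  data.frame(label = c("five_prime", "three_prime"),
             seq = c(TMRNA_FIVE_MOTIF, TMRNA_THREE_MOTIF),
             stringsAsFactors = FALSE)
}

tmrna_template <- function() {
  paste0(TMRNA_FIVE_MOTIF, TMRNA_LINKER1, TMRNA_TAG_ORF, TMRNA_LINKER2,
         TMRNA_THREE_MOTIF)
}

trna_template <- function(anticodon = "CGC") {
  sub("NNN", anticodon, TRNA_TEMPLATE, fixed = TRUE)
}

#' Specification of a synthetic-genome fixture
#'
#' Defaults describe a small but realistic single-replicon test genome:
#' a 20 kb contig carrying 3 tmRNA and 8 tRNA template genes, predictor
#' calls jittered by ~2 nt at the termini, a 5% miss rate, 3 false
#' positives per predictor family, Cove-like scores around 65 +/- 10 and
#' 30% background divergence for ortholog sets. Identical spec + seed
#' give byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param contig_length background contig length (nt).
#' @param n_tmrna,n_trna numbers of planted template genes.
#' @param topology `"linear"` or `"circular"`.
#' @param jitter_sd terminus jitter standard deviation (nt).
#' @param miss_rate per-call probability a predictor misses a gene.
#' @param n_false_positive false-positive calls per predictor family.
#' @param score_mean,score_sd Cove-like score distribution for true
#'   tRNA calls (false positives score ~30 lower).
#' @param divergence per-site substitution probability outside planted
#'   ORFs in ortholog sets.
#' @param ... overrides stored verbatim.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, contig_length = 20000L, n_tmrna = 3L,
                         n_trna = 8L, topology = "linear",
                         jitter_sd = 2, miss_rate = 0.05,
                         n_false_positive = 3L, score_mean = 65,
                         score_sd = 10, divergence = 0.3, ...) {
  spec <- list(seed = as.integer(seed),
               contig_length = as.integer(contig_length),
               n_tmrna = as.integer(n_tmrna), n_trna = as.integer(n_trna),
               topology = topology, jitter_sd = jitter_sd,
               miss_rate = miss_rate,
               n_false_positive = as.integer(n_false_positive),
               score_mean = score_mean, score_sd = score_sd,
               divergence = divergence, ...)
  if (spec$contig_length < (spec$n_tmrna + spec$n_trna) * 400L)
    stop_usage("contig too short for the requested planted genes")
  structure(spec, class = "fixture_spec")
}

#' Simulate a genome with planted template genes
#'
#' Plants non-overlapping tmRNA and tRNA template genes (each tmRNA
#' carries the distinct 5'/3' terminus motifs, a 12-codon tag ORF and a
#' terminal NCCA; each tRNA a fixed consensus body with a random
#' anticodon) on random background sequence, on random strands. The
#' truth table records exact coordinates, families (`ssrA` / isotype)
#' and Cove-like score metadata for the tRNAs.
#'
#' @param spec a [fixture_spec()].
#' @return list with `genome` (a [genome]), `truth` (a [gene_calls]
#'   table) and `spec`.
#' @export
simulate_genome <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    L <- spec$contig_length
    bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    n_genes <- spec$n_tmrna + spec$n_trna
    truth <- NULL
    if (n_genes > 0L) {
      slot <- L %/% n_genes
      kinds <- sample(rep(c("tmRNA", "tRNA"),
                          c(spec$n_tmrna, spec$n_trna)))
      rows <- list()
      isotypes <- c("Ala", "Gly", "Leu", "Ser", "Phe", "Val", "Thr",
                    "Ile", "Met", "Arg")
      anticodons <- c("CGC", "GCC", "CAA", "GCT", "GAA", "TAC", "TGT",
                      "GAT", "CAT", "ACG")
      for (g in seq_len(n_genes)) {
        if (kinds[g] == "tmRNA") {
          tpl <- tmrna_template()
          iso <- NA_character_; anti <- NA_character_
          fam <- "ssrA"; score <- NA_real_
        } else {
          pick <- sample(length(isotypes), 1L)
          iso <- isotypes[pick]; anti <- anticodons[pick]
          tpl <- trna_template(anti)
          fam <- paste0("tRNA-", iso)
          score <- NA_real_
        }
        w <- nchar(tpl)
        start <- (g - 1L) * slot +
          sample.int(max(1L, slot - w - 100L), 1L) + 50L
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "-") revcomp_chr(tpl) else tpl
        bg[(start + 1L):(start + w)] <- strsplit(ins, "")[[1]]
        rows[[g]] <- data.frame(
          id = sprintf("%s_%d", tolower(kinds[g]), g), contig = "chr",
          start = start, end = start + w, strand = strand, part = 1L,
          type = kinds[g], source = "truth", score = score,
          isotype = iso, anticodon = anti, family = fam,
          stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rows)
    }
    g <- genome(stats::setNames(paste(bg, collapse = ""), "chr"),
                topology = spec$topology)
    list(genome = g,
         truth = if (is.null(truth)) gene_calls() else gene_calls(truth),
         spec = spec)
  })
}

jitter_ends <- function(n, sd) {
  if (sd <= 0) rep(0L, n) else as.integer(round(stats::rnorm(n, 0, sd)))
}

perturb_calls <- function(truth, spec, source, contig_len,
                          score_shift = 0) {
  n <- nrow(truth)
  keep <- if (spec$miss_rate > 0)
    stats::runif(n) >= spec$miss_rate else rep(TRUE, n)
  out <- as.data.frame(truth[keep, , drop = FALSE])
  if (nrow(out)) {
    ds <- jitter_ends(nrow(out), spec$jitter_sd)
    de <- jitter_ends(nrow(out), spec$jitter_sd)
    out$start <- pmax(0L, out$start + ds)
    out$end <- pmin(contig_len, pmax(out$start + 20L, out$end + de))
    out$source <- source
    out$id <- sprintf("%s.%s", tolower(source), out$id)
    out$score <- ifelse(out$type == "tRNA",
                        stats::rnorm(nrow(out), spec$score_mean,
                                     spec$score_sd) + score_shift,
                        NA_real_)
  }
  out
}

false_positive_calls <- function(spec, source, contig_len, type) {
  n <- spec$n_false_positive
  if (n <= 0L) return(NULL)
  w <- if (type == "tmRNA") 300L else 75L
  start <- sample.int(contig_len - w, n)
  data.frame(id = sprintf("%s.fp%d", tolower(source), seq_len(n)),
             contig = "chr", start = start, end = start + w,
             strand = sample(c("+", "-"), n, replace = TRUE), part = 1L,
             type = type, source = source,
             score = if (type == "tRNA")
               stats::rnorm(n, spec$score_mean - 30, spec$score_sd)
             else NA_real_,
             pseudo = FALSE, undetermined = FALSE,
             isotype = if (type == "tRNA") "Undet" else NA_character_,
             anticodon = NA_character_, family = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate predictor call sets from a truth table
#'
#' Emulates the raw output of the tmRNA callers (BRUCE and ARAGORN) and
#' the two tRNA callers (tRNAscan-SE and ARAGORN): truth calls are
#' perturbed by terminus jitter, dropped at the miss rate, and false
#' positives are placed uniformly in the background with depressed
#' scores. With a zero-noise spec every call reproduces its truth
#' coordinates exactly.
#'
#' @param fix output of [simulate_genome()].
#' @return list of [gene_calls] tables: `bruce` and `aragorn_tmrna`
#'   (tmRNA calls), `trnascan` and `aragorn_trna` (tRNA calls).
#' @export
simulate_predictor_calls <- function(fix) {
  spec <- fix$spec
  L <- contig_lengths(fix$genome)[["chr"]]
  tm <- fix$truth[fix$truth$type == "tmRNA", , drop = FALSE]
  tr <- fix$truth[fix$truth$type == "tRNA", , drop = FALSE]
  with_seed(spec$seed + 1L, {
    mk <- function(df) if (is.null(df) || nrow(df) == 0L) gene_calls()
                       else gene_calls(df)
    list(
      bruce = mk(rbind(perturb_calls(tm, spec, "BRUCE", L),
                       false_positive_calls(spec, "BRUCE", L, "tmRNA"))),
      aragorn_tmrna = mk(perturb_calls(tm, spec, "ARAGORN", L)),
      trnascan = mk(rbind(perturb_calls(tr, spec, "tRNAscan-SE", L),
                          false_positive_calls(spec, "tRNAscan-SE", L,
                                               "tRNA"))),
      aragorn_trna = mk(perturb_calls(tr, spec, "ARAGORN", L)))
  })
}

format_trnascan <- function(calls) {
  hdr <- c(paste0("Sequence\t\ttRNA\tBounds\t\ttRNA\tAnti\tIntron ",
                  "Bounds\tCove"),
           "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
           paste(rep("--------", 9L), collapse = "\t"))
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    b <- if (r$strand == "-") r$end else r$start + 1L
    e <- if (r$strand == "-") r$start + 1L else r$end
    note <- if (isTRUE(r$pseudo)) "\tpseudo" else ""
    sprintf("%s\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f%s", r$contig, i, b, e,
            r$isotype %||% "Undet",
            if (is.na(r$anticodon)) "NNN" else r$anticodon, r$score,
            note)
  }, "")
  c(hdr, rows)
}

format_aragorn <- function(calls) {
  out <- character()
  for (ctg in unique(calls$contig)) {
    out <- c(out, paste0(">", ctg))
    sub <- calls[calls$contig == ctg, , drop = FALSE]
    out <- c(out, sprintf("%d genes found", nrow(sub)))
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      gene <- if (r$type == "tmRNA") "tmRNA"
              else paste0("tRNA-", r$isotype)
      coord <- sprintf("%s[%d,%d]", if (r$strand == "-") "c" else "",
                       r$start + 1L, r$end)
      anti <- if (r$type == "tRNA" && !is.na(r$anticodon))
        sprintf("\t(%s)", tolower(r$anticodon)) else ""
      out <- c(out, sprintf("%d\t%s\t%s\t%d%s", i, gene, coord,
                            (r$start + r$end) %/% 2L, anti))
    }
  }
  out
}

#' Write a fixture's genome and predictor files in every dialect
#'
#' @param fix output of [simulate_genome()].
#' @param calls output of [simulate_predictor_calls()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_fixture_files <- function(fix, calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    truth_gff3 = file.path(dir, "truth.gff3"),
    truth_bed = file.path(dir, "truth.bed"),
    trnascan = file.path(dir, "trnascan.txt"),
    aragorn = file.path(dir, "aragorn.txt"),
    bruce_tsv = file.path(dir, "bruce.tsv"),
    terminus_db = file.path(dir, "termini.fasta"))
  write_genome(fix$genome, paths[["genome"]])
  write_calls(fix$truth, paths[["truth_gff3"]], "gff3")
  write_calls(fix$truth, paths[["truth_bed"]], "bed6")
  writeLines(format_trnascan(calls$trnascan), paths[["trnascan"]])
  writeLines(format_aragorn(bind_calls(calls$aragorn_tmrna,
                                       calls$aragorn_trna)),
             paths[["aragorn"]])
  b <- as.data.frame(calls$bruce)
  utils::write.table(
    data.frame(contig = b$contig, start = b$start, end = b$end,
               strand = b$strand, type = b$type, source = b$source,
               score = ifelse(is.na(b$score), ".",
                              as.character(b$score)),
               attrs = sprintf("id=%s;part=%d", b$id, b$part)),
    paths[["bruce_tsv"]], sep = "\t", quote = FALSE, row.names = FALSE)
  db <- fixture_terminus_db()
  writeLines(sprintf(">%s_%d %s\n%s", db$label, seq_len(nrow(db)),
                     db$label, db$seq),
             paths[["terminus_db"]])
  paths
}

#' Planted CDS x RNA-gene overlap scenarios
#'
#' One CDS/RNA pair per orientation x positional-class cell (8 pairs),
#' plus a ninth same-strand pair mimicking the smpB CDS intruding into
#' the 5' end of ssrA, the configuration expected to produce non-stop
#' smpB mRNAs.
#'
#' @param seed seed for the background genome sequence.
#' @return list with `genome`, `cds_calls`, `rna_calls` and `expected`
#'   (a data.frame of the planted cell per pair).
#' @export
make_overlap_scenarios <- function(seed = 1L) {
  block <- function(i) (i - 1L) * 1200L
  geom <- list( # cds offsets, rna offsets within a block, cds strand
    list("cds_upstream", c(300L, 600L), c(500L, 700L)),
    list("cds_downstream", c(600L, 900L), c(500L, 700L)),
    list("cds_internal", c(550L, 650L), c(500L, 700L)),
    list("cds_spanning", c(400L, 800L), c(500L, 700L)))
  cds <- list(); rna <- list(); exp <- list()
  i <- 0L
  for (orient in c("same", "opposite")) for (gm in geom) {
    i <- i + 1L
    off <- block(i)
    cds[[i]] <- data.frame(
      id = sprintf("cds_%d", i), contig = "scn",
      start = off + gm[[2]][1], end = off + gm[[2]][2],
      strand = if (orient == "same") "+" else "-", part = 1L,
      type = "CDS", source = "annotation", score = NA_real_,
      family = sprintf("PF%04d", i), stringsAsFactors = FALSE)
    rna[[i]] <- data.frame(
      id = sprintf("rna_%d", i), contig = "scn",
      start = off + gm[[3]][1], end = off + gm[[3]][2], strand = "+",
      part = 1L, type = "tRNA", source = "annotation",
      score = NA_real_, stringsAsFactors = FALSE)
    exp[[i]] <- data.frame(cds_id = sprintf("cds_%d", i),
                           rna_id = sprintf("rna_%d", i),
                           orientation = orient,
                           position_class = gm[[1]],
                           stringsAsFactors = FALSE)
  }
  ## Carsonella-style smpB -> ssrA intrusion: same strand, CDS past the
  ## RNA's 5' boundary
  off <- block(9L)
  cds[[9L]] <- data.frame(id = "smpB_cds", contig = "scn",
                          start = off + 200L, end = off + 520L,
                          strand = "+", part = 1L, type = "CDS",
                          source = "annotation", score = NA_real_,
                          family = "SmpB", stringsAsFactors = FALSE)
  rna[[9L]] <- data.frame(id = "ssrA", contig = "scn",
                          start = off + 470L, end = off + 820L,
                          strand = "+", part = 1L, type = "tmRNA",
                          source = "annotation", score = NA_real_,
                          stringsAsFactors = FALSE)
  exp[[9L]] <- data.frame(cds_id = "smpB_cds", rna_id = "ssrA",
                          orientation = "same",
                          position_class = "cds_upstream",
                          stringsAsFactors = FALSE)
  L <- block(10L)
  g <- with_seed(seed, genome(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), "scn")))
  list(genome = g,
       cds_calls = gene_calls(do.call(rbind, cds)),
       rna_calls = gene_calls(do.call(rbind, rna)),
       expected = do.call(rbind, exp))
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

synonymous_codons <- local({
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
})

#' Simulate a gapped alignment of orthologous tmRNA genes
#'
#' All rows derive from one random ancestor. Within the planted ORF,
#' substitutions are synonymous (the encoded amino acids stay
#' identical across rows); outside it every site mutates independently
#' with probability `divergence`. Optional short deletions are planted
#' outside the ORF only, so the ORF columns stay gap-free. Columns are
#' preserved by construction, making the rows a valid alignment.
#'
#' @param n number of orthologs (>= 3 for conservation scoring).
#' @param length_nt ungapped ancestor length.
#' @param frame planted reading-frame offset (0/1/2).
#' @param orf_codons ORF length in codons.
#' @param orf_codon_start 0-based codon index of the ORF start within
#'   the frame (default centers the ORF).
#' @param divergence per-site background substitution probability.
#' @param indels plant short deletions outside the ORF.
#' @param seed RNG seed.
#' @return list with `alignment` (named character vector), `frame`,
#'   `orf_start` (0-based nt) and `orf_codons`.
#' @export
make_ortholog_set <- function(n = 5L, length_nt = 360L, frame = 1L,
                              orf_codons = 20L, orf_codon_start = NULL,
                              divergence = 0.3, indels = FALSE,
                              seed = 1L) {
  stopifnot(frame %in% 0:2, n >= 2L)
  n_codons <- (length_nt - frame) %/% 3L
  if (is.null(orf_codon_start))
    orf_codon_start <- max(0L, (n_codons - orf_codons) %/% 2L)
  if (orf_codon_start + orf_codons > n_codons)
    stop_usage("ORF does not fit in the sequence")
  with_seed(seed, {
    anc <- sample(c("A", "C", "G", "T"), length_nt, replace = TRUE)
    orf_nt0 <- frame + orf_codon_start * 3L      # 0-based
    orf_pos <- (orf_nt0 + 1L):(orf_nt0 + orf_codons * 3L)
    orf_cod <- sample(SENSE_CODONS, orf_codons, replace = TRUE)
    anc[orf_pos] <- unlist(strsplit(orf_cod, ""))
    rows <- list()
    for (s in seq_len(n)) {
      x <- anc
      bg <- setdiff(seq_len(length_nt), orf_pos)
      mut <- bg[stats::runif(length(bg)) < divergence]
      for (p in mut)
        x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
      for (j in seq_len(orf_codons)) {
        if (stats::runif(1) < divergence) {
          cod <- paste(x[orf_pos[(j - 1L) * 3L + 1:3]], collapse = "")
          syn <- synonymous_codons[[Biostrings::GENETIC_CODE[[cod]]]]
          x[orf_pos[(j - 1L) * 3L + 1:3]] <-
            strsplit(sample(syn, 1L), "")[[1]]
        }
      }
      if (indels && s > 1L) {
        w <- sample(1:4, 1L)
        cand <- bg[bg + w - 1L < orf_pos[1] | bg > orf_pos[length(orf_pos)]]
        cand <- cand[cand + w <= length_nt]
        at <- sample(cand, 1L)
        x[at:(at + w - 1L)] <- "-"
      }
      rows[[s]] <- paste(x, collapse = "")
    }
    list(alignment = stats::setNames(unlist(rows),
                                     sprintf("strain%02d", seq_len(n))),
         frame = frame, orf_start = orf_nt0, orf_codons = orf_codons)
  })
}
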