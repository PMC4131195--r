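test_that("merging collapses >= 1 bp overlaps but not abutting calls", {
  expect_equal(nrow(merge_calls(gene_calls())), 0L)
  calls <- gene_calls(data.frame(
    id = c("a", "b", "c"), contig = "c1",
    start = c(10L, 19L, 30L), end = c(20L, 30L, 40L),
    strand = "+", type = "other", source = c("A", "B", "A"),
    stringsAsFactors = FALSE))
  m <- merge_calls(calls)
  expect_equal(nrow(m), 2L)            # (10,30) merged; 30 abuts, stays
  expect_equal(m$start, c(10L, 30L))
  expect_equal(m$end, c(30L, 40L))
  expect_setequal(m$members[[1]], c("a", "b"))
  expect_equal(m$source_family[1], "A+B")
})

test_that("merging equals the brute-force overlap-closure oracle", {
  withr::local_seed(101)
  for (rep in 1:40) {
    calls <- random_calls(sample(0:50, 1))
    for (mode in c("ignore", "require_same")) {
      got <- merged_as_plain(merge_calls(calls, mode))
      want <- brute_merge(calls, mode)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[, c("contig", "start", "end")],
                   want[, c("contig", "start", "end")])
      expect_equal(got$members, want$members)
    }
  }
})

mk_trnascan <- function(score, pseudo = FALSE, undet = FALSE,
                        start = 100L, strand = "+", anticodon = "CGC",
                        id = "ts1") {
  gene_calls(data.frame(id = id, contig = "c1", start = start,
                        end = start + 72L, strand = strand, type = "tRNA",
                        source = "tRNAscan-SE", score = score,
                        pseudo = pseudo, undetermined = undet,
                        isotype = "Ala", anticodon = anticodon,
                        stringsAsFactors = FALSE))
}

mk_corrob <- function(start = 110L, strand = "+", anticodon = "CGC",
                      id = "ar1") {
  gene_calls(data.frame(id = id, contig = "c1", start = start,
                        end = start + 70L, strand = strand,
                        type = "tRNA", source = "ARAGORN",
                        anticodon = anticodon, stringsAsFactors = FALSE))
}

test_that("tRNA validity needs score, flags and corroboration", {
  # the reference case: high score, unflagged, corroborated
  r <- classify_trnas(mk_trnascan(61.2), mk_corrob())
  expect_equal(r$status[r$source == "tRNAscan-SE"], "tRNA_valid")
  # boundary is strict: a score of exactly 50 (or below) is not "above"
  r <- classify_trnas(mk_trnascan(49.9), mk_corrob())
  expect_true(all(r$status == "tRNA_questionable"))
  r <- classify_trnas(mk_trnascan(50.0), mk_corrob())
  expect_true(all(r$status == "tRNA_questionable"))
  # Pseudo / Undetermined exclude validity outright
  r <- classify_trnas(mk_trnascan(80, pseudo = TRUE), mk_corrob())
  expect_true(all(r$status == "tRNA_questionable"))
  r <- classify_trnas(mk_trnascan(80, undet = TRUE), mk_corrob())
  expect_true(all(r$status == "tRNA_questionable"))
  # no corroborating overlap at all
  r <- classify_trnas(mk_trnascan(80), mk_corrob(start = 5000L))
  expect_setequal(r$status, "tRNA_questionable")
  expect_equal(nrow(r), 2L)
  # corroboration must be same strand
  r <- classify_trnas(mk_trnascan(80), mk_corrob(strand = "-"))
  expect_setequal(r$status, "tRNA_questionable")
  # anticodon disagreement blocks corroboration when both report one
  r <- classify_trnas(mk_trnascan(80), mk_corrob(anticodon = "GCC"))
  expect_setequal(r$status, "tRNA_questionable")
  r <- classify_trnas(mk_trnascan(80),
                      mk_corrob(anticodon = NA_character_))
  expect_equal(r$status[r$source == "tRNAscan-SE"], "tRNA_valid")
})

test_that("a missing Cove score warns and classifies questionable", {
  expect_warning(r <- classify_trnas(mk_trnascan(NA_real_), mk_corrob()),
                 "without Cove score")
  expect_true(all(r$status == "tRNA_questionable"))
})

test_that("valid and questionable partition the deduplicated call set", {
  withr::local_seed(7)
  fix <- simulate_genome(fixture_spec(seed = 20, jitter_sd = 1,
                                      miss_rate = 0.1,
                                      n_false_positive = 4L))
  pc <- simulate_predictor_calls(fix)
  r <- classify_trnas(pc$trnascan, pc$aragorn_trna)
  expect_true(all(r$status %in% c("tRNA_valid", "tRNA_questionable")))
  key <- paste(r$contig, r$start, r$end, r$strand)
  expect_false(any(duplicated(key)))
  # every tRNAscan call is accounted for: valid, or questionable, or
  # equal to a retained interval
  expect_true(all(pc$trnascan$id %in% r$id |
                    paste(pc$trnascan$contig, pc$trnascan$start,
                          pc$trnascan$end, pc$trnascan$strand) %in% key))
})

test_that("tmRNA duplicate resolution applies the rejection rules", {
  fix <- simulate_genome(zero_noise_spec(seed = 31))
  db <- fixture_terminus_db()
  tm <- fix$truth[fix$truth$type == "tmRNA", ]
  trna_truth <- fix$truth[fix$truth$type == "tRNA", ]
  valid <- classify_trnas(
    gene_calls(transform(as.data.frame(trna_truth), score = 80,
                         source = "tRNAscan-SE")),
    gene_calls(transform(as.data.frame(trna_truth),
                         id = paste0("ar.", id), source = "ARAGORN")))
  # clean full-length calls with both termini are accepted
  res <- resolve_tmrna_duplicates(tm, valid, db, fix$genome)
  expect_true(all(res$status == "tmRNA_accepted"))
  # a call overlapping a valid tRNA is rejected for that reason
  vt <- valid[valid$status == "tRNA_valid", ][1, ]
  clash <- gene_call("dup1", vt$contig, vt$start + 5L, vt$end + 200L,
                     strand = "-", type = "tmRNA")  # either strand counts
  res <- resolve_tmrna_duplicates(clash, valid, db, fix$genome)
  expect_equal(res$status, "rejected")
  expect_equal(res$rejection_reason, "overlaps_valid_trna")
  # questionable tRNAs never trigger that rejection
  quest_only <- valid
  quest_only$status <- "tRNA_questionable"
  res <- resolve_tmrna_duplicates(clash, quest_only)
  expect_equal(res$status, "tmRNA_accepted")
  # a 5'-truncated pseudogene (missing one end) is rejected
  cut <- tm[1, ]
  cut$start <- cut$start + if (cut$strand == "+") 40L else 0L
  cut$end <- cut$end - if (cut$strand == "-") 40L else 0L
  res <- resolve_tmrna_duplicates(gene_calls(as.data.frame(cut)), valid,
                                  db, fix$genome)
  expect_equal(res$status, "rejected")
  expect_equal(res$rejection_reason, "missing_terminus")
})

test_that("multiple accepted tmRNAs per replicon are flagged, kept", {
  fix <- simulate_genome(zero_noise_spec(seed = 31))
  tm <- fix$truth[fix$truth$type == "tmRNA", ]
  res <- resolve_tmrna_duplicates(tm, gene_calls())
  expect_true(all(res$status == "tmRNA_accepted"))
  expect_true(all(res$multi_allele))   # 3 accepted alleles on one contig
  res1 <- resolve_tmrna_duplicates(tm[tm$id == tm$id[1], ], gene_calls())
  expect_false(any(res1$multi_allele))
})

test_that("terminus refinement recovers planted motif boundaries", {
  fix <- simulate_genome(zero_noise_spec(seed = 5))
  db <- fixture_terminus_db()
  tm <- fix$truth[fix$truth$type == "tmRNA", ][1, ]
  exact <- seq_region(tm$contig, tm$start, tm$end, tm$strand)
  r <- refine_termini(fix$genome, exact, db)
  expect_equal(c(r$region$start, r$region$end), c(tm$start, tm$end))
  expect_equal(r$report$mismatches, c(0L, 0L))
  expect_equal(r$report$shift, c(0L, 0L))
  # candidate trimmed 12 nt into the gene at its 5' end: the 5'
  # boundary moves back by -12
  trim <- if (tm$strand == "+")
    seq_region(tm$contig, tm$start + 12L, tm$end, tm$strand)
  else seq_region(tm$contig, tm$start, tm$end - 12L, tm$strand)
  r <- refine_termini(fix$genome, trim, db)
  expect_equal(c(r$region$start, r$region$end), c(tm$start, tm$end))
  expect_equal(r$report$shift[r$report$class == "five_prime"], -12L)
  # with no 3' motif in range, that boundary is reported unrefined
  db5 <- db[db$label == "five_prime", ]
  db5no3 <- rbind(db5, data.frame(label = "three_prime",
                                  seq = "GGGGGGGGGGGGGGG"))
  r <- refine_termini(fix$genome, exact, db5no3)
  expect_false(r$report$refined[r$report$class == "three_prime"])
  expect_equal(r$region$end - r$region$start, tm$end - tm$start)
})

test_that("terminus refinement tolerates mismatches up to the cap", {
  fix <- simulate_genome(zero_noise_spec(seed = 5))
  db <- fixture_terminus_db()
  # mutate 2 bases of the planted 5' motif in the genome copy
  tm <- fix$truth[fix$truth$type == "tmRNA", ][1, ]
  seqs <- as.character(fix$genome$seq)
  ch <- strsplit(seqs[["chr"]], "")[[1]]
  pos <- if (tm$strand == "+") tm$start + c(2L, 6L) else
    tm$end - 1L - c(2L, 6L)
  ch[pos + 1L] <- ifelse(ch[pos + 1L] == "A", "C", "A")
  g2 <- genome(c(chr = paste(ch, collapse = "")))
  r <- refine_termini(g2, seq_region(tm$contig, tm$start, tm$end,
                                     tm$strand), db)
  expect_true(all(r$report$refined))
  expect_equal(r$report$mismatches[r$report$class == "five_prime"], 2L)
  r3 <- refine_termini(g2, seq_region(tm$contig, tm$start, tm$end,
                                      tm$strand), db, max_mismatch = 1L)
  expect_false(r3$report$refined[r3$report$class == "five_prime"])
})

test_that("terminus databases are validated", {
  expect_error(refine_termini(
    genome(c(c1 = "ACGTACGTACGT")), seq_region("c1", 0, 8),
    data.frame(label = "five_prime", seq = "ACGTA")), "10-40 nt")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">m1 five_prime", "ACGTACGTACGTACG",
               ">m2 three_prime", "GGGTACGTACGTACG"), f)
  db <- read_terminus_db(f)
  expect_equal(db$label, c("five_prime", "three_prime"))
  writeLines(c(">m1 fiveprime", "ACGTACGTACGTACG"), f)
  expect_error(read_terminus_db(f), "five_prime or three_prime")
})

test_that("profile thresholds are factor x best decoy", {
  hits <- data.frame(query_id = sprintf("q%d", 1:6),
                     profile_id = rep(c("P1", "P2"), each = 3),
                     score = c(50, 40, 90, 10, 35, 20),
                     label = c("decoy", "decoy", "target",
                               "decoy", "decoy", "decoy"))
  th <- calibrate_profile_threshold(hits)
  expect_equal(unname(th["P1"]), 70)     # 1.4 x 50
  expect_equal(unname(th["P2"]), 49)     # 1.4 x 35
  cl <- classify_profile_hits(hits, th)
  expect_equal(cl$category[cl$score == 90], "above_threshold")
  # a profile without decoys cannot be calibrated
  expect_error(calibrate_profile_threshold(
    data.frame(query_id = "q", profile_id = "P3", score = 5,
               label = "target")), "no decoy")
})

test_that("with factor > 1 no decoy is ever above threshold", {
  withr::local_seed(55)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    hits <- data.frame(
      query_id = sprintf("q%d", seq_len(n)),
      profile_id = sample(c("A", "B"), n, replace = TRUE),
      score = round(stats::runif(n, 0.1, 100), 2),
      label = sample(c("target", "decoy"), n, replace = TRUE,
                     prob = c(0.4, 0.6)))
    for (p in unique(hits$profile_id))
      if (!any(hits$label[hits$profile_id == p] == "decoy"))
        hits$label[which(hits$profile_id == p)[1]] <- "decoy"
    th <- calibrate_profile_threshold(hits, factor = 1.4)
    decoys <- hits[hits$label == "decoy", ]
    expect_true(all(decoys$score < th[decoys$profile_id]))
  }
})

test_that("reconciliation statuses are invariant under genome-wide
           reverse complement", {
  fix <- simulate_genome(fixture_spec(seed = 77, jitter_sd = 1,
                                      miss_rate = 0,
                                      n_false_positive = 3L))
  pc <- simulate_predictor_calls(fix)
  lens <- contig_lengths(fix$genome)
  r1 <- classify_trnas(pc$trnascan, pc$aragorn_trna)
  r2 <- classify_trnas(reverse_complement_calls(pc$trnascan, lens),
                       reverse_complement_calls(pc$aragorn_trna, lens))
  expect_equal(sort(paste(r1$id, r1$status)),
               sort(paste(r2$id, r2$status)))
  g2 <- reverse_complement_genome(fix$genome)
  db <- fixture_terminus_db()
  tm <- fix$truth[fix$truth$type == "tmRNA", ]
  s1 <- resolve_tmrna_duplicates(tm, r1, db, fix$genome)
  s2 <- resolve_tmrna_duplicates(reverse_complement_calls(tm, lens),
                                 r2, db, g2)
  expect_equal(sort(paste(s1$id, s1$status)),
               sort(paste(s2$id, s2$status)))
})
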