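# one-piece tmRNA-like sequence with a prescribed acceptor stem:
# stem 5' side at positions 0..6, 3' side at L-5-i, terminal ACCA
mk_tmrna_seq <- function(five = "GGGGCTG", three = NULL, mid = 40L) {
  if (is.null(three))
    three <- paste(rev(chartr("ACGT", "TGCA",
                              strsplit(five, "")[[1]])), collapse = "")
  paste0(five, strrep("A", mid), three, "ACCA")
}

test_that("acceptor-stem pairs classify by identity", {
  s <- mk_tmrna_seq()                      # closing pair G:C
  r <- check_acceptor_pairs(s)
  expect_equal(r$pairs$class[1], "canonical_GC")
  expect_true(all(r$pairs$class %in%
                    c("canonical_GC", "watson_crick", "wobble_GU")))
  # the anomalous A:U closing pair is Watson-Crick but not canonical
  s2 <- mk_tmrna_seq(five = "AGGGCTG",
                     three = "CAGCCCT")    # pos0 A : pos L-5 T
  r2 <- check_acceptor_pairs(s2)
  expect_equal(r2$pairs$class[1], "watson_crick")
  # the post-deletion G:U pair is a wobble
  s3 <- mk_tmrna_seq(five = "GGGGCTG", three = "CAGCCCT")
  r3 <- check_acceptor_pairs(s3)
  expect_equal(r3$pairs$class[1], "wobble_GU")
  # non-pairing
  s4 <- mk_tmrna_seq(five = "AGGGCTG", three = "CAGCCCC")
  expect_equal(check_acceptor_pairs(s4)$pairs$class[1], "non_pairing")
})

test_that("the G3:U70-style determinant is read at stem index 2", {
  # make pair index 2 (third pair) G:U
  s <- mk_tmrna_seq(five = "GGGGCTG", three = "CAGCTCC")
  r <- check_acceptor_pairs(s)
  expect_true(r$determinant_3_70)
  expect_false(check_acceptor_pairs(mk_tmrna_seq())$determinant_3_70)
})

test_that("a non-CCA sequence demands an explicit stem map", {
  expect_error(check_acceptor_pairs("GGGGAAACCCCTTT"), "stem_map")
  sm <- stem_map(0:1, c(13L, 12L))
  r <- check_acceptor_pairs("GGGGAAACCCCTTT", sm)
  expect_equal(nrow(r$pairs), 2L)
  expect_error(stem_map(3L, 2L), "five_prime_index")
})

test_that("substitutions only affect pairs containing them (locality)", {
  withr::local_seed(77)
  s <- mk_tmrna_seq()
  base <- check_acceptor_pairs(s)$pairs$class
  ch <- strsplit(s, "")[[1]]
  for (rep in 1:20) {
    i <- sample(seq_along(ch), 1)
    ch2 <- ch
    ch2[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    s2 <- paste(ch2, collapse = "")
    if (!endsWith(s2, "CCA")) next
    now <- check_acceptor_pairs(s2)$pairs$class
    touched <- check_acceptor_pairs(s2)$pairs$five_prime_index == i - 1L |
      check_acceptor_pairs(s2)$pairs$three_prime_index == i - 1L
    expect_equal(now[!touched], base[!touched])
  }
})

test_that("tag-frame scan recovers a planted frame", {
  for (f in 0:2) {
    os <- make_ortholog_set(seed = 40 + f, frame = f)
    r <- find_tag_frame(os$alignment)
    expect_equal(r$frame, f)
    expect_lte(abs(r$start - os$orf_start), 3L)   # within 1 codon
    expect_gt(r$score, 0.95)
  }
})

test_that("identical rows tie-break to frame 0, leftmost window", {
  aln <- stats::setNames(rep(paste(rep("ATGGCTGCA", 12), collapse = ""),
                             4), paste0("s", 1:4))
  r <- find_tag_frame(aln, window_codons = 10)
  expect_equal(r$frame, 0L)
  expect_equal(r$start, 0L)
  expect_equal(r$score, 1.0)
  expect_error(find_tag_frame(aln[1:2]), "fewer than 3")
})

test_that("a stop conserved across rows is annotated in the result", {
  # identical rows with TAA at codon 3: every frame-0 window scores 1.0
  # and the winning leftmost window must report the modal stop
  row <- paste0("ATGGCT", "TAA",
                paste(rep(c("GCA", "CTG", "GAT"), 4), collapse = ""))
  aln <- stats::setNames(rep(row, 4), paste0("s", 1:4))
  r <- find_tag_frame(aln, window_codons = 10)
  expect_equal(r$frame, 0L)
  expect_equal(r$stop_codons, 3L)
})

test_that("gaps project as missing codons, not errors", {
  os <- make_ortholog_set(seed = 51, frame = 1, indels = TRUE)
  expect_true(any(grepl("-", os$alignment, fixed = TRUE)))
  r <- find_tag_frame(os$alignment)
  expect_equal(r$frame, 1L)
})

test_that("ORF integrity classifies intact genes and pseudogenes", {
  withr::local_seed(88)
  ref <- random_protein(100)
  nt <- back_translate(ref)
  expect_equal(orf_integrity(nt, ref)$verdict, "intact")
  # two in-frame TAA insertions -> pseudogene with 2 located stops
  nt2 <- paste0(substr(nt, 1, 90), "TAA", substr(nt, 91, 180), "TAA",
                substr(nt, 181, 300))
  r <- orf_integrity(nt2, ref)
  expect_equal(r$verdict, "pseudogene_stops")
  expect_equal(r$internal_stops, c(31L, 62L))
  # degenerate input
  r0 <- orf_integrity(strrep("A", 60), random_protein(20))
  expect_equal(r0$verdict, "truncated")
})

test_that("verdicts are mutually exclusive over perturbed fixtures", {
  withr::local_seed(89)
  for (rep in 1:10) {
    ref <- random_protein(80)
    nt <- back_translate(ref)
    cases <- list(
      nt,
      paste0(substr(nt, 1, 99), "TAA", substr(nt, 100, 240)),
      paste0(substr(nt, 1, 119), substr(nt, 121, 240)),
      substr(nt, 1, 120))
    verdicts <- vapply(cases, function(x)
      orf_integrity(x, ref)$verdict, "")
    expect_equal(verdicts, c("intact", "pseudogene_stops",
                             "frameshifted", "truncated"))
  }
})

test_that("a planted single-nucleotide deletion is localized", {
  withr::local_seed(90)
  for (rep in 1:10) {
    ref <- random_protein(150)
    nt <- back_translate(ref)
    b <- sample(30:120, 1)
    nt_del <- paste0(substr(nt, 1, b * 3 - 1), substr(nt, b * 3 + 1,
                                                      450))
    r <- orf_integrity(nt_del, ref)
    expect_equal(r$verdict, "frameshifted")
    expect_lte(abs(r$frameshift$breakpoint - b), 3L)
    expect_equal(r$frameshift$frame_before, 0L)
  }
})

test_that("truncations report uncovered reference ends", {
  withr::local_seed(91)
  ref <- random_protein(100)
  nt <- back_translate(ref)
  r <- orf_integrity(substr(nt, 91, 300), ref)   # first 30 codons gone
  expect_equal(r$verdict, "truncated")
  expect_equal(r$n_truncation, 30L)
  expect_equal(r$c_truncation, 0L)
})

mk_aln <- function(rows) {
  stats::setNames(rows, sprintf("s%d", seq_along(rows)))
}

test_that("region presence applies the gap-fraction threshold", {
  aln <- mk_aln(c("MKLVAEQRTYW",          # reference, ungapped
                  "MKLV-----YW",          # loop fully gapped -> absent
                  "MKLVAE--TYW",          # 40% gapped -> present
                  "MKLVAEQRTYW"))
  r <- region_presence(aln, list(loop = c(5L, 9L)), gap_threshold = 0.8)
  expect_equal(unname(r$presence[, "loop"]),
               c("present", "absent", "present", "present"))
  # 50% gaps at threshold 0.5 counts as absent (>= rule)
  r2 <- region_presence(aln, list(loop = c(5L, 8L)),
                        gap_threshold = 0.5)
  expect_equal(unname(r2$presence[2:3, "loop"]), c("absent", "absent"))
  expect_error(region_presence(aln, list(loop = c(5L, 99L))),
               "outside")
  expect_error(region_presence(aln[c(2, 1, 3, 4)],
                               list(loop = c(5L, 9L))), "gapped over")
})

test_that("region presence reports C-terminal extensions", {
  aln <- mk_aln(c("MKLVAEQRT--", "MKLVAEQRTYW", "MKLVAEQRT-W"))
  r <- region_presence(aln, list(core = c(1L, 9L)))
  expect_equal(unname(r$extensions), c(0L, 2L, 1L))
  # deletions in exactly 3 of 10 rows are the 3 absences
  rows <- rep("MKLVAEQRTYW", 10)
  rows[c(2, 5, 9)] <- "MKLV-----YW"
  r2 <- region_presence(mk_aln(rows), list(loop = c(5L, 9L)))
  expect_equal(unname(which(r2$presence[, "loop"] == "absent")),
               c(2L, 5L, 9L))
})

test_that("region presence ignores columns outside the named regions", {
  aln <- mk_aln(c("MKLVAEQRTYW", "MKLV-----YW", "MK--AEQRTYW"))
  r1 <- region_presence(aln, list(loop = c(5L, 9L)))
  # permute columns outside the region (swap 1:2 with 10:11)
  perm <- function(s) paste0(substr(s, 10, 11), substr(s, 3, 9),
                             substr(s, 1, 2))
  aln2 <- mk_aln(vapply(aln, perm, ""))
  r2 <- region_presence(aln2, list(loop = c(5L, 9L)))
  expect_equal(unname(r2$presence[, 1]), unname(r1$presence[, 1]))
})
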