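test_that("IUPAC patterns expand to the documented concrete motifs", {
  expect_setequal(expand_iupac("GUURUA"), c("GUUAUA", "GUUGUA"))
  expect_setequal(expand_iupac("YRU"), c("UAU", "UGU", "CAU", "CGU"))
  expect_setequal(expand_iupac("N"), c("A", "C", "G", "U"))
  expect_setequal(expand_iupac("GUUYMA"),
                  c("GUUCAA", "GUUCCA", "GUUUAA", "GUUUCA"))
  expect_identical(length(expand_iupac("NNN")), 64L)
  expect_error(expand_iupac("GUX"), "invalid IUPAC")
  # DNA spelling accepted
  expect_setequal(expand_iupac("YRT"), c("UAU", "UGU", "CAU", "CGU"))
})

test_that("the default motif set covers the six ADE variants plus CDE", {
  pats <- roquin_motifs()
  expect_identical(nrow(pats), 7L)
  ade <- unlist(lapply(pats$iupac[pats$label != "CDE"], expand_iupac))
  # every expanded hexaloop keeps the invariant UU at positions 2-3
  expect_true(all(substr(ade, 2, 3) == "UU"))
  # the variant motifs extend beyond the canonical GUUYUA consensus, which
  # is deliberately not part of the novel-element search set
  expect_false(any(expand_iupac("GUUYUA") %in% ade))
  expect_true("GUUGUA" %in% ade)
})

test_that("find_candidates requires both a motif match and a closing stem", {
  utr <- paste0(strrep("A", 20), "GGCGGCG", "GUUGUA", "CGCCGCC",
                strrep("A", 20))
  cand <- find_candidates(utr, min_stem = 6, seq_id = "toy")
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$loop, "GUUGUA")
  expect_identical(cand$loop_start, 27L)
  expect_identical(cand$loop_end, 33L)
  expect_gte(cand$stem_len, 6L)
  # motif present but no complementary flanks
  expect_identical(nrow(find_candidates(paste0(strrep("A", 10), "GUUGUA",
                                               strrep("A", 10)))), 0L)
  expect_identical(nrow(find_candidates(strrep("A", 60))), 0L)
  expect_identical(nrow(find_candidates("")), 0L)
})

test_that("predicted elements carry folding probabilities and status flags", {
  good <- paste0(strrep("A", 20), "GGCGGCG", "GUUGUA", "CGCCGCC",
                 strrep("A", 20))
  scrambled <- paste0(strrep("A", 20), "GGCGGCG", "GUUGUA", "CCCGGGC",
                      strrep("A", 20))
  sc <- predict_elements(c(good = good, bad = scrambled))
  expect_identical(nrow(sc), 1L)   # scrambled arm never forms the stem
  expect_identical(sc$seq_id, "good")
  expect_gt(sc$p_fold, 0.19)
  expect_identical(sc$status, "high_confidence")
  per_seq <- attr(sc, "per_sequence")
  expect_identical(nrow(per_seq), 1L)
  # FASTA record order does not change the candidate set
  sc2 <- predict_elements(c(bad = scrambled, good = good))
  expect_identical(sc$p_fold, sc2$p_fold)
  expect_identical(nrow(predict_elements(character(0))), 0L)
})

test_that("weak stems are excluded below the folding threshold", {
  # AU-only 6 bp stem with competing context folds poorly
  weak <- paste0("GUAUAUAUCC", "AUAUAU", "GUUGUA", "AUAUAU", "GGAUAUAUAC")
  sc <- predict_elements(c(w = weak), exclude_below = 0.05, high_conf = 0.19)
  if (nrow(sc) > 0) {
    expect_true(all(sc$p_fold[sc$status == "excluded"] < 0.05))
    expect_true(all(sc$p_fold[sc$status == "high_confidence"] >= 0.19))
  }
  # strengthening thresholds never increases reported candidates
  good <- paste0(strrep("A", 20), "GGCGGCG", "GUUGUA", "CGCCGCC",
                 strrep("A", 20))
  n_rep <- function(min_stem, hc) {
    sc <- predict_elements(c(g = good), min_stem = min_stem, high_conf = hc)
    sum(sc$status == "high_confidence")
  }
  expect_gte(n_rep(6, 0.19), n_rep(7, 0.19))
  expect_gte(n_rep(6, 0.19), n_rep(6, 0.60))
})

test_that("scan reads FASTA, skips bad records and writes TSV + BED", {
  fa <- tempfile(fileext = ".fa")
  good <- paste0(strrep("A", 20), "GGCGGCG", "GUUGUA", "CGCCGCC",
                 strrep("A", 20))
  writeLines(c(">utr1 some description", chartr("U", "T", good),
               ">utr2", "ACGTNNNACGT"), fa)
  expect_warning(sc <- predict_elements(fa), "non-nucleotide")
  expect_identical(sc$seq_id, "utr1")
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_scan(sc, tsv = tsv, bed = bed)
  out <- read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(out$loop, "GUUGUA")
  b <- read.table(bed, sep = "\t")
  expect_identical(b$V2, 27L)                      # 0-based start
  expect_identical(b$V3, 33L)                      # half-open end
  expect_identical(b$V5, as.integer(round(1000 * sc$p_fold)))
  expect_identical(b$V4, paste0(sc$pattern, "|", sc$loop))
})

test_that("wobble stems are admitted only with allow_wobble", {
  utr <- paste0(strrep("A", 15), "GGUGGUG", "GUUGUA", "UGCCGCC",
                strrep("A", 15))
  # the closing stem contains G-U pairs
  n_wc <- nrow(find_candidates(utr, min_stem = 6, allow_wobble = FALSE))
  n_wb <- nrow(find_candidates(utr, min_stem = 6, allow_wobble = TRUE))
  expect_identical(n_wc, 0L)
  expect_identical(n_wb, 1L)
})
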