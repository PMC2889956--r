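test_that("mt translation handles complete and polyadenylation-completed stops", {
  t1 <- translate_mt("ATGTGATAA")
  expect_equal(t1$protein, "MW")   # TGA is Trp in the mt code
  expect_equal(t1$stop_status, "complete")
  expect_true(t1$valid)

  t2 <- translate_mt("ATGGCCT")
  expect_equal(t2$protein, "MA")
  expect_equal(t2$stop_status, "completed_by_polyadenylation")
  expect_equal(t2$stop_codon, "T")

  t3 <- translate_mt("ATGGCCTA")
  expect_equal(t3$stop_codon, "TA")

  t4 <- translate_mt("ATGGCCT", allow_abbreviated_stop = FALSE)
  expect_equal(t4$stop_status, "missing")
  expect_false(t4$valid)

  # AGA is a stop in the vertebrate mt code: internal stop is a
  # validation failure, not an exception
  t5 <- translate_mt("ATGAGATAA")
  expect_equal(t5$internal_stops, 1)
  expect_false(t5$valid)

  expect_equal(translate_mt("ATGNNNTAA")$protein, "MX")
  expect_error(translate_mt("AT"), "at least one codon")
  expect_error(translate_mt("ATGXYZ"), "A/C/G/T/N")
})

test_that("the codon table matches an independent table on all 64 codons", {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  code <- mt_genetic_code()
  expect_length(code, 64)
  for (cd in codons) {
    expect_equal(unname(code[cd]), oracle_mt_translate(cd), label = cd)
  }
  expect_equal(unname(code[c("AGA", "AGG", "ATA", "TGA")]),
               c("*", "*", "M", "W"))
})

test_that("translation of random open frames matches the oracle codon-by-codon", {
  for (s in 1:50) {
    n_codons <- 300
    seqr <- random_seq(3 * n_codons, seed = 6000 + s)
    codons <- substring(seqr, seq(1, 3 * n_codons, 3), seq(3, 3 * n_codons, 3))
    aa <- oracle_mt_translate(codons)
    got <- translate_mt(seqr, allow_abbreviated_stop = FALSE)
    ref <- if (aa[n_codons] == "*") {
      paste(aa[-n_codons], collapse = "")
    } else {
      paste(aa, collapse = "")
    }
    # internal stops are retained in the reported protein string
    expect_equal(got$protein, ref)
    expect_equal(got$internal_stops, sum(aa[-n_codons] == "*"))
  }
})

test_that("planted anticodons are recovered from cloverleaf-consistent tRNAs", {
  expect_equal(extract_anticodon(simulate_trna("TGG", seed = 1)$sequence)$anticodon,
               "TGG")
  expect_equal(extract_anticodon(simulate_trna("CGG", seed = 2)$sequence)$anticodon,
               "CGG")
  ok <- 0
  for (s in 1:50) {
    set.seed(s + 800)
    ac <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                collapse = "")
    tr <- simulate_trna(ac, seed = s)
    got <- extract_anticodon(tr$sequence)
    if (identical(got$anticodon, ac)) ok <- ok + 1
  }
  expect_equal(ok, 50)
})

test_that("anticodon extraction is invariant to short acceptor-end padding", {
  for (s in 1:20) {
    tr <- simulate_trna("TGG", seed = 100 + s)
    base <- extract_anticodon(tr$sequence)
    for (pad in 1:3) {
      left <- random_seq(pad, seed = 7000 + s)
      right <- random_seq(pad, seed = 7100 + s)
      padded <- paste0(left, tr$sequence, right)
      got <- extract_anticodon(padded)
      expect_equal(got$anticodon, base$anticodon)
    }
  }
})

test_that("anticodon extraction bounds and degenerate inputs behave", {
  expect_error(extract_anticodon(strrep("A", 40)), "length")
  expect_error(extract_anticodon(strrep("A", 120)), "length")
  # a homopolymer folds nothing: undetermined result, not an exception
  res <- extract_anticodon(strrep("A", 70))
  expect_false(res$determined)
  expect_true(is.na(res$anticodon))
})

test_that("a planted perfect stem-loop is called with its geometry", {
  w <- simulate_wancy(TRUE, seed = 4, stem_length = 8, loop_length = 5)
  call <- detect_ol_hairpin(w$sequence, min_stem = 6)
  expect_true(call$present)
  expect_gte(call$stem_length, 8)
  expect_equal(call$loop_end - call$loop_start + 1, call$loop_length)
  expect_equal(call$stem_end - call$stem_start + 1,
               2 * call$stem_length + call$loop_length)
})

test_that("hairpin presence agrees with a brute-force pairing oracle", {
  n_present <- 0
  for (s in 1:100) {
    seqr <- random_seq(40, seed = 9000 + s)
    got <- detect_ol_hairpin(seqr, min_stem = 8)$present
    expect_equal(got, oracle_has_hairpin(seqr, min_stem = 8))
    if (got) n_present <- n_present + 1
  }
  # chance 8-bp perfect stems in 40 nt are rare under the null
  expect_lt(n_present, 20)
})

test_that("hairpin calls are monotone in the stem threshold", {
  for (s in 1:30) {
    seqr <- random_seq(60, seed = 9500 + s)
    calls <- vapply(4:9, function(k) {
      detect_ol_hairpin(seqr, min_stem = k)$present
    }, logical(1))
    # once absent at a threshold, absent at every higher threshold
    expect_true(all(diff(as.integer(calls)) <= 0))
  }
  expect_warning(out <- detect_ol_hairpin(""), "empty")
  expect_false(out$present)
})

test_that("fixture replication-origin states match the reported taxa", {
  fx <- study_fixture()
  expect_equal(sum(fx$characters$C4 == "present"), 27)
  absent <- fx$characters$taxon[fx$characters$C4 == "absent"]
  expect_setequal(absent, c("Uromastyx_benti", "Hydrosaurus_amboinensis",
                            "Pogona_vitticeps", "Chlamydosaurus_kingii"))
  # orders mirror the states: OL dropped exactly for those taxa
  for (i in seq_len(nrow(fx$records))) {
    ord <- linearize(fx$records[i, ])
    expect_equal("OL" %in% ord$name,
                 fx$characters$C4[i] == "present")
  }
})
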