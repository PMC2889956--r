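test_that("planted motifs are found exactly once at the planted position", {
  set.seed(7)
  boxd <- default_motifs()$pattern[default_motifs()$name == "BoxD"]
  bg <- paste(sample(c("G", "C"), 400, replace = TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 150), boxd, substr(bg, 151, 400))
  hits <- find_motifs(seq, default_motifs()[default_motifs()$name == "BoxD", ])
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 151)
  expect_equal(hits$mismatches, 0)

  none <- find_motifs(strrep("G", 200), tibble::tibble(
    name = "X", pattern = "ATTTAAT", max_mismatches = 1L))
  expect_equal(nrow(none), 0)

  expect_error(find_motifs("ACGT", tibble::tibble(
    name = "bad", pattern = "AZT", max_mismatches = 0L)), "non-IUPAC")
})

test_that("the mismatch budget is a sharp boundary", {
  defs <- tibble::tibble(name = "M", pattern = "ACGTACGTACGTACG",
                         max_mismatches = 3L)
  bg <- strrep("G", 100)
  base <- defs$pattern
  for (n_mut in c(3, 4)) {
    set.seed(n_mut)
    chars <- strsplit(base, "")[[1]]
    pos <- sample(length(chars), n_mut)
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    planted <- paste(chars, collapse = "")
    expect_equal(oracle_hamming(planted, base), n_mut)
    seq <- paste0(substr(bg, 1, 40), planted, substr(bg, 41, 100))
    hits <- find_motifs(seq, defs)
    if (n_mut <= 3) {
      expect_true(41 %in% hits$start)
    } else {
      expect_false(41 %in% hits$start)
    }
  }
})

test_that("overlapping hits of one motif reduce to the best, 5'-most window", {
  defs <- tibble::tibble(name = "A4", pattern = "AAAA", max_mismatches = 1L)
  hits <- find_motifs(paste0("TT", strrep("A", 6), "TT"), defs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 3)   # first zero-mismatch window
  expect_equal(hits$mismatches, 0)
})

test_that("perfect dinucleotide repeats are reported with exact geometry", {
  arr <- detect_tandem_repeats("ATATATATAT", min_period = 2, max_period = 3,
                               min_copies = 3)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$period, 2)
  expect_equal(arr$unit, "AT")
  expect_equal(arr$copies, 5)
  expect_equal(arr$purity, 1)
  expect_equal(c(arr$start, arr$end), c(1, 10))
})

test_that("noisy long-unit tandem arrays are recovered with the right period", {
  for (s in 1:15) {
    cr <- simulate_cr(style = "plain", include_tandem = TRUE,
                      tandem_unit = 64, tandem_copies = 8,
                      tandem_noise = 0.02, motifs = NULL, seed = s)
    truth <- cr$manifest$repeats[cr$manifest$repeats$kind == "tandem", ]
    det <- detect_tandem_repeats(cr$sequence)
    hit <- det[det$period == truth$period, ]
    expect_equal(nrow(hit), 1)
    expect_lte(abs(hit$copies - truth$copies), 1)
  }
})

test_that("random sequence yields no long-period tandem calls", {
  empty <- 0
  for (s in 1:50) {
    det <- detect_tandem_repeats(random_seq(2000, seed = 5000 + s),
                                 min_period = 10, max_period = 200,
                                 min_copies = 3, min_identity = 0.9)
    if (nrow(det) == 0) empty <- empty + 1
  }
  expect_gte(empty, 48)
})

test_that("raising the identity floor never grows the reported array set", {
  cr <- simulate_cr(style = "plain", include_tandem = TRUE,
                    tandem_noise = 0.05, motifs = NULL, seed = 99)
  counts <- vapply(c(0.75, 0.85, 0.95), function(t) {
    nrow(detect_tandem_repeats(cr$sequence, min_identity = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("AT-rich arrays classify into block and dinucleotide kinds", {
  blk <- classify_at_arrays("AAATTAAATTAAATT", min_len = 10)
  expect_equal(nrow(blk), 1)
  expect_equal(blk$kind, "AT_block")
  expect_equal(blk$unit, "A3T2")
  expect_equal(blk$copies, 3)

  din <- classify_at_arrays("ATATATAT", min_len = 8, min_copies = 3)
  expect_equal(din$kind, "AT_dinucleotide")
  expect_equal(din$copies, 4)

  # below the length floor nothing is reported
  expect_equal(nrow(classify_at_arrays("ATATAT", min_len = 8)), 0)

  # a region qualifying as both is labelled by the stricter pattern
  both <- classify_at_arrays(paste0(strrep("G", 5), strrep("AT", 15),
                                    strrep("G", 5)), min_len = 10)
  expect_equal(both$kind, "AT_dinucleotide")
})

test_that("domain partition follows the anchors and falls back when absent", {
  cr <- simulate_cr(style = "chamaeleonid", seed = 3)
  hits <- find_motifs(cr$sequence)
  dom <- partition_domains(cr$sequence, hits)
  expect_false(attr(dom, "low_confidence"))
  expect_equal(dom$start, cr$manifest$domains$start)
  expect_equal(dom$end, cr$manifest$domains$end)
  expect_equal(dom$start[1], 1)
  expect_equal(dom$end[3], nchar(cr$sequence))
  expect_true(all(dom$start <= dom$end))

  empty_hits <- find_motifs(strrep("G", 300))
  fb <- partition_domains(strrep("G", 300), empty_hits)
  expect_true(attr(fb, "low_confidence"))
  expect_equal(fb$end[1], 100)
  expect_equal(fb$end[2], 200)

  bad <- tibble::tibble(motif = c("CSB1", "ETAS1"), start = c(10, 500),
                        end = c(31, 523), mismatches = c(0L, 0L))
  expect_error(partition_domains(strrep("A", 600), bad,
                                 on_disorder = "error"), "canonical")
  flagged <- partition_domains(strrep("A", 600), bad, on_disorder = "flag")
  expect_true(attr(flagged, "low_confidence"))
  expect_error(partition_domains("", empty_hits), "empty")
})

test_that("cr_profile reproduces the two chamaeleonid AT-array geometries", {
  cham <- simulate_cr(style = "chamaeleonid", seed = 11)
  ann <- cr_profile(cham$sequence, trnp = cham$manifest$trnp)
  at <- ann$repeats[ann$repeats$kind != "tandem", ]
  expect_setequal(unique(at$kind), c("AT_block", "AT_dinucleotide"))
  expect_equal(length(unique(at$kind)), 2)
  expect_equal(at$context[at$kind == "AT_block"], "5prime")
  expect_equal(at$context[at$kind == "AT_dinucleotide"], "3prime")

  brk <- simulate_cr(style = "brookesia", seed = 12)
  ann2 <- cr_profile(brk$sequence, trnp = brk$manifest$trnp)
  at2 <- ann2$repeats[ann2$repeats$kind == "AT_dinucleotide", ]
  expect_setequal(at2$context, c("5prime", "3prime"))

  plain <- simulate_cr(style = "plain", include_tandem = FALSE, seed = 13)
  ann3 <- cr_profile(plain$sequence)
  expect_equal(nrow(ann3$repeats), 0)
  expect_equal(nrow(ann3$domains), 3)
})

test_that("annotation intervals stay inside the sequence and do not overlap", {
  for (s in c(21, 22, 23)) {
    cr <- simulate_cr(style = "chamaeleonid", seed = s)
    ann <- cr_profile(cr$sequence, trnp = cr$manifest$trnp)
    L <- nchar(cr$sequence)
    items <- rbind(ann$motifs[, c("start", "end")],
                   ann$repeats[, c("start", "end")],
                   ann$domains[, c("start", "end")])
    expect_true(all(items$start >= 1 & items$end <= L))
    for (kind in unique(ann$repeats$kind)) {
      k <- ann$repeats[ann$repeats$kind == kind, ]
      if (nrow(k) > 1) {
        k <- k[order(k$start), ]
        expect_true(all(k$start[-1] > k$end[-nrow(k)]))
      }
    }
    doms <- ann$domains
    expect_true(all(doms$start[-1] == doms$end[-3] + 1))
  }
})

test_that("the packaged config file loads to the shipped defaults", {
  path <- system.file("extdata", "cr_config.yaml", package = "mitorder")
  cfg <- read_cr_config(path)
  expect_equal(as.data.frame(cfg$motifs), as.data.frame(default_motifs()))
  expect_equal(cfg$tandem$min_identity, 0.85)
  expect_equal(cfg$at$min_len, 20)
})

test_that("annotation configs round-trip through YAML and JSON", {
  cfg <- cr_config(tandem = list(min_period = 5, max_period = 120,
                                 min_copies = 4, min_identity = 0.9))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cr_config(cfg, path)
    back <- read_cr_config(path)
    expect_equal(back$tandem$min_copies, 4)
    expect_equal(back$tandem$min_identity, 0.9)
    expect_equal(as.data.frame(back$motifs), as.data.frame(cfg$motifs))
  }
})

test_that("annotations serialize to BED-like TSV and JSON", {
  cr <- simulate_cr(style = "chamaeleonid", seed = 31)
  ann <- cr_profile(cr$sequence, trnp = cr$manifest$trnp)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_cr_annotation(ann, tsv, "tsv")
  write_cr_annotation(ann, json, "json")
  tab <- utils::read.delim(tsv)
  expect_setequal(unique(tab$type), c("domain", "motif", "repeat", "gene"))
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$length, nchar(cr$sequence))
  expect_equal(nrow(js$motifs), nrow(ann$motifs))
})
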