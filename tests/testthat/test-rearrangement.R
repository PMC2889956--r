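test_that("the canonical order encodes to the ancestral state vector", {
  st <- encode_characters(canonical_vertebrate_order(),
                          ol_status = "present", anticodon = "TGG")
  expect_equal(unlist(st), c(C1 = "IQM", C2 = "typical", C3 = "single",
                             C4 = "present", C5 = "TGG"))
})

test_that("draconine-style and agamine/chamaeleonid-style orders encode correctly", {
  # QIM swap + inverted tRNA-Pro + lost replication origin (the
  # Calotes/Acanthosaura pattern)
  drac <- apply_rearrangements(tibble::tibble(
    C1 = "QIM", C2 = "inverted", C3 = "single", C4 = "absent"))
  st <- encode_characters(drac, anticodon = "TGG")
  expect_equal(unlist(st), c(C1 = "QIM", C2 = "inverted", C3 = "single",
                             C4 = "absent", C5 = "TGG"))
  # tRNA-Pro 3' of the CR (between CR and tRNA-Phe) keeps its strand
  p <- match("P", drac$name)
  expect_equal(drac$orientation[p], "+")

  # translocated tRNA-Pro plus a duplicate CR between ND5 and ND6
  amph <- apply_rearrangements(tibble::tibble(
    C1 = "QIM", C2 = "translocated_3prime_CR", C3 = "duplicate_ND5_ND6"))
  st2 <- encode_characters(amph)
  expect_equal(st2$C2, "translocated_3prime_CR")
  expect_equal(st2$C3, "duplicate_ND5_ND6")
  nd5 <- match("ND5", amph$name); nd6 <- match("ND6", amph$name)
  expect_equal(amph$name[nd5 + 1], "CR-1")
  expect_lt(nd5 + 1, nd6)
  expect_equal(amph$name[nrow(amph)], "P")   # 3' of CR-2, 5' of trnF
})

test_that("encoding rejects missing or displaced tRNA-Pro", {
  ord <- canonical_vertebrate_order()
  no_p <- new_gene_order(ord$name[ord$name != "P"],
                         ord$orientation[ord$name != "P"], anchor = "F")
  expect_error(encode_characters(no_p), "tRNA-Pro")
  # P displaced into the middle of the genome matches neither context
  nm <- ord$name[ord$name != "P"]
  or <- ord$orientation[ord$name != "P"]
  i <- match("COI", nm)
  nm <- append(nm, "P", after = i); or <- append(or, "-", after = i)
  expect_error(encode_characters(new_gene_order(nm, or, anchor = "F")),
               "ambiguous")
  expect_error(encode_characters(ord, ol_status = "sometimes"), "ol_status")
})

test_that("unknown replication-origin status and anticodon give missing states", {
  st <- encode_characters(canonical_vertebrate_order(),
                          ol_status = "unknown", anticodon = "unknown")
  expect_equal(st$C4, "?")
  expect_equal(st$C5, "?")
})

test_that("order_diff classifies moved, inverted, gained and lost symbols", {
  can <- canonical_vertebrate_order()
  d0 <- order_diff(can, can)
  expect_equal(nrow(d0$moved), 0)
  expect_length(d0$inverted, 0)
  expect_length(d0$gained, 0)
  expect_length(d0$lost, 0)

  qim <- apply_rearrangements(tibble::tibble(C1 = "QIM"))
  d1 <- order_diff(qim, can)
  expect_equal(d1$moved$name, "Q")
  expect_length(d1$inverted, 0)

  inv <- apply_rearrangements(tibble::tibble(C2 = "inverted"))
  d2 <- order_diff(inv, can)
  expect_equal(d2$inverted, "P")
  expect_equal(nrow(d2$moved), 0)   # location unchanged, strand flipped

  lost <- apply_rearrangements(tibble::tibble(C4 = "absent"))
  d3 <- order_diff(lost, can)
  expect_equal(d3$lost, "OL")

  dup <- apply_rearrangements(tibble::tibble(C3 = "duplicate_ND5_ND6"))
  d4 <- order_diff(dup, can)
  expect_setequal(d4$gained, c("CR-1", "CR-2"))
  expect_equal(d4$lost, "CR")
})

test_that("single planted rearrangements produce single-symbol diffs", {
  for (s in 1:25) {
    sim <- simulate_arrangements(tree = 6, seed = s)
    for (i in seq_len(nrow(sim$matrix))) {
      row <- sim$matrix[i, ]
      if (row$C1 == "QIM" && row$C2 == "typical" && row$C3 == "single" &&
          row$C4 == "present") {
        d <- order_diff(sim$orders[[row$taxon]])
        expect_equal(d$moved$name, "Q")
      }
    }
  }
})

test_that("breakpoint distance equals the adjacency-set oracle and is symmetric", {
  can <- canonical_vertebrate_order()
  expect_equal(breakpoint_distance(can, can), 0)
  qim <- apply_rearrangements(tibble::tibble(C1 = "QIM"))
  expect_equal(breakpoint_distance(can, qim), oracle_breakpoints(can, qim))
  expect_gt(breakpoint_distance(can, qim), 0)

  for (s in 1:100) {
    set.seed(s)
    perm <- sample(nrow(can))
    ori <- sample(c("+", "-"), nrow(can), replace = TRUE)
    other <- new_gene_order(can$name[perm], ori, anchor = can$name[perm][1])
    expect_equal(breakpoint_distance(can, other), oracle_breakpoints(can, other))
    expect_equal(breakpoint_distance(can, other),
                 breakpoint_distance(other, can))
  }
  trimmed <- new_gene_order(can$name[-5], can$orientation[-5], anchor = "F")
  expect_error(breakpoint_distance(can, trimmed), "symbol set")
})

test_that("character matrices round-trip through TSV and NEXUS dialects", {
  fx <- study_fixture()
  m <- fx$characters
  m$C5[3] <- "?"   # exercise the missing marker
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nex <- withr::local_tempfile(fileext = ".nex")
  write_character_matrix(m, tsv, format = "tsv")
  write_character_matrix(m, nex, format = "nexus")
  expect_equal(as.data.frame(read_character_matrix(tsv, "tsv")),
               as.data.frame(m))
  expect_equal(as.data.frame(read_character_matrix(nex, "nexus")),
               as.data.frame(m))
})

test_that("arrangement character definitions are internally consistent", {
  chars <- arrangement_characters()
  for (i in seq_len(nrow(chars))) {
    expect_true(chars$ancestral_state[i] %in% chars$states[[i]])
    expect_gte(length(chars$states[[i]]), 2)
  }
})
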