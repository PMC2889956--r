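#' Default feature-name synonym table for GenBank input
#'
#' Maps common spellings of mitochondrial feature names (gene and product
#' qualifiers) to the package vocabulary. The leucine/serine isoacceptor
#' numbering follows the anticodon-numbered convention used by automated
#' mitogenome annotators (`trnL1` = Leu(CUN), `trnL2` = Leu(UUR),
#' `trnS1` = Ser(AGY), `trnS2` = Ser(UCN)); supply your own table if your
#' annotations number them differently.
#'
#' @return Named character vector: lowercase alias -> vocabulary symbol.
#' @export
default_synonyms <- function() {
  aa <- c(
    phe = "F", val = "V", ile = "I", gln = "Q", met = "M", trp = "W",
    ala = "A", asn = "N", cys = "C", tyr = "Y", asp = "D", lys = "K",
    gly = "G", arg = "R", his = "H", glu = "E", thr = "T", pro = "P"
  )
  trna <- c(
    stats::setNames(unname(aa), paste0("trna-", names(aa))),
    stats::setNames(unname(aa), paste0("trn", tolower(unname(aa)))),
    "trna-leu(uur)" = "L(UUR)", "trna-leu(cun)" = "L(CUN)",
    "trnl2" = "L(UUR)", "trnl1" = "L(CUN)",
    "trna-ser(ucn)" = "S(UCN)", "trna-ser(agy)" = "S(AGY)",
    "trns2" = "S(UCN)", "trns1" = "S(AGY)"
  )
  prot <- c(
    "nd1" = "ND1", "nd2" = "ND2", "nd3" = "ND3", "nd4" = "ND4",
    "nd4l" = "ND4L", "nd5" = "ND5", "nd6" = "ND6",
    "nad1" = "ND1", "nad2" = "ND2", "nad3" = "ND3", "nad4" = "ND4",
    "nad4l" = "ND4L", "nad5" = "ND5", "nad6" = "ND6",
    "cox1" = "COI", "cox2" = "COII", "cox3" = "COIII",
    "co1" = "COI", "co2" = "COII", "co3" = "COIII",
    "coi" = "COI", "coii" = "COII", "coiii" = "COIII",
    "atp6" = "ATP6", "atp8" = "ATP8", "atpase 6" = "ATP6",
    "atpase 8" = "ATP8", "cytb" = "CYTB", "cob" = "CYTB",
    "cytochrome b" = "CYTB"
  )
  other <- c(
    "12s" = "12S", "12s rrna" = "12S", "12s ribosomal rna" = "12S",
    "rrns" = "12S", "s-rrna" = "12S",
    "16s" = "16S", "16s rrna" = "16S", "16s ribosomal rna" = "16S",
    "rrnl" = "16S", "l-rrna" = "16S",
    "d-loop" = "CR", "control region" = "CR", "cr" = "CR",
    "ol" = "OL", "l-strand origin" = "OL",
    "origin of l-strand replication" = "OL",
    "light strand replication origin" = "OL"
  )
  c(trna, prot, other)
}

resolve_synonym <- function(labels, synonyms) {
  labels <- tolower(trimws(labels))
  hits <- unname(synonyms[labels])
  hits[!is.na(hits)][1] %||% NA_character_
}

#' Read a GenBank flat file into a mitogenome record
#'
#' Minimal parser for GenBank-flavoured feature tables: `CDS`, `tRNA`,
#' `rRNA`, `D-loop` and `rep_origin` features with plain or
#' `complement(...)` spans are mapped to the package vocabulary via a
#' synonym table (gene qualifier first, then product, then note).
#' Unmappable features are skipped with a warning; joined/multi-segment
#' locations are not supported.
#'
#' @param path Path to a GenBank flat file.
#' @param synonyms Synonym table, see [default_synonyms()].
#' @param family Optional family label for the record.
#' @return A one-row mitogenome-record tibble.
#' @export
read_genbank_features <- function(path, synonyms = default_synonyms(),
                                  family = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("malformed GenBank record: no LOCUS line")
  locus_f <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  taxon <- locus_f[2] %||% "unknown"
  genome_length <- suppressWarnings(as.integer(locus_f[3]))

  f_start <- grep("^FEATURES", lines)
  if (length(f_start) == 0) stop("malformed GenBank record: no FEATURES table")
  f_end <- grep("^(ORIGIN|//)", lines)
  f_end <- if (length(f_end) > 0) min(f_end[f_end > f_start[1]]) else length(lines) + 1L
  ftab <- lines[(f_start[1] + 1L):(f_end - 1L)]

  # A feature header line has its key at column 6; qualifier/continuation
  # lines are indented further.
  is_key <- grepl("^ {5}\\S", ftab)
  if (!any(is_key)) stop("malformed GenBank record: empty feature table")
  idx <- cumsum(is_key)
  feats <- split(ftab, idx)[as.character(unique(idx[is_key]))]

  keep_keys <- c("CDS", "tRNA", "rRNA", "D-loop", "rep_origin")
  rows <- list()
  for (blk in feats) {
    head_f <- strsplit(trimws(blk[1]), "[[:space:]]+")[[1]]
    key <- head_f[1]
    if (key == "source") next
    if (!(key %in% keep_keys)) next
    loc <- paste(head_f[-1], collapse = "")
    strand <- if (grepl("complement", loc)) "L" else "H"
    span <- regmatches(loc, regexpr("[0-9]+\\.\\.[0-9]+", loc))
    if (length(span) == 0) {
      warning("unsupported location '", loc, "' for ", key, " feature; skipped")
      next
    }
    se <- as.integer(strsplit(span, "\\.\\.")[[1]])
    qual <- function(q) {
      m <- regmatches(blk, regexpr(paste0("/", q, "=\"[^\"]*\""), blk))
      if (length(m) == 0) return(character())
      sub("\"$", "", sub(paste0("/", q, "=\""), "", m))
    }
    labels <- c(qual("gene"), qual("product"), qual("note"))
    if (key == "D-loop") labels <- c(labels, "d-loop")
    if (key == "rep_origin") labels <- c(labels, "ol")
    sym <- resolve_synonym(labels, synonyms)
    if (is.na(sym)) {
      warning("unmappable ", key, " feature (", paste(labels, collapse = "; "),
              "); skipped")
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = sym, start = se[1], end = se[2], strand = strand
    )
  }
  if (length(rows) == 0) {
    warning("no mappable features in ", path)
    features <- NULL
  } else {
    features <- dplyr::bind_rows(rows)
    # duplicate symbols get -1/-2 suffixes in genome order
    features <- features[order(features$start), , drop = FALSE]
    dup <- names(which(table(features$name) > 1))
    for (d in dup) {
      k <- which(features$name == d)
      features$name[k] <- paste0(d, "-", seq_along(k))
    }
  }
  new_mitogenome_record(taxon = taxon, family = family, features = features,
                        genome_length = genome_length)
}
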