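#' The vertebrate mitochondrial genetic code
#'
#' Codon table for translation table 2 (vertebrate mitochondrial):
#' relative to the standard code, AGA/AGG are stops, ATA codes Met and
#' TGA codes Trp. Start codons and the abbreviated stops completed by
#' polyadenylation of the mRNA (`T`, `TA`) are carried as attributes.
#'
#' @return Named character vector codon -> one-letter amino acid
#'   (`"*"` = stop), with attributes `start_codons` and
#'   `abbreviated_stops`.
#' @export
mt_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")   # vertebrate mitochondrial
  code <- stats::setNames(as.character(code), chartr("U", "T", names(code)))
  attr(code, "start_codons") <- c("ATG", "ATA", "GTG", "ATT", "ATC")
  attr(code, "abbreviated_stops") <- c("T", "TA")
  code
}

#' Translate a mitochondrial protein-coding sequence
#'
#' Translates under the vertebrate mitochondrial code. A trailing `T` or
#' `TA` is accepted as a stop codon completed by polyadenylation of the
#' transcript when `allow_abbreviated_stop = TRUE` and is reported as
#' such. Codons containing `N` translate to `X`. Internal stops are
#' reported as validation failures, not errors.
#'
#' @param cds_seq Coding sequence (character scalar over
#'   `A`,`C`,`G`,`T`,`N`), length >= 3, read in frame from position 1.
#' @param allow_abbreviated_stop Accept `T`/`TA` abbreviated stops?
#' @return One-row tibble: `protein` (amino acids, stop excluded),
#'   `stop_codon`, `stop_status` (`"complete"`,
#'   `"completed_by_polyadenylation"`, `"missing"`), `internal_stops`
#'   (count), `valid` (no internal stops and a stop found).
#' @examples
#' translate_mt("ATGTGATAA")  # TGA = Trp under the mt code
#' @export
translate_mt <- function(cds_seq, allow_abbreviated_stop = TRUE) {
  x <- toupper(cds_seq)
  n <- nchar(x)
  if (n < 3) stop("coding sequence must be at least one codon long")
  if (grepl("[^ACGTN]", x)) stop("sequence must be over A/C/G/T/N")
  code <- mt_genetic_code()
  n_codon <- n %/% 3L
  rest <- substr(x, 3L * n_codon + 1L, n)
  codons <- substring(x, seq(1L, by = 3L, length.out = n_codon),
                      seq(3L, by = 3L, length.out = n_codon))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  stop_codon <- NA_character_
  stop_status <- "missing"
  if (length(aa) > 0 && aa[length(aa)] == "*" && rest == "") {
    stop_codon <- codons[length(codons)]
    stop_status <- "complete"
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  } else if (allow_abbreviated_stop && rest %in% c("T", "TA")) {
    stop_codon <- rest
    stop_status <- "completed_by_polyadenylation"
  }
  internal <- sum(aa == "*")
  tibble::tibble(
    protein = paste(aa, collapse = ""),
    stop_codon = stop_codon,
    stop_status = stop_status,
    internal_stops = internal,
    valid = internal == 0 && stop_status != "missing"
  )
}

# Watson-Crick plus (optionally) G.U wobble pairing on DNA alphabet.
bases_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) {
    wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  wc
}

#' Extract the anticodon of a tRNA gene from its cloverleaf geometry
#'
#' Enumerates candidate anticodon arms: a 5-bp stem (at least
#' `min_pairs` of the 5 positions pairing, Watson-Crick or G-U) closing a
#' 7-nt loop whose centre lies in the middle third of the gene, where the
#' anticodon arm of a cloverleaf-folded tRNA sits. The anticodon is read
#' from loop positions 3-5 of the best-scoring candidate (most stem
#' pairs; ties resolved 5'-most). No full secondary-structure folding is
#' attempted: this is a bounded heuristic sufficient for annotated genes.
#'
#' @param trna_seq tRNA gene sequence (sense strand; typical mt tRNA
#'   length 55-95 nt, bounds configurable).
#' @param min_pairs Minimum paired positions in the 5-bp stem (default 4).
#' @param len_range Accepted sequence length range.
#' @param allow_gu Count G-U as a pair?
#' @return One-row tibble: `anticodon` (`NA` when undetermined),
#'   `confidence` (stem pairs / 5), `loop_start`, `determined`.
#' @export
extract_anticodon <- function(trna_seq, min_pairs = 4,
                              len_range = c(55, 95), allow_gu = TRUE) {
  x <- toupper(trna_seq)
  L <- nchar(x)
  if (L < len_range[1] || L > len_range[2]) {
    stop("tRNA sequence length ", L, " outside the accepted range [",
         len_range[1], ", ", len_range[2], "]")
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  mid <- c(floor(L / 3) + 1L, ceiling(2 * L / 3))
  best <- NULL
  # loop occupies positions j..j+6; stem pairs (j-1, j+7) .. (j-5, j+11)
  for (j in seq(6L, L - 12L)) {
    centre <- j + 3L
    if (centre < mid[1] || centre > mid[2]) next
    five <- chars[(j - 1L):(j - 5L)]
    three <- chars[(j + 7L):(j + 11L)]
    pairs <- sum(bases_pair(five, three, allow_gu))
    if (pairs >= min_pairs && (is.null(best) || pairs > best$pairs)) {
      best <- list(j = j, pairs = pairs)
      if (pairs == 5L) break   # cannot improve; 5'-most wins ties anyway
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(anticodon = NA_character_, confidence = NA_real_,
                          loop_start = NA_integer_, determined = FALSE))
  }
  tibble::tibble(
    anticodon = paste(chars[(best$j + 2L):(best$j + 4L)], collapse = ""),
    confidence = best$pairs / 5,
    loop_start = best$j,
    determined = TRUE
  )
}

#' Detect the light-strand replication-origin stem-loop
#'
#' Scans a WANCY-cluster spacer (typically the region between the
#' tRNA-Asn and tRNA-Cys genes plus a flank) for a hairpin: a perfect
#' contiguous stem of at least `min_stem` pairs (Watson-Crick, plus G-U
#' when `allow_gu`) enclosing a loop of `loop_range` nt. The call reports
#' the longest such stem (ties: 5'-most). Bulged stems are not
#' considered.
#'
#' @param wancy_seq Sequence of the region scanned (heavy strand).
#' @param min_stem Minimum stem length in bp (default 6).
#' @param loop_range Allowed loop lengths in nt.
#' @param allow_gu Count G-U as a pair?
#' @return One-row tibble: `present`, `stem_start`, `loop_start`,
#'   `loop_end`, `stem_end`, `stem_length`, `loop_length`.
#' @export
detect_ol_hairpin <- function(wancy_seq, min_stem = 6,
                              loop_range = c(3, 20), allow_gu = TRUE) {
  absent <- tibble::tibble(
    present = FALSE, stem_start = NA_integer_, loop_start = NA_integer_,
    loop_end = NA_integer_, stem_end = NA_integer_,
    stem_length = NA_integer_, loop_length = NA_integer_
  )
  x <- toupper(wancy_seq)
  L <- nchar(x)
  if (L == 0) {
    warning("empty region scanned for the replication-origin stem-loop")
    return(absent)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  best <- NULL
  max_stem <- (L - loop_range[1]) %/% 2L
  if (max_stem >= min_stem) {
    for (k in max_stem:min_stem) {       # longest stem first
      for (i in seq_len(L - 2L * k - loop_range[1] + 1L)) {  # then 5'-most
        for (l in loop_range[1]:loop_range[2]) {
          span <- 2L * k + l
          if (i + span - 1L > L) break
          five <- chars[(i + k - 1L):i]
          three <- chars[(i + k + l):(i + span - 1L)]
          if (all(bases_pair(five, three, allow_gu))) {
            best <- list(i = i, k = k, l = l)
            break
          }
        }
        if (!is.null(best)) break
      }
      if (!is.null(best)) break
    }
  }
  if (is.null(best)) return(absent)
  tibble::tibble(
    present = TRUE,
    stem_start = best$i,
    loop_start = best$i + best$k,
    loop_end = best$i + best$k + best$l - 1L,
    stem_end = best$i + 2L * best$k + best$l - 1L,
    stem_length = best$k,
    loop_length = best$l
  )
}
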