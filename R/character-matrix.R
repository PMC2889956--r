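#' Write / read an arrangement character matrix
#'
#' A character matrix is a tibble with a `taxon` column and one column per
#' character (states as labels, `"?"` for missing). Two on-disk dialects
#' are supported and round-trip exactly:
#'
#' * `"tsv"` — plain tab-separated table, header row.
#' * `"nexus"` — a NEXUS-style `DATA` block; multi-letter state labels are
#'   mapped to integer symbols per character, with the label legend stored
#'   in a `[state legend: ...]` comment that the reader consumes.
#'
#' @param matrix Character-matrix tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"nexus"`.
#' @return `path` invisibly (writer); a character-matrix tibble (reader).
#' @export
write_character_matrix <- function(matrix, path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  chars <- setdiff(names(matrix), "taxon")
  legends <- lapply(chars, function(ch) {
    sort(unique(matrix[[ch]][matrix[[ch]] != "?"]))
  })
  names(legends) <- chars
  sym <- vapply(seq_along(chars), function(k) {
    st <- matrix[[chars[k]]]
    out <- as.character(match(st, legends[[k]]) - 1L)
    out[st == "?"] <- "?"
    out
  }, character(nrow(matrix)))
  if (nrow(matrix) == 1L) sym <- matrix(sym, nrow = 1L)
  legend_txt <- paste(vapply(chars, function(ch) {
    paste0(ch, "=", paste(legends[[ch]], collapse = ","))
  }, character(1)), collapse = "; ")
  lines <- c(
    "#NEXUS",
    paste0("[state legend: ", legend_txt, "]"),
    "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", nrow(matrix), " NCHAR=", length(chars), ";"),
    "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"0123456789\";",
    "  MATRIX",
    paste0("    ", format(matrix$taxon, width = max(nchar(matrix$taxon))),
           " ", apply(sym, 1, paste, collapse = "")),
    "  ;",
    "END;"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_character_matrix
#' @export
read_character_matrix <- function(path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(tibble::as_tibble(
      utils::read.delim(path, sep = "\t", colClasses = "character",
                        check.names = FALSE)))
  }
  lines <- readLines(path, warn = FALSE)
  leg_line <- grep("^\\[state legend:", lines, value = TRUE)
  if (length(leg_line) == 0) stop("NEXUS matrix lacks a state legend comment")
  leg_txt <- sub("\\]$", "", sub("^\\[state legend: ", "", leg_line[1]))
  legends <- lapply(strsplit(leg_txt, "; ")[[1]], function(entry) {
    kv <- strsplit(entry, "=", fixed = TRUE)[[1]]
    list(char = kv[1], states = strsplit(kv[2], ",", fixed = TRUE)[[1]])
  })
  m0 <- grep("MATRIX", lines)
  m1 <- grep("^  ;", lines)
  rows <- trimws(lines[(m0[1] + 1L):(m1[1] - 1L)])
  parts <- strsplit(rows, "[[:space:]]+")
  out <- tibble::tibble(taxon = vapply(parts, `[[`, character(1), 1))
  codes <- vapply(parts, `[[`, character(1), 2)
  for (k in seq_along(legends)) {
    digit <- substr(codes, k, k)
    st <- rep("?", length(digit))
    ok <- digit != "?"
    st[ok] <- legends[[k]]$states[as.integer(digit[ok]) + 1L]
    out[[legends[[k]]$char]] <- st
  }
  out
}
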