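#' Construct an annotated mitogenome record
#'
#' A record is one row of a nested tibble: per-taxon metadata plus a
#' `features` list-column holding the feature table (one row per gene or
#' noncoding element, 1-based inclusive coordinates, strand `H`/`L`).
#'
#' @param taxon Taxon identifier.
#' @param family Family label (e.g. `"Agamidae"`, `"Chamaeleonidae"`,
#'   `"Iguanidae"`).
#' @param features Tibble with columns `name`, `start`, `end`, `strand`
#'   and optionally `feature_class` (filled from the vocabulary when
#'   absent).
#' @param genome_length,cr_length Optional lengths in bp (`NA` when
#'   unresolved, e.g. a control region that could not be fully sequenced).
#' @param accession Optional sequence accession.
#' @param circular Is the genome circular? Default `TRUE`.
#' @param sequence Optional nucleotide sequence (character scalar).
#' @return A one-row tibble of class `mitogenome_record` stacked with
#'   other records into plain tibbles.
#' @export
new_mitogenome_record <- function(taxon, family = NA_character_,
                                  features = NULL,
                                  genome_length = NA_integer_,
                                  cr_length = NA_integer_,
                                  accession = NA_character_,
                                  circular = TRUE,
                                  sequence = NA_character_) {
  features <- validate_features(features, taxon = taxon,
                                genome_length = genome_length,
                                sequence = sequence)
  tibble::tibble(
    taxon = as.character(taxon),
    family = as.character(family),
    accession = as.character(accession),
    genome_length = as.integer(genome_length),
    cr_length = as.integer(cr_length),
    circular = isTRUE(circular),
    features = list(features),
    sequence = as.character(sequence)
  )
}

validate_features <- function(features, taxon = "?", genome_length = NA,
                              sequence = NA_character_) {
  if (is.null(features)) {
    features <- tibble::tibble(name = character(), start = integer(),
                               end = integer(), strand = character(),
                               feature_class = character())
  }
  features <- tibble::as_tibble(features)
  needed <- c("name", "start", "end", "strand")
  miss <- setdiff(needed, names(features))
  if (length(miss) > 0) {
    stop("feature table for ", taxon, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- features$name[!is_vocabulary_symbol(features$name)]
  if (length(bad) > 0) {
    stop("unknown gene symbol(s) for ", taxon, ": ",
         paste(unique(bad), collapse = ", "))
  }
  if (nrow(features) > 0 && any(features$start < 1, na.rm = TRUE)) {
    stop("feature coordinates must be >= 1 (taxon ", taxon, ")")
  }
  if (!all(features$strand %in% c("H", "L"))) {
    stop("strand must be 'H' or 'L' (taxon ", taxon, ")")
  }
  dup <- table(features$name)
  if (any(dup > 1)) {
    stop("duplicated feature names must be suffixed -1/-2 (taxon ",
         taxon, "): ", paste(names(dup)[dup > 1], collapse = ", "))
  }
  if (!is.na(sequence) && nrow(features) > 0 &&
      any(features$end > nchar(sequence))) {
    stop("feature coordinates exceed sequence length (taxon ", taxon, ")")
  }
  if (!("feature_class" %in% names(features))) {
    features$feature_class <- feature_class_of(features$name)
  }
  features[order(features$start), , drop = FALSE]
}

#' Read a gene-order table (TSV) into mitogenome records
#'
#' The table is tab-separated with a header and one row per feature:
#' columns `taxon`, `family`, `gene`, `start`, `end`, `strand` (`H`/`L`),
#' `class`, plus optional per-taxon metadata columns `genome_length`,
#' `cr_length`, `accession` (repeated on every row of a taxon). Parse
#' failures name the offending line (1-based, counting the header).
#'
#' @param path Path to the TSV file.
#' @return A tibble of mitogenome records (one row per taxon).
#' @seealso [write_gene_order_table()] for the exact inverse.
#' @export
read_gene_order_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  needed <- c("taxon", "family", "gene", "start", "end", "strand", "class")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0) {
    stop("gene-order table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  line_no <- seq_len(nrow(tab)) + 1L   # header is line 1
  for (col in c("start", "end")) {
    num <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(num)) {
      bad <- line_no[is.na(num)][1]
      stop("non-numeric ", col, " at line ", bad, " of ", path)
    }
    tab[[col]] <- num
  }
  bad <- !is_vocabulary_symbol(tab$gene)
  if (any(bad)) {
    stop("unknown gene symbol '", tab$gene[bad][1], "' at line ",
         line_no[bad][1], " of ", path)
  }
  meta_col <- function(df, col, default = NA_character_) {
    if (col %in% names(df)) df[[col]][1] else default
  }
  tab |>
    dplyr::group_by(.data$taxon) |>
    dplyr::group_map(function(df, key) {
      new_mitogenome_record(
        taxon = key$taxon,
        family = df$family[1],
        features = tibble::tibble(
          name = df$gene, start = df$start, end = df$end,
          strand = df$strand, feature_class = df$class
        ),
        genome_length = suppressWarnings(
          as.integer(meta_col(df, "genome_length"))),
        cr_length = suppressWarnings(as.integer(meta_col(df, "cr_length"))),
        accession = meta_col(df, "accession")
      )
    }) |>
    dplyr::bind_rows()
}

#' Write mitogenome records back to a gene-order TSV
#'
#' Inverse of [read_gene_order_table()]: reading the written file yields
#' records identical to the input (up to row order by taxon then start).
#'
#' @param records Tibble of mitogenome records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_order_table <- function(records, path) {
  rows <- purrr::pmap(records, function(taxon, family, accession,
                                        genome_length, cr_length, circular,
                                        features, sequence, ...) {
    tibble::tibble(
      taxon = taxon, family = family, gene = features$name,
      start = features$start, end = features$end,
      strand = features$strand, class = features$feature_class,
      genome_length = genome_length, cr_length = cr_length,
      accession = accession
    )
  }) |> dplyr::bind_rows()
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Linearize a circular mitogenome at an anchor feature
#'
#' Rotates the feature list of a record (or a feature tibble) so that the
#' anchor is element 1, and converts strands to orientation signs
#' (`H` -> `+`, `L` -> `-`). All order comparisons in the package are
#' performed after linearization at tRNA-Phe (`"F"`), the element the
#' typical vertebrate arrangement is drawn from.
#'
#' @param record A one-row record tibble, or a feature tibble with
#'   `name`/`strand` columns, or a `gene_order`.
#' @param anchor Feature symbol to place at position 1 (default `"F"`).
#' @return A `gene_order` tibble.
#' @export
linearize <- function(record, anchor = "F") {
  if (inherits(record, "gene_order")) {
    nm <- record$name
    ori <- record$orientation
  } else {
    feats <- if ("features" %in% names(record)) record$features[[1]] else record
    feats <- feats[order(feats$start), , drop = FALSE]
    nm <- feats$name
    ori <- ifelse(feats$strand == "H", "+", "-")
  }
  i <- match(anchor, nm)
  if (is.na(i)) stop("anchor '", anchor, "' absent from record")
  idx <- c(i:length(nm), seq_len(i - 1L))
  if (i == 1L) idx <- seq_along(nm)
  new_gene_order(nm[idx], ori[idx], anchor = anchor)
}

#' Mean control-region length by family
#'
#' Arithmetic mean of `cr_length` over the records of one family (or all
#' families), excluding taxa whose control-region length is unresolved
#' (`NA`, e.g. repeat-rich regions that could not be sequenced through).
#' Means are rounded to the nearest integer with ties away from zero.
#'
#' @param records Tibble of mitogenome records with `family` and
#'   `cr_length` columns.
#' @param family Optional family label; default summarises every family.
#' @return Tibble with columns `family`, `mean_cr_length` (integer bp) and
#'   `n` (taxa included).
#' @export
mean_cr_length <- function(records, family = NULL) {
  if (!is.null(family)) {
    records <- dplyr::filter(records, .data$family %in% !!family)
  }
  records <- dplyr::filter(records, !is.na(.data$cr_length))
  if (nrow(records) == 0) {
    stop("no records with resolved cr_length",
         if (!is.null(family)) paste0(" in family ", family) else "")
  }
  records |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      mean_cr_length = round_half_away(mean(.data$cr_length)),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# round() in R rounds half to even; summaries here use the convention of
# half away from zero (2505.5 -> 2506).
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
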