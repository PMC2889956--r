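#' Controlled vocabulary of mitochondrial genome features
#'
#' The 37 genes of a typical vertebrate mitochondrial genome (13 proteins,
#' 22 tRNAs, 2 rRNAs) plus the two canonical noncoding elements: the
#' light-strand replication origin (`OL`) and the control region (`CR`).
#' tRNAs are named by the one-letter amino-acid code as in comparative
#' mitogenomics figures, with the two leucine and two serine isoacceptors
#' disambiguated by codon family: `L(UUR)`/`L(CUN)` and `S(UCN)`/`S(AGY)`.
#' Duplicated features (e.g. the duplicate control region of amphibolurine
#' agamids) carry `-1`/`-2` suffixes in genome order.
#'
#' @return A tibble with columns `name` (feature symbol) and
#'   `feature_class` (`protein`, `tRNA`, `rRNA` or `noncoding`).
#' @examples
#' gene_vocabulary()
#' @export
gene_vocabulary <- function() {
  proteins <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB")
  trnas <- c("F", "V", "L(UUR)", "I", "Q", "M", "W", "A", "N", "C", "Y",
             "S(UCN)", "D", "K", "G", "R", "H", "S(AGY)", "L(CUN)", "E",
             "T", "P")
  tibble::tibble(
    name = c(proteins, trnas, "12S", "16S", "CR", "OL"),
    feature_class = c(
      rep("protein", length(proteins)),
      rep("tRNA", length(trnas)),
      "rRNA", "rRNA", "noncoding", "noncoding"
    )
  )
}

# Strip a duplicate suffix ("CR-2" -> "CR") to resolve a symbol in the
# vocabulary. Suffixes are only meaningful on duplicated features.
base_symbol <- function(name) {
  sub("-[0-9]+$", "", name)
}

#' Test whether feature names resolve in the controlled vocabulary
#'
#' @param name Character vector of feature symbols (duplicate suffixes such
#'   as `CR-1` are allowed).
#' @return Logical vector.
#' @export
is_vocabulary_symbol <- function(name) {
  base_symbol(name) %in% gene_vocabulary()$name
}

feature_class_of <- function(name) {
  voc <- gene_vocabulary()
  voc$feature_class[match(base_symbol(name), voc$name)]
}

#' The typical vertebrate mitochondrial gene order
#'
#' The gene organisation found in most major vertebrate groups, linearized
#' from tRNA-Phe on the heavy strand. Heavy-strand features carry
#' orientation `+`, light-strand features `-`. The order has 39 elements:
#' the 37 genes plus the light-strand replication origin (`OL`, inside the
#' WANCY tRNA cluster) and the control region (`CR`, between tRNA-Pro and
#' tRNA-Phe).
#'
#' @return A `gene_order` tibble with columns `position`, `name`,
#'   `orientation` and `feature_class`, anchored at `F`.
#' @examples
#' ord <- canonical_vertebrate_order()
#' sum(ord$feature_class != "noncoding")  # 37 genes
#' @export
canonical_vertebrate_order <- function() {
  els <- c(
    "F" = "+", "12S" = "+", "V" = "+", "16S" = "+", "L(UUR)" = "+",
    "ND1" = "+", "I" = "+", "Q" = "-", "M" = "+", "ND2" = "+",
    "W" = "+", "A" = "-", "N" = "-", "OL" = "+", "C" = "-", "Y" = "-",
    "COI" = "+", "S(UCN)" = "-", "D" = "+", "COII" = "+", "K" = "+",
    "ATP8" = "+", "ATP6" = "+", "COIII" = "+", "G" = "+", "ND3" = "+",
    "R" = "+", "ND4L" = "+", "ND4" = "+", "H" = "+", "S(AGY)" = "+",
    "L(CUN)" = "+", "ND5" = "+", "ND6" = "-", "E" = "-", "CYTB" = "+",
    "T" = "+", "P" = "-", "CR" = "+"
  )
  new_gene_order(names(els), unname(els), anchor = "F")
}

#' Construct a gene-order tibble
#'
#' A gene order is the signed, linearized sequence of features of one
#' (circular) mitogenome: a tibble with one row per feature in genome
#' order, an `anchor` attribute naming the element placed at position 1.
#'
#' @param name Character vector of feature symbols.
#' @param orientation Character vector of `"+"` (heavy strand) / `"-"`
#'   (light strand).
#' @param anchor Symbol of the element at position 1.
#' @return A tibble of class `gene_order`.
#' @export
new_gene_order <- function(name, orientation, anchor = name[[1]]) {
  stopifnot(length(name) == length(orientation))
  bad <- name[!is_vocabulary_symbol(name)]
  if (length(bad) > 0) {
    stop("unknown gene symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  if (!all(orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-'")
  }
  dup <- table(name)
  if (any(dup > 1)) {
    stop("duplicate symbols must carry distinct -1/-2 suffixes: ",
         paste(names(dup)[dup > 1], collapse = ", "))
  }
  out <- tibble::tibble(
    position = seq_along(name),
    name = as.character(name),
    orientation = as.character(orientation),
    feature_class = feature_class_of(name)
  )
  class(out) <- c("gene_order", class(out))
  attr(out, "anchor") <- anchor
  out
}

#' @export
print.gene_order <- function(x, ...) {
  cat("Gene order (", nrow(x), " elements, anchored at ",
      attr(x, "anchor") %||% x$name[[1]], "):\n", sep = "")
  signed <- ifelse(x$orientation == "-", paste0("-", x$name), x$name)
  cat(strwrap(paste(signed, collapse = " "), width = 78, indent = 2,
              exdent = 2), sep = "\n")
  invisible(x)
}

# Signed labels ("-Q" for light strand) used for order comparison.
signed_elements <- function(order) {
  paste0(ifelse(order$orientation == "-", "-", ""), order$name)
}
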