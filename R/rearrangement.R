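#' The five discrete mitogenome-arrangement characters
#'
#' Character definitions for the rearrangement features that vary among
#' iguanian mitogenomes:
#'
#' * `C1` — order of the tRNA-Ile/Gln/Met cluster: `IQM` (typical) or
#'   `QIM` (the acrodont-shared rearranged state).
#' * `C2` — tRNA-Pro position/orientation: `typical` (light strand,
#'   between tRNA-Thr and the CR), `inverted` (same location, heavy
#'   strand), or `translocated_3prime_CR` (moved 3' of the CR, upstream of
#'   tRNA-Phe).
#' * `C3` — control-region copy number: `single` or `duplicate_ND5_ND6`
#'   (an extra CR inserted between ND5 and ND6).
#' * `C4` — light-strand replication origin in the WANCY cluster:
#'   `present` or `absent`.
#' * `C5` — tRNA-Pro anticodon: `TGG` (usual) or `CGG`.
#'
#' @return Tibble with columns `id`, `name`, `states` (list-column),
#'   `ancestral_state`, `description`.
#' @export
arrangement_characters <- function() {
  tibble::tibble(
    id = paste0("C", 1:5),
    name = c("IQM_cluster_order", "trnP_position", "CR_copy",
             "OL_presence", "trnP_anticodon"),
    states = list(
      c("IQM", "QIM"),
      c("typical", "inverted", "translocated_3prime_CR"),
      c("single", "duplicate_ND5_ND6"),
      c("present", "absent"),
      c("TGG", "CGG")
    ),
    ancestral_state = c("IQM", "typical", "single", "present", "TGG"),
    description = c(
      "relative order of the tRNA-Ile, tRNA-Gln, tRNA-Met genes",
      "position and strand of the tRNA-Pro gene relative to the CR",
      "duplicate control region between ND5 and ND6",
      "stem-loop light-strand replication origin in the WANCY cluster",
      "anticodon triplet of the tRNA-Pro gene"
    )
  )
}

#' Encode the arrangement-character states of one gene order
#'
#' Compares a gene order (linearized at tRNA-Phe) to the typical
#' vertebrate arrangement and reads off the five discrete characters of
#' [arrangement_characters()]. The stem-loop status of the replication
#' origin and the tRNA-Pro anticodon are sequence-level observations and
#' are supplied separately; `ol_status = "auto"` falls back to the
#' presence of an `OL` element in the order.
#'
#' @param order A `gene_order` (anchored at `"F"`).
#' @param ol_status `"present"`, `"absent"`, `"unknown"`, or `"auto"`.
#' @param anticodon tRNA-Pro anticodon triplet (DNA alphabet, e.g.
#'   `"TGG"`), or `"unknown"`.
#' @return One-row tibble with columns `C1`..`C5`; unknown inputs yield
#'   `"?"`.
#' @examples
#' encode_characters(canonical_vertebrate_order())
#' @export
encode_characters <- function(order, ol_status = "auto",
                              anticodon = "TGG") {
  if (!identical(attr(order, "anchor"), "F")) {
    order <- linearize(order, "F")
  }
  pos <- function(sym) match(sym, order$name)

  # C1: Q before I within the I/Q/M cluster?
  if (is.na(pos("I")) || is.na(pos("Q"))) {
    stop("order lacks the tRNA-Ile/Gln/Met cluster")
  }
  c1 <- if (pos("Q") < pos("I")) "QIM" else "IQM"

  # C2: where is tRNA-Pro relative to T and the CR?
  p <- pos("P")
  if (is.na(p)) stop("tRNA-Pro (P) absent from order")
  cr_pos <- which(base_symbol(order$name) == "CR")
  t_pos <- pos("T")
  main_cr <- max(cr_pos)   # the CR 3' of CYTB/T in the F-anchored order
  p_ori <- order$orientation[p]
  if (p > main_cr) {
    c2 <- "translocated_3prime_CR"
  } else if (!is.na(t_pos) && p > t_pos && p < main_cr) {
    c2 <- if (p_ori == "+") "inverted" else "typical"
  } else {
    stop("ambiguous tRNA-Pro placement: found at position ", p,
         " (T at ", t_pos, ", CR at ", main_cr, ")")
  }

  # C3: any CR copy strictly between ND5 and ND6?
  nd5 <- pos("ND5"); nd6 <- pos("ND6")
  c3 <- if (any(cr_pos > nd5 & cr_pos < nd6)) "duplicate_ND5_ND6" else "single"

  if (identical(ol_status, "auto")) {
    ol_status <- if (any(order$name == "OL")) "present" else "absent"
  }
  c4 <- switch(ol_status, present = "present", absent = "absent",
               unknown = "?",
               stop("ol_status must be present/absent/unknown/auto"))
  c5 <- if (identical(anticodon, "unknown") || is.na(anticodon)) "?" else
    toupper(anticodon)

  tibble::tibble(C1 = c1, C2 = c2, C3 = c3, C4 = c4, C5 = c5)
}

#' Encode arrangement characters for a set of taxa
#'
#' @param orders Named list of `gene_order` objects (names are taxa).
#' @param ol_status Named character vector of per-taxon stem-loop status,
#'   or a single value recycled (default `"auto"`).
#' @param anticodon Named character vector of per-taxon tRNA-Pro
#'   anticodons, or a single value recycled.
#' @return Character-matrix tibble: `taxon` plus columns `C1`..`C5`.
#' @export
encode_character_matrix <- function(orders, ol_status = "auto",
                                    anticodon = "TGG") {
  taxa <- names(orders)
  stopifnot(!is.null(taxa))
  get1 <- function(x, taxon, default) {
    if (length(x) == 1 && is.null(names(x))) return(x)
    x[[taxon]] %||% default
  }
  purrr::map2(orders, taxa, function(ord, tx) {
    dplyr::bind_cols(
      tibble::tibble(taxon = tx),
      encode_characters(ord,
                        ol_status = get1(ol_status, tx, "auto"),
                        anticodon = get1(anticodon, tx, "TGG"))
    )
  }) |> dplyr::bind_rows()
}

#' Difference between two gene orders
#'
#' Aligns two signed gene orders by longest common subsequence over
#' signed symbols and classifies off-LCS symbols: `moved` (present in
#' both, relative position changed), `inverted` (orientation flipped; a
#' symbol may be both moved and inverted), `gained` (absent from the
#' reference) and `lost` (absent from the observed order). Ties in the
#' LCS are broken deterministically in favour of keeping the reference's
#' 5'-most elements fixed.
#'
#' @param order Observed `gene_order`.
#' @param reference Reference `gene_order` (default the typical vertebrate
#'   arrangement).
#' @return List of class `order_diff` with tibbles `moved` (`name`,
#'   `reference_position`, `observed_position`), and character vectors
#'   `inverted`, `gained`, `lost`.
#' @export
order_diff <- function(order, reference = canonical_vertebrate_order()) {
  ref_s <- signed_elements(reference)
  obs_s <- signed_elements(order)
  gained <- setdiff(order$name, reference$name)
  lost <- setdiff(reference$name, order$name)
  common_ref <- reference[reference$name %in% order$name, , drop = FALSE]
  common_obs <- order[order$name %in% reference$name, , drop = FALSE]
  inverted <- common_ref$name[
    common_obs$orientation[match(common_ref$name, common_obs$name)] !=
      common_ref$orientation
  ]
  # signed LCS over the common symbols; inverted symbols can never match
  keep <- lcs_keep(signed_elements(common_ref), signed_elements(common_obs))
  off <- setdiff(common_ref$name, sub("^-", "", keep))
  # an inverted symbol only counts as moved if it is also off the
  # name-only LCS (its relative location changed, not just its strand)
  keep_names <- lcs_keep(common_ref$name, common_obs$name)
  moved_names <- union(setdiff(off, inverted),
                       intersect(inverted, setdiff(common_ref$name, keep_names)))
  moved <- tibble::tibble(
    name = moved_names,
    reference_position = match(moved_names, reference$name),
    observed_position = match(moved_names, order$name)
  ) |> dplyr::arrange(.data$reference_position)
  structure(
    list(moved = moved, inverted = inverted, gained = gained, lost = lost),
    class = "order_diff"
  )
}

#' @export
print.order_diff <- function(x, ...) {
  cat("Gene-order difference:\n")
  cat("  moved:   ", if (nrow(x$moved)) paste(x$moved$name, collapse = ", ")
      else "none", "\n")
  cat("  inverted:", if (length(x$inverted)) paste(x$inverted, collapse = ", ")
      else "none", "\n")
  cat("  gained:  ", if (length(x$gained)) paste(x$gained, collapse = ", ")
      else "none", "\n")
  cat("  lost:    ", if (length(x$lost)) paste(x$lost, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

# Elements of `a` kept by a longest common subsequence of a and b.
# Backtracking from the front; on ties the b-element is skipped first,
# which keeps a's 5'-most elements on the LCS.
lcs_keep <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(character())
  # dp[i+1, j+1] = LCS length of a[i..n], b[j..m] (suffixes)
  dp <- matrix(0L, n + 1L, m + 1L)
  for (i in n:1) {
    for (j in m:1) {
      dp[i, j] <- if (a[i] == b[j]) dp[i + 1L, j + 1L] + 1L else
        max(dp[i + 1L, j], dp[i, j + 1L])
    }
  }
  keep <- character()
  i <- 1L; j <- 1L
  while (i <= n && j <= m) {
    if (a[i] == b[j] && dp[i, j] == dp[i + 1L, j + 1L] + 1L) {
      keep <- c(keep, a[i]); i <- i + 1L; j <- j + 1L
    } else if (dp[i, j + 1L] >= dp[i + 1L, j]) {
      j <- j + 1L   # skip observed element first (tie-break)
    } else {
      i <- i + 1L
    }
  }
  keep
}

#' Breakpoint distance between two gene orders
#'
#' Counts the oriented gene adjacencies of one order that are absent from
#' the other. Orders are treated as circular (the linearization junction
#' contributes an adjacency), and each adjacency is read strand-symmetrically:
#' `(a, b)` is the same adjacency as `(-b, -a)`. The distance is symmetric
#' and zero iff the signed circular orders coincide.
#'
#' @param order_a,order_b `gene_order` objects over the same symbol set.
#' @return Integer count.
#' @export
breakpoint_distance <- function(order_a, order_b) {
  if (!setequal(order_a$name, order_b$name) ||
      nrow(order_a) != nrow(order_b)) {
    stop("orders must share the same symbol set")
  }
  a <- adjacency_set(order_a)
  b <- adjacency_set(order_b)
  length(setdiff(a, b))
}

# Canonical oriented adjacency labels of a circular signed order.
adjacency_set <- function(order) {
  s <- signed_elements(order)
  nxt <- c(s[-1], s[1])
  flip <- function(x) ifelse(startsWith(x, "-"), sub("^-", "", x),
                             paste0("-", x))
  fwd <- paste(s, nxt, sep = "|")
  rev <- paste(flip(nxt), flip(s), sep = "|")
  ifelse(fwd <= rev, fwd, rev)   # strand-symmetric canonical form
}
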