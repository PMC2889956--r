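IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Default conserved-motif definitions for vertebrate control regions
#'
#' Shipped IUPAC consensus strings in the ETAS / central-conserved-box /
#' CSB nomenclature of the vertebrate control-region literature. These
#' are configurable defaults, not gospel: supply your own tibble (or a
#' YAML/JSON config, see [read_cr_config()]) with columns `name`,
#' `pattern`, `max_mismatches` to use lineage-specific consensi. The
#' default mismatch budget is `floor(pattern length / 5)`. Note that
#' CSB2 is commonly absent from acrodont control regions and CSB3 from
#' agamid ones; absence of a motif is reported as no hit, never an error.
#'
#' @return Tibble with columns `name`, `pattern`, `max_mismatches`.
#' @export
default_motifs <- function() {
  pat <- c(
    ETAS1 = "TACATATTATGTATWATYGTGCAT",
    ETAS2 = "ACATAGTACATWAWATCATGCWTA",
    BoxC  = "TGGCATCTGGTTCTTAYTTCAGG",
    BoxD  = "TCTCACGAGAAATCAGCAACCC",
    BoxF  = "GTACATAGCACATTWCAGTCAA",
    CSB1  = "TTAATGCTTGTAGGACATAATA",
    CSB2  = "AAACCCCCCCTCCCCC",
    CSB3  = "TGCCAAACCCCAAAAACAAGAC"
  )
  tibble::tibble(
    name = names(pat),
    pattern = unname(pat),
    max_mismatches = as.integer(floor(nchar(pat) / 5))
  )
}

#' Find degenerate motifs in a nucleotide sequence
#'
#' Scans the given strand for windows matching each IUPAC pattern with at
#' most `max_mismatches` Hamming mismatches (an `N` in the sequence only
#' matches a pattern `N`). Overlapping hits of the same motif are reduced
#' to the lowest-mismatch hit (ties: 5'-most).
#'
#' @param seq Nucleotide sequence (character scalar over `A`,`C`,`G`,`T`,`N`).
#' @param motif_defs Tibble as from [default_motifs()].
#' @return Tibble with columns `motif`, `start`, `end` (1-based
#'   inclusive), `mismatches`.
#' @export
find_motifs <- function(seq, motif_defs = default_motifs()) {
  x <- toupper(seq)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- list()
  for (i in seq_len(nrow(motif_defs))) {
    pat <- toupper(motif_defs$pattern[i])
    mm_max <- motif_defs$max_mismatches[i]
    pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
    bad <- setdiff(pchars, names(IUPAC_SETS))
    if (length(bad) > 0) {
      stop("non-IUPAC symbol(s) in pattern ", motif_defs$name[i], ": ",
           paste(bad, collapse = ", "))
    }
    m <- length(pchars)
    if (m > L) next
    npos <- L - m + 1L
    mm <- integer(npos)
    for (j in seq_len(m)) {
      allowed <- IUPAC_SETS[[pchars[j]]]
      mm <- mm + !(chars[j:(j + npos - 1L)] %in% allowed)
    }
    starts <- which(mm <= mm_max)
    if (length(starts) == 0) next
    hits <- tibble::tibble(
      motif = motif_defs$name[i],
      start = starts, end = starts + m - 1L,
      mismatches = mm[starts]
    )
    out[[length(out) + 1L]] <- reduce_overlaps(hits)
  }
  if (length(out) == 0) {
    return(tibble::tibble(motif = character(), start = integer(),
                          end = integer(), mismatches = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$start, .data$motif)
}

# Collapse overlapping windows of one motif to the best hit per cluster.
reduce_overlaps <- function(hits) {
  hits <- hits[order(hits$start), , drop = FALSE]
  cluster <- cumsum(c(TRUE, hits$start[-1] > cummax(hits$end)[-nrow(hits)]))
  hits |>
    dplyr::mutate(.cluster = cluster) |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::slice_min(.data$mismatches, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".cluster")
}

#' Detect tandem repeat arrays
#'
#' For each candidate period `p`, positions where `s[i] == s[i + p]` are
#' scanned for maximal regions whose positional identity is at least
#' `min_identity`; adjacent match runs are merged greedily while the
#' merged identity stays above the threshold. Regions spanning at least
#' `min_copies` copies are reported with a majority-vote consensus unit,
#' fractional copy number and purity. A region already reported at a
#' smaller period is suppressed at its multiples (smallest period wins).
#'
#' @param seq Nucleotide sequence.
#' @param min_period,max_period Period range searched (bp).
#' @param min_copies Minimum copy number (fractional region length / p).
#' @param min_identity Minimum positional identity within the array.
#' @return Tibble with columns `kind` (`"tandem"`), `start`, `end`,
#'   `period`, `unit`, `copies`, `purity`.
#' @export
detect_tandem_repeats <- function(seq, min_period = 10, max_period = 200,
                                  min_copies = 3, min_identity = 0.85) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  max_period <- min(max_period, floor(L / min_copies))
  regions <- list()
  p <- min_period
  while (p <= max_period) {
    m <- chars[seq_len(L - p)] == chars[seq_len(L - p) + p]
    # cheap vectorized screen: a qualifying region must contain a window
    # of ~(min_copies - 1) periods near the identity floor; random
    # background (identity ~ 0.25-0.3) never does, so most periods are
    # skipped without segmentation
    w <- min(length(m), max(1L, as.integer(ceiling(p * (min_copies - 1)))))
    cm <- c(0, cumsum(m))
    roll_max <- max(cm[(w + 1):length(cm)] - cm[seq_len(length(cm) - w)]) / w
    if (roll_max < min_identity - 0.05) {
      p <- p + 1L
      next
    }
    for (seg in max_scoring_segments(m, min_identity)) {
      len <- seg[2] - seg[1] + 1L + p
      copies <- len / p
      purity <- mean(m[seg[1]:seg[2]])
      if (copies >= min_copies && purity >= min_identity) {
        regions[[length(regions) + 1L]] <- tibble::tibble(
          kind = "tandem", start = seg[1], end = seg[1] + len - 1L,
          period = p, unit = consensus_unit(chars, seg[1], len, p),
          copies = copies, purity = purity
        )
      }
    }
    p <- p + 1L
  }
  if (length(regions) == 0) {
    return(tibble::tibble(kind = character(), start = integer(),
                          end = integer(), period = integer(),
                          unit = character(), copies = numeric(),
                          purity = numeric()))
  }
  regs <- dplyr::bind_rows(regions) |> dplyr::arrange(.data$period, .data$start)
  suppress_multiples(regs)
}

# Maximal segments of a logical match vector with identity above the
# threshold, as all maximal-scoring subsequences (Ruzzo-Tompa) under
# match = +(1 - t), mismatch = -t. Every reported segment has identity
# > t and cannot be extended or trimmed to a higher score, so a pure
# array never dilutes itself by absorbing chance matches in flanking
# background.
max_scoring_segments <- function(m, min_identity) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ti <- which(r$values)
  if (length(ti) == 0) return(list())
  # cumulative score at run boundaries; candidates are whole match runs
  run_score <- r$lengths * ifelse(r$values, 1 - min_identity, -min_identity)
  cum <- c(0, cumsum(run_score))
  segs <- list()   # each: c(start, end, L, R) with cumulative scores
  for (k in ti) {
    cur <- c(starts[k], ends[k], cum[k], cum[k + 1])
    repeat {
      j <- length(segs)
      while (j >= 1 && segs[[j]][3] >= cur[3]) j <- j - 1
      if (j == 0 || segs[[j]][4] >= cur[4]) {
        segs[[length(segs) + 1L]] <- cur
        break
      }
      # merge with segment j and everything after it
      cur <- c(segs[[j]][1], cur[2], segs[[j]][3], cur[4])
      segs <- segs[seq_len(j - 1L)]
    }
  }
  lapply(segs, function(s) c(s[1], s[2]))
}

consensus_unit <- function(chars, start, len, p) {
  unit <- character(p)
  for (j in seq_len(p)) {
    idx <- seq(start + j - 1L, start + len - 1L, by = p)
    idx <- idx[idx <= start + len - 1L]
    unit[j] <- names(which.max(table(chars[idx])))
  }
  paste(unit, collapse = "")
}

suppress_multiples <- function(regs) {
  keep <- rep(TRUE, nrow(regs))
  for (i in seq_len(nrow(regs))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(regs))) {
      if (i == j || !keep[j]) next
      if (regs$period[j] > regs$period[i] &&
          regs$period[j] %% regs$period[i] == 0) {
        ov <- min(regs$end[i], regs$end[j]) - max(regs$start[i], regs$start[j]) + 1
        if (ov >= 0.8 * (regs$end[j] - regs$start[j] + 1)) keep[j] <- FALSE
      }
    }
  }
  regs[keep, , drop = FALSE]
}

#' Classify the two AT-rich repeat types of squamate control regions
#'
#' Detects the two AT-rich sequence classes seen at large scale in
#' chamaeleonid control regions: `AT_dinucleotide`, a maximal run of the
#' period-2 unit `AT`/`TA`, and `AT_block`, a maximal concatenation of at
#' least two blocks each of the form `A^xT^y` with `x >= 2` and
#' `y >= 2`. Regions shorter than `min_len` are discarded; a region
#' qualifying as both is labelled `AT_dinucleotide` (the stricter
#' pattern wins).
#'
#' @param seq Nucleotide sequence.
#' @param min_len Minimum array length (bp).
#' @param min_copies Minimum copy count (dinucleotide: AT units;
#'   block: blocks, with an absolute floor of 2 blocks).
#' @param max_impurity Fraction of off-pattern positions tolerated when
#'   bridging two alternating runs separated by at most 2 nt (dinucleotide
#'   arrays only; block arrays are reported exact).
#' @return Tibble with columns `kind`, `start`, `end`, `unit`, `copies`,
#'   `purity`.
#' @export
classify_at_arrays <- function(seq, min_len = 20, min_copies = 3,
                               max_impurity = 0) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  empty <- tibble::tibble(kind = character(), start = integer(),
                          end = integer(), unit = character(),
                          copies = numeric(), purity = numeric())
  if (L == 0) return(empty)

  # --- AT/TA dinucleotide arrays ---
  is_at <- chars %in% c("A", "T")
  alt <- if (L >= 2) {
    is_at[-L] & is_at[-1] & chars[-L] != chars[-1]
  } else logical(0)
  din <- list()
  segs <- true_runs(alt)
  segs <- lapply(segs, function(s) c(s[1], s[2] + 1L))  # region on sequence
  # bridge neighbouring runs across tiny gaps when impurity allows
  if (max_impurity > 0 && length(segs) > 1) {
    merged <- list(segs[[1]])
    for (s in segs[-1]) {
      last <- merged[[length(merged)]]
      gap <- s[1] - last[2] - 1L
      len <- s[2] - last[1] + 1L
      if (gap <= 2 && gap / len <= max_impurity) {
        merged[[length(merged)]] <- c(last[1], s[2])
      } else {
        merged[[length(merged) + 1L]] <- s
      }
    }
    segs <- merged
  }
  for (s in segs) {
    len <- s[2] - s[1] + 1L
    copies <- floor(len / 2)
    if (len >= min_len && copies >= min_copies) {
      span <- chars[s[1]:s[2]]
      pure <- sum(span[-length(span)] != span[-1] & span[-1] %in% c("A", "T") &
                    span[-length(span)] %in% c("A", "T")) + 1L
      din[[length(din) + 1L]] <- tibble::tibble(
        kind = "AT_dinucleotide", start = s[1], end = s[2],
        unit = substr(paste(span[1:2], collapse = ""), 1, 2),
        copies = copies, purity = min(1, pure / len)
      )
    }
  }

  # --- A^xT^y block arrays ---
  r <- rle(chars)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  blk <- list()
  i <- 1
  while (i < length(r$values)) {
    if (r$values[i] == "A" && r$lengths[i] >= 2 &&
        r$values[i + 1] == "T" && r$lengths[i + 1] >= 2) {
      j <- i
      profile <- list()
      while (j < length(r$values) && r$values[j] == "A" &&
             r$lengths[j] >= 2 && r$values[j + 1] == "T" &&
             r$lengths[j + 1] >= 2) {
        profile[[length(profile) + 1L]] <- c(r$lengths[j], r$lengths[j + 1])
        j <- j + 2
      }
      n_blocks <- length(profile)
      a <- rstart[i]
      b <- rend[i + 2 * n_blocks - 1L]
      len <- b - a + 1L
      if (n_blocks >= 2 && len >= min_len) {
        modal <- names(which.max(table(vapply(profile, function(xy) {
          paste0("A", xy[1], "T", xy[2])
        }, character(1)))))
        blk[[length(blk) + 1L]] <- tibble::tibble(
          kind = "AT_block", start = a, end = b, unit = modal,
          copies = n_blocks, purity = 1
        )
      }
      i <- j
    } else {
      i <- i + 1
    }
  }

  din_tbl <- if (length(din)) dplyr::bind_rows(din) else empty
  blk_tbl <- if (length(blk)) dplyr::bind_rows(blk) else empty
  # stricter pattern wins: drop block arrays contained in a dinucleotide
  if (nrow(blk_tbl) > 0 && nrow(din_tbl) > 0) {
    contained <- vapply(seq_len(nrow(blk_tbl)), function(i) {
      any(din_tbl$start <= blk_tbl$start[i] & din_tbl$end >= blk_tbl$end[i])
    }, logical(1))
    blk_tbl <- blk_tbl[!contained, , drop = FALSE]
  }
  dplyr::bind_rows(din_tbl, blk_tbl) |> dplyr::arrange(.data$start)
}

true_runs <- function(x) {
  if (length(x) == 0) return(list())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ti <- which(r$values)
  lapply(ti, function(k) c(starts[k], ends[k]))
}

#' Partition a control region into its three domains
#'
#' Domain 1 runs from the 5' end through the 3'-most ETAS hit; Domain 2
#' from there through the 3'-most central conserved box (C/D/F) hit;
#' Domain 3 is the remainder (CSBs and AT-rich arrays). When an anchor
#' class has no hits the corresponding boundary falls back to a
#' configured fractional position and the partition is flagged
#' low-confidence. Anchors out of canonical order (a CSB upstream of the
#' ETAS region, or boxes upstream of ETAS) either raise an error or fall
#' back to the fractional partition with a flag, per `on_disorder`.
#'
#' @param seq Control-region sequence.
#' @param hits Motif hits from [find_motifs()].
#' @param fallback Fractional boundary positions used when anchors are
#'   missing (defaults: 1/3 and 2/3 of the CR).
#' @param on_disorder `"flag"` or `"error"`.
#' @return Tibble with columns `domain` (1:3), `start`, `end`; attributes
#'   `low_confidence` (logical) and `notes` (character).
#' @export
partition_domains <- function(seq, hits, fallback = c(1 / 3, 2 / 3),
                              on_disorder = c("flag", "error")) {
  on_disorder <- match.arg(on_disorder)
  L <- nchar(seq)
  if (L == 0) stop("empty control-region sequence")
  etas_end <- suppressWarnings(
    max(hits$end[hits$motif %in% c("ETAS1", "ETAS2")]))
  box_end <- suppressWarnings(
    max(hits$end[hits$motif %in% c("BoxC", "BoxD", "BoxF")]))
  csb_start <- suppressWarnings(
    min(hits$start[hits$motif %in% c("CSB1", "CSB2", "CSB3")]))
  low <- FALSE
  notes <- character()
  disorder <- (is.finite(etas_end) && is.finite(box_end) &&
                 box_end <= etas_end) ||
    (is.finite(csb_start) && is.finite(box_end) && csb_start <= box_end) ||
    (is.finite(csb_start) && is.finite(etas_end) && csb_start <= etas_end)
  if (disorder) {
    if (on_disorder == "error") {
      stop("motif anchors out of canonical ETAS < Box < CSB order")
    }
    low <- TRUE
    notes <- c(notes, "anchors out of canonical order; fractional fallback")
    etas_end <- box_end <- -Inf
  }
  if (!is.finite(etas_end)) {
    etas_end <- max(1L, round(L * fallback[1]))
    low <- TRUE
    notes <- c(notes, "no ETAS anchor; fractional Domain 1/2 boundary")
  }
  if (!is.finite(box_end) || box_end <= etas_end) {
    box_end <- max(etas_end + 1L, round(L * fallback[2]))
    low <- TRUE
    notes <- c(notes, "no central-box anchor; fractional Domain 2/3 boundary")
  }
  box_end <- min(box_end, L - 1L)
  etas_end <- min(etas_end, box_end - 1L)
  out <- tibble::tibble(
    domain = 1:3,
    start = c(1L, etas_end + 1L, box_end + 1L),
    end = c(etas_end, box_end, L)
  )
  attr(out, "low_confidence") <- low
  attr(out, "notes") <- notes
  out
}

#' Default control-region annotation configuration
#'
#' @param motifs Motif definition tibble.
#' @param tandem Tandem-repeat thresholds (see [detect_tandem_repeats()]).
#' @param at AT-array thresholds (see [classify_at_arrays()]).
#' @param domains Domain-partition settings (see [partition_domains()]).
#' @return A named list of class `cr_config`.
#' @export
cr_config <- function(motifs = default_motifs(),
                      tandem = list(min_period = 10, max_period = 200,
                                    min_copies = 3, min_identity = 0.85),
                      at = list(min_len = 20, min_copies = 3,
                                max_impurity = 0),
                      domains = list(fallback = c(1 / 3, 2 / 3),
                                     on_disorder = "flag")) {
  structure(list(motifs = motifs, tandem = tandem, at = at,
                 domains = domains), class = "cr_config")
}

#' Read / write a control-region annotation config (YAML or JSON)
#'
#' The file may override any subset of the defaults; motifs are given as
#' a list of `name`/`pattern`/`max_mismatches` entries.
#'
#' @param path Config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `cr_config` list.
#' @export
read_cr_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- cr_config()
  if (!is.null(raw$motifs)) {
    m <- tibble::as_tibble(dplyr::bind_rows(raw$motifs))
    if (!("max_mismatches" %in% names(m))) {
      m$max_mismatches <- as.integer(floor(nchar(m$pattern) / 5))
    }
    base$motifs <- m
  }
  for (grp in c("tandem", "at", "domains")) {
    for (key in names(raw[[grp]])) base[[grp]][[key]] <- raw[[grp]][[key]]
  }
  base
}

#' @rdname read_cr_config
#' @param config A `cr_config` list.
#' @export
write_cr_config <- function(config, path) {
  obj <- list(
    motifs = purrr::pmap(config$motifs, function(name, pattern,
                                                 max_mismatches, ...) {
      list(name = name, pattern = pattern, max_mismatches = max_mismatches)
    }),
    tandem = config$tandem, at = config$at, domains = config$domains
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Full structural annotation of one control region
#'
#' Runs the motif search, tandem-repeat detection, AT-array
#' classification and domain partition on a control-region sequence, and
#' labels each AT-rich array by its position relative to an embedded or
#' adjacent tRNA-Pro gene (when its interval is supplied): `5prime`,
#' `3prime`, `overlapping`, or `no_trnP`.
#'
#' @param seq Control-region sequence (heavy strand).
#' @param trnp Optional `c(start, end)` of a tRNA-Pro gene, 1-based
#'   inclusive on the CR.
#' @param config A `cr_config` list.
#' @return Object of class `cr_annotation`: list with tibbles `motifs`,
#'   `domains`, `repeats` (tandem + AT arrays, with a `context` column),
#'   plus `trnp`, `length` and `low_confidence`.
#' @export
cr_profile <- function(seq, trnp = NULL, config = cr_config()) {
  motifs <- find_motifs(seq, config$motifs)
  tandem <- do.call(detect_tandem_repeats, c(list(seq), config$tandem))
  at <- do.call(classify_at_arrays, c(list(seq), config$at))
  # AT-rich arrays belong to the AT classifier; drop generic-tandem views
  # of the same region (an AT array is also a short-period tandem)
  if (nrow(tandem) > 0 && nrow(at) > 0) {
    redundant <- vapply(seq_len(nrow(tandem)), function(i) {
      ov <- pmin(tandem$end[i], at$end) - pmax(tandem$start[i], at$start) + 1
      any(ov >= 0.5 * (tandem$end[i] - tandem$start[i] + 1))
    }, logical(1))
    tandem <- tandem[!redundant, , drop = FALSE]
  }
  domains <- partition_domains(seq, motifs,
                               fallback = config$domains$fallback,
                               on_disorder = config$domains$on_disorder)
  reps <- dplyr::bind_rows(
    if (nrow(tandem)) dplyr::mutate(tandem, unit = .data$unit) else NULL,
    at
  )
  if (nrow(reps) > 0) {
    reps$context <- if (is.null(trnp)) {
      "no_trnP"
    } else {
      dplyr::case_when(
        reps$end < trnp[1] ~ "5prime",
        reps$start > trnp[2] ~ "3prime",
        TRUE ~ "overlapping"
      )
    }
  } else {
    reps$context <- character()
  }
  structure(
    list(motifs = motifs, domains = domains, repeats = reps,
         trnp = trnp, length = nchar(seq),
         low_confidence = attr(domains, "low_confidence")),
    class = "cr_annotation"
  )
}

#' @export
print.cr_annotation <- function(x, ...) {
  cat("Control-region annotation (", x$length, " bp",
      if (x$low_confidence) ", low-confidence domains" else "", ")\n",
      sep = "")
  cat("Domains:\n"); print(x$domains)
  cat("Motif hits: ", nrow(x$motifs), "\n", sep = "")
  if (nrow(x$motifs)) print(x$motifs)
  cat("Repeat arrays: ", nrow(x$repeats), "\n", sep = "")
  if (nrow(x$repeats)) print(x$repeats)
  invisible(x)
}

#' Write a control-region annotation to disk
#'
#' `"tsv"` emits a BED-like table (1-based inclusive coordinates) with
#' one row per domain, motif hit, repeat array and tRNA-Pro interval;
#' `"json"` serializes the whole annotation.
#'
#' @param x A `cr_annotation`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cr_annotation <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(length = x$length, low_confidence = x$low_confidence,
           domains = x$domains, motifs = x$motifs, repeats = x$repeats,
           trnp = x$trnp),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  rows <- dplyr::bind_rows(
    tibble::tibble(type = "domain", name = paste0("Domain", x$domains$domain),
                   start = x$domains$start, end = x$domains$end,
                   detail = NA_character_),
    if (nrow(x$motifs)) tibble::tibble(
      type = "motif", name = x$motifs$motif, start = x$motifs$start,
      end = x$motifs$end, detail = paste0("mismatches=", x$motifs$mismatches)),
    if (nrow(x$repeats)) tibble::tibble(
      type = "repeat", name = x$repeats$kind, start = x$repeats$start,
      end = x$repeats$end,
      detail = paste0("unit=", x$repeats$unit, ";copies=",
                      signif(x$repeats$copies, 4), ";purity=",
                      signif(x$repeats$purity, 4), ";context=",
                      x$repeats$context)),
    if (!is.null(x$trnp)) tibble::tibble(
      type = "gene", name = "trnP", start = x$trnp[1], end = x$trnp[2],
      detail = NA_character_)
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings FASTA I/O returning plain named
#' character vectors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}
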