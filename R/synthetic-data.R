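# Seeded generators with ground-truth manifests. Every generator calls
# with_seed() so that a fixed seed reproduces its output exactly and the
# caller's RNG stream is left untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

#' Simulate gene orders evolving by discrete rearrangement events on a tree
#'
#' Every lineage starts at the typical vertebrate arrangement; planted
#' events (state transitions of the arrangement characters `C1`..`C5`)
#' are applied along branches and propagated tipward. Events are either
#' supplied explicitly or sampled: `mode = "single_event"` plants at most
#' one event per character (a uniformly chosen branch, with probability
#' `p_char`), the regime in which every planted change is recoverable
#' exactly; `mode = "per_branch"` draws an independent event on each
#' branch of each character with probability `event_prob`.
#'
#' @param tree A rooted `ape::phylo`, or an integer tip count for a
#'   random topology.
#' @param events Optional explicit event tibble with columns `character`,
#'   `branch` (tip/node label or node id) and `to` (target state). Two
#'   events for one character on the same branch are an error.
#' @param mode Sampling mode when `events` is `NULL`.
#' @param p_char Probability a character changes at all
#'   (`"single_event"` mode).
#' @param event_prob Per-branch transition probability (`"per_branch"`
#'   mode).
#' @param seed Random seed.
#' @return List with `orders` (named list of tip `gene_order`s),
#'   `matrix` (tip character-state tibble), `tree`, and `manifest`
#'   (planted events with `from`/`to`, tip states, seed, parameters).
#' @export
simulate_arrangements <- function(tree = 10, events = NULL,
                                  mode = c("single_event", "per_branch"),
                                  p_char = 0.7, event_prob = 0.05,
                                  seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (is.numeric(tree)) {
      tree <- ape::rtree(as.integer(tree), br = NULL)
      tree$tip.label <- paste0("t", seq_len(ape::Ntip(tree)))
    }
    chars <- arrangement_characters()
    ntip <- ape::Ntip(tree)
    n_nodes <- ntip + tree$Nnode
    root <- ntip + 1L

    if (is.null(events)) {
      ev <- list()
      for (i in seq_len(nrow(chars))) {
        if (mode == "single_event") {
          if (stats::runif(1) > p_char) next
          node <- sample(setdiff(seq_len(n_nodes), root), 1)
          anc <- chars$ancestral_state[i]
          to <- sample(setdiff(chars$states[[i]], anc), 1)
          ev[[length(ev) + 1L]] <- tibble::tibble(
            character = chars$id[i], node = node, to = to)
        } else {
          for (node in setdiff(seq_len(n_nodes), root)) {
            if (stats::runif(1) < event_prob) {
              ev[[length(ev) + 1L]] <- tibble::tibble(
                character = chars$id[i], node = node, to = NA_character_)
            }
          }
        }
      }
      events <- if (length(ev)) dplyr::bind_rows(ev) else
        tibble::tibble(character = character(), node = integer(),
                       to = character())
    } else {
      events <- tibble::as_tibble(events)
      events$node <- vapply(events$branch, resolve_node, integer(1),
                            tree = tree)
    }
    key <- paste(events$character, events$node)
    if (anyDuplicated(key)) {
      stop("conflicting events: two changes for one character on branch ",
           events$node[duplicated(key)][1])
    }

    # propagate states root-to-tip
    states <- matrix(rep(chars$ancestral_state, each = n_nodes),
                     n_nodes, nrow(chars),
                     dimnames = list(NULL, chars$id))
    po <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
    events$from <- NA_character_
    for (e in seq_len(nrow(pre))) {
      p <- pre[e, 1]; child <- pre[e, 2]
      states[child, ] <- states[p, ]
      hit <- which(events$node == child)
      for (h in hit) {
        ch <- events$character[h]
        from <- states[p, ch]
        to <- events$to[h]
        if (is.na(to)) {
          to <- sample(setdiff(chars$states[[match(ch, chars$id)]], from), 1)
          events$to[h] <- to
        }
        events$from[h] <- from
        states[child, ch] <- to
      }
    }
    events$branch <- vapply(events$node, node_label, character(1),
                            tree = tree)

    tips <- tree$tip.label
    matrix_tbl <- dplyr::bind_cols(
      tibble::tibble(taxon = tips),
      tibble::as_tibble(states[seq_len(ntip), , drop = FALSE])
    )
    orders <- lapply(seq_len(ntip), function(i) {
      apply_rearrangements(matrix_tbl[i, ])
    })
    names(orders) <- tips
    list(
      orders = orders,
      matrix = matrix_tbl,
      tree = tree,
      manifest = list(
        seed = seed, mode = mode,
        events = events[, c("character", "branch", "node", "from", "to")],
        tip_states = matrix_tbl
      )
    )
  })
}

# Materialize one concrete instance of an IUPAC pattern.
realize_iupac <- function(pattern) {
  pchars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(pchars, function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (is.null(opts)) stop("non-IUPAC symbol in pattern: ", ch)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

mutate_seq <- function(x, n_subs) {
  if (n_subs <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), min(n_subs, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a control-region sequence with planted structure
#'
#' Assembles a control region in the three-domain layout: Domain 1 with
#' an optional tandem-repeat array and the ETAS motifs, Domain 2 with
#' central conserved boxes F, C and D in random background, Domain 3 with
#' CSB motifs, AT-rich arrays and an optional embedded tRNA-Pro placed a
#' configurable spacer distance from the 3' end (the chamaeleonid
#' geometry: 200-400 bp upstream of tRNA-Phe). Styles:
#' `"chamaeleonid"` plants an `(A^xT^y)n` block array 5' of tRNA-Pro and
#' an `(AT)n` array 3' of it; `"brookesia"` plants `(AT)n` on both
#' sides; `"plain"` plants neither arrays nor tRNA-Pro.
#'
#' @param style Layout preset (see above).
#' @param motifs Motif definitions planted (exact realizations of each
#'   IUPAC pattern); `NULL` plants none.
#' @param include_tandem Plant the Domain-1 tandem array?
#' @param tandem_unit,tandem_copies,tandem_noise Unit length (bp), copy
#'   number, and per-position substitution rate of the Domain-1 array.
#' @param motif_noise Substitutions applied to each planted motif
#'   instance.
#' @param at_block `c(x, y, copies)` of the block array.
#' @param at_dinucleotide Copy number of the `(AT)n` arrays.
#' @param spacer_range tRNA-Pro to 3'-end distance range (bp).
#' @param gc Background GC content.
#' @param domain_lengths Approximate background budget per domain (bp).
#' @param seed Random seed.
#' @param max_tries Regeneration attempts used to avoid chance motif
#'   hits or arrays in the background (an oracle check against the
#'   annotator's own thresholds before emitting).
#' @return List with `sequence` and `manifest` (planted motif positions,
#'   repeat arrays, domain boundaries, tRNA-Pro interval, seed, params).
#' @export
simulate_cr <- function(style = c("chamaeleonid", "brookesia", "plain"),
                        motifs = default_motifs(),
                        include_tandem = TRUE, tandem_unit = 64,
                        tandem_copies = 8, tandem_noise = 0.02,
                        motif_noise = 0,
                        at_block = c(x = 3, y = 2, copies = 8),
                        at_dinucleotide = 15,
                        spacer_range = c(200, 400), gc = 0.4,
                        domain_lengths = c(150, 250, 150),
                        seed = 1, max_tries = 25) {
  style <- match.arg(style)
  for (try in seq_len(max_tries)) {
    out <- with_seed(seed + 1000L * (try - 1L),
                     build_cr(style, motifs, include_tandem, tandem_unit,
                              tandem_copies, tandem_noise, motif_noise,
                              at_block, at_dinucleotide, spacer_range, gc,
                              domain_lengths, seed))
    if (cr_truth_clean(out, motifs)) return(out)
  }
  stop("could not generate an unambiguous control region in ", max_tries,
       " attempts; relax the layout or change the seed")
}

build_cr <- function(style, motifs, include_tandem, tandem_unit,
                     tandem_copies, tandem_noise, motif_noise,
                     at_block, at_dinucleotide, spacer_range, gc,
                     domain_lengths, seed) {
  parts <- character()
  pos <- 0L
  planted_motifs <- list()
  planted_repeats <- list()
  trnp <- NULL

  emit <- function(x) {
    parts[[length(parts) + 1L]] <<- x
    pos <<- pos + nchar(x)
  }
  bg <- function(n) emit(random_dna(n, gc))
  plant_motif <- function(name) {
    if (is.null(motifs)) return()
    i <- match(name, motifs$name)
    if (is.na(i)) return()
    inst <- mutate_seq(realize_iupac(motifs$pattern[i]), motif_noise)
    planted_motifs[[length(planted_motifs) + 1L]] <<- tibble::tibble(
      motif = name, start = pos + 1L, end = pos + nchar(inst),
      mismatches = motif_noise)
    emit(inst)
  }
  plant_repeat <- function(kind, x) {
    planted_repeats[[length(planted_repeats) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(kind = kind, start = pos + 1L, end = pos + nchar(x)),
      tibble::as_tibble(attr(x, "info") %||% list()))
    emit(unclass(x))
  }

  # --- Domain 1 ---
  if (include_tandem) {
    unit <- random_dna(tandem_unit, gc)
    arr <- paste(rep(unit, tandem_copies), collapse = "")
    arr <- mutate_seq(arr, round(tandem_noise * nchar(arr)))
    attr(arr, "info") <- list(period = tandem_unit, copies = tandem_copies,
                              unit = unit)
    plant_repeat("tandem", arr)
    bg(30)
  }
  bg(domain_lengths[1] %/% 2)
  plant_motif("ETAS1")
  bg(30)
  plant_motif("ETAS2")
  d1_end <- pos   # the annotator's Domain 1 ends at the 3'-most ETAS

  # --- Domain 2 ---
  bg(domain_lengths[2] %/% 4)
  plant_motif("BoxF")
  bg(domain_lengths[2] %/% 4)
  plant_motif("BoxC")
  bg(domain_lengths[2] %/% 4)
  plant_motif("BoxD")
  d2_end <- pos   # Domain 2 ends at the 3'-most central box
  bg(domain_lengths[2] %/% 4)

  # --- Domain 3 ---
  bg(domain_lengths[3] %/% 2)
  plant_motif("CSB1")
  bg(30)
  plant_motif("CSB3")
  bg(domain_lengths[3] %/% 2)

  at_din <- function() {
    x <- paste(rep("AT", at_dinucleotide), collapse = "")
    attr(x, "info") <- list(unit = "AT", copies = at_dinucleotide)
    x
  }
  at_blk <- function() {
    x <- paste(rep(paste0(strrep("A", at_block[["x"]]),
                          strrep("T", at_block[["y"]])),
                   at_block[["copies"]]), collapse = "")
    attr(x, "info") <- list(unit = paste0("A", at_block[["x"]], "T",
                                          at_block[["y"]]),
                            copies = at_block[["copies"]])
    x
  }
  # G/C guards stop arrays from bleeding into AT-ish background
  guard <- function() emit("GC")

  if (style != "plain") {
    guard()
    if (style == "chamaeleonid") {
      plant_repeat("AT_block", at_blk())
    } else {
      plant_repeat("AT_dinucleotide", at_din())
    }
    guard()
    trnp_seq <- simulate_trna("TGG", seed = seed + 7L)$sequence
    trnp <- c(pos + 1L, pos + nchar(trnp_seq))
    emit(trnp_seq)
    spacer <- sample(seq(spacer_range[1], spacer_range[2]), 1)
    guard()
    plant_repeat("AT_dinucleotide", at_din())
    guard()
    tail_bg <- spacer - (pos - trnp[2])
    bg(max(tail_bg, 10))
  } else {
    bg(60)
  }

  seq <- paste(parts, collapse = "")
  list(
    sequence = seq,
    manifest = list(
      seed = seed, style = style,
      motifs = if (length(planted_motifs)) dplyr::bind_rows(planted_motifs)
      else tibble::tibble(motif = character(), start = integer(),
                          end = integer(), mismatches = integer()),
      repeats = if (length(planted_repeats)) dplyr::bind_rows(planted_repeats)
      else tibble::tibble(kind = character(), start = integer(),
                          end = integer()),
      domains = tibble::tibble(domain = 1:3,
                               start = c(1L, d1_end + 1L, d2_end + 1L),
                               end = c(d1_end, d2_end, nchar(seq))),
      trnp = trnp,
      length = nchar(seq)
    )
  )
}

# Oracle check before emitting: the planted motifs must be the only hits,
# and no chance AT array may reach the annotator's default thresholds
# outside the planted intervals.
cr_truth_clean <- function(out, motifs) {
  man <- out$manifest
  if (!is.null(motifs) && nrow(man$motifs) > 0) {
    hits <- find_motifs(out$sequence, motifs)
    planted <- man$motifs[order(man$motifs$start), ]
    hits <- hits[order(hits$start), ]
    if (nrow(hits) != nrow(planted) ||
        !all(hits$start == planted$start & hits$motif == planted$motif)) {
      return(FALSE)
    }
  }
  arrays <- classify_at_arrays(out$sequence)
  pl <- man$repeats[man$repeats$kind != "tandem", , drop = FALSE]
  if (nrow(arrays) != nrow(pl)) return(FALSE)
  if (nrow(arrays) > 0 &&
      !all(sort(arrays$start) == sort(pl$start))) return(FALSE)
  TRUE
}

#' Simulate a cloverleaf-consistent tRNA gene
#'
#' Builds a tRNA gene sequence with paired acceptor, D, anticodon and T
#' stems (Watson-Crick pairs), random loops, and the requested anticodon
#' at positions 3-5 of the 7-nt anticodon loop. The generator verifies
#' with the cloverleaf heuristic that the planted anticodon arm is the
#' best-scoring candidate before emitting (resampling otherwise), so the
#' planted anticodon is recoverable by construction.
#'
#' @param anticodon Anticodon triplet (DNA alphabet, 5'->3').
#' @param seed Random seed.
#' @param max_tries Resampling bound.
#' @return List with `sequence` and `manifest` (anticodon, its position,
#'   seed).
#' @export
simulate_trna <- function(anticodon, seed = 1, max_tries = 25) {
  anticodon <- toupper(anticodon)
  if (!grepl("^[ACGT]{3}$", anticodon)) {
    stop("anticodon must be a DNA triplet")
  }
  pair_of <- c(A = "T", T = "A", G = "C", C = "G")
  for (try in seq_len(max_tries)) {
    out <- with_seed(seed + 1000L * (try - 1L), {
      stem <- function(n) random_dna(n, gc = 0.5)
      rc <- function(x) paste(rev(pair_of[strsplit(x, "", TRUE)[[1]]]),
                              collapse = "")
      acc <- stem(7)
      d_stem <- stem(4)
      ac_stem <- stem(5)
      t_stem <- stem(5)
      loop_d <- random_dna(8, 0.3)
      ac_loop <- paste0(random_dna(2, 0.3), anticodon, random_dna(2, 0.3))
      var_loop <- random_dna(4, 0.4)
      loop_t <- random_dna(7, 0.3)
      seq <- paste0(acc, "TA",
                    d_stem, loop_d, rc(d_stem), "A",
                    ac_stem, ac_loop, rc(ac_stem),
                    var_loop,
                    t_stem, loop_t, rc(t_stem),
                    rc(acc))
      ac_start <- nchar(acc) + 2 + 2 * nchar(d_stem) + nchar(loop_d) + 1 +
        nchar(ac_stem) + 3
      list(sequence = seq,
           manifest = list(anticodon = anticodon,
                           anticodon_start = ac_start, seed = seed))
    })
    got <- extract_anticodon(out$sequence)
    if (isTRUE(got$determined) &&
        identical(got$anticodon, anticodon)) {
      return(out)
    }
  }
  stop("could not build an unambiguous tRNA in ", max_tries, " attempts")
}

#' Simulate a WANCY-cluster spacer with or without a replication-origin
#' hairpin
#'
#' With `with_hairpin = TRUE`, a perfect stem-loop of the requested size
#' is embedded in random background. With `with_hairpin = FALSE`, the
#' background is resampled until no stem of at least `guard_min_stem`
#' pairs exists (checked against the hairpin detector's own pairing
#' rule), so a negative region is genuinely negative at that threshold.
#'
#' @param with_hairpin Plant a hairpin?
#' @param seed Random seed.
#' @param length Region length (nt).
#' @param stem_length,loop_length Planted hairpin geometry.
#' @param guard_min_stem Threshold at which a hairpin-free region is
#'   guaranteed free.
#' @param gc Background GC content.
#' @param max_tries Resampling bound.
#' @return List with `sequence` and `manifest` (planted coordinates or
#'   `NULL`, seed).
#' @export
simulate_wancy <- function(with_hairpin = TRUE, seed = 1, length = 40,
                           stem_length = 8, loop_length = 5,
                           guard_min_stem = 8, gc = 0.4, max_tries = 50) {
  pair_of <- c(A = "T", T = "A", G = "C", C = "G")
  for (try in seq_len(max_tries)) {
    out <- with_seed(seed + 1000L * (try - 1L), {
      if (with_hairpin) {
        arm <- random_dna(stem_length, 0.5)
        loop <- random_dna(loop_length, 0.3)
        hp <- paste0(arm, loop,
                     paste(rev(pair_of[strsplit(arm, "", TRUE)[[1]]]),
                           collapse = ""))
        flank <- length - nchar(hp)
        left <- sample(0:max(flank, 0), 1)
        seq <- paste0(random_dna(left, gc), hp,
                      random_dna(max(flank - left, 0), gc))
        list(sequence = seq,
             manifest = list(hairpin = list(stem_start = left + 1L,
                                            stem_length = stem_length,
                                            loop_length = loop_length),
                             seed = seed))
      } else {
        list(sequence = random_dna(length, gc),
             manifest = list(hairpin = NULL, seed = seed))
      }
    })
    if (with_hairpin) {
      call <- detect_ol_hairpin(out$sequence, min_stem = stem_length)
      if (isTRUE(call$present)) return(out)
    } else {
      call <- detect_ol_hairpin(out$sequence, min_stem = guard_min_stem)
      if (!isTRUE(call$present)) return(out)
    }
  }
  stop("could not build the requested WANCY region in ", max_tries,
       " attempts")
}

#' Write a generator's outputs and truth manifest to a directory
#'
#' Emits, as applicable: gene orders as TSV, the character matrix as TSV,
#' the tree as Newick, sequences as FASTA, and the manifest as JSON.
#'
#' @param sim A generator result (from [simulate_arrangements()],
#'   [simulate_cr()], [simulate_trna()] or [simulate_wancy()]).
#' @param dir Target directory (created if needed).
#' @param name Stem for file names.
#' @return The manifest JSON path, invisibly.
#' @export
write_simulation <- function(sim, dir, name = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$orders)) {
    records <- purrr::imap(sim$orders, function(ord, tx) {
      new_mitogenome_record(taxon = tx, family = "simulated",
                            features = order_to_features(ord))
    }) |> dplyr::bind_rows()
    write_gene_order_table(records, file.path(dir, paste0(name, "_orders.tsv")))
  }
  if (!is.null(sim$matrix)) {
    write_character_matrix(sim$matrix,
                           file.path(dir, paste0(name, "_characters.tsv")))
  }
  if (!is.null(sim$tree)) {
    ape::write.tree(sim$tree, file.path(dir, paste0(name, ".nwk")))
  }
  if (!is.null(sim$sequence)) {
    write_fasta(stats::setNames(sim$sequence, name),
                file.path(dir, paste0(name, ".fasta")))
  }
  man_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(sim$manifest, man_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(man_path)
}
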