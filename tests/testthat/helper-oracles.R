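# Independent oracles used to validate the package's implementations.
# Each is written from the definition, sharing no code with R/.

# --- exhaustive parsimony oracle ---------------------------------------
# Enumerates every assignment of states to internal nodes (and to "?"
# tips), scoring each labeling by summing substitution costs over all
# edges. Returns the minimum cost, the exact number of minimum-cost
# labelings, and the min/max number of gain edges of a derived state.
oracle_parsimony <- function(tree, tip_states, states,
                             root_state = NULL, derived = NULL,
                             pins = NULL) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  k <- length(states)
  obs <- tip_states[tree$tip.label]
  free_tips <- which(obs == "?")
  fixed_tips <- setdiff(seq_len(ntip), free_tips)
  free_nodes <- c(free_tips, ntip + seq_len(nnode))
  n_free <- length(free_nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_free)))
  n_lab <- nrow(grid)
  full <- matrix(0L, n_lab, ntip + nnode)
  full[, free_nodes] <- grid
  for (i in fixed_tips) full[, i] <- match(obs[i], states)
  if (!is.null(root_state)) {
    keep <- full[, ntip + 1L] == match(root_state, states)
    full <- full[keep, , drop = FALSE]
  }
  if (!is.null(pins)) {
    for (nd in names(pins)) {
      keep <- full[, as.integer(nd)] == match(pins[[nd]], states)
      full <- full[keep, , drop = FALSE]
    }
  }
  e <- tree$edge
  costs <- rep(0L, nrow(full))
  for (r in seq_len(nrow(e))) {
    costs <- costs + (full[, e[r, 1]] != full[, e[r, 2]])
  }
  mc <- min(costs)
  opt <- full[costs == mc, , drop = FALSE]
  out <- list(min_cost = mc, n_mpr = nrow(opt),
              one_labeling = states[opt[1, ]])
  if (!is.null(derived)) {
    d <- match(derived, states)
    gains <- rep(0L, nrow(opt))
    for (r in seq_len(nrow(e))) {
      gains <- gains + (opt[, e[r, 2]] == d & opt[, e[r, 1]] != d)
    }
    out$origins <- c(min(gains), max(gains))
    # branches (child nodes) on which the derived state is gained in
    # every minimum-cost labeling
    always <- vapply(seq_len(nrow(e)), function(r) {
      all(opt[, e[r, 2]] == d & opt[, e[r, 1]] != d)
    }, logical(1))
    out$always_gained_nodes <- e[always, 2]
  }
  out
}

# --- adjacency-set breakpoint oracle -----------------------------------
# Enumerates the oriented adjacency multiset of a circular signed order
# directly from its element list, reading each adjacency on both strands.
oracle_breakpoints <- function(order_a, order_b) {
  adj <- function(ord) {
    sgn <- ifelse(ord$orientation == "-", "-", "+")
    lab <- paste0(sgn, ord$name)
    n <- length(lab)
    pairs <- character(n)
    for (i in seq_len(n)) {
      a <- lab[i]
      b <- lab[if (i == n) 1L else i + 1L]
      flip <- function(x) {
        if (substr(x, 1, 1) == "+") sub("^\\+", "-", x) else sub("^-", "+", x)
      }
      one <- paste(a, b)
      two <- paste(flip(b), flip(a))
      pairs[i] <- if (one < two) one else two
    }
    pairs
  }
  length(setdiff(adj(order_a), adj(order_b)))
}

# --- independent vertebrate-mt codon table -----------------------------
# Hand-written from the standard code plus the four vertebrate-mt
# reassignments; never touches mt_genetic_code().
oracle_mt_translate <- function(codon) {
  standard <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  mito <- standard
  mito["ATA"] <- "M"
  mito["TGA"] <- "W"
  mito["AGA"] <- "*"
  mito["AGG"] <- "*"
  unname(mito[codon])
}

# --- brute-force hairpin oracle ----------------------------------------
# Checks every (start, stem, loop) combination by direct base pairing.
oracle_has_hairpin <- function(seq, min_stem, loop_range = c(3, 20),
                               allow_gu = TRUE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  pair <- function(a, b) {
    ok <- paste0(a, b) %in% c("AT", "TA", "GC", "CG")
    if (allow_gu) ok <- ok || paste0(a, b) %in% c("GT", "TG")
    ok
  }
  max_stem <- (L - loop_range[1]) %/% 2
  if (max_stem < min_stem) return(FALSE)
  for (k in min_stem:max_stem) {
    for (l in loop_range[1]:loop_range[2]) {
      span <- 2 * k + l
      if (span > L) next
      for (i in seq_len(L - span + 1)) {
        all_pair <- TRUE
        for (t in seq_len(k)) {
          if (!pair(chars[i + t - 1], chars[i + span - t])) {
            all_pair <- FALSE
            break
          }
        }
        if (all_pair) return(TRUE)
      }
    }
  }
  FALSE
}

# --- direct IUPAC Hamming distance -------------------------------------
oracle_hamming <- function(window, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  w <- strsplit(toupper(window), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  sum(vapply(seq_along(p), function(i) !(w[i] %in% iupac[[p[i]]]),
             logical(1)))
}

# --- small utilities ---------------------------------------------------
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_seq <- function(n, seed, letters = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
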