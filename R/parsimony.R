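#' @section Parsimony machinery:
#' Ancestral-state reconstruction uses Sankoff dynamic programming from
#' tips to root on a rooted `ape::phylo` tree (polytomies allowed, treated
#' as soft multifurcations). With the default uniform cost matrix (0 on
#' the diagonal, 1 off it) the minimum equals the Fitch parsimony count.
#' @name parsimony
#' @keywords internal
NULL

# --- internal core -----------------------------------------------------

# Resolve a node reference (tip label, internal node label, or "node_<id>")
# to a node number.
resolve_node <- function(tree, ref) {
  if (is.numeric(ref)) return(as.integer(ref))
  ntip <- ape::Ntip(tree)
  i <- match(ref, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(ref, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  if (grepl("^node_[0-9]+$", ref)) {
    return(as.integer(sub("node_", "", ref)))
  }
  stop("cannot resolve node reference '", ref, "' in tree")
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
  if (is.na(lab) || lab == "") paste0("node_", node) else lab
}

uniform_cost <- function(k) {
  m <- matrix(1, k, k)
  diag(m) <- 0
  m
}

# Sankoff tip-to-root tables. tip_states: named character vector
# (names = tip labels), "?" allowed. Returns list with S (node x state
# min-cost matrix), states, cost, root, postorder edges, min_cost and the
# set of optimal root states (after optional pinning/constraints).
sankoff_core <- function(tree, tip_states, states = NULL, cost = NULL,
                         root_state = NULL, node_constraints = NULL) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss) > 0) {
    stop("tree tip(s) without states: ", paste(miss, collapse = ", "))
  }
  obs <- tip_states[tree$tip.label]
  if (is.null(states)) {
    states <- sort(unique(obs[obs != "?"]))
  }
  bad <- setdiff(obs[obs != "?"], states)
  if (length(bad) > 0) {
    stop("tip state(s) outside the character's state set: ",
         paste(unique(bad), collapse = ", "))
  }
  k <- length(states)
  if (k < 1) stop("character has no observed states")
  if (is.null(cost)) cost <- uniform_cost(k)
  stopifnot(nrow(cost) == k, ncol(cost) == k)

  pins <- integer(0)
  if (!is.null(node_constraints) && length(node_constraints) > 0) {
    nodes <- vapply(names(node_constraints), resolve_node,
                    integer(1), tree = tree)
    st <- match(unlist(node_constraints), states)
    if (anyNA(st)) {
      stop("constraint state(s) outside the character's state set")
    }
    pins <- stats::setNames(st, nodes)
  }

  S <- matrix(0, ntip + nnode, k)
  for (i in seq_len(ntip)) {
    if (obs[i] != "?") {
      S[i, ] <- Inf
      S[i, match(obs[i], states)] <- 0
    }
  }
  mask <- function(node, row) {
    key <- as.character(node)
    if (key %in% names(pins)) {
      keep <- pins[[key]]
      out <- rep(Inf, k)
      out[keep] <- row[keep]
      return(out)
    }
    row
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    child_row <- mask(child, S[child, ])
    S[parent, ] <- S[parent, ] +
      apply(cost + matrix(child_row, k, k, byrow = TRUE), 1, min)
  }
  root <- ntip + 1L
  root_row <- mask(root, S[root, ])
  if (!is.null(root_state)) {
    ri <- match(root_state, states)
    if (is.na(ri)) stop("root_state '", root_state,
                        "' outside the character's state set")
    keep <- rep(Inf, k); keep[ri] <- root_row[ri]
    root_row <- keep
  }
  min_cost <- min(root_row)
  if (!is.finite(min_cost)) stop("constraints are unsatisfiable")
  list(S = S, states = states, cost = cost, root = root,
       edges_post = po$edge, min_cost = min_cost,
       root_choices = which(root_row == min_cost),
       mask = mask, k = k, ntip = ntip)
}

# Argmin child-state choices for an edge given the parent's state index.
edge_choices <- function(core, parent_state, child) {
  vals <- core$cost[parent_state, ] + core$mask(child, core$S[child, ])
  which(vals == min(vals))
}

# --- exported operations ----------------------------------------------

#' Minimum parsimony change count of characters on a rooted tree
#'
#' Sankoff dynamic programming over a rooted tree; with the default
#' uniform cost matrix this is the Fitch parsimony length. Tips coded
#' `"?"` are unconstrained (zero cost in every state).
#'
#' @param tree A rooted `ape::phylo`; tip labels must match the matrix
#'   taxa.
#' @param matrix Character-matrix tibble (`taxon` column plus one column
#'   per character), or a named character vector for a single character.
#' @param cost_matrix Optional square substitution-cost matrix (rows/cols
#'   in state order); default uniform 1 off-diagonal.
#' @param characters Optional character-definition tibble as from
#'   [arrangement_characters()], used for state sets; defaults to the
#'   observed states per character.
#' @param root_state Optional named vector pinning the root state per
#'   character (default free root).
#' @param prune If `TRUE`, tree tips without matrix rows are pruned and
#'   matrix taxa absent from the tree are dropped; if `FALSE` (default)
#'   any mismatch is an error.
#' @return Tibble with columns `character` and `min_changes`.
#' @export
sankoff_min_changes <- function(tree, matrix, cost_matrix = NULL,
                                characters = NULL, root_state = NULL,
                                prune = FALSE) {
  prep <- prep_matrix(tree, matrix, prune)
  purrr::map(prep$chars, function(ch) {
    core <- sankoff_core(prep$tree, prep$states[[ch]],
                         states = char_states(characters, ch),
                         cost = cost_matrix,
                         root_state = root_state[[ch]] %||% NULL)
    tibble::tibble(character = ch, min_changes = core$min_cost)
  }) |> dplyr::bind_rows()
}

prep_matrix <- function(tree, matrix, prune = FALSE) {
  if (!is.data.frame(matrix)) {
    matrix <- tibble::tibble(taxon = names(matrix), char = unname(matrix))
  }
  extra <- setdiff(matrix$taxon, tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, matrix$taxon)
  if (!prune && (length(extra) > 0 || length(missing_tips) > 0)) {
    stop("tree tips and matrix taxa differ (set prune = TRUE to prune): ",
         paste(c(extra, missing_tips), collapse = ", "))
  }
  if (prune) {
    if (length(missing_tips) > 0) tree <- ape::drop.tip(tree, missing_tips)
    matrix <- matrix[matrix$taxon %in% tree$tip.label, , drop = FALSE]
  }
  chars <- setdiff(names(matrix), "taxon")
  states <- lapply(chars, function(ch) {
    stats::setNames(as.character(matrix[[ch]]), matrix$taxon)
  })
  names(states) <- chars
  list(tree = tree, chars = chars, states = states)
}

char_states <- function(characters, ch) {
  if (is.null(characters)) return(NULL)
  i <- match(ch, characters$id)
  if (is.na(i)) return(NULL)
  characters$states[[i]]
}

char_ancestral <- function(characters, ch) {
  if (is.null(characters)) return(NULL)
  i <- match(ch, characters$id)
  if (is.na(i)) return(NULL)
  characters$ancestral_state[[i]]
}

#' Map most-parsimonious rearrangement events onto branches
#'
#' Backtracks the Sankoff tables to assign state changes to branches. The
#' default resolution is DELTRAN (ties push changes tipward); `"ACCTRAN"`
#' prefers changes on the rootward edge; `"all"` enumerates every
#' most-parsimonious reconstruction (up to `max_mpr`; beyond that, random
#' resolutions are sampled under `seed` when `sample_mpr = TRUE`, and the
#' result is flagged approximate) and reports the union of events with a
#' flag for events not shared by all reconstructions.
#'
#' For characters whose definitions are given (default: the arrangement
#' characters `C1`..`C5`), the root is conditioned on the character's
#' ancestral state — the typical vertebrate arrangement is the outgroup
#' condition; pass `root = "free"` for a cost-minimal root.
#'
#' @inheritParams sankoff_min_changes
#' @param resolution `"DELTRAN"`, `"ACCTRAN"` or `"all"`.
#' @param characters Character definitions; default
#'   [arrangement_characters()].
#' @param root `"ancestral"` (default) or `"free"`.
#' @param max_mpr Enumeration bound for `resolution = "all"`.
#' @param sample_mpr Sample reconstructions when the bound is exceeded?
#' @param seed Seed for sampling (default 0).
#' @return An object of class `event_map`: list with `events` (tibble:
#'   `character`, `branch` (label of the child node of the edge), `node`,
#'   `from`, `to`, `ambiguous`, `in_all_mprs`), `summary` (tibble:
#'   `character`, `min_changes`, `n_events`, `n_mpr`, `approximate`) and
#'   the tree. `tidy()` returns the events, `glance()` the summary.
#' @export
map_events <- function(tree, matrix,
                       resolution = c("DELTRAN", "ACCTRAN", "all"),
                       characters = arrangement_characters(),
                       cost_matrix = NULL, root = c("ancestral", "free"),
                       prune = FALSE, max_mpr = 10000, sample_mpr = FALSE,
                       seed = 0) {
  resolution <- match.arg(resolution)
  root <- match.arg(root)
  prep <- prep_matrix(tree, matrix, prune)
  events <- list()
  summaries <- list()
  for (ch in prep$chars) {
    anc <- if (root == "ancestral") char_ancestral(characters, ch) else NULL
    core <- sankoff_core(prep$tree, prep$states[[ch]],
                         states = char_states(characters, ch),
                         cost = cost_matrix, root_state = anc)
    n_mpr <- count_mprs(core)
    approx <- FALSE
    if (resolution == "all") {
      if (n_mpr > max_mpr && !sample_mpr) {
        stop("character ", ch, " has ", n_mpr, " reconstructions ",
             "(bound ", max_mpr, "); raise max_mpr or set sample_mpr = TRUE")
      }
      approx <- n_mpr > max_mpr
      assigns <- if (approx) {
        sample_assignments(core, max_mpr, seed)
      } else {
        enumerate_assignments(core)
      }
      ev_list <- lapply(assigns, function(a) assignment_events(core, a))
      all_ev <- dplyr::bind_rows(ev_list)
      if (nrow(all_ev) > 0) {
        key <- paste(all_ev$node, all_ev$from, all_ev$to)
        tab <- table(key)
        uniq <- all_ev[!duplicated(key), , drop = FALSE]
        uniq$in_all_mprs <- as.vector(tab[paste(uniq$node, uniq$from,
                                                uniq$to)]) == length(assigns)
        uniq$ambiguous <- !uniq$in_all_mprs
        ev <- uniq
      } else {
        ev <- empty_events()
      }
    } else {
      a <- backtrack_one(core, resolution)
      ev <- assignment_events(core, a$assign)
      if (nrow(ev) > 0) {
        ev$ambiguous <- a$ambiguous[as.character(ev$node)]
        ev$in_all_mprs <- NA
      } else {
        ev <- empty_events()
      }
    }
    if (nrow(ev) > 0) {
      ev$character <- ch
      ev$branch <- vapply(ev$node, node_label, character(1),
                          tree = prep$tree)
      events[[ch]] <- ev[, c("character", "branch", "node", "from", "to",
                             "ambiguous", "in_all_mprs")]
    }
    summaries[[ch]] <- tibble::tibble(
      character = ch, min_changes = core$min_cost,
      n_events = if (resolution == "all") core$min_cost else nrow(ev),
      n_mpr = n_mpr, approximate = approx
    )
  }
  structure(
    list(events = if (length(events) > 0) dplyr::bind_rows(events) else
      empty_events(),
         summary = dplyr::bind_rows(summaries),
         tree = prep$tree, resolution = resolution),
    class = "event_map"
  )
}

empty_events <- function() {
  tibble::tibble(character = character(), branch = character(),
                 node = integer(), from = character(), to = character(),
                 ambiguous = logical(), in_all_mprs = logical())
}

# Single-resolution backtrack. DELTRAN keeps the parent state on ties
# (delays changes tipward); ACCTRAN prefers a change when one is among
# the optimal choices (edge-local acceleration).
backtrack_one <- function(core, resolution) {
  edges_pre <- core$edges_post[rev(seq_len(nrow(core$edges_post))), ,
                               drop = FALSE]
  n_nodes <- nrow(core$S)
  assign <- rep(NA_integer_, n_nodes)
  ambiguous <- logical(n_nodes)
  rc <- core$root_choices
  assign[core$root] <- rc[1]
  ambiguous[core$root] <- length(rc) > 1
  for (e in seq_len(nrow(edges_pre))) {
    p <- edges_pre[e, 1]; ch <- edges_pre[e, 2]
    choices <- edge_choices(core, assign[p], ch)
    pick <- if (resolution == "DELTRAN") {
      if (assign[p] %in% choices) assign[p] else choices[1]
    } else {
      alt <- setdiff(choices, assign[p])
      if (length(alt) > 0) alt[1] else assign[p]
    }
    assign[ch] <- pick
    ambiguous[ch] <- length(choices) > 1
  }
  list(assign = assign,
       ambiguous = stats::setNames(ambiguous, seq_len(n_nodes)))
}

# Events (state changes on edges) implied by a full node-state assignment.
assignment_events <- function(core, assign) {
  e <- core$edges_post
  chg <- assign[e[, 1]] != assign[e[, 2]]
  tibble::tibble(
    node = e[chg, 2],
    from = core$states[assign[e[chg, 1]]],
    to = core$states[assign[e[chg, 2]]]
  )
}

# Exact number of most-parsimonious reconstructions, by DP:
# N(v, s) = prod over children c of sum over optimal child states s' of
# N(c, s').
count_mprs <- function(core) {
  n_nodes <- nrow(core$S)
  N <- matrix(1, n_nodes, core$k)
  po <- core$edges_post
  # child-counts must be complete before the parent is used; postorder
  # guarantees this, but each parent accumulates multiplicatively per edge
  acc <- matrix(1, n_nodes, core$k)
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    child_row <- core$mask(ch, core$S[ch, ])
    for (s in seq_len(core$k)) {
      vals <- core$cost[s, ] + child_row
      opt <- which(vals == min(vals))
      acc[p, s] <- acc[p, s] * sum(acc[ch, opt])
    }
  }
  sum(acc[core$root, core$root_choices])
}

# Enumerate all optimal assignments (small cases; callers bound this).
enumerate_assignments <- function(core) {
  edges_pre <- core$edges_post[rev(seq_len(nrow(core$edges_post))), ,
                               drop = FALSE]
  n_nodes <- nrow(core$S)
  partial <- lapply(core$root_choices, function(s) {
    v <- rep(NA_integer_, n_nodes); v[core$root] <- s; v
  })
  for (e in seq_len(nrow(edges_pre))) {
    p <- edges_pre[e, 1]; ch <- edges_pre[e, 2]
    nxt <- list()
    for (a in partial) {
      for (s in edge_choices(core, a[p], ch)) {
        b <- a; b[ch] <- s
        nxt[[length(nxt) + 1L]] <- b
      }
    }
    partial <- nxt
  }
  partial
}

sample_assignments <- function(core, n, seed) {
  edges_pre <- core$edges_post[rev(seq_len(nrow(core$edges_post))), ,
                               drop = FALSE]
  n_nodes <- nrow(core$S)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  withr_seed({
    lapply(seq_len(n), function(i) {
      a <- rep(NA_integer_, n_nodes)
      a[core$root] <- sample_one(core$root_choices)
      for (e in seq_len(nrow(edges_pre))) {
        p <- edges_pre[e, 1]; ch <- edges_pre[e, 2]
        a[ch] <- sample_one(edge_choices(core, a[p], ch))
      }
      a
    })
  })
}

sample_one <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

#' Range of independent origins of a derived state over all MPRs
#'
#' Counts, by dynamic programming restricted to optimal reconstructions,
#' the minimum and maximum number of branches on which `derived_state` is
#' gained (edge whose parent is in another state and whose child is in
#' `derived_state`) across all most-parsimonious reconstructions.
#'
#' @inheritParams sankoff_min_changes
#' @param tip_states Named character vector of tip states (or a
#'   single-character matrix tibble).
#' @param derived_state The state whose origins are counted; must belong
#'   to the character's state set.
#' @param states Optional state set (default: observed states).
#' @param root_state Optional root pin (e.g. the ancestral state).
#' @return Tibble with columns `min_origins`, `max_origins`,
#'   `min_changes`.
#' @export
count_state_origins <- function(tree, tip_states, derived_state,
                                states = NULL, cost_matrix = NULL,
                                root_state = NULL, prune = FALSE) {
  prep <- prep_matrix(tree, tip_states, prune)
  if (length(prep$chars) != 1) {
    stop("count_state_origins expects a single character")
  }
  tips <- prep$states[[1]]
  core <- sankoff_core(prep$tree, tips, states = states,
                       cost = cost_matrix, root_state = root_state)
  d <- match(derived_state, core$states)
  if (is.na(d)) {
    stop("derived_state '", derived_state,
         "' is not in the character's state set")
  }
  n_nodes <- nrow(core$S)
  gmin <- matrix(0, n_nodes, core$k)
  gmax <- matrix(0, n_nodes, core$k)
  po <- core$edges_post
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    child_row <- core$mask(ch, core$S[ch, ])
    for (s in seq_len(core$k)) {
      vals <- core$cost[s, ] + child_row
      opt <- which(vals == min(vals))
      gain <- as.integer(opt == d & s != d)
      gmin[p, s] <- gmin[p, s] + min(gain + gmin[ch, opt])
      gmax[p, s] <- gmax[p, s] + max(gain + gmax[ch, opt])
    }
  }
  tibble::tibble(
    min_origins = min(gmin[core$root, core$root_choices]),
    max_origins = max(gmax[core$root, core$root_choices]),
    min_changes = core$min_cost
  )
}

#' Minimum change count subject to pinned internal-node states
#'
#' Computes the Sankoff minimum with named internal nodes constrained to
#' given states — e.g. to quantify how many extra changes a single-origin
#' hypothesis would require compared with the unconstrained optimum.
#'
#' @inheritParams count_state_origins
#' @param node_constraints Named list/vector: node label (tip label,
#'   internal node label, or `"node_<id>"`) -> pinned state.
#' @return Minimum cost (numeric scalar).
#' @export
constrained_cost <- function(tree, tip_states, node_constraints = NULL,
                             states = NULL, cost_matrix = NULL,
                             root_state = NULL, prune = FALSE) {
  prep <- prep_matrix(tree, tip_states, prune)
  if (length(prep$chars) != 1) {
    stop("constrained_cost expects a single character")
  }
  core <- sankoff_core(prep$tree, prep$states[[1]], states = states,
                       cost = cost_matrix, root_state = root_state,
                       node_constraints = node_constraints)
  core$min_cost
}

# --- event_map methods -------------------------------------------------

#' @export
print.event_map <- function(x, ...) {
  cat("Parsimony event map (", x$resolution, " resolution)\n", sep = "")
  print(x$summary)
  if (nrow(x$events) > 0) {
    cat("\nEvents:\n")
    print(x$events)
  } else {
    cat("\nNo events (all characters constant).\n")
  }
  invisible(x)
}

#' @describeIn map_events Tidy the per-branch events of an event map.
#' @param x An `event_map`.
#' @param ... Unused.
#' @method tidy event_map
#' @export
tidy.event_map <- function(x, ...) x$events

#' @describeIn map_events One row per character: minimum changes, event
#'   count and number of most-parsimonious reconstructions.
#' @method glance event_map
#' @export
glance.event_map <- function(x, ...) x$summary

#' Serialize an event map
#'
#' Writes the per-branch events as TSV, the whole map as JSON, or the
#' tree in Newick form with `events:`-prefixed annotations appended to
#' the labels of nodes subtending event branches.
#'
#' @param x An `event_map`.
#' @param path Output path.
#' @param format `"tsv"`, `"json"` or `"newick"`.
#' @return `path`, invisibly.
#' @export
write_event_map <- function(x, path, format = c("tsv", "json", "newick")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x$events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(resolution = x$resolution, summary = x$summary,
           events = x$events),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    tree <- x$tree
    ntip <- ape::Ntip(tree)
    if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
    for (i in seq_len(nrow(x$events))) {
      ev <- x$events[i, ]
      tag <- paste0("|", ev$character, "_", ev$from, ".", ev$to)
      if (ev$node <= ntip) {
        tree$tip.label[ev$node] <- paste0(tree$tip.label[ev$node], tag)
      } else {
        j <- ev$node - ntip
        tree$node.label[j] <- paste0(tree$node.label[j], tag)
      }
    }
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}
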