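two_tip <- ape::read.tree(text = "(a,b);")

test_that("degenerate characters give the forced parsimony counts", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  const <- stats::setNames(rep("s", 4), c("a", "b", "c", "d"))
  expect_equal(sankoff_min_changes(tr, const)$min_changes, 0)
  expect_equal(sankoff_min_changes(two_tip,
                                   c(a = "x", b = "y"))$min_changes, 1)
  # weighted substitution cost scales the forced change
  cost <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(sankoff_min_changes(two_tip, c(a = "x", b = "y"),
                                   cost_matrix = cost)$min_changes, 5)
  # missing data is unconstrained
  expect_equal(sankoff_min_changes(tr, stats::setNames(
    c("x", "?", "?", "x"), c("a", "b", "c", "d")))$min_changes, 0)
})

test_that("Sankoff DP equals exhaustive enumeration and Fitch on random trees", {
  for (i in 1:120) {
    set.seed(i)
    n <- sample(4:8, 1)
    k <- sample(2:4, 1)
    tr <- random_tree(n, seed = i)
    states <- letters[seq_len(k)]
    tips <- stats::setNames(sample(states, n, replace = TRUE), tr$tip.label)
    dp <- sankoff_min_changes(tr, tips)$min_changes
    oracle <- oracle_parsimony(tr, tips, states)
    expect_equal(dp, oracle$min_cost)
    dat <- phangorn::phyDat(matrix(tips[tr$tip.label], ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = states)
    expect_equal(dp, as.numeric(phangorn::fitch(tr, dat)))
  }
})

test_that("the number of most-parsimonious reconstructions matches enumeration", {
  for (i in 1:40) {
    set.seed(1000 + i)
    n <- sample(4:7, 1)
    k <- sample(2:3, 1)
    tr <- random_tree(n, seed = 1000 + i)
    states <- letters[seq_len(k)]
    tips <- stats::setNames(sample(states, n, replace = TRUE), tr$tip.label)
    em <- map_events(tr, tibble::tibble(taxon = names(tips), X = unname(tips)),
                     resolution = "all", root = "free")
    oracle <- oracle_parsimony(tr, tips, states)
    expect_equal(em$summary$n_mpr, oracle$n_mpr)
  }
})

test_that("every resolution's event count equals the DP minimum", {
  for (i in 1:40) {
    set.seed(2000 + i)
    n <- sample(5:9, 1)
    tr <- random_tree(n, seed = 2000 + i)
    tips <- stats::setNames(sample(c("a", "b", "c"), n, replace = TRUE),
                            tr$tip.label)
    m <- tibble::tibble(taxon = names(tips), X = unname(tips))
    mc <- sankoff_min_changes(tr, m)$min_changes
    for (res in c("DELTRAN", "ACCTRAN")) {
      em <- map_events(tr, m, resolution = res, root = "free")
      expect_equal(nrow(em$events), mc)
      expect_equal(em$summary$min_changes, mc)
    }
  }
})

test_that("event mapping on constant characters is empty", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  m <- tibble::tibble(taxon = c("a", "b", "c", "d"), X = "s")
  em <- map_events(tr, m, root = "free")
  expect_equal(nrow(em$events), 0)
  expect_equal(em$summary$min_changes, 0)
  expect_s3_class(tidy(em), "tbl_df")
  expect_equal(glance(em)$n_mpr, 1)
})

test_that("state-origin ranges match the exhaustive oracle", {
  # forced cases first
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(unlist(count_state_origins(
    tr, stats::setNames(rep("d", 4), c("a", "b", "c", "d")), "d")[1:2],
    use.names = FALSE), c(0, 0))
  expect_equal(unlist(count_state_origins(
    tr, stats::setNames(c("d", "a", "a", "a"), c("a", "b", "c", "d")),
    "d")[1:2], use.names = FALSE), c(1, 1))
  # random comparisons
  for (i in 1:40) {
    set.seed(3000 + i)
    n <- sample(4:7, 1)
    tr <- random_tree(n, seed = 3000 + i)
    states <- c("anc", "der")
    tips <- stats::setNames(sample(states, n, replace = TRUE), tr$tip.label)
    got <- count_state_origins(tr, tips, "der", states = states)
    oracle <- oracle_parsimony(tr, tips, states, derived = "der")
    expect_equal(c(got$min_origins, got$max_origins), oracle$origins)
  }
  quartet <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(count_state_origins(quartet, stats::setNames(
    rep("a", 4), c("a", "b", "c", "d")), "zz", states = c("a", "b")),
    "state set")
})

test_that("constrained costs agree with the oracle and the unconstrained DP", {
  for (i in 1:25) {
    set.seed(4000 + i)
    n <- sample(4:6, 1)
    tr <- random_tree(n, seed = 4000 + i)
    states <- c("a", "b")
    tips <- stats::setNames(sample(states, n, replace = TRUE), tr$tip.label)
    free <- constrained_cost(tr, tips, states = states)
    expect_equal(free, sankoff_min_changes(tr, tips)$min_changes)
    # pin an internal node to each state and compare with enumeration
    node <- ape::Ntip(tr) + sample(tr$Nnode, 1)
    for (s in states) {
      pin <- stats::setNames(list(s), paste0("node_", node))
      got <- constrained_cost(tr, tips, node_constraints = pin,
                              states = states)
      oracle <- oracle_parsimony(tr, tips, states,
                                 pins = stats::setNames(list(s), node))
      expect_equal(got, oracle$min_cost)
      expect_gte(got, free)
    }
  }
  expect_error(constrained_cost(two_tip, c(a = "x", b = "y"),
                                node_constraints = list(Nowhere = "x")),
               "cannot resolve")
})

test_that("a constraint equal to an MPR labeling leaves the cost unchanged", {
  for (i in 1:10) {
    tr <- random_tree(7, seed = 40 + i)
    set.seed(40 + i)
    tips <- stats::setNames(sample(c("a", "b"), 7, replace = TRUE),
                            tr$tip.label)
    oracle <- oracle_parsimony(tr, tips, c("a", "b"))
    internal <- ape::Ntip(tr) + seq_len(tr$Nnode)
    pins <- stats::setNames(as.list(oracle$one_labeling[internal]),
                            paste0("node_", internal))
    got <- constrained_cost(tr, tips, node_constraints = pins)
    expect_equal(got, oracle$min_cost)
  }
})

test_that("tip/taxon mismatches error unless pruning is requested", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  m <- tibble::tibble(taxon = c("a", "b", "c"), X = c("x", "x", "y"))
  expect_error(sankoff_min_changes(tr, m), "prune")
  pruned <- sankoff_min_changes(tr, m, prune = TRUE)
  expect_equal(pruned$min_changes, 1)
})

test_that("polytomies are handled as soft multifurcations", {
  tr <- ape::read.tree(text = "((a,b,c),(d,e));")
  tips <- c(a = "x", b = "x", c = "y", d = "y", e = "y")
  dp <- sankoff_min_changes(tr, tips)$min_changes
  oracle <- oracle_parsimony(tr, tips, c("x", "y"))
  expect_equal(dp, oracle$min_cost)
})

test_that("event maps serialize to TSV, JSON and annotated Newick", {
  fx <- study_fixture()
  em <- map_events(fx$tree, fx$characters)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_event_map(em, tsv, "tsv")
  write_event_map(em, json, "json")
  write_event_map(em, nwk, "newick")
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(em$events))
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(nrow(js$events), nrow(em$events))
  annotated <- ape::read.tree(nwk)
  expect_true(any(grepl("C1_IQM.QIM", annotated$node.label, fixed = TRUE)))
})
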