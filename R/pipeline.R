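#' Run the full comparative-mitogenomics report
#'
#' Orchestrates the analysis end to end: linearizes every record at
#' tRNA-Phe, encodes the arrangement characters, maps rearrangement
#' events onto the supplied rooted tree by parsimony, annotates
#' control-region sequences when supplied, and summarises control-region
#' lengths per family. The report carries a provenance block (seed,
#' configuration hash, package version); regenerating from the same
#' inputs yields an identical report body.
#'
#' @param records Mitogenome-record tibble (e.g. from
#'   [read_gene_order_table()] or [study_fixture()]).
#' @param tree Rooted `ape::phylo` whose tips match the record taxa.
#' @param cr_sequences Optional named character vector of control-region
#'   sequences (names are taxa).
#' @param ol_status,anticodon Per-taxon observations passed to
#'   [encode_character_matrix()].
#' @param resolution Event-mapping resolution, see [map_events()].
#' @param cr_cfg Control-region annotation configuration.
#' @param seed Seed recorded in the provenance block (and used for any
#'   sampled reconstruction).
#' @return Object of class `mito_report`: list with `characters`,
#'   `events` (an `event_map`), `cr_annotations` (named list or `NULL`),
#'   `family_summary`, `provenance`.
#' @examples
#' fx <- study_fixture()
#' rep <- run_report(fx$records, fx$tree,
#'                   anticodon = setNames(fx$characters$C5,
#'                                        fx$characters$taxon))
#' rep$family_summary
#' @export
run_report <- function(records, tree, cr_sequences = NULL,
                       ol_status = "auto", anticodon = "TGG",
                       resolution = "DELTRAN", cr_cfg = cr_config(),
                       seed = 0) {
  if (is.null(records) || nrow(records) == 0) {
    stop("report stage 'inputs': no mitogenome records supplied")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("report stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  orders <- stage("linearize", {
    out <- lapply(seq_len(nrow(records)), function(i) {
      linearize(records[i, ], anchor = "F")
    })
    names(out) <- records$taxon
    out
  })
  characters <- stage("encode", {
    encode_character_matrix(orders, ol_status = ol_status,
                            anticodon = anticodon)
  })
  events <- stage("map-events", {
    map_events(tree, characters, resolution = resolution, seed = seed)
  })
  cr_annotations <- NULL
  if (!is.null(cr_sequences)) {
    cr_annotations <- stage("annotate-cr", {
      lapply(cr_sequences, cr_profile, config = cr_cfg)
    })
  }
  family_summary <- if (all(is.na(records$cr_length))) {
    tibble::tibble(family = character(), mean_cr_length = integer(),
                   n = integer())
  } else {
    stage("summarise", mean_cr_length(records))
  }
  structure(
    list(
      characters = characters,
      events = events,
      cr_annotations = cr_annotations,
      family_summary = family_summary,
      provenance = list(
        seed = seed,
        n_taxa = nrow(records),
        resolution = resolution,
        config_hash = config_hash(list(resolution = resolution,
                                       cr = cr_cfg)),
        package_version = as.character(utils::packageVersion("mitorder"))
      )
    ),
    class = "mito_report"
  )
}

config_hash <- function(x) {
  # small stable digest (sum of char codes of the serialized config);
  # enough to detect a changed configuration in a report header
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' @export
print.mito_report <- function(x, ...) {
  cat("Comparative mitogenome report (", x$provenance$n_taxa, " taxa, seed ",
      x$provenance$seed, ", config ", x$provenance$config_hash, ")\n\n",
      sep = "")
  cat("Mean control-region length by family:\n")
  for (i in seq_len(nrow(x$family_summary))) {
    cat(sprintf("  %-16s %5d bp over %2d taxa\n",
                x$family_summary$family[i],
                x$family_summary$mean_cr_length[i],
                x$family_summary$n[i]))
  }
  cat("\nRearrangement events (", x$events$resolution, "):\n", sep = "")
  print(x$events$summary)
  if (!is.null(x$cr_annotations)) {
    cat("\nControl regions annotated: ", length(x$cr_annotations), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write a report to JSON
#'
#' @param x A `mito_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  obj <- list(
    provenance = x$provenance,
    family_summary = x$family_summary,
    characters = x$characters,
    events = list(summary = x$events$summary, events = x$events$events),
    cr_annotations = lapply(x$cr_annotations, function(a) {
      list(length = a$length, domains = a$domains, motifs = a$motifs,
           repeats = a$repeats, low_confidence = a$low_confidence)
    })
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Number of trees retained from an MCMC run
#'
#' Bookkeeping for Bayesian tree sampling: with trees sampled every
#' `sample_interval` generations and the initial `burnin_fraction` of the
#' sample discarded as burn-in, the retained count is
#' `floor(total_generations / sample_interval) * (1 - burnin_fraction)`.
#' (The burn-in fraction is applied to the sample, so a run of 2,500,000
#' generations sampled every 100 with a quarter discarded keeps 18,750
#' trees.)
#'
#' @param total_generations Total MCMC generations (non-negative).
#' @param sample_interval Sampling interval in generations (must divide
#'   `total_generations`).
#' @param burnin_fraction Fraction of samples discarded, in `[0, 1)`.
#' @return Integer count of retained trees.
#' @examples
#' mcmc_tree_count(2500000, 100, 0.25)
#' @export
mcmc_tree_count <- function(total_generations, sample_interval,
                            burnin_fraction) {
  if (sample_interval <= 0) stop("sample_interval must be positive")
  if (total_generations < 0) stop("total_generations must be non-negative")
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  if (total_generations %% sample_interval != 0) {
    stop("sample_interval must divide total_generations")
  }
  n_samples <- total_generations %/% sample_interval
  as.integer(n_samples * (1 - burnin_fraction))
}
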