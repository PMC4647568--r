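#' Species summary stage
#'
#' Applies [summarize_species()] per species, excluding hybrid tokens, and
#' returns the summary table (the analogue of the published
#' central-population table when `zone_filter = "central"`).
#'
#' @param records a `"vertebral_records"` table.
#' @param zone_filter optional `"central"` or `"fringe"`.
#' @return data.frame from [summary_table()].
#' @export
run_summaries <- function(records, zone_filter = NULL) {
  summary_table(records, zone_filter = zone_filter, include_hybrids = FALSE)
}

#' Interspecific rank-correlation stage
#'
#' Computes the four species-level Spearman correlations of the analysis on
#' a summary table: T_n against T_var, T_n against T_range, S_tr against
#' T_var and S_tr against T_range.
#'
#' @param summaries data.frame from [run_summaries()].
#' @param permutations optional permutation count for permutation p-values.
#' @param seed seed for the permutation draw.
#' @return named list of `"spearman_result"` objects
#'   (`Tn_Tvar`, `Tn_Trange`, `Str_Tvar`, `Str_Trange`).
#' @export
run_correlations <- function(summaries, permutations = NULL, seed = NULL) {
  list(
    Tn_Tvar = spearman_cor(summaries$T_n, summaries$T_var, permutations, seed),
    Tn_Trange = spearman_cor(summaries$T_n, summaries$T_range, permutations, seed),
    Str_Tvar = spearman_cor(summaries$S_tr, summaries$T_var, permutations, seed),
    Str_Trange = spearman_cor(summaries$S_tr, summaries$T_range, permutations, seed)
  )
}

## modal/non-modal x central/fringe table for one species; modal count taken
## from the central populations. Rows = zones, columns = (modal, nonmodal).
modal_zone_table <- function(records, species) {
  central <- summarize_species(records, species, zone_filter = "central")
  score <- thoracic_score(records)
  m <- matrix(0L, 2, 2, dimnames = list(ZONE_LEVELS, c("modal", "nonmodal")))
  for (z in ZONE_LEVELS) {
    sel <- records$species == species & records$zone == z
    m[z, "modal"] <- sum(sel & score == central$T_n)
    m[z, "nonmodal"] <- sum(sel & score != central$T_n)
  }
  m
}

#' Group-comparison stage
#'
#' Builds, for every non-hybrid species sampled in both zones, the 2 x 2
#' table of modal/non-modal vertebral formula against central/fringe zone
#' (a specimen is modal when its half-integral score equals the species'
#' central-population modal count) and applies the [g_test()]; species
#' present in a single zone are skipped with a warning. A pooled 2 x 2 test
#' over all such species is reported alongside, labelled as pooled. When F1
#' hybrid records are present, the transitional-sacrum frequencies of the
#' hybrid and its two parental species are compared in a 3 x 2 G-test.
#'
#' @param records a `"vertebral_records"` table.
#' @param williams apply the Williams correction to all G-tests.
#' @return list with `per_species` (named list of `"g_test_result"`),
#'   `per_species_tables`, `pooled`, and `hybrid_vs_parents` (NULL when no
#'   hybrids are present).
#' @export
run_group_tests <- function(records, williams = FALSE) {
  species <- unique(records$species)
  plain <- species[!is_hybrid(species)]
  tables <- list()
  tests <- list()
  for (sp in plain) {
    zones <- unique(records$zone[records$species == sp])
    if (length(zones) < 2) {
      warning("species '", sp, "' sampled in a single zone; skipped")
      next
    }
    tab <- modal_zone_table(records, sp)
    tables[[sp]] <- tab
    tests[[sp]] <- g_test(tab, williams = williams)
  }
  pooled <- NULL
  if (length(tables) > 0) {
    pooled <- g_test(Reduce(`+`, tables), williams = williams)
  }

  hybrid_test <- NULL
  hybrids <- species[is_hybrid(species)]
  if (length(hybrids) > 0) {
    hy <- hybrids[1]
    parents <- strsplit(hy, "_x_", fixed = TRUE)[[1]]
    groups <- c(hy, parents)
    if (all(parents %in% plain)) {
      tr <- records$sacral_state %in% TRANSITIONAL_STATES
      tab <- t(vapply(groups, function(g) {
        sel <- records$species == g
        c(transitional = sum(sel & tr), regular = sum(sel & !tr))
      }, numeric(2)))
      hybrid_test <- list(table = tab, test = g_test(tab, williams = williams))
    } else {
      warning("parental species of '", hy, "' not both present; ",
              "hybrid comparison skipped")
    }
  }
  list(per_species = tests, per_species_tables = tables, pooled = pooled,
       hybrid_vs_parents = hybrid_test)
}

#' Phylogenetic comparative stage
#'
#' For each of the four species-level statistics (T_n, T_var, T_range,
#' S_tr) runs the tip-permutation signal test, then computes independent
#' contrasts and the four through-origin contrast regressions of the
#' analysis: T_var and T_range each on T_n and on S_tr.
#'
#' @param summaries data.frame from [run_summaries()]; `species` must match
#'   the tree tips.
#' @param tree a rooted binary `"phylo"` tree covering the summarised
#'   species.
#' @param iterations permutations for the signal test (default 10000).
#' @param seed integer root seed; each trait's test gets a derived seed,
#'   all recorded in the results.
#' @param weighted use branch-length-weighted squared change.
#' @return list with `signal` (named list of `"permutation_result"`),
#'   `contrasts` (named list of `"contrast_set"`), `regressions` (named list
#'   from [contrast_regression()]).
#' @export
run_phylo <- function(summaries, tree, iterations = 10000, seed = 1,
                      weighted = FALSE) {
  traits <- c("T_n", "T_var", "T_range", "S_tr")
  vecs <- lapply(traits, function(tr) {
    stats::setNames(summaries[[tr]], summaries$species)
  })
  names(vecs) <- traits
  set.seed(seed)
  sub_seeds <- stats::setNames(sample.int(.Machine$integer.max - 1L,
                                          length(traits)), traits)
  signal <- lapply(traits, function(tr) {
    signal_permutation_test(tree, vecs[[tr]], iterations = iterations,
                            seed = sub_seeds[[tr]], weighted = weighted)
  })
  names(signal) <- traits
  contrasts <- lapply(vecs, function(v) pic_contrasts(tree, v))
  regressions <- list(
    Tvar_on_Tn = contrast_regression(contrasts$T_n, contrasts$T_var),
    Trange_on_Tn = contrast_regression(contrasts$T_n, contrasts$T_range),
    Tvar_on_Str = contrast_regression(contrasts$S_tr, contrasts$T_var),
    Trange_on_Str = contrast_regression(contrasts$S_tr, contrasts$T_range)
  )
  list(signal = signal, contrasts = contrasts, regressions = regressions)
}

## md5 digest of an arbitrary R object, via a canonical serialisation
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Full analysis report
#'
#' Runs every stage of the analysis on a record table and a species tree:
#' species summaries and transformation tallies, the four interspecific
#' Spearman correlations, the central/fringe and hybrid G-tests, and the
#' phylogenetic signal tests and contrast regressions. Hybrid records are
#' excluded from species-level summaries (the group-test stage uses them
#' for the hybrid-versus-parents comparison). Re-running with the same
#' inputs and seed reproduces the report bit-for-bit; the metadata element
#' records the seed, iteration count, package version and content digests
#' of the inputs.
#'
#' @param records a `"vertebral_records"` table.
#' @param tree optional `"phylo"` tree; when NULL the phylogenetic stage is
#'   skipped.
#' @param zone_filter zone restriction for the summary/correlation stages
#'   (default `"central"`, matching the published species table).
#' @param iterations signal-test permutations (default 10000).
#' @param seed integer root seed.
#' @param williams Williams correction flag for the G-tests.
#' @return an object of class `"vertebral_report"`: list with `summaries`,
#'   `tallies`, `correlations`, `group_tests`, `phylo`, `metadata`.
#' @export
vertebral_report <- function(records, tree = NULL, zone_filter = "central",
                             iterations = 10000, seed = 1, williams = FALSE) {
  records <- validate_records(as.data.frame(records))
  summaries <- run_summaries(records, zone_filter = zone_filter)
  tallies <- tally_table(records, include_hybrids = FALSE)
  correlations <- run_correlations(summaries)
  group_tests <- tryCatch(
    suppressWarnings(run_group_tests(records, williams = williams)),
    error = function(e) NULL)
  phylo <- NULL
  if (!is.null(tree)) {
    keep <- summaries$species %in% tree$tip.label
    if (any(!keep)) {
      warning("species not on the tree dropped from the phylogenetic stage: ",
              paste(summaries$species[!keep], collapse = ", "))
    }
    phylo <- run_phylo(summaries[keep, ], tree, iterations = iterations,
                       seed = seed)
  }
  structure(
    list(summaries = summaries, tallies = tallies,
         correlations = correlations, group_tests = group_tests,
         phylo = phylo,
         metadata = list(
           seed = seed, iterations = iterations,
           zone_filter = zone_filter, williams = williams,
           n_records = nrow(records),
           package_version = as.character(utils::packageVersion("vertvar")),
           records_digest = object_digest(as.data.frame(records)),
           tree_digest = if (is.null(tree)) NA_character_ else
             object_digest(write_newick(tree)))),
    class = "vertebral_report")
}

#' @export
print.vertebral_report <- function(x, ...) {
  cat("Vertebral-formula variation report\n")
  cat("==================================\n\n")
  s <- x$summaries
  s$T_var <- round_half_up(s$T_var)
  s$S_tr <- round_half_up(s$S_tr)
  cat("Species summaries (", x$metadata$zone_filter, " populations):\n", sep = "")
  print(s, row.names = FALSE)
  cat("\nSpearman correlations:\n")
  for (nm in names(x$correlations)) {
    r <- x$correlations[[nm]]
    cat(sprintf("  %-11s r_s = %5.2f  (p_t = %.3f)\n", nm, r$r_s, r$p_t))
  }
  if (!is.null(x$phylo)) {
    cat("\nPhylogenetic signal (tip-permutation, ",
        x$metadata$iterations, " iterations):\n", sep = "")
    for (nm in names(x$phylo$signal)) {
      cat(sprintf("  %-8s p = %.4f\n", nm, x$phylo$signal[[nm]]$p))
    }
    cat("\nContrast regressions (through origin):\n")
    for (nm in names(x$phylo$regressions)) {
      r <- x$phylo$regressions[[nm]]
      cat(sprintf("  %-13s slope = %7.3f  t = %6.2f  p = %.4f\n",
                  nm, r$slope, r$t, r$p))
    }
  }
  invisible(x)
}
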