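#' Round half away from zero
#'
#' Reporting helper for percentages: 24.55 rounds to 24.6. Internal values
#' are kept unrounded; rounding happens only when a table is printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise the thoracic-count distribution of one species
#'
#' Tallies the half-integral thoracic scores of the selected records and
#' derives the four species-level statistics used throughout the analysis:
#'
#' * `T_n` — the modal integer thoracic count (ties broken toward the smaller
#'   count, with a warning; the empirical tables contain no ties);
#' * `T_var` — the percentage of specimens whose complete thoracic count
#'   differs from `T_n`. Specimens with a transitional sacral vertebra (half
#'   scores) are excluded from the numerator: a specimen contributes to at
#'   most one of `T_var` and `S_tr`;
#' * `T_range` — the span (max minus min) of the integer scores observed;
#' * `S_tr` — the percentage of specimens with a transitional sacral
#'   vertebra.
#'
#' Percentages are stored unrounded; round to one decimal with
#' [round_half_up()] when reporting.
#'
#' @param records a `"vertebral_records"` table.
#' @param species the species token to summarise.
#' @param zone_filter optional `"central"` or `"fringe"` to restrict the
#'   selection.
#' @return an object of class `"species_summary"`: a list with elements
#'   `species`, `n`, `score_distribution` (named numeric: score -> count),
#'   `T_n`, `T_var`, `T_range`, `S_tr`.
#' @export
#' @examples
#' rec <- expand_distribution(data.frame(
#'   species = "marmoratus", zone = "central",
#'   score = c(12, 12.5, 13), count = c(46, 4, 8)))
#' s <- summarize_species(rec, "marmoratus")
#' round_half_up(s$T_var)  # 13.8
summarize_species <- function(records, species, zone_filter = NULL) {
  sel <- records$species == species
  if (!is.null(zone_filter)) {
    zone_filter <- match.arg(zone_filter, ZONE_LEVELS)
    sel <- sel & records$zone == zone_filter
  }
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0) {
    stop("no records for species '", species, "'",
         if (!is.null(zone_filter)) paste0(" in zone '", zone_filter, "'"))
  }
  n <- nrow(r)
  score <- thoracic_score(r)
  dist <- table(score)
  score_distribution <- stats::setNames(as.numeric(dist),
                                        names(dist))

  is_half <- score %% 1 != 0
  int_counts <- table(r$thoracic_complete[!is_half])
  if (length(int_counts) == 0) {
    stop("species '", species, "' has no specimens with an integral score; ",
         "modal count undefined")
  }
  max_count <- max(int_counts)
  modal_candidates <- as.integer(names(int_counts)[int_counts == max_count])
  if (length(modal_candidates) > 1) {
    warning("modal thoracic count tie for '", species, "' (",
            paste(modal_candidates, collapse = ", "),
            "); using the smallest")
  }
  T_n <- min(modal_candidates)

  # half-score specimens are excluded from the T_var numerator
  T_var <- 100 * sum(!is_half & r$thoracic_complete != T_n) / n
  S_tr <- 100 * sum(r$sacral_state %in% TRANSITIONAL_STATES) / n
  int_observed <- unique(r$thoracic_complete[!is_half])
  T_range <- max(int_observed) - min(int_observed)

  structure(
    list(species = species, n = n, score_distribution = score_distribution,
         T_n = T_n, T_var = T_var, T_range = T_range, S_tr = S_tr),
    class = "species_summary")
}

#' @export
print.species_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, T_n = %d, T_var = %.1f%%, T_range = %d, S_tr = %.1f%%\n",
              x$species, x$n, x$T_n, round_half_up(x$T_var), x$T_range,
              round_half_up(x$S_tr)))
  invisible(x)
}

#' Species summary table
#'
#' Applies [summarize_species()] to every non-hybrid species in the record
#' table and returns one row per species. Species with no records after zone
#' filtering are omitted with a warning.
#'
#' @inheritParams summarize_species
#' @param include_hybrids keep hybrid tokens (`"a_x_b"`) as rows; off by
#'   default.
#' @return a data.frame with columns `species, n, T_n, T_var, T_range, S_tr`
#'   (percentages unrounded).
#' @export
summary_table <- function(records, zone_filter = NULL, include_hybrids = FALSE) {
  species <- unique(records$species)
  if (!include_hybrids) species <- species[!is_hybrid(species)]
  rows <- list()
  for (sp in species) {
    s <- tryCatch(summarize_species(records, sp, zone_filter),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning("species '", sp, "' has no records after filtering; omitted")
      next
    }
    rows[[sp]] <- data.frame(species = s$species, n = s$n, T_n = s$T_n,
                             T_var = s$T_var, T_range = s$T_range,
                             S_tr = s$S_tr, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no species left after filtering")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally homeotic transformations for one species
#'
#' Counts, over the selected specimens, each transformation category once per
#' specimen: complete and incomplete cervical-to-thoracic transformations,
#' left- and right-sided transitional sacral vertebrae, and one-sided
#' thoracic-to-sacral changes that leave the sacral vertebra regular.
#' `any_transformation` counts specimens carrying any non-regular state; in
#' the empirical material no specimen carries two, so it equals the sum of
#' the categories.
#'
#' @param records a `"vertebral_records"` table.
#' @param species species token.
#' @return an object of class `"transformation_tally"`: list with `species`,
#'   `n`, `any_transformation`, `cervical_complete`, `cervical_incomplete`,
#'   `sacral_left`, `sacral_right`, `thoracic_to_sacral_incomplete`.
#' @export
tally_transformations <- function(records, species) {
  r <- records[records$species == species, , drop = FALSE]
  if (nrow(r) == 0) stop("no records for species '", species, "'")
  transitional <- r$sacral_state %in% TRANSITIONAL_STATES
  any_tr <- r$cervical_state != "regular" | r$sacral_state != "regular"
  structure(
    list(species = species,
         n = nrow(r),
         any_transformation = sum(any_tr),
         cervical_complete = sum(r$cervical_state == "complete_to_thoracic"),
         cervical_incomplete = sum(r$cervical_state == "incomplete_to_thoracic"),
         sacral_left = sum(transitional & r$asymmetry == "left"),
         sacral_right = sum(transitional & r$asymmetry == "right"),
         thoracic_to_sacral_incomplete = sum(r$sacral_state == "thoracic_incomplete")),
    class = "transformation_tally")
}

#' Transformation tally table
#'
#' [tally_transformations()] for every species in the table (hybrids excluded
#' by default), plus a `Total` row.
#'
#' @inheritParams summary_table
#' @return a data.frame, one row per species and a final `Total` row.
#' @export
tally_table <- function(records, include_hybrids = FALSE) {
  species <- unique(records$species)
  if (!include_hybrids) species <- species[!is_hybrid(species)]
  rows <- lapply(species, function(sp) {
    t <- tally_transformations(records, sp)
    data.frame(species = t$species, n = t$n,
               any_transformation = t$any_transformation,
               cervical_complete = t$cervical_complete,
               cervical_incomplete = t$cervical_incomplete,
               sacral_left = t$sacral_left, sacral_right = t$sacral_right,
               thoracic_to_sacral_incomplete = t$thoracic_to_sacral_incomplete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(species = "Total", t(colSums(out[, -1])))
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Expand a score distribution into specimen records
#'
#' Turns summary rows (`species, zone, score, count`) into a record table
#' with deterministic synthetic specimen ids, so that published distribution
#' tables can drive the record-level code paths. Integral scores become
#' regular specimens; half scores become specimens with a transitional sacral
#' vertebra (`"transitional_single"`), alternating left/right asymmetry
#' unless a tally dictates the split. `summarize_species()` composed with
#' `expand_distribution()` reproduces the input distribution exactly.
#'
#' @param distribution data.frame with columns `species`, `score`, `count`
#'   and optionally `zone` (default `"central"`).
#' @param tally optional data.frame in the layout of [tally_table()] giving,
#'   per species, annotation counts (`cervical_complete`,
#'   `cervical_incomplete`, `sacral_left`, `sacral_right`,
#'   `thoracic_to_sacral_incomplete`) to distribute over the expanded
#'   records. `sacral_left + sacral_right` must equal the number of
#'   half-score specimens of that species; annotations are assigned to
#'   disjoint specimens.
#' @return a `"vertebral_records"` table.
#' @export
#' @examples
#' expand_distribution(data.frame(species = "pygmaeus", score = 12, count = 2))
expand_distribution <- function(distribution, tally = NULL) {
  stopifnot(all(c("species", "score", "count") %in% names(distribution)))
  if (!("zone" %in% names(distribution))) distribution$zone <- "central"
  if (any(distribution$count < 0)) stop("counts must be nonnegative")
  if (any(distribution$score %% 0.5 != 0)) stop("scores must be half-integral")

  pieces <- lapply(seq_len(nrow(distribution)), function(i) {
    row <- distribution[i, ]
    k <- row$count
    if (k == 0) return(NULL)
    half <- row$score %% 1 != 0
    data.frame(
      species = rep(row$species, k),
      zone = rep(row$zone, k),
      score = rep(row$score, k),
      thoracic_complete = rep(as.integer(floor(row$score)), k),
      sacral_state = rep(if (half) "transitional_single" else "regular", k),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) stop("distribution expands to zero records")

  out <- list()
  for (sp in unique(df$species)) {
    d <- df[df$species == sp, , drop = FALSE]
    d <- d[order(d$score), , drop = FALSE]
    nh <- sum(d$sacral_state != "regular")
    d$asymmetry <- "none"
    d$cervical_state <- "regular"

    if (!is.null(tally) && sp %in% tally$species) {
      t <- tally[tally$species == sp, ]
      if (t$sacral_left + t$sacral_right != nh) {
        stop("inconsistent annotation totals for '", sp, "': ",
             t$sacral_left, " + ", t$sacral_right,
             " transitional sides but ", nh, " half-score specimens")
      }
      half_idx <- which(d$sacral_state != "regular")
      d$asymmetry[half_idx] <- rep(c("left", "right"),
                                   c(t$sacral_left, t$sacral_right))
      reg_idx <- which(d$sacral_state == "regular")
      need <- t$cervical_complete + t$cervical_incomplete +
        t$thoracic_to_sacral_incomplete
      if (need > length(reg_idx)) {
        stop("inconsistent annotation totals for '", sp,
             "': more annotations than regular specimens")
      }
      # disjoint assignment: cervical states first, then one-sided
      # thoracic-to-sacral changes
      take <- reg_idx[seq_len(need)]
      d$cervical_state[take[seq_len(t$cervical_complete)]] <- "complete_to_thoracic"
      d$cervical_state[take[t$cervical_complete + seq_len(t$cervical_incomplete)]] <-
        "incomplete_to_thoracic"
      d$sacral_state[take[t$cervical_complete + t$cervical_incomplete +
                            seq_len(t$thoracic_to_sacral_incomplete)]] <-
        "thoracic_incomplete"
    } else {
      d$asymmetry[d$sacral_state != "regular"] <-
        rep_len(c("left", "right"), nh)
    }
    d$specimen_id <- sprintf("%s_%04d", sp, seq_len(nrow(d)))
    d$population_id <- paste0(sp, "_pop1")
    out[[sp]] <- d[, RECORD_COLUMNS]
  }
  validate_records(do.call(rbind, out))
}

#' Expand a transformation tally into specimen records
#'
#' Reconstructs a minimal record table consistent with a published
#' transformation tally (one row per species, layout of [tally_table()]):
#' the full-population score distributions behind such tallies are not
#' published, so all regular specimens are placed at an arbitrary modal
#' count. Transformations are assigned to disjoint specimens, with the
#' transitional sacral specimens taking half scores. Useful for prevalence
#' computations (`S_tr`, transformation totals), not for `T_var`/`T_range`.
#'
#' @param tally data.frame in the layout of [tally_table()] (without the
#'   `Total` row), requiring columns `species`, `n` and the five annotation
#'   counts.
#' @param modal_count integer thoracic count given to every specimen.
#' @return a `"vertebral_records"` table with `sum(tally$n)` rows.
#' @export
expand_tally <- function(tally, modal_count = 13L) {
  rows <- lapply(seq_len(nrow(tally)), function(i) {
    t <- tally[i, ]
    n_half <- t$sacral_left + t$sacral_right
    dist <- data.frame(species = t$species, zone = "central",
                       score = c(modal_count, modal_count + 0.5),
                       count = c(t$n - n_half, n_half))
    expand_distribution(dist, tally = t)
  })
  validate_records(do.call(rbind, rows))
}
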