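#' Published Triturus tables
#'
#' Loaders for the packaged data behind the published analysis:
#'
#' * `triturus_table1()` — per-species thoracic-score distributions of the
#'   central populations of the eight species (`species, zone, score,
#'   count`);
#' * `triturus_table2()` — per-species homeotic-transformation tallies over
#'   all populations, hybrids excluded;
#' * `triturus_table3()` — score distributions of the F1
#'   cristatus x marmoratus hybrids and both parental species;
#' * `triturus_table4()` — counts of specimens with modal and non-modal
#'   vertebral formulae in central and fringe populations of the five
#'   species with parapatric distributions.
#'
#' The record-level variants `table1_records()`, `table2_records()` and
#' `table3_records()` expand these tables into `"vertebral_records"` via
#' [expand_distribution()] / [expand_tally()], so the published numbers flow
#' through exactly the code paths used for raw specimen data.
#'
#' @return a data.frame (`triturus_table*`) or a `"vertebral_records"` table
#'   (`table*_records`).
#' @name triturus_tables
NULL

#' @rdname triturus_tables
#' @export
triturus_table1 <- function() {
  utils::read.csv(vertvar_example("table1_distribution.csv"))
}

#' @rdname triturus_tables
#' @export
triturus_table2 <- function() {
  utils::read.csv(vertvar_example("table2_transformations.csv"))
}

#' @rdname triturus_tables
#' @export
triturus_table3 <- function() {
  utils::read.csv(vertvar_example("table3_distribution.csv"))
}

#' @rdname triturus_tables
#' @export
triturus_table4 <- function() {
  utils::read.csv(vertvar_example("table4_zone_counts.csv"))
}

#' @rdname triturus_tables
#' @export
table1_records <- function() {
  expand_distribution(triturus_table1())
}

#' @rdname triturus_tables
#' @param modal_count passed to [expand_tally()]; the tally table does not
#'   publish full score distributions, so regular specimens sit at an
#'   arbitrary count.
#' @export
table2_records <- function(modal_count = 13L) {
  expand_tally(triturus_table2(), modal_count = modal_count)
}

#' @rdname triturus_tables
#' @export
table3_records <- function() {
  expand_distribution(triturus_table3())
}

#' Expand published zone counts into records
#'
#' Turns a `species, zone, modal, nonmodal` count table into records whose
#' modal/non-modal classification reproduces the input: modal specimens at
#' `modal_count`, non-modal ones at `modal_count + 1`.
#'
#' @param zone_counts data.frame as returned by [triturus_table4()].
#' @param modal_count integer count used for the modal specimens.
#' @return a `"vertebral_records"` table.
#' @export
expand_zone_counts <- function(zone_counts, modal_count = 13L) {
  pieces <- lapply(seq_len(nrow(zone_counts)), function(i) {
    z <- zone_counts[i, ]
    expand_distribution(data.frame(
      species = z$species, zone = z$zone,
      score = c(modal_count, modal_count + 1L),
      count = c(z$modal, z$nonmodal)))
  })
  rec <- do.call(rbind, pieces)
  # re-key specimen ids across zones of the same species
  rec$specimen_id <- sprintf("%s_%s_%04d", rec$species, rec$zone,
                             stats::ave(seq_len(nrow(rec)),
                                        rec$species, rec$zone,
                                        FUN = seq_along))
  validate_records(rec)
}
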