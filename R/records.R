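#' @keywords internal
"_PACKAGE"

## Enum tokens for the record table. Lower-case, matching the CSV dialect.
ZONE_LEVELS <- c("central", "fringe")
CERVICAL_LEVELS <- c("regular", "incomplete_to_thoracic", "complete_to_thoracic")
SACRAL_LEVELS <- c("regular", "transitional_two_vertebra", "transitional_single",
                   "thoracic_incomplete")
ASYMMETRY_LEVELS <- c("none", "left", "right")
TRANSITIONAL_STATES <- c("transitional_two_vertebra", "transitional_single")

RECORD_COLUMNS <- c("specimen_id", "species", "population_id", "zone",
                    "cervical_state", "thoracic_complete", "sacral_state",
                    "asymmetry")

#' Construct a table of vertebral records
#'
#' A vertebral record describes one cleared-and-stained or X-rayed specimen:
#' its species, sampling population and zone (central populations lie >= 50 km
#' from the range of a congeneric species, fringe populations closer), the
#' state of its single cervical vertebra (the atlas), the number of complete
#' rib-bearing thoracic vertebrae, and the state of the thoraco-sacral
#' boundary. A transitional sacral vertebra carries a thoracic rib on one side
#' and a sacral rib on the other; it is recorded either as
#' `"transitional_two_vertebra"` (followed by a second transitional vertebra)
#' or `"transitional_single"` (followed by a regular sacral vertebra), with
#' the side of the remaining thoracic rib in `asymmetry`. A one-sided change
#' of a thoracic vertebra that leaves the sacral vertebra regular is recorded
#' as `sacral_state = "thoracic_incomplete"`.
#'
#' @param specimen_id character vector of unique specimen identifiers.
#' @param species character vector of species tokens; F1 hybrids use tokens of
#'   the form `"cristatus_x_marmoratus"`.
#' @param population_id character vector of population identifiers.
#' @param zone `"central"` or `"fringe"`.
#' @param cervical_state one of `"regular"`, `"incomplete_to_thoracic"`,
#'   `"complete_to_thoracic"`.
#' @param thoracic_complete integer count of complete rib-bearing vertebrae,
#'   between 10 and 20.
#' @param sacral_state one of `"regular"`, `"transitional_two_vertebra"`,
#'   `"transitional_single"`, `"thoracic_incomplete"`.
#' @param asymmetry side of the thoracic rib on a transitional sacral
#'   vertebra: `"none"`, `"left"` or `"right"`. Must be `"none"` exactly when
#'   `sacral_state` is not transitional.
#'
#' @return A validated `data.frame` with class `"vertebral_records"`.
#' @seealso [read_records()], [thoracic_score()], [summarize_species()]
#' @export
#' @examples
#' vertebral_records(
#'   specimen_id = c("s1", "s2"), species = "marmoratus",
#'   population_id = "p1", zone = "central",
#'   cervical_state = "regular", thoracic_complete = c(12L, 12L),
#'   sacral_state = c("regular", "transitional_single"),
#'   asymmetry = c("none", "right"))
vertebral_records <- function(specimen_id, species, population_id, zone,
                              cervical_state, thoracic_complete, sacral_state,
                              asymmetry) {
  df <- data.frame(
    specimen_id = as.character(specimen_id),
    species = as.character(species),
    population_id = as.character(population_id),
    zone = as.character(zone),
    cervical_state = as.character(cervical_state),
    thoracic_complete = as.integer(thoracic_complete),
    sacral_state = as.character(sacral_state),
    asymmetry = as.character(asymmetry),
    stringsAsFactors = FALSE
  )
  validate_records(df)
}

#' Validate a table of vertebral records
#'
#' Checks the enum tokens and the record invariants: `thoracic_complete` lies
#' in 10..20, and `asymmetry` differs from `"none"` exactly when the specimen
#' carries a transitional sacral vertebra. The cervical region is modelled as
#' the single atlas vertebra, so no cervical count column exists.
#'
#' @param records a data.frame with the columns of [vertebral_records()].
#' @return the validated records, classed `"vertebral_records"`.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("record table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, RECORD_COLUMNS]

  check_enum <- function(col, levels) {
    bad <- which(!(records[[col]] %in% levels))
    if (length(bad) > 0) {
      stop(sprintf("format error in row %d: unknown %s token '%s'",
                   bad[1], col, records[[col]][bad[1]]))
    }
  }
  check_enum("zone", ZONE_LEVELS)
  check_enum("cervical_state", CERVICAL_LEVELS)
  check_enum("sacral_state", SACRAL_LEVELS)
  check_enum("asymmetry", ASYMMETRY_LEVELS)

  tc <- records$thoracic_complete
  if (any(is.na(tc)) || any(tc != as.integer(tc))) {
    stop("thoracic_complete must be integer")
  }
  bad <- which(tc < 10 | tc > 20)
  if (length(bad) > 0) {
    stop(sprintf("validation error for specimen '%s': thoracic_complete = %d outside [10, 20]",
                 records$specimen_id[bad[1]], tc[bad[1]]))
  }

  transitional <- records$sacral_state %in% TRANSITIONAL_STATES
  bad <- which(transitional != (records$asymmetry != "none"))
  if (length(bad) > 0) {
    stop(sprintf(paste0("validation error for specimen '%s': asymmetry must be ",
                        "'left' or 'right' exactly for transitional sacral states"),
                 records$specimen_id[bad[1]]))
  }

  class(records) <- c("vertebral_records", "data.frame")
  records
}

#' Read vertebral records from CSV
#'
#' Reads the record dialect: a UTF-8 CSV with header
#' `specimen_id,species,population_id,zone,cervical_state,thoracic_complete,sacral_state,asymmetry`
#' and lower-case enum tokens. Row order is preserved and all invariants are
#' validated.
#'
#' @param source path to a record CSV file.
#' @return a `"vertebral_records"` data.frame.
#' @seealso [write_records()]
#' @export
read_records <- function(source) {
  df <- utils::read.csv(source, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!("thoracic_complete" %in% names(df))) {
    stop("record file lacks a thoracic_complete column: ", source)
  }
  df$thoracic_complete <- as.integer(df$thoracic_complete)
  validate_records(df)
}

#' Write vertebral records to CSV
#'
#' Writes the canonical record dialect. A file produced by `write_records()`
#' and re-read with [read_records()] round-trips byte-identically.
#'
#' @param records a `"vertebral_records"` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(as.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Thoracic score of each specimen
#'
#' The number of complete rib-bearing thoracic vertebrae, plus 0.5 when the
#' specimen carries a transitional sacral vertebra (a vertebra with half
#' thoracic and half sacral identity). The score is half-integral exactly for
#' specimens with a transitional sacral vertebra; a one-sided
#' thoracic change without change of the sacral vertebra
#' (`sacral_state = "thoracic_incomplete"`) does not add 0.5.
#'
#' @param records a `"vertebral_records"` table (or one row of it).
#' @return numeric vector of half-integral scores, one per record.
#' @export
#' @examples
#' r <- vertebral_records("s1", "dobrogicus", "p1", "central", "regular",
#'                        16L, "transitional_two_vertebra", "left")
#' thoracic_score(r)  # 16.5
thoracic_score <- function(records) {
  records$thoracic_complete +
    0.5 * (records$sacral_state %in% TRANSITIONAL_STATES)
}

#' Identify hybrid records
#'
#' Hybrid specimens carry species tokens of the form `"a_x_b"`; they are
#' excluded from species-level summaries unless explicitly requested.
#'
#' @param species character vector of species tokens.
#' @return logical vector.
#' @export
is_hybrid <- function(species) {
  grepl("_x_", species, fixed = TRUE)
}
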