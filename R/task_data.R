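#' Construct a table of test-phase trial records
#'
#' A trial record holds one test-phase trial of the source-monitoring task:
#' the true vertical position of the object (`up`, `down`, or `new` for
#' distractors), the old/new item response (`miss` when no answer was given
#' within the deadline), and, when the item answer was "old", the up/down
#' source response. The source prompt only follows an "old" answer, so
#' `source_response` must be `"none"` exactly when `item_response` is not
#' `"old"`.
#'
#' @param participant_id character vector of participant identifiers.
#' @param group `"young"` or `"older"`.
#' @param block integer block index, 1..8 in the standard design.
#' @param item_id character item identifier.
#' @param true_position `"up"`, `"down"`, or `"new"`.
#' @param item_response `"old"`, `"new"`, or `"miss"`.
#' @param source_response `"up"`, `"down"`, or `"none"`.
#' @param rt_item item-response reaction time in seconds, `NA` if absent.
#' @param rt_source source-response reaction time in seconds, `NA` if absent.
#'
#' @return A `data.frame` with one row per trial and validated columns.
#' @export
trial_records <- function(participant_id, group, block, item_id,
                          true_position, item_response, source_response,
                          rt_item = NA_real_, rt_source = NA_real_) {
  df <- data.frame(
    participant_id = as.character(participant_id),
    group = as.character(group),
    block = as.integer(block),
    item_id = as.character(item_id),
    true_position = as.character(true_position),
    item_response = as.character(item_response),
    source_response = as.character(source_response),
    rt_item = as.numeric(rt_item),
    rt_source = as.numeric(rt_source),
    stringsAsFactors = FALSE
  )
  validate_trials(df)
  df
}

#' Validate a trial-record table
#'
#' Checks enum domains, the coupling between item and source responses
#' (a source answer is present iff the item answer was "old"), and that
#' missed trials carry no item reaction time.
#'
#' @param trials a trial-record `data.frame`.
#' @return The input, invisibly, if valid; otherwise an error is thrown
#'   naming the offending row and column.
#' @export
validate_trials <- function(trials) {
  required <- c("participant_id", "group", "block", "item_id",
                "true_position", "item_response", "source_response",
                "rt_item", "rt_source")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  check_enum <- function(col, levels) {
    bad <- which(!trials[[col]] %in% levels)
    if (length(bad) > 0L) {
      stop(sprintf("row %d, column '%s': invalid value '%s' (expected one of %s)",
                   bad[1L], col, trials[[col]][bad[1L]],
                   paste(levels, collapse = "/")))
    }
  }
  check_enum("group", .GROUPS)
  check_enum("true_position", .POSITIONS)
  check_enum("item_response", .ITEM_RESPONSES)
  check_enum("source_response", .SOURCE_RESPONSES)

  is_old <- trials$item_response == "old"
  has_source <- trials$source_response != "none"
  bad <- which(is_old != has_source)
  if (length(bad) > 0L) {
    stop(sprintf(paste0("row %d: source_response must be given exactly when ",
                        "item_response is 'old' (got item_response='%s', ",
                        "source_response='%s')"),
                 bad[1L], trials$item_response[bad[1L]],
                 trials$source_response[bad[1L]]))
  }
  bad_rt <- which(trials$item_response == "miss" & !is.na(trials$rt_item))
  if (length(bad_rt) > 0L) {
    stop(sprintf("row %d: missed trial must not carry rt_item", bad_rt[1L]))
  }
  invisible(trials)
}

#' Read test-phase trial records from CSV
#'
#' The interchange dialect is a UTF-8 comma-separated file with header
#' `participant_id, group, block, item_id, true_position, item_response,
#' source_response, rt_item, rt_source`; absent reaction times are empty
#' strings and an absent source response is `none`.
#'
#' @param path path to the trial CSV.
#' @return A validated trial-record `data.frame`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  expected <- c("participant_id", "group", "block", "item_id",
                "true_position", "item_response", "source_response",
                "rt_item", "rt_source")
  if (!identical(names(df), expected)) {
    stop("unexpected trial CSV header: ", paste(names(df), collapse = ","))
  }
  blk <- suppressWarnings(as.integer(df$block))
  if (anyNA(blk) && nrow(df) > 0L) {
    stop(sprintf("row %d, column 'block': not an integer",
                 which(is.na(blk))[1L]))
  }
  num_or_na <- function(x, col) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("row %d, column '%s': not a number", bad[1L], col))
    }
    out
  }
  trial_records(df$participant_id, df$group, blk, df$item_id,
                df$true_position, df$item_response, df$source_response,
                num_or_na(df$rt_item, "rt_item"),
                num_or_na(df$rt_source, "rt_source"))
}

#' Write trial records to CSV
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, f))` returns `x`.
#'
#' @param trials validated trial-record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials
  out$rt_item <- ifelse(is.na(out$rt_item), "", format(out$rt_item, digits = 15, trim = TRUE, scientific = FALSE))
  out$rt_source <- ifelse(is.na(out$rt_source), "", format(out$rt_source, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an MPT response-frequency table
#'
#' @param counts 3x3 non-negative integer matrix; rows are the trial trees
#'   `UP`, `DOWN`, `NEW` (true position) and columns the response categories
#'   `old_up`, `old_down`, `new`.
#' @param n_miss number of trials excluded because no item response was given.
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(counts, n_miss = 0L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) stop("counts must be 3x3")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(.TREES, .CATEGORIES)
  structure(list(counts = counts, n_miss = as.integer(n_miss)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("MPT response frequencies (rows: trial type, cols: response)\n")
  print(x$counts)
  cat("missed trials:", x$n_miss, "\n")
  invisible(x)
}

#' Tabulate MPT response frequencies for one participant
#'
#' Each answered trial increments exactly one cell: the row is the true
#' position of the item (tree), the column is the response category
#' (`old_up`, `old_down` from an "old" answer plus the source judgment,
#' `new` from a "new" answer). Missed trials are excluded from the counts
#' and recorded in `n_miss` — the model has no "no response" branch.
#'
#' @param trials trial records of a single participant.
#' @return A [freq_table()].
#' @export
tabulate_mpt <- function(trials) {
  validate_trials(trials)
  if (length(unique(trials$participant_id)) > 1L) {
    stop("tabulate_mpt expects trials of a single participant, got: ",
         paste(unique(trials$participant_id), collapse = ", "))
  }
  counts <- matrix(0, 3L, 3L, dimnames = list(.TREES, .CATEGORIES))
  answered <- trials$item_response != "miss"
  if (any(answered)) {
    tree <- c(up = "UP", down = "DOWN", new = "NEW")[trials$true_position[answered]]
    resp <- ifelse(trials$item_response[answered] == "new", "new",
                   ifelse(trials$source_response[answered] == "up",
                          "old_up", "old_down"))
    tab <- table(factor(tree, .TREES), factor(resp, .CATEGORIES))
    counts <- counts + unclass(tab)
  }
  freq_table(counts, n_miss = sum(!answered))
}

#' Assemble a cohort table from trial records
#'
#' Splits a multi-participant trial log by participant, tabulates each, and
#' attaches group labels (and optional per-participant covariates, e.g. a
#' 0/1 sex indicator used as a latent-mean covariate in the hierarchical
#' model).
#'
#' @param trials trial records from one or more participants.
#' @param covariates optional named numeric vector or single-column
#'   data.frame indexed by participant id.
#' @return An object of class `cohort_table`: list with `tables` (named list
#'   of `freq_table`), `group` (named character vector), `covariate`
#'   (named numeric vector or NULL).
#' @export
cohort_table <- function(trials, covariates = NULL) {
  validate_trials(trials)
  ids <- unique(trials$participant_id)
  tables <- lapply(ids, function(id) {
    tabulate_mpt(trials[trials$participant_id == id, , drop = FALSE])
  })
  names(tables) <- ids
  group <- vapply(ids, function(id) {
    g <- unique(trials$group[trials$participant_id == id])
    if (length(g) != 1L) stop("participant ", id, " has inconsistent group labels")
    g
  }, character(1))
  cov <- NULL
  if (!is.null(covariates)) {
    if (is.data.frame(covariates)) covariates <- stats::setNames(covariates[[2L]], covariates[[1L]])
    if (is.null(names(covariates)) || !all(ids %in% names(covariates))) {
      stop("covariates must be named by participant id and cover all participants")
    }
    cov <- covariates[ids]
  }
  structure(list(tables = tables, group = group, covariate = cov),
            class = "cohort_table")
}

#' Subset a cohort table to one group
#' @param cohort a `cohort_table`.
#' @param group `"young"` or `"older"`.
#' @return A `cohort_table` containing only that group's participants.
#' @export
cohort_subset <- function(cohort, group) {
  group <- match.arg(group, .GROUPS)
  keep <- names(cohort$group)[cohort$group == group]
  if (length(keep) == 0L) stop("no participants in group '", group, "'")
  structure(list(tables = cohort$tables[keep],
                 group = cohort$group[keep],
                 covariate = if (is.null(cohort$covariate)) NULL else cohort$covariate[keep]),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort of", length(x$tables), "participants (",
      sum(x$group == "young"), "young,", sum(x$group == "older"), "older )\n")
  invisible(x)
}
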