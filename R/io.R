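#' Read and validate an event-driven battle log
#'
#' Expects a comma-separated file with header
#' `time,nA,nB,nAB,nABB,nABBB`: one row per observed reaction event, `time`
#' in seconds.  Validation reports the offending row number for:
#' non-monotone (decreasing) times, negative or non-integer counts, and
#' population totals exceeding the totals of the first row (individuals
#' cannot be created during a battle).
#'
#' @param path CSV file path.
#' @return an `event_series` data frame (columns `time`, species counts)
#'   with `totalA`/`totalB` columns appended.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time", SPECIES)
  if (!all(need %in% names(df)))
    stop("event table must have columns ", paste(need, collapse = ","))
  if (nrow(df) == 0L) stop("event table is empty: ", path)
  df <- df[need]
  validate_event_series(df)
  tot <- population_totals(df[SPECIES])
  df$totalA <- tot[, "totalA"]
  df$totalB <- tot[, "totalB"]
  class(df) <- c("event_series", "data.frame")
  df
}

# Schema checks shared by the reader and the synthetic generator.
validate_event_series <- function(df) {
  bad_time <- which(diff(df$time) < 0)
  if (length(bad_time))
    stop("event times decrease at row ", bad_time[1] + 1L)
  cnt <- as.matrix(df[SPECIES])
  bad <- which(rowSums(cnt < 0 | cnt != round(cnt)) > 0)
  if (length(bad))
    stop("negative or non-integer count at row ", bad[1])
  tot <- population_totals(df[SPECIES])
  badA <- which(tot[, "totalA"] > tot[1, "totalA"] + 1e-9)
  badB <- which(tot[, "totalB"] > tot[1, "totalB"] + 1e-9)
  if (length(badA)) stop("totalA exceeds its initial value at row ", badA[1])
  if (length(badB)) stop("totalB exceeds its initial value at row ", badB[1])
  invisible(df)
}

#' Label the reaction events behind a logged battle
#'
#' Each consecutive state difference in the log is decomposed into a
#' minimal non-negative integer combination of registry stoichiometries.
#' A transition matching a single channel is labelled uniquely; one that
#' needs several firings (observers may merge near-simultaneous events) is
#' decomposed with the fewest events first, ties broken by lowest channel
#' index, and flagged `multi`; a difference outside the reaction cone is
#' flagged `undecomposable`.
#'
#' @param series a validated `event_series`.
#' @param max_events deepest decomposition attempted per transition.
#' @return data frame with one row per transition: `from_time`, `to_time`,
#'   `channels` (comma-separated indices, `""` for a no-change row),
#'   `n_events`, `flag` (`"ok"`, `"multi"`, or `"undecomposable"`).
#' @examples
#' path <- system.file("extdata", "interaction_example.csv",
#'                     package = "antbattle")
#' infer_events(read_event_table(path))
#' @export
infer_events <- function(series, max_events = 4L) {
  if (nrow(series) < 2L)
    return(data.frame(from_time = numeric(0), to_time = numeric(0),
                      channels = character(0), n_events = integer(0),
                      flag = character(0)))
  S <- stoich_matrix()
  out <- vector("list", nrow(series) - 1L)
  for (i in seq_len(nrow(series) - 1L)) {
    delta <- as.numeric(series[i + 1L, SPECIES]) - as.numeric(series[i, SPECIES])
    combo <- decompose_delta(delta, S, max_events)
    out[[i]] <- data.frame(
      from_time = series$time[i], to_time = series$time[i + 1L],
      channels = if (is.null(combo)) NA_character_
                 else paste(combo, collapse = ","),
      n_events = if (is.null(combo)) NA_integer_ else length(combo),
      flag = if (is.null(combo)) "undecomposable"
             else if (length(combo) > 1L) "multi" else "ok")
  }
  do.call(rbind, out)
}

# Breadth-first search over multisets of channels (fewest events first,
# lexicographically smallest index sequence first).  Returns an integer
# vector of channel indices, integer(0) for a zero difference, or NULL.
decompose_delta <- function(delta, S, max_events) {
  if (all(delta == 0)) return(integer(0))
  for (depth in 1:max_events) {
    hit <- search_combo(delta, S, depth, start = 1L)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

search_combo <- function(delta, S, depth, start) {
  if (depth == 0L) return(if (all(delta == 0)) integer(0) else NULL)
  for (j in start:ncol(S)) {
    rest <- search_combo(delta - S[, j], S, depth - 1L, j)
    if (!is.null(rest)) return(c(j, rest))
  }
  NULL
}

#' Read / write an hourly mortality table
#'
#' Schema: CSV with columns `time_s,survivors_A,survivors_B` — survivor
#' counts of the two species at (hourly) observation times.  Survivor
#' entries may be fractional, being means over replicate experiments.
#' Validation requires increasing times, non-negative values and
#' non-increasing survivor counts.
#'
#' @param path CSV file path.
#' @return data frame with the three schema columns.
#' @export
read_mortality_table <- function(path) {
  if (!file.exists(path)) stop("mortality table not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "survivors_A", "survivors_B")
  if (!all(need %in% names(df)))
    stop("mortality table must have columns ", paste(need, collapse = ","))
  df <- df[need]
  validate_mortality_table(df)
  df
}

validate_mortality_table <- function(df) {
  if (nrow(df) == 0L) stop("mortality table is empty")
  if (any(diff(df$time_s) <= 0)) stop("mortality times must increase")
  if (any(df$survivors_A < 0 | df$survivors_B < 0))
    stop("negative survivor count")
  badA <- which(diff(df$survivors_A) > 1e-9)
  badB <- which(diff(df$survivors_B) > 1e-9)
  if (length(badA)) stop("survivors_A increases at row ", badA[1] + 1L)
  if (length(badB)) stop("survivors_B increases at row ", badB[1] + 1L)
  invisible(df)
}

#' @rdname read_mortality_table
#' @param table data frame with columns `time_s,survivors_A,survivors_B`.
#' @export
write_mortality_table <- function(table, path) {
  utils::write.csv(table[c("time_s", "survivors_A", "survivors_B")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Bundled experimental mortality data
#'
#' The seven mortality experiments: mean survivor counts (over 5 replicate
#' battles each) at hourly intervals over 5 hours, for seven initial
#' force-size pairs: (10,10), (5,10), (5,11), (5,12), (5,13), (5,14),
#' (5,15) given as (A, B).
#'
#' @param set integer 1..7.
#' @return a mortality table data frame (`time_s,survivors_A,survivors_B`).
#' @examples
#' mortality_data(1)   # the 10 vs 10 experiment used for calibration
#' @export
mortality_data <- function(set) {
  if (!set %in% 1:7) stop("set must be 1..7")
  read_mortality_table(system.file("extdata",
                                   sprintf("mortality_set%d.csv", set),
                                   package = "antbattle"))
}

#' Bundled example interaction log
#'
#' A published excerpt of one 10-vs-10 interaction experiment: 17 logged
#' events between t = 714 s and t = 858 s.  Every row conserves
#' `totalA = totalB = 10` (no casualties in this window).
#'
#' @return an `event_series` data frame.
#' @export
interaction_example <- function() {
  read_event_table(system.file("extdata", "interaction_example.csv",
                               package = "antbattle"))
}
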