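## FUCCI phase analytics: per-cell ordered phase intervals (G1 / S-G2 / M)
## with a terminal event, phase-length extraction, death-phase attribution,
## and stratification of mitotic entry and fate by the phase at movie start.

FUCCI_PHASES <- c("G1", "SG2", "M")
FUCCI_EVENTS <- c("DIVISION", "DEATH", "MOVIE_END")
.legal_next <- list(G1 = "SG2", SG2 = "M", M = "G1")

.track_cols <- c("cell_id", "lineage_id", "parent_id", "generation",
                 "segment_index", "phase", "start_min", "end_min",
                 "terminal_event")

#' Assemble FUCCI phase tracks
#'
#' A track is the ordered list of cell-cycle phase intervals (G1, S/G2, M) of
#' one cell, as classified from the FUCCI reporters, ending in a terminal
#' event: division, death, or the end of the movie.  Segments tile the
#' observation window of the cell without gaps; phases follow the legal order
#' G1 -> S/G2 -> M (a track may start mid-cycle).  A death occurring exactly
#' at a phase boundary is encoded inside the phase being entered (which may
#' give a zero-length terminal segment), making death-phase attribution
#' deterministic.
#'
#' @param segments long-format data.frame with columns `cell_id`,
#'   `lineage_id`, `parent_id`, `generation`, `segment_index`, `phase`,
#'   `start_min`, `end_min`, `terminal_event` (non-`NA` on the last segment
#'   of each cell only).
#' @param movie_duration,frame_interval movie metadata in minutes.
#' @param check validate invariants (default `TRUE`).
#' @return Object of class `fucci_tracks` (a data.frame with metadata
#'   attributes).
#' @export
fucci_tracks <- function(segments, movie_duration = 4320, frame_interval = 10,
                         check = TRUE) {
  stopifnot(is.data.frame(segments))
  for (col in c("cell_id", "lineage_id", "parent_id", "phase",
                "terminal_event"))
    segments[[col]] <- as.character(segments[[col]])
  for (col in c("start_min", "end_min"))
    segments[[col]] <- as.numeric(segments[[col]])
  segments$generation <- as.integer(segments$generation)
  segments$segment_index <- as.integer(segments$segment_index)
  segments <- segments[order(segments$cell_id, segments$segment_index),
                       .track_cols]
  rownames(segments) <- NULL
  out <- structure(segments, class = c("fucci_tracks", "data.frame"),
                   movie_duration = as.numeric(movie_duration),
                   frame_interval = as.numeric(frame_interval))
  if (check) {
    v <- validate_fucci(out)
    if (nrow(v) > 0L)
      stop("invalid FUCCI tracks: ",
           paste0(v$rule, " [", v$cell_id, "]", collapse = "; "))
  }
  out
}

#' Report invariant violations of FUCCI tracks
#'
#' Checks contiguity (each segment starts where the previous ended), legal
#' phase order, frame quantization, the placement of the terminal event on
#' the last segment only, and that `MOVIE_END` tracks end at the movie
#' duration.
#'
#' @param tracks a `fucci_tracks` object (possibly built with
#'   `check = FALSE`).
#' @return data.frame of violations (`cell_id`, `rule`).
#' @export
validate_fucci <- function(tracks) {
  s <- as.data.frame(tracks)
  md <- attr(tracks, "movie_duration")
  fi <- attr(tracks, "frame_interval")
  out <- list()
  bad <- function(ids, rule) {
    ids <- unique(ids)
    if (length(ids) > 0L)
      out[[length(out) + 1L]] <<- data.frame(cell_id = as.character(ids),
                                             rule = rule,
                                             stringsAsFactors = FALSE)
  }
  bad(s$cell_id[!s$phase %in% FUCCI_PHASES], "unknown phase token")
  bad(s$cell_id[!is.na(s$terminal_event) &
                  !s$terminal_event %in% FUCCI_EVENTS],
      "unknown terminal event")
  q <- function(x) !is.na(x) & abs(x / fi - round(x / fi)) > 1e-9
  bad(s$cell_id[q(s$start_min) | q(s$end_min)],
      "time not a multiple of the frame interval")
  bad(s$cell_id[s$start_min > s$end_min | s$start_min < 0 | s$end_min > md],
      "segment times not ordered within [0, movie_duration]")
  for (d in split(s, s$cell_id)) {
    id <- d$cell_id[1L]
    if (any(d$segment_index != seq_len(nrow(d))))
      bad(id, "segment_index not 1..k")
    if (nrow(d) > 1L) {
      if (any(d$start_min[-1L] != d$end_min[-nrow(d)]))
        bad(id, "segments not contiguous")
      if (all(d$phase %in% FUCCI_PHASES)) {
        trans <- vapply(seq_len(nrow(d) - 1L), function(i)
          identical(.legal_next[[d$phase[i]]], d$phase[i + 1L]), logical(1L))
        if (!all(trans)) bad(id, "illegal phase order")
      }
    }
    term <- d$terminal_event
    if (!all(is.na(term[-nrow(d)])) || is.na(term[nrow(d)]))
      bad(id, "terminal event must sit on the last segment only")
    ev <- term[nrow(d)]
    if (!is.na(ev)) {
      if (ev == "DIVISION" && d$phase[nrow(d)] != "M")
        bad(id, "division must terminate an M segment")
      if (ev == "MOVIE_END" && d$end_min[nrow(d)] != md)
        bad(id, "MOVIE_END track must end at movie_duration")
    }
  }
  if (length(out) == 0L)
    return(data.frame(cell_id = character(), rule = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Read / write FUCCI tracks (long CSV)
#'
#' @param file path to a long-format CSV with the columns of
#'   [fucci_tracks()].
#' @param movie_duration,frame_interval movie metadata in minutes.
#' @return `parse_fucci_tracks`: a validated `fucci_tracks` object.
#' @export
parse_fucci_tracks <- function(file, movie_duration = 4320,
                               frame_interval = 10) {
  d <- read.csv(file, colClasses = "character", check.names = FALSE)
  missing <- setdiff(.track_cols, names(d))
  if (length(missing) > 0L)
    stop("FUCCI file lacks column(s): ", paste(missing, collapse = ", "))
  blank_na <- function(x) ifelse(x == "", NA_character_, x)
  d$parent_id <- blank_na(d$parent_id)
  d$terminal_event <- blank_na(d$terminal_event)
  fucci_tracks(d, movie_duration = movie_duration,
               frame_interval = frame_interval)
}

#' @rdname parse_fucci_tracks
#' @param tracks a `fucci_tracks` object.
#' @return `write_fucci_tracks`: `file`, invisibly.
#' @export
write_fucci_tracks <- function(tracks, file) {
  s <- as.data.frame(tracks)
  s$parent_id <- ifelse(is.na(s$parent_id), "", s$parent_id)
  s$terminal_event <- ifelse(is.na(s$terminal_event), "", s$terminal_event)
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE)
  s$start_min <- fmt(s$start_min); s$end_min <- fmt(s$end_min)
  write.table(s, file, sep = ",", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(file)
}

# last segment of every track, as a data.frame
.terminal_segments <- function(tracks) {
  s <- as.data.frame(tracks)
  last <- tapply(seq_len(nrow(s)), s$cell_id, function(i) i[which.max(s$segment_index[i])])
  s[unlist(last), ]
}

#' Fully observed phase lengths
#'
#' Lengths of a given phase for cells of a given generation, keeping only
#' phases observed in full: both boundaries inside the movie, not truncated
#' by death or movie end, and not birth-censored (generation-1 first
#' segments start mid-phase and are excluded).
#'
#' @param tracks validated `fucci_tracks`.
#' @param generation generation to analyze (2 for daughters of an observed
#'   division).
#' @param phase `"G1"` or `"SG2"`.
#' @return list with `samples` (minutes), `median`, `q25`, `q75`, `n`, and
#'   `n_excluded` (truncated or censored phases of that generation/phase).
#' @export
phase_lengths <- function(tracks, generation, phase = c("G1", "SG2")) {
  phase <- match.arg(phase)
  s <- as.data.frame(tracks)
  s <- s[s$generation == generation & s$phase == phase, ]
  truncated <- !is.na(s$terminal_event) &
    s$terminal_event %in% c("DEATH", "MOVIE_END")
  censored_birth <- s$generation == 1L & s$segment_index == 1L
  keep <- !truncated & !censored_birth
  x <- s$end_min[keep] - s$start_min[keep]
  list(samples = x, n = length(x),
       median = if (length(x)) median(x) else NA_real_,
       q25 = if (length(x)) unname(quantile(x, 0.25)) else NA_real_,
       q75 = if (length(x)) unname(quantile(x, 0.75)) else NA_real_,
       n_excluded = sum(!keep))
}

#' Distribution of deaths across cell-cycle phases
#'
#' Assigns every death to the phase containing it (boundary deaths belong to
#' the phase being entered, by track construction) and reports the
#' percentage of deaths per phase.
#'
#' @param tracks validated `fucci_tracks`.
#' @return `fate_distribution` over G1 / SG2 / M (percentages of all
#'   deaths); `n_total = 0` when no track dies.
#' @export
death_phase_distribution <- function(tracks) {
  term <- .terminal_segments(tracks)
  deaths <- term[!is.na(term$terminal_event) & term$terminal_event == "DEATH", ]
  counts <- table(factor(deaths$phase, levels = FUCCI_PHASES))
  n <- sum(counts)
  structure(list(counts = c(counts), n_total = n,
                 percent = if (n > 0) c(counts) / n * 100 else
                   setNames(rep(NA_real_, 3L), FUCCI_PHASES),
                 group = "death phase", per_replicate = NULL),
            class = "fate_distribution")
}

# tracks present at movie start, with their starting phase
.start_phase <- function(tracks) {
  s <- as.data.frame(tracks)
  first <- s[s$segment_index == 1L & s$start_min == 0, ]
  setNames(first$phase, first$cell_id)
}

#' Mitotic entry time by phase at movie start
#'
#' For cells present at time 0, the time the first M segment begins, grouped
#' by the phase the cell was in at movie start.  Cells born mid-movie are
#' not part of this analysis; cells that never reach mitosis are excluded
#' and counted.
#'
#' @param tracks validated `fucci_tracks`.
#' @return list with `samples` (`cell_id`, `group`, `entry_min`), per-group
#'   `summary` (median/IQR) and `exclusions`.
#' @export
entry_time_by_start_phase <- function(tracks) {
  sp <- .start_phase(tracks)
  s <- as.data.frame(tracks)
  s <- s[s$cell_id %in% names(sp) & s$phase == "M", ]
  entry <- tapply(s$start_min, s$cell_id, min)
  ids <- names(sp)[names(sp) %in% names(entry)]
  samples <- data.frame(cell_id = ids, group = unname(sp[ids]),
                        entry_min = unname(entry[ids]),
                        stringsAsFactors = FALSE)
  summary <- NULL
  if (nrow(samples) > 0L) {
    summary <- do.call(rbind, lapply(split(samples, samples$group), function(d)
      data.frame(group = d$group[1L], n = nrow(d),
                 median = median(d$entry_min),
                 q25 = unname(quantile(d$entry_min, 0.25)),
                 q75 = unname(quantile(d$entry_min, 0.75)),
                 stringsAsFactors = FALSE)))
    rownames(summary) <- NULL
  }
  list(samples = samples, summary = summary,
       exclusions = c(no_mitotic_entry = sum(!names(sp) %in% names(entry))))
}

#' Death vs survival by phase at movie start
#'
#' Contingency of the phase at movie start against dying during the movie
#' (pooled over the phase of death), with the two-sided Fisher exact test on
#' the G1 vs S/G2 rows.
#'
#' @param tracks validated `fucci_tracks`.
#' @return list with `contingency` (start phase x died/survived), `p_value`
#'   and `test_table` (the 2x2 used for the exact test, `NULL` when either
#'   start phase is absent).
#' @export
fate_by_start_phase <- function(tracks) {
  sp <- .start_phase(tracks)
  term <- .terminal_segments(tracks)
  term <- term[term$cell_id %in% names(sp), ]
  died <- ifelse(term$terminal_event == "DEATH", "died", "survived")
  start <- sp[term$cell_id]
  contingency <- table(factor(start, levels = FUCCI_PHASES),
                       factor(died, levels = c("died", "survived")))
  p <- NA_real_
  test_table <- NULL
  if (all(rowSums(contingency[c("G1", "SG2"), ]) > 0L)) {
    test_table <- contingency[c("G1", "SG2"), ]
    p <- fisher_exact_2x2(test_table)$p_value
  }
  list(contingency = contingency, p_value = p, test_table = test_table)
}
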