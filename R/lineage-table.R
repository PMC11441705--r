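#' @useDynLib centrofate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif rexp
#'   setNames sd chisq.test fisher.test pchisq cor.test aggregate
#' @importFrom utils read.csv write.table head
NULL

## Canonical vocabularies ----------------------------------------------------

#' Mitotic phenotype and fate vocabularies
#'
#' Canonical tokens for the behaviour of a cell during mitosis and for its
#' terminal fate, as annotated in long-term live imaging of dividing cells.
#' Bipolar divisions are split by the severity of chromosome mis-segregation
#' (none, slight = a single lagging chromosome / bridge / mis-alignment,
#' high = multiple concurrent errors); multipolar divisions, cytokinesis
#' failure and mitotic slippage complete the taxonomy.  Death during mitosis
#' aborts the division and is recorded as a fate, not a phenotype.
#'
#' @format Character vectors of tokens.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
MITOTIC_PHENOTYPES <- c("NO_MISSEG", "SLIGHT_MISSEG", "HIGH_MISSEG",
                        "MULTIPOLAR", "FAILED_CYTOKINESIS", "SLIPPAGE")

#' @rdname vocabularies
#' @export
CELL_FATES <- c("DIVIDED", "DEATH_INTERPHASE", "DEATH_MITOSIS", "ALIVE_AT_END")

# daughters each phenotype must produce (MULTIPOLAR checked as >= 3)
.expected_daughters <- c(NO_MISSEG = 2L, SLIGHT_MISSEG = 2L, HIGH_MISSEG = 2L,
                         FAILED_CYTOKINESIS = 1L, SLIPPAGE = 1L)

.record_cols <- c("condition", "replicate_id", "lineage_id", "cell_id",
                  "parent_id", "generation", "birth_time", "mitosis_start",
                  "end_time", "phenotype", "fate", "n_daughters")

## Constructor ----------------------------------------------------------------

#' Assemble a table of tracked cell lineages
#'
#' A lineage table is the central object of the live-imaging analyses: one row
#' per tracked cell, holding its parentage, generation, event times (minutes
#' from movie start, quantized to the frame interval), the mitotic phenotype of
#' its division (if it divided) and its terminal fate.  Roots are the cells
#' present at movie start; their birth is censored at time 0.
#'
#' @param records data.frame with columns `lineage_id`, `cell_id`, `parent_id`
#'   (`NA` for roots), `birth_time`, `mitosis_start` (`NA` if mitosis was never
#'   observed), `end_time`, `phenotype` (`NA` unless the cell divided), `fate`,
#'   `n_daughters`; optionally `condition`, `replicate_id` and `generation`
#'   (recomputed from parentage when absent).
#' @param movie_duration movie length in minutes.
#' @param frame_interval acquisition cadence in minutes.
#' @param condition,replicate_id defaults used when `records` lacks the
#'   corresponding columns.
#' @param check if `TRUE` (default) the invariants are enforced and any
#'   violation raises an error; use `FALSE` to build deliberately inconsistent
#'   tables for [validate_lineages()].
#' @return An object of class `lineage_table`: the records data.frame with
#'   attributes `movie_duration` and `frame_interval`.
#' @seealso [parse_event_log()], [validate_lineages()], [simulate_lineages()]
#' @export
lineage_table <- function(records, movie_duration = 4320, frame_interval = 10,
                          condition = "untreated", replicate_id = "R1",
                          check = TRUE) {
  stopifnot(is.data.frame(records), movie_duration > 0, frame_interval > 0)
  if (is.null(records$condition)) records$condition <- condition
  if (is.null(records$replicate_id)) records$replicate_id <- replicate_id
  for (col in c("lineage_id", "cell_id", "parent_id", "phenotype", "fate",
                "condition", "replicate_id"))
    records[[col]] <- as.character(records[[col]])
  for (col in c("birth_time", "mitosis_start", "end_time"))
    records[[col]] <- as.numeric(records[[col]])
  records$n_daughters <- as.integer(records$n_daughters)
  if (is.null(records$generation)) {
    records$generation <- .generations_from_parentage(records)
  } else {
    records$generation <- as.integer(records$generation)
  }
  records <- records[, .record_cols]
  rownames(records) <- NULL
  out <- structure(records, class = c("lineage_table", "data.frame"),
                   movie_duration = as.numeric(movie_duration),
                   frame_interval = as.numeric(frame_interval))
  if (check) {
    v <- validate_lineages(out)
    if (nrow(v) > 0L)
      stop("invalid lineage table: ",
           paste0(v$rule, " [", v$cell_id, "]", collapse = "; "))
  }
  out
}

#' @export
print.lineage_table <- function(x, ...) {
  cat(sprintf("<lineage_table> %d cells, %d lineages, movie %g min @ %g min/frame\n",
              nrow(x), length(unique(x$lineage_id)),
              attr(x, "movie_duration"), attr(x, "frame_interval")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# breadth-first generation numbering from parentage (roots = 1)
.generations_from_parentage <- function(records) {
  gen <- rep(NA_integer_, nrow(records))
  names(gen) <- records$cell_id
  parent <- records$parent_id
  gen[is.na(parent)] <- 1L
  g <- 1L
  while (anyNA(gen) && g <= nrow(records)) {
    this_gen <- names(gen)[!is.na(gen) & gen == g]
    child <- !is.na(parent) & parent %in% this_gen
    gen[child] <- g + 1L
    g <- g + 1L
  }
  unname(gen)
}

## Validation -----------------------------------------------------------------

#' Report invariant violations of a lineage table
#'
#' Checks the structural rules a consistent event log must satisfy: unique
#' ids, resolvable acyclic parentage with one root per lineage, ordered and
#' frame-quantized times, fate/daughter-count consistency and the
#' phenotype-specific daughter counts (bipolar phenotypes produce 2 daughters,
#' multipolar at least 3, cytokinesis failure and slippage exactly 1
#' continuing cell).
#'
#' @param table a `lineage_table` (possibly built with `check = FALSE`).
#' @return data.frame with columns `cell_id`, `rule`, `detail`; zero rows iff
#'   the table is consistent.
#' @export
validate_lineages <- function(table) {
  r <- as.data.frame(table)
  md <- attr(table, "movie_duration")
  fi <- attr(table, "frame_interval")
  out <- list()
  bad <- function(ids, rule, detail = "") {
    if (length(ids) > 0L)
      out[[length(out) + 1L]] <<- data.frame(cell_id = as.character(ids),
                                             rule = rule, detail = detail,
                                             stringsAsFactors = FALSE)
  }

  dup <- r$cell_id[duplicated(r$cell_id)]
  bad(unique(dup), "duplicate cell_id")
  bad(r$cell_id[!r$fate %in% CELL_FATES], "unknown fate token")
  bad(r$cell_id[!is.na(r$phenotype) & !r$phenotype %in% MITOTIC_PHENOTYPES],
      "unknown phenotype token")

  known <- r$parent_id %in% r$cell_id
  bad(r$cell_id[!is.na(r$parent_id) & !known], "parent_id not in table")

  # time ordering and quantization
  t_ok <- with(r, !is.na(birth_time) & !is.na(end_time) &
                 birth_time >= 0 & end_time <= md & birth_time <= end_time &
                 (is.na(mitosis_start) |
                    (mitosis_start >= birth_time & mitosis_start <= end_time)))
  bad(r$cell_id[!t_ok], "times not ordered within [0, movie_duration]")
  q <- function(x) !is.na(x) & abs(x / fi - round(x / fi)) > 1e-9
  bad(r$cell_id[q(r$birth_time) | q(r$end_time) | q(r$mitosis_start)],
      "time not a multiple of the frame interval")

  # fate vs daughter count
  bad(r$cell_id[r$fate == "DIVIDED" & r$n_daughters < 1L],
      "DIVIDED requires n_daughters >= 1")
  bad(r$cell_id[r$fate != "DIVIDED" & r$n_daughters != 0L],
      "non-divided cell with daughters")
  # phenotype vs daughter count, phenotype only on completed divisions
  bad(r$cell_id[!is.na(r$phenotype) & r$fate != "DIVIDED"],
      "phenotype recorded without completed division")
  ph <- r$phenotype
  exp_n <- .expected_daughters[ph]
  fixed <- !is.na(ph) & ph %in% names(.expected_daughters) & r$fate == "DIVIDED"
  exp_n[!fixed] <- -1L
  bad(r$cell_id[fixed & r$n_daughters != exp_n],
      "daughter count inconsistent with phenotype")
  bad(r$cell_id[!is.na(ph) & ph == "MULTIPOLAR" & r$fate == "DIVIDED" &
                  r$n_daughters < 3L],
      "MULTIPOLAR requires n_daughters >= 3")
  bad(r$cell_id[r$fate == "DEATH_MITOSIS" &
                  (is.na(r$mitosis_start) | !is.na(r$phenotype))],
      "DEATH_MITOSIS requires mitosis_start and no phenotype")

  # parent/daughter relations
  pidx <- match(r$parent_id, r$cell_id)
  has_p <- !is.na(pidx)
  bad(r$cell_id[has_p & r$generation != r$generation[pidx] + 1L],
      "generation is not parent generation + 1")
  bad(r$cell_id[has_p & r$birth_time != r$end_time[pidx]],
      "birth_time differs from parent end_time")
  bad(r$cell_id[has_p & r$lineage_id != r$lineage_id[pidx]],
      "lineage_id differs from parent's")
  n_obs <- table(factor(r$parent_id[has_p], levels = r$cell_id))
  mism <- r$fate == "DIVIDED" & as.integer(n_obs) != r$n_daughters
  bad(r$cell_id[mism], "observed daughters differ from n_daughters")

  # roots and acyclicity
  roots <- is.na(r$parent_id)
  bad(r$cell_id[roots & r$generation != 1L], "root generation must be 1")
  bad(r$cell_id[roots & r$birth_time != 0], "root birth_time must be 0")
  nroot <- tapply(roots, r$lineage_id, sum)
  bad(names(nroot)[nroot != 1L], "lineage must have exactly one root",
      "lineage_id reported in cell_id column")
  # cycle detection: follow parents at most n steps
  step <- pidx
  reached_root <- roots
  for (k in seq_len(nrow(r))) {
    if (all(reached_root | is.na(step))) break
    reached_root <- reached_root | (!is.na(step) & roots[step])
    step <- pidx[step]
  }
  bad(r$cell_id[!reached_root & has_p & known[seq_len(nrow(r))]],
      "parent chain does not reach a root (cycle)")

  if (length(out) == 0L)
    return(data.frame(cell_id = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## Event-log serialization ----------------------------------------------------

.log_header <- c("experiment_id", "condition", "replicate_id", "lineage_id",
                 "cell_id", "parent_id", "birth_time_min", "mitosis_start_min",
                 "end_time_min", "mitotic_phenotype", "fate", "n_daughters")

#' Read an annotated event log
#'
#' Parses the comma-separated event-log format produced by manual annotation
#' of time-lapse movies (one row per tracked cell) into a validated
#' [lineage_table()].  Generations are recomputed from parentage; if the file
#' carries a `generation` column it is checked against the recomputation.
#'
#' @param file path or connection to a CSV event log.
#' @param movie_duration,frame_interval movie metadata in minutes.
#' @return A validated `lineage_table`.
#' @export
parse_event_log <- function(file, movie_duration = 4320, frame_interval = 10) {
  d <- read.csv(file, colClasses = "character", check.names = FALSE)
  missing <- setdiff(setdiff(.log_header, "experiment_id"), names(d))
  if (length(missing) > 0L)
    stop("event log lacks required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(d$cell_id))
    stop("duplicate cell_id in event log: ",
         paste(unique(d$cell_id[duplicated(d$cell_id)]), collapse = ", "))
  blank_na <- function(x) ifelse(x == "", NA_character_, x)
  num <- function(x) as.numeric(blank_na(x))
  records <- data.frame(
    condition = d$condition, replicate_id = d$replicate_id,
    lineage_id = d$lineage_id, cell_id = d$cell_id,
    parent_id = blank_na(d$parent_id),
    birth_time = num(d$birth_time_min),
    mitosis_start = num(d$mitosis_start_min),
    end_time = num(d$end_time_min),
    phenotype = blank_na(d$mitotic_phenotype),
    fate = d$fate, n_daughters = as.integer(d$n_daughters),
    stringsAsFactors = FALSE)
  gen <- .generations_from_parentage(records)
  if (!is.null(d$generation)) {
    claimed <- as.integer(d$generation)
    if (any(claimed != gen, na.rm = TRUE))
      stop("generation column disagrees with parentage for cell(s): ",
           paste(d$cell_id[which(claimed != gen)], collapse = ", "))
  }
  records$generation <- gen
  lineage_table(records, movie_duration = movie_duration,
                frame_interval = frame_interval)
}

#' Write an event log in canonical form
#'
#' Serializes a lineage table to the canonical CSV column order with empty
#' fields for absent values, so that `write_event_log(parse_event_log(f))`
#' reproduces `f` byte for byte for canonical files.
#'
#' @param table a `lineage_table`.
#' @param file output path.
#' @param experiment_id token written in the `experiment_id` column.
#' @return `file`, invisibly.
#' @export
write_event_log <- function(table, file, experiment_id = "EXP1") {
  r <- as.data.frame(table)
  fmt_t <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                   scientific = FALSE))
  out <- data.frame(
    experiment_id = experiment_id, condition = r$condition,
    replicate_id = r$replicate_id, lineage_id = r$lineage_id,
    cell_id = r$cell_id,
    parent_id = ifelse(is.na(r$parent_id), "", r$parent_id),
    birth_time_min = fmt_t(r$birth_time),
    mitosis_start_min = fmt_t(r$mitosis_start),
    end_time_min = fmt_t(r$end_time),
    mitotic_phenotype = ifelse(is.na(r$phenotype), "", r$phenotype),
    fate = r$fate, n_daughters = r$n_daughters,
    stringsAsFactors = FALSE)
  write.table(out, file, sep = ",", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(file)
}
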