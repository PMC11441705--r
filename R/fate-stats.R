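## Headline lineage analyses: per-lineage fate counts, generation fate
## percentages, mother-mitosis x progeny-fate cross-tabulation, durations,
## mitotic entry timing, and the exact/chi-square tests used to compare
## conditions.

.fate_factor <- function(x) factor(x, levels = CELL_FATES)

.sem <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))

#' Per-lineage fate counts
#'
#' For each starting cell (lineage root), counts how many cells of its tree
#' adopt each fate; every cell, the root included, contributes its own fate
#' exactly once.  The summary reports the mean number of cells per lineage
#' adopting each fate, with the SEM taken across replicates when at least two
#' `replicate_id`s are present and across lineages otherwise.
#'
#' @param table a validated `lineage_table`.
#' @return list with `per_lineage` (one row per root: counts per fate and
#'   lineage size), `summary` (per fate: mean, sem, basis of the SEM) and
#'   `sem_basis`.
#' @export
lineage_fate_counts <- function(table) {
  r <- as.data.frame(table)
  if (nrow(r) == 0L) stop("empty lineage table")
  tab <- table(r$lineage_id, .fate_factor(r$fate))
  per <- data.frame(lineage_id = rownames(tab),
                    replicate_id = r$replicate_id[match(rownames(tab),
                                                        r$lineage_id)],
                    as.data.frame.matrix(tab), check.names = FALSE,
                    stringsAsFactors = FALSE)
  per$n_cells <- rowSums(tab)
  rownames(per) <- NULL

  reps <- unique(per$replicate_id)
  basis <- if (length(reps) >= 2L) "replicates" else "lineages"
  summ <- do.call(rbind, lapply(CELL_FATES, function(f) {
    if (basis == "replicates") {
      v <- tapply(per[[f]], per$replicate_id, mean)
    } else {
      v <- per[[f]]
    }
    data.frame(fate = f, mean = mean(v), sem = .sem(as.numeric(v)),
               stringsAsFactors = FALSE)
  }))
  list(per_lineage = per, summary = summ, sem_basis = basis)
}

#' Fate percentages within one generation
#'
#' Percentage of the cells of a given generation adopting each fate; cells
#' still alive at movie end are part of the denominator.
#'
#' @param table a validated `lineage_table`.
#' @param generation generation number (roots = 1).
#' @return list of class `fate_distribution` with `counts`, `percent` (named
#'   by fate, summing to 100), `n_total`, `group`, and per-replicate
#'   percentages with mean/SEM when at least two replicates are present.
#' @export
generation_fate_percent <- function(table, generation) {
  r <- as.data.frame(table)
  gens <- sort(unique(r$generation))
  if (!generation %in% gens)
    stop("generation ", generation, " absent; available: ",
         paste(gens, collapse = ", "))
  g <- r[r$generation == generation, ]
  counts <- table(.fate_factor(g$fate))
  n <- sum(counts)
  reps <- unique(g$replicate_id)
  per_rep <- NULL
  if (length(reps) >= 2L) {
    m <- prop.table(table(g$replicate_id, .fate_factor(g$fate)), 1L) * 100
    per_rep <- list(percent = as.data.frame.matrix(m),
                    mean = colMeans(m),
                    sem = apply(m, 2L, .sem))
  }
  structure(list(counts = c(counts), n_total = n,
                 percent = c(counts) / n * 100,
                 group = paste0("generation ", generation),
                 per_replicate = per_rep),
            class = "fate_distribution")
}

#' @export
print.fate_distribution <- function(x, ...) {
  cat(sprintf("<fate_distribution> %s (n = %d)\n", x$group, x$n_total))
  print(round(x$percent, 2L))
  invisible(x)
}

#' Mother mitosis vs progeny fate cross-tabulation
#'
#' Correlates the behaviour of a mother cell during mitosis with the fate of
#' its progeny.  The marginal distribution is the frequency of each mitotic
#' phenotype among divisions, with death in mitosis kept as its own marginal
#' class (it leaves no progeny, so it has no conditional row).  Each
#' phenotype's conditional row is the fate distribution of the daughters of
#' mothers showing that phenotype; daughters censored by the movie end count
#' as `ALIVE_AT_END`.  Because the marginal basis of the published bar widths
#' is ambiguous, frequencies among divisions and among progeny are both
#' reported.
#'
#' @param table a validated `lineage_table`.
#' @param mother_generation optional; restrict to mothers of this generation
#'   (e.g. 1 for the first observed mitosis of each lineage).
#' @return list of class `mitosis_fate_crosstab` with `marginal` (per
#'   phenotype class: number of mothers, frequency among divisions, frequency
#'   weighted by progeny), `rows` (per completed-division phenotype: daughter
#'   fate proportions summing to 1, and n), `n_divisions`, `n_progeny`.
#' @export
mitosis_fate_crosstab <- function(table, mother_generation = NULL) {
  r <- as.data.frame(table)
  mothers <- r[r$fate %in% c("DIVIDED", "DEATH_MITOSIS"), ]
  if (!is.null(mother_generation))
    mothers <- mothers[mothers$generation %in% mother_generation, ]
  classes <- c(MITOTIC_PHENOTYPES, "DEATH_MITOSIS")
  if (nrow(mothers) == 0L) {
    return(structure(list(
      marginal = data.frame(class = classes, n_mothers = 0L,
                            freq_divisions = NA_real_, freq_progeny = NA_real_,
                            stringsAsFactors = FALSE),
      rows = NULL, n_divisions = 0L, n_progeny = 0L),
      class = "mitosis_fate_crosstab"))
  }
  cls <- ifelse(mothers$fate == "DEATH_MITOSIS", "DEATH_MITOSIS",
                mothers$phenotype)
  n_div <- nrow(mothers)
  n_m <- table(factor(cls, levels = classes))
  prog <- tapply(mothers$n_daughters, factor(cls, levels = classes), sum)
  prog[is.na(prog)] <- 0L
  marginal <- data.frame(class = classes, n_mothers = as.integer(n_m),
                         freq_divisions = as.integer(n_m) / n_div,
                         freq_progeny = as.numeric(prog) / sum(prog),
                         stringsAsFactors = FALSE)

  daughters <- r[!is.na(r$parent_id) & r$parent_id %in% mothers$cell_id, ]
  rows <- NULL
  if (nrow(daughters) > 0L) {
    mother_cls <- cls[match(daughters$parent_id, mothers$cell_id)]
    tab <- table(factor(mother_cls, levels = MITOTIC_PHENOTYPES),
                 .fate_factor(daughters$fate))
    keep <- rowSums(tab) > 0L
    prop <- prop.table(tab[keep, , drop = FALSE], 1L)
    rows <- data.frame(phenotype = rownames(prop),
                       as.data.frame.matrix(prop),
                       n_daughters = rowSums(tab[keep, , drop = FALSE]),
                       check.names = FALSE, stringsAsFactors = FALSE)
    rownames(rows) <- NULL
  }
  structure(list(marginal = marginal, rows = rows, n_divisions = n_div,
                 n_progeny = as.integer(sum(prog))),
            class = "mitosis_fate_crosstab")
}

#' @export
print.mitosis_fate_crosstab <- function(x, ...) {
  cat(sprintf("<mitosis_fate_crosstab> %d divisions, %d progeny\n",
              x$n_divisions, x$n_progeny))
  print(x$marginal)
  if (!is.null(x$rows)) print(x$rows)
  invisible(x)
}

#' Interphase and mitosis durations
#'
#' Interphase length is `mitosis_start - birth_time`, defined only for
#' non-root cells (roots are birth-censored) that were observed entering
#' mitosis.  Mitosis length is `end_time - mitosis_start` for cells that
#' completed division or died in mitosis; cells censored by the movie end
#' while in mitosis are excluded.  Summaries report the median and
#' interquartile range per condition.
#'
#' @param table a validated `lineage_table`.
#' @return list with `interphase` and `mitosis` sample data.frames
#'   (`cell_id`, `condition`, `minutes`), per-condition `summary`
#'   (median/IQR), and an `exclusions` count table.
#' @export
durations <- function(table) {
  r <- as.data.frame(table)
  ip_ok <- !is.na(r$parent_id) & !is.na(r$mitosis_start)
  interphase <- data.frame(cell_id = r$cell_id[ip_ok],
                           condition = r$condition[ip_ok],
                           minutes = r$mitosis_start[ip_ok] - r$birth_time[ip_ok],
                           stringsAsFactors = FALSE)
  mi_ok <- r$fate %in% c("DIVIDED", "DEATH_MITOSIS") & !is.na(r$mitosis_start)
  mitosis <- data.frame(cell_id = r$cell_id[mi_ok],
                        condition = r$condition[mi_ok],
                        minutes = r$end_time[mi_ok] - r$mitosis_start[mi_ok],
                        stringsAsFactors = FALSE)
  summarize <- function(d) {
    if (nrow(d) == 0L) return(NULL)
    do.call(rbind, lapply(split(d, d$condition), function(s)
      data.frame(condition = s$condition[1L], n = nrow(s),
                 median = median(s$minutes),
                 q25 = unname(quantile(s$minutes, 0.25)),
                 q75 = unname(quantile(s$minutes, 0.75)),
                 stringsAsFactors = FALSE)))
  }
  list(interphase = interphase, mitosis = mitosis,
       summary = list(interphase = summarize(interphase),
                      mitosis = summarize(mitosis)),
       exclusions = c(
         interphase_root_censored = sum(is.na(r$parent_id)),
         interphase_no_mitosis = sum(!is.na(r$parent_id) & is.na(r$mitosis_start)),
         mitosis_censored_or_absent = sum(!mi_ok)))
}

#' Time of mitotic entry by mitotic phenotype
#'
#' Extracts, for first-generation cells, the time at which they entered
#' their (first) mitosis, grouped by the phenotype of that mitosis; death in
#' mitosis forms its own group.  Cells that never entered mitosis, or whose
#' mitosis was cut short by the movie end before resolving, are excluded and
#' counted.
#'
#' @param table a validated `lineage_table`.
#' @return list with `samples` (`cell_id`, `group`, `entry_min`), per-group
#'   `summary` (median/IQR) and `exclusions`.
#' @export
mitotic_entry_times <- function(table) {
  r <- as.data.frame(table)
  g1 <- r[r$generation == 1L, ]
  resolved <- !is.na(g1$mitosis_start) &
    g1$fate %in% c("DIVIDED", "DEATH_MITOSIS")
  s <- g1[resolved, ]
  grp <- ifelse(s$fate == "DEATH_MITOSIS", "DEATH_MITOSIS", s$phenotype)
  samples <- data.frame(cell_id = s$cell_id, group = grp,
                        entry_min = s$mitosis_start, stringsAsFactors = FALSE)
  summary <- NULL
  if (nrow(samples) > 0L)
    summary <- do.call(rbind, lapply(split(samples, samples$group), function(d)
      data.frame(group = d$group[1L], n = nrow(d),
                 median = median(d$entry_min),
                 q25 = unname(quantile(d$entry_min, 0.25)),
                 q75 = unname(quantile(d$entry_min, 0.75)),
                 stringsAsFactors = FALSE)))
  if (!is.null(summary)) rownames(summary) <- NULL
  list(samples = samples, summary = summary,
       exclusions = c(no_mitotic_entry = sum(is.na(g1$mitosis_start)),
                      unresolved_mitosis = sum(!is.na(g1$mitosis_start) &
                                                 !resolved)))
}

## Condition-comparison tests -------------------------------------------------

#' Two-sided Fisher exact test of a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities not
#' exceeding that of the observed table (the minimum-likelihood convention,
#' ties included).  A table with a zero margin is reported as degenerate with
#' p = 1.
#'
#' @param m 2x2 integer matrix.
#' @return list with `p_value`, `table`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0))
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  p <- if (degenerate) 1 else fisher.test(m, alternative = "two.sided")$p.value
  list(p_value = min(p, 1), table = m, degenerate = degenerate)
}

#' Fisher exact test on pooled cell-death counts
#'
#' Compares two conditions on the number of cell death events, pooling death
#' in interphase and death in mitosis, against all other cells.  Counts are
#' per cell, not per lineage.
#'
#' @param table_a,table_b validated `lineage_table`s for the two conditions.
#' @param labels length-2 condition labels for the output table.
#' @return list with the 2x2 `table` (died / not died x condition),
#'   `p_value` and `degenerate` flag.
#' @export
fisher_pooled_death <- function(table_a, table_b,
                                labels = c("A", "B")) {
  count <- function(t) {
    f <- as.data.frame(t)$fate
    if (length(f) == 0L) stop("empty lineage table")
    c(died = sum(f %in% c("DEATH_INTERPHASE", "DEATH_MITOSIS")),
      not_died = sum(!f %in% c("DEATH_INTERPHASE", "DEATH_MITOSIS")))
  }
  m <- cbind(count(table_a), count(table_b))
  colnames(m) <- labels
  res <- fisher_exact_2x2(m)
  res
}

#' Chi-square comparison of mitotic phenotype spectra
#'
#' Pearson chi-square test (no continuity correction) of the phenotype x
#' condition contingency table built from completed divisions plus death in
#' mitosis; classes empty in both conditions are dropped.
#'
#' @param table_a,table_b validated `lineage_table`s.
#' @return list with `statistic`, `df`, `p_value` and the counts `table`.
#' @export
chi_square_phenotypes <- function(table_a, table_b) {
  classes <- c(MITOTIC_PHENOTYPES, "DEATH_MITOSIS")
  count <- function(t) {
    r <- as.data.frame(t)
    m <- r[r$fate %in% c("DIVIDED", "DEATH_MITOSIS"), ]
    cls <- ifelse(m$fate == "DEATH_MITOSIS", "DEATH_MITOSIS", m$phenotype)
    table(factor(cls, levels = classes))
  }
  m <- cbind(A = count(table_a), B = count(table_b))
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("fewer than 2 non-empty phenotype classes")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = m)
}

#' Per-cell time-coded state matrix
#'
#' One row per cell, one column per movie frame; each entry codes the state
#' of the cell during that frame: `PRE` before birth, `INTER` in interphase,
#' `MIT:<phenotype>` in a mitosis that completed with the given phenotype
#' (`MIT` when the outcome was death in mitosis or censoring), `DEAD` from
#' the death frame onward, and `GONE` after a completed division (the
#' daughters take over).  Rows are ordered by lineage, generation, birth
#' time, then cell id.
#'
#' @param table a validated `lineage_table`.
#' @return character matrix with cell ids as row names.
#' @export
profile_matrix <- function(table) {
  r <- as.data.frame(table)
  fi <- attr(table, "frame_interval")
  nf <- as.integer(round(attr(table, "movie_duration") / fi))
  ord <- order(r$lineage_id, r$generation, r$birth_time, r$cell_id)
  r <- r[ord, ]
  m <- matrix("PRE", nrow = nrow(r), ncol = nf,
              dimnames = list(r$cell_id, NULL))
  frame <- function(t) as.integer(round(t / fi))
  for (i in seq_len(nrow(r))) {
    b <- frame(r$birth_time[i]); e <- frame(r$end_time[i])
    ms <- if (is.na(r$mitosis_start[i])) e else frame(r$mitosis_start[i])
    if (ms > b) m[i, (b + 1L):ms] <- "INTER"
    if (e > ms) {
      code <- if (!is.na(r$phenotype[i])) paste0("MIT:", r$phenotype[i]) else "MIT"
      m[i, (ms + 1L):e] <- code
    }
    if (e < nf) {
      after <- if (r$fate[i] %in% c("DEATH_INTERPHASE", "DEATH_MITOSIS"))
        "DEAD" else "GONE"
      m[i, (e + 1L):nf] <- after
    }
  }
  m
}
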