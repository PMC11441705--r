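## Seeded generators producing inputs with the statistical structure each
## analysis assumes: branching lineages with condition- and
## phenotype-dependent death and movie-end censoring, FUCCI phase tracks
## with drug-induced S/G2 lengthening, per-division chromosome
## mis-segregation, a cohort whose relapse hazard depends on the CNR group,
## and spot images with known focus counts.  Every generator is a pure
## function of its configuration (seed included).

.default_config <- function() {
  list(
    seed = 1L,
    movie_duration_min = 4320,
    frame_interval_min = 10,
    lineage = list(
      n_lineages = 20L,
      # interphase length (minutes); lognormal around a 20 h median
      cycle_length = list(family = "lognormal", meanlog = log(1200),
                          sdlog = 0.15),
      mitosis_length = list(family = "fixed", value = 40),
      phenotype_probabilities = c(NO_MISSEG = 0.55, SLIGHT_MISSEG = 0.25,
                                  HIGH_MISSEG = 0.10, MULTIPOLAR = 0.05,
                                  FAILED_CYTOKINESIS = 0.025, SLIPPAGE = 0.025),
      phenotype_probabilities_late = NULL,  # optional switch after t_switch
      t_switch_min = 1440,
      death_in_mitosis_probability = 0.02,
      daughter_death_probability = c(NO_MISSEG = 0.12, SLIGHT_MISSEG = 0.20,
                                     HIGH_MISSEG = 0.45, MULTIPOLAR = 0.50,
                                     FAILED_CYTOKINESIS = 0.30,
                                     SLIPPAGE = 0.30),
      root_death_probability = 0.05,
      multipolar_daughter_probabilities = c(`3` = 0.8, `4` = 0.2),
      condition = "simulated", replicate_id = "R1"
    ),
    fucci = list(
      n_tracks = 200L,
      g1_min = 480, sg2_min = 720, m_min = 60,
      sg2_extension_g1_start = 0,  # drug-induced S/G2 lengthening (min)
      death_probability = 0.10,
      death_phase_weights = c(G1 = 0.1, SG2 = 0.8, M = 0.1),
      generations = 2L
    ),
    karyotype = list(
      n_cells = 20L, n_chromosomes = 22L, bins_per_chromosome = 5L,
      bin_width_range = c(5e5, 1.5e6),
      missegregation_probability = 0.05, generations = 3L,
      expected_ploidy = 2,
      mean_total_reads = 60000
    ),
    cohort = list(
      n_samples = 88L, p_high = 33 / 88,
      cnr_low_mean = 1.20, cnr_high_mean = 1.70, cnr_sd = 0.08,
      changepoint = 1.45,
      fields_per_sample = 10L, nuclei_per_field = 50,
      relapse_rate_low = log(2) / 12,  # per month; 12-month median, low CNR
      hazard_ratio = 0.5,              # high vs low CNR relapse hazard
      os_rate_low = log(2) / 30, os_hazard_ratio = 0.5,
      censoring_rate = 0.01, followup_months = 120
    ),
    image = list(
      size = 96L, n_spots = 25L, amplitude = 80, background = 10,
      noise_sd = 3, sigma = 2, n_slices = 3L,
      slice_weights = c(0.6, 1, 0.6)
    )
  )
}

#' Simulation configuration
#'
#' Builds the parameter object shared by all synthetic-data generators.  A
#' single global seed drives every generator through deterministically
#' derived sub-streams, so adding one generator never perturbs the output of
#' another.  Component lists (`lineage`, `fucci`, `karyotype`, `cohort`,
#' `image`) are merged over documented defaults; see the package vignette
#' for what each default emulates.
#'
#' @param seed integer global seed.
#' @param movie_duration_min,frame_interval_min movie metadata shared by the
#'   lineage and FUCCI generators.
#' @param lineage,fucci,karyotype,cohort,image named lists overriding the
#'   per-generator defaults.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, movie_duration_min = 4320,
                              frame_interval_min = 10,
                              lineage = list(), fucci = list(),
                              karyotype = list(), cohort = list(),
                              image = list()) {
  cfg <- .default_config()
  cfg$seed <- as.integer(seed)
  cfg$movie_duration_min <- movie_duration_min
  cfg$frame_interval_min <- frame_interval_min
  merge1 <- function(base, over) {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown) > 0L)
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    base[names(over)] <- over
    base
  }
  cfg$lineage <- merge1(cfg$lineage, lineage)
  cfg$fucci <- merge1(cfg$fucci, fucci)
  cfg$karyotype <- merge1(cfg$karyotype, karyotype)
  cfg$cohort <- merge1(cfg$cohort, cohort)
  cfg$image <- merge1(cfg$image, image)
  .validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_config <- function(cfg) {
  chk_prob <- function(p, what) {
    if (any(p < 0 | p > 1))
      stop(what, " must lie in [0, 1]")
  }
  chk_simplex <- function(p, what) {
    chk_prob(p, what)
    if (abs(sum(p) - 1) > 1e-9)
      stop(what, " must sum to 1")
  }
  ln <- cfg$lineage
  chk_simplex(ln$phenotype_probabilities, "phenotype_probabilities")
  if (!is.null(ln$phenotype_probabilities_late))
    chk_simplex(ln$phenotype_probabilities_late,
                "phenotype_probabilities_late")
  chk_prob(ln$daughter_death_probability, "daughter_death_probability")
  chk_prob(ln$death_in_mitosis_probability, "death_in_mitosis_probability")
  chk_prob(ln$root_death_probability, "root_death_probability")
  chk_simplex(ln$multipolar_daughter_probabilities,
              "multipolar_daughter_probabilities")
  if (!all(names(ln$phenotype_probabilities) %in% MITOTIC_PHENOTYPES))
    stop("phenotype_probabilities must be named by mitotic phenotype")
  chk_prob(cfg$fucci$death_probability, "fucci death_probability")
  chk_simplex(cfg$fucci$death_phase_weights / sum(cfg$fucci$death_phase_weights),
              "death_phase_weights")
  if (any(c(cfg$fucci$g1_min, cfg$fucci$sg2_min, cfg$fucci$m_min) <= 0))
    stop("FUCCI phase durations must be positive")
  chk_prob(cfg$karyotype$missegregation_probability,
           "missegregation_probability")
  chk_prob(cfg$cohort$p_high, "p_high")
  if (cfg$movie_duration_min <= 0 || cfg$frame_interval_min <= 0)
    stop("movie duration and frame interval must be positive")
  invisible(cfg)
}

# deterministic sub-stream seed for generator i (1 = lineages, 2 = fucci,
# 3 = karyotype, 4 = cohort, 5 = image)
.substream_seed <- function(config, i) {
  set.seed(config$seed)
  sample.int(2147483646L, 8L)[i]
}

.quantize <- function(x, fi, min_frames = 1L) {
  pmax(round(x / fi), min_frames) * fi
}

.draw_duration <- function(n, spec, fi, min_frames = 1L) {
  x <- switch(spec$family,
              fixed = rep(spec$value, n),
              lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
              uniform = runif(n, spec$min, spec$max),
              stop("unknown duration family: ", spec$family))
  .quantize(x, fi, min_frames)
}

## Lineages -------------------------------------------------------------------

#' Simulate annotated cell lineages
#'
#' Discrete-time branching process emulating manually annotated time-lapse
#' event logs.  Each cell draws an interphase length from the configured
#' distribution; a cell destined to die in interphase dies at a uniformly
#' drawn frame within that interphase.  At mitotic entry the cell may die in
#' mitosis; otherwise it completes division with a mitotic phenotype drawn
#' from the configured categorical distribution, which may switch after
#' `t_switch_min` to emulate damage-dependent mis-segregation arising only
#' after prolonged drug exposure.  Daughter counts follow the phenotype
#' (bipolar = 2, multipolar = 3-4, cytokinesis failure / slippage = 1
#' continuing cell) and each daughter independently inherits a death
#' probability conditional on its mother's phenotype.  All cells are
#' truncated at the movie end as `ALIVE_AT_END`.
#'
#' @param config a [simulation_config()].
#' @return A validated [lineage_table()].
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream_seed(config, 1L))
  ln <- config$lineage
  md <- config$movie_duration_min
  fi <- config$frame_interval_min

  draw_phenotype <- function(t_mitosis) {
    p <- ln$phenotype_probabilities
    if (!is.null(ln$phenotype_probabilities_late) &&
        t_mitosis >= ln$t_switch_min)
      p <- ln$phenotype_probabilities_late
    sample(names(p), 1L, prob = p)
  }
  n_daughters_for <- function(ph) {
    switch(ph,
           MULTIPOLAR = as.integer(sample(
             names(ln$multipolar_daughter_probabilities), 1L,
             prob = ln$multipolar_daughter_probabilities)),
           FAILED_CYTOKINESIS = 1L, SLIPPAGE = 1L, 2L)
  }
  uniform_frame <- function(from, to) {
    # a frame time drawn uniformly from {from + fi, ..., to}
    k <- as.integer(round((to - from) / fi))
    from + sample.int(k, 1L) * fi
  }

  rows <- vector("list", 4096L)
  nrow_used <- 0L
  push <- function(row) {
    nrow_used <<- nrow_used + 1L
    if (nrow_used > length(rows)) length(rows) <<- 2L * length(rows)
    rows[[nrow_used]] <<- row
  }

  for (l in seq_len(ln$n_lineages)) {
    lid <- sprintf("L%04d", l)
    # queue entries: cell id path, birth, generation, death prob at birth
    queue <- list(list(id = paste0(lid, ".1"), birth = 0, gen = 1L,
                       p_death = ln$root_death_probability))
    while (length(queue) > 0L) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      interphase <- .draw_duration(1L, ln$cycle_length, fi, min_frames = 2L)
      m_len <- .draw_duration(1L, ln$mitosis_length, fi)
      t_mit <- cell$birth + interphase
      dies <- runif(1L) < cell$p_death
      death_time <- if (dies) uniform_frame(cell$birth, t_mit) else Inf

      if (dies && death_time <= md && death_time <= t_mit) {
        push(list(lid, cell$id, NA_character_, cell$gen, cell$birth,
                  NA_real_, death_time, NA_character_, "DEATH_INTERPHASE", 0L))
        next
      }
      if (t_mit >= md) {  # never reached mitosis on film
        push(list(lid, cell$id, NA_character_, cell$gen, cell$birth,
                  NA_real_, md, NA_character_, "ALIVE_AT_END", 0L))
        next
      }
      t_end <- t_mit + m_len
      if (t_end > md) {  # censored while in mitosis
        push(list(lid, cell$id, NA_character_, cell$gen, cell$birth,
                  t_mit, md, NA_character_, "ALIVE_AT_END", 0L))
        next
      }
      if (runif(1L) < ln$death_in_mitosis_probability) {
        d <- uniform_frame(t_mit, t_end)
        push(list(lid, cell$id, NA_character_, cell$gen, cell$birth,
                  t_mit, d, NA_character_, "DEATH_MITOSIS", 0L))
        next
      }
      ph <- draw_phenotype(t_mit)
      nd <- n_daughters_for(ph)
      push(list(lid, cell$id, NA_character_, cell$gen, cell$birth,
                t_mit, t_end, ph, "DIVIDED", nd))
      for (d in seq_len(nd)) {
        queue[[length(queue) + 1L]] <- list(
          id = paste0(cell$id, ".", d), birth = t_end,
          gen = cell$gen + 1L,
          p_death = ln$daughter_death_probability[[ph]])
      }
    }
  }

  rows <- rows[seq_len(nrow_used)]
  records <- data.frame(
    lineage_id = vapply(rows, `[[`, "", 1L),
    cell_id = vapply(rows, `[[`, "", 2L),
    parent_id = NA_character_,
    generation = vapply(rows, `[[`, 0L, 4L),
    birth_time = vapply(rows, `[[`, 0, 5L),
    mitosis_start = vapply(rows, function(r) as.numeric(r[[6L]]), 0),
    end_time = vapply(rows, `[[`, 0, 7L),
    phenotype = vapply(rows, function(r) as.character(r[[8L]]), ""),
    fate = vapply(rows, `[[`, "", 9L),
    n_daughters = vapply(rows, `[[`, 0L, 10L),
    stringsAsFactors = FALSE)
  # parent of "L0001.1.2" is "L0001.1"
  records$parent_id <- sub("\\.[0-9]+$", "", records$cell_id)
  records$parent_id[records$generation == 1L] <- NA_character_
  ord <- order(records$lineage_id, records$generation, records$birth_time,
               records$cell_id)
  records <- records[ord, ]
  lineage_table(records, movie_duration = md, frame_interval = fi,
                condition = ln$condition, replicate_id = ln$replicate_id)
}

## FUCCI ----------------------------------------------------------------------

#' Simulate FUCCI phase tracks
#'
#' Generates first-generation tracks starting at time 0 somewhere inside G1
#' or S/G2 (start-phase occupancy proportional to the programmed phase
#' durations) and, optionally, the second-generation daughters of observed
#' divisions.  Cells in G1 at movie start traverse S phase under the drug
#' and receive the configured S/G2 extension; deaths are placed in a phase
#' drawn from the configured weights, at a uniform frame within that phase.
#'
#' @param config a [simulation_config()].
#' @return A validated [fucci_tracks()] object.
#' @export
simulate_fucci <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream_seed(config, 2L))
  fc <- config$fucci
  md <- config$movie_duration_min
  fi <- config$frame_interval_min
  g1 <- .quantize(fc$g1_min, fi)
  sg2 <- .quantize(fc$sg2_min, fi)
  ext <- .quantize(fc$sg2_extension_g1_start, fi, min_frames = 0L)
  m <- .quantize(fc$m_min, fi)

  segs <- list()
  add_cell <- function(id, lineage, parent, gen, bounds) {
    # bounds: data.frame(phase, start, end) already clipped/terminated
    n <- nrow(bounds)
    segs[[length(segs) + 1L]] <<- data.frame(
      cell_id = id, lineage_id = lineage, parent_id = parent,
      generation = gen, segment_index = seq_len(n), phase = bounds$phase,
      start_min = bounds$start, end_min = bounds$end,
      terminal_event = c(rep(NA_character_, n - 1L), bounds$event[n]),
      stringsAsFactors = FALSE)
  }

  # build one cell's segments from phase durations starting at t0 with an
  # offset already consumed in the first phase
  build_cell <- function(t0, phases, durations) {
    start <- t0 + c(0, cumsum(durations))[seq_along(durations)]
    end <- t0 + cumsum(durations)
    data.frame(phase = phases, start = start, end = end,
               event = NA_character_, stringsAsFactors = FALSE)
  }

  # death/censoring post-processing: truncate at movie end; maybe kill.
  # the death phase is drawn from the configured weights, renormalized over
  # the phases the track actually contains; the death time is uniform on the
  # frame grid within that phase (a draw landing on the phase boundary is
  # encoded as a zero-length segment of the entered phase, the tie rule of
  # the analysis module).  a death falling beyond the movie end is not
  # observed and the track is censored instead.
  finalize <- function(b, dies) {
    b$event <- NA_character_
    if (dies) {
      w <- fc$death_phase_weights[b$phase]
      if (sum(w) > 0) {
        k <- sample.int(nrow(b), 1L, prob = w)
        span <- as.integer(round((b$end[k] - b$start[k]) / fi))
        death <- b$start[k] + sample.int(max(span, 1L), 1L) * fi
        if (death >= b$end[k] && k < nrow(b)) {
          k <- k + 1L                      # boundary: entered phase
          death <- b$start[k]
        }
        if (death <= md) {
          b <- b[seq_len(k), ]
          b$end[k] <- death
          b$event[k] <- "DEATH"
          return(b)
        }
      }
    }
    if (b$end[nrow(b)] <= md) {
      b$event[nrow(b)] <- "DIVISION"
      return(b)
    }
    keep <- b$start < md
    b <- b[keep, ]
    b$end[nrow(b)] <- md
    b$event[nrow(b)] <- "MOVIE_END"
    b
  }

  cycle_total <- g1 + sg2
  counter <- 0L
  for (i in seq_len(fc$n_tracks)) {
    counter <- counter + 1L
    lid <- sprintf("F%04d", i)
    id <- paste0(lid, ".1")
    # uniform position within G1 + S/G2 on the frame grid
    off <- (sample.int(cycle_total / fi, 1L) - 1L) * fi
    if (off < g1) {
      b <- build_cell(0, c("G1", "SG2", "M"),
                      c(g1 - off, sg2 + ext, m))
    } else {
      b <- build_cell(0, c("SG2", "M"), c(cycle_total - off, m))
    }
    dies <- runif(1L) < fc$death_probability
    b <- finalize(b, dies)
    add_cell(id, lid, NA_character_, 1L, b)
    if (fc$generations >= 2L && b$event[nrow(b)] == "DIVISION") {
      for (d in 1:2) {
        bd <- build_cell(b$end[nrow(b)], c("G1", "SG2", "M"),
                         c(g1, sg2, m))
        dd <- runif(1L) < fc$death_probability
        bd <- finalize(bd, dd)
        add_cell(paste0(id, ".", d), lid, id, 2L, bd)
      }
    }
  }
  fucci_tracks(do.call(rbind, segs), movie_duration = md,
               frame_interval = fi)
}

## Copy numbers ---------------------------------------------------------------

#' Simulate single-cell copy-number call matrices
#'
#' Every cell starts at the expected ploidy; over each of `generations`
#' divisions, every chromosome independently gains or loses one copy (equal
#' probability, floored at 0) with the per-division mis-segregation
#' probability.  Bins inherit the copy number of their chromosome; variable
#' bin widths are drawn once per matrix.  Per-library total read counts are
#' emitted for the depth filter.
#'
#' @param config a [simulation_config()].
#' @return A [cn_matrix()].
#' @export
simulate_copy_numbers <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream_seed(config, 3L))
  ka <- config$karyotype
  n_bins <- ka$n_chromosomes * ka$bins_per_chromosome
  widths <- round(runif(n_bins, ka$bin_width_range[1L], ka$bin_width_range[2L]))
  chrom <- rep(paste0("chr", seq_len(ka$n_chromosomes)),
               each = ka$bins_per_chromosome)
  start <- unlist(lapply(split(widths, chrom)[unique(chrom)], function(w)
    c(0, cumsum(w))[seq_along(w)]), use.names = FALSE)
  bins <- data.frame(chrom = chrom, start = start, end = start + widths,
                     stringsAsFactors = FALSE)

  copies <- matrix(rep(ka$expected_ploidy, ka$n_chromosomes * ka$n_cells),
                   nrow = ka$n_chromosomes, ncol = ka$n_cells)
  for (g in seq_len(ka$generations)) {
    hit <- matrix(runif(length(copies)) < ka$missegregation_probability,
                  nrow = nrow(copies))
    sign <- matrix(sample(c(-1L, 1L), length(copies), replace = TRUE),
                   nrow = nrow(copies))
    copies <- pmax(copies + hit * sign, 0L)
  }
  calls <- copies[rep(seq_len(ka$n_chromosomes),
                      each = ka$bins_per_chromosome), , drop = FALSE]
  colnames(calls) <- sprintf("cell%03d", seq_len(ka$n_cells))
  storage.mode(calls) <- "integer"
  read_totals <- setNames(
    round(ka$mean_total_reads * runif(ka$n_cells, 0.5, 2)),
    colnames(calls))
  cn_matrix(bins, calls, expected_ploidy = ka$expected_ploidy,
            read_totals = read_totals)
}

## Cohort ---------------------------------------------------------------------

#' Simulate a CNR cohort with outcome
#'
#' Per-sample true CNR drawn from a two-component normal mixture either side
#' of the configured changepoint; field counts are Poisson (nuclei around
#' the configured density, centrosomes around true CNR x nuclei).  Relapse
#' and overall-survival times are exponential with the configured hazard
#' ratio between the high- and low-CNR groups, under independent exponential
#' censoring capped at the follow-up horizon; the binary 6-month relapse
#' outcome derives from the observed relapse endpoint.
#'
#' @param config a [simulation_config()].
#' @return list with `fields` (field-count data.frame), `cohort`
#'   (per-sample outcome table including the latent `true_cnr` and
#'   `true_group`), and `config` echo.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream_seed(config, 4L))
  co <- config$cohort
  n <- co$n_samples
  high <- runif(n) < co$p_high
  true_cnr <- rnorm(n, ifelse(high, co$cnr_high_mean, co$cnr_low_mean),
                    co$cnr_sd)
  true_cnr <- pmax(true_cnr, 0.05)
  sample_id <- sprintf("S%03d", seq_len(n))

  fields <- do.call(rbind, lapply(seq_len(n), function(i) {
    nuc <- rpois(co$fields_per_sample, co$nuclei_per_field)
    nuc <- pmax(nuc, 1L)
    cen <- rpois(co$fields_per_sample, true_cnr[i] * nuc)
    data.frame(sample_id = sample_id[i],
               field_index = seq_len(co$fields_per_sample),
               n_centrosomes = cen, n_nuclei = nuc,
               stringsAsFactors = FALSE)
  }))

  rate_rel <- co$relapse_rate_low * ifelse(high, co$hazard_ratio, 1)
  rate_os <- co$os_rate_low * ifelse(high, co$os_hazard_ratio, 1)
  t_rel <- rexp(n, rate_rel)
  t_os <- rexp(n, rate_os)
  cens <- pmin(rexp(n, co$censoring_rate), co$followup_months)

  relapse_event <- as.integer(t_rel <= cens)
  relapse_time <- pmin(t_rel, cens)
  os_event <- as.integer(t_os <= cens)
  os_time <- pmin(t_os, cens)

  cohort <- data.frame(
    sample_id = sample_id,
    true_cnr = true_cnr,
    true_group = ifelse(high, "high", "low"),
    relapse_within_6mo = as.integer(relapse_event == 1L & relapse_time <= 6),
    time_to_relapse_months = relapse_time,
    relapse_event = relapse_event,
    os_months = os_time,
    os_event = os_event,
    figo_stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                        prob = c(0.08, 0.13, 0.59, 0.20)),
    stringsAsFactors = FALSE)
  list(fields = fields, cohort = cohort, config = config)
}

## Spot images ----------------------------------------------------------------

#' Simulate a spot image stack with known focus counts
#'
#' Plants Gaussian spots of fixed amplitude on a constant background, on a
#' jittered grid guaranteeing at least 4 sigma of separation between spot
#' centres, adds per-slice Gaussian noise, and rounds intensities to
#' integers (the scale of a camera count).  Slices are weighted copies of
#' the spot plane so a maximum projection restores the full amplitude.
#'
#' @param config a [simulation_config()].
#' @return list with `stack` (rows x cols x slices), `mask` (all-`TRUE`
#'   logical matrix), `spots` (data.frame of centre coordinates, 1-based
#'   row/col), and `config` echo.
#' @export
simulate_spot_image <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.substream_seed(config, 5L))
  im <- config$image
  sz <- im$size
  if (im$n_spots == 0L) {
    stack <- array(pmax(round(im$background +
                                rnorm(sz * sz * im$n_slices, 0, im$noise_sd)),
                        0),
                   dim = c(sz, sz, im$n_slices))
    return(list(stack = stack, mask = matrix(TRUE, sz, sz),
                spots = data.frame(row = numeric(0), col = numeric(0)),
                config = config))
  }
  grid_n <- ceiling(sqrt(im$n_spots))
  pitch <- sz / grid_n
  if (pitch < 4 * im$sigma + 2)
    stop("cannot place ", im$n_spots, " spots at 4-sigma separation in a ",
         sz, "x", sz, " grid")
  jitter_max <- max(floor((pitch - 4 * im$sigma) / 2) - 1, 0)
  centers <- expand.grid(gr = seq_len(grid_n), gc = seq_len(grid_n))
  centers <- centers[seq_len(im$n_spots), ]
  row <- round((centers$gr - 0.5) * pitch +
                 runif(im$n_spots, -jitter_max, jitter_max))
  col <- round((centers$gc - 0.5) * pitch +
                 runif(im$n_spots, -jitter_max, jitter_max))
  row <- pmin(pmax(row, 3), sz - 2)
  col <- pmin(pmax(col, 3), sz - 2)

  rr <- matrix(seq_len(sz), sz, sz)
  cc <- t(rr)
  plane <- matrix(0, sz, sz)
  for (s in seq_len(im$n_spots)) {
    plane <- plane + im$amplitude *
      exp(-((rr - row[s])^2 + (cc - col[s])^2) / (2 * im$sigma^2))
  }
  stack <- array(0, dim = c(sz, sz, im$n_slices))
  w <- rep_len(im$slice_weights, im$n_slices)
  for (k in seq_len(im$n_slices)) {
    stack[, , k] <- pmax(round(im$background + w[k] * plane +
                                 rnorm(sz * sz, 0, im$noise_sd)), 0)
  }
  list(stack = stack, mask = matrix(TRUE, sz, sz),
       spots = data.frame(row = row, col = col),
       config = config)
}
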