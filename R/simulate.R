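#' Simulation specification for wound morphometry tables
#'
#' Defines the per-group-per-day mean and SD of each of the ten wound-geometry
#' measurements (`D`, `DPA`, `EPI`, `L`, `N`, `NEO`, `S`, `T`, `H`, `B`), the
#' number of animals per group, and the seed. By default the moments equal
#' the bundled reference summary ([reference_morphometry()]): `CONT` takes the
#' control column, `NAC30` its own day-7 column (reverting to the pooled
#' `gNAC` column at days 14 and 60, where no separate NAC30 summary exists),
#' and `NAC15`/`NAC45` the pooled `gNAC` column.
#'
#' @param n_per_group animals per group and day, `>= 2`.
#' @param moments data.frame with columns `group`, `day`, `variable`, `mean`,
#'   `sd`; defaults as described above.
#' @param seed integer seed.
#' @return a `morphometry_sim_spec` object.
#' @export
morphometry_sim_spec <- function(n_per_group = 9, moments = NULL, seed = 1L) {
  if (n_per_group < 2) stop("need at least 2 animals per group")
  if (is.null(moments)) moments <- default_morphometry_moments()
  need <- c("group", "day", "variable", "mean", "sd")
  if (!all(need %in% names(moments))) stop("malformed moments table")
  if (any(moments$sd < 0)) stop("SDs must be nonnegative")
  structure(list(n_per_group = as.integer(n_per_group), moments = moments,
                 seed = as.integer(seed)), class = "morphometry_sim_spec")
}

measurement_vars <- function() {
  c("D", "DPA", "EPI", "L", "N", "NEO", "S", "T", "H", "B")
}

default_morphometry_moments <- function() {
  ref <- reference_morphometry()
  ref <- ref[ref$variable %in% measurement_vars(), ]
  src <- function(group, day) {
    col <- if (group == "CONT") "CONT"
      else if (group == "NAC30" && day == 7) "NAC30" else "gNAC"
    r <- ref[ref$day == day & ref$group == col, ]
    data.frame(group = group, day = day, variable = r$variable,
               mean = r$mean, sd = r$sd)
  }
  grid <- expand.grid(group = c("CONT", "NAC15", "NAC30", "NAC45"),
                      day = c(7, 14, 60), stringsAsFactors = FALSE)
  do.call(rbind, Map(src, grid$group, grid$day))
}

# Zero-truncated Gaussian via resampling (exact truncation).
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, sd)
  x
}

#' Generate a synthetic wound morphometry table
#'
#' Samples each measurement independently per animal from a Gaussian with the
#' cell's mean and SD, truncated at 0 (measurements are lengths and areas).
#' One row per animal and day with the ten measurement columns.
#' Deterministic per seed.
#'
#' @param spec a [morphometry_sim_spec()].
#' @return data.frame with columns `animal`, `group`, `day`, `D`, `DPA`,
#'   `EPI`, `L`, `N`, `NEO`, `S`, `T`, `H`, `B`.
#' @examples
#' tab <- generate_morphometry_table(morphometry_sim_spec(n_per_group = 3))
#' head(tab)
#' @export
generate_morphometry_table <- function(spec) {
  stopifnot(inherits(spec, "morphometry_sim_spec"))
  mo <- spec$moments
  cells <- unique(mo[c("group", "day")])
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      g <- cells$group[i]; d <- cells$day[i]
      out <- data.frame(
        animal = sprintf("%s_d%d_%02d", g, d, seq_len(spec$n_per_group)),
        group = g, day = d)
      for (v in measurement_vars()) {
        cell <- mo[mo$group == g & mo$day == d & mo$variable == v, ]
        if (nrow(cell) != 1) stop("missing moments for ", g, " day ", d,
                                  " ", v)
        out[[v]] <- rnorm_trunc0(spec$n_per_group, cell$mean, cell$sd)
      }
      out
    })
    do.call(rbind, rows)
  })
}

#' Default per-group parameters for the scar time-series generator
#'
#' Exponential-decay parameters for scar area, length, and width over the
#' 11-day photographic observation schedule. The incision is 15 mm long and
#' about 2 mm wide at day 1; widths and areas decay fast, lengths slowly.
#' `NAC30` carries a faster early area/width decay (smaller early scar area),
#' the effect the generator can inject; the other arms equal the control.
#'
#' @return named list of per-group parameter lists with fields `area0_mm2`,
#'   `length0_mm`, `width0_mm`, `area_decay`, `length_decay`, `width_decay`
#'   (per day) and `noise_sdlog` (lognormal noise SD).
#' @export
scar_group_params <- function() {
  base <- list(area0_mm2 = 30, length0_mm = 15, width0_mm = 2,
               area_decay = 0.08, length_decay = 0.005, width_decay = 0.075,
               noise_sdlog = 0.15)
  nac30 <- base
  nac30$area_decay <- 0.14
  nac30$width_decay <- 0.13
  list(CONT = base, NAC15 = base, NAC30 = nac30, NAC45 = base)
}

#' Standard photographic observation days
#'
#' @return the 11 post-operative days on which wounds are photographed.
#' @export
observation_days <- function() c(1, 2, 3, 4, 7, 14, 21, 28, 35, 45, 60)

#' Generate synthetic scar planimetry time-series
#'
#' Per-wound area, length, and width follow a monotone exponential decay with
#' multiplicative lognormal noise:
#' `area(d) = area0 * exp(-r * d) * exp(eps)`, `eps ~ N(0, noise_sdlog^2)`,
#' and analogously for length and width. With zero noise the closed form is
#' exact.
#'
#' @param group_params named list of per-group parameters
#'   ([scar_group_params()]); all decay rates must be positive.
#' @param days observation days, non-empty; default [observation_days()].
#' @param n_wounds_per_group wounds (animal x site) per group.
#' @param seed integer seed.
#' @return data.frame with columns `animal`, `wound_site`, `group`, `day`,
#'   `area_mm2`, `length_mm`, `width_mm`.
#' @export
generate_scar_timeseries <- function(group_params = scar_group_params(),
                                     days = observation_days(),
                                     n_wounds_per_group = 18, seed = 1L) {
  if (length(days) == 0) stop("empty day list")
  sites <- c("rostral", "central", "caudal")
  for (p in group_params)
    if (p$area_decay <= 0 || p$length_decay <= 0 || p$width_decay <= 0)
      stop("decay rates must be positive")
  with_seed(seed, {
    rows <- list()
    for (g in names(group_params)) {
      p <- group_params[[g]]
      for (wound in seq_len(n_wounds_per_group)) {
        animal <- sprintf("%s_%02d", g, ceiling(wound / length(sites)))
        site <- sites[(wound - 1) %% length(sites) + 1]
        eps <- function(n) exp(stats::rnorm(n, 0, p$noise_sdlog))
        rows[[length(rows) + 1]] <- data.frame(
          animal = animal, wound_site = site, group = g, day = days,
          area_mm2 = p$area0_mm2 * exp(-p$area_decay * days) *
            eps(length(days)),
          length_mm = p$length0_mm * exp(-p$length_decay * days) *
            eps(length(days)),
          width_mm = p$width0_mm * exp(-p$width_decay * days) *
            eps(length(days)))
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate synthetic visual-analog-scale rater scores
#'
#' Each of `n_raters` blinded raters scores each sample-parameter truth with
#' additive Gaussian noise; scores are clipped to the scale range and rounded
#' to the 0.1 increment of the VAS slider.
#'
#' @param truth data.frame with columns `sample`, `parameter`, `truth`, or a
#'   named numeric vector of per-parameter truths for a single sample.
#' @param n_raters number of raters, `>= 1`; default 3.
#' @param noise_sd rater noise SD on the VAS scale, `>= 0`.
#' @param scale_range two-element numeric, default `c(0, 3)` (continuous
#'   extension of the ordinal 0-3 grading).
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `parameter`, `rater`, `value`.
#' @export
generate_rater_scores <- function(truth, n_raters = 3, noise_sd = 0.3,
                                  scale_range = c(0, 3), seed = 1L) {
  if (n_raters < 1) stop("need at least one rater")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.data.frame(truth))
    truth <- data.frame(sample = "s1", parameter = names(truth),
                        truth = as.numeric(truth))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
      v <- truth$truth + stats::rnorm(nrow(truth), 0, noise_sd)
      v <- pmin(scale_range[2], pmax(scale_range[1], v))
      data.frame(sample = truth$sample, parameter = truth$parameter,
                 rater = sprintf("rater%d", r), value = round(v * 10) / 10)
    }))
    rownames(out) <- NULL
    out
  })
}
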