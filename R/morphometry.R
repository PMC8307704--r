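#' Wound healing and remodeling indices
#'
#' Dimensionless indices computed from the standard wound-geometry
#' measurements of an incisional-scar section (all in micrometres /
#' square micrometres):
#' \describe{
#'   \item{`sci(L, S)`}{superficial contraction index `(L - S) / L`, from the
#'     re-epithelialization zone length `L` and the distance `S` between the
#'     wound borders.}
#'   \item{`dci(N, D)`}{deep contraction index `(N - D) / N`, from the natural
#'     dermis thickness `N` and the wound depth `D`.}
#'   \item{`wsi(N, T)`}{wound severity index `(N - T) / N`, from `N` and the
#'     connective-tissue thickness `T` at the wound center.}
#'   \item{`rhi(H0, H)`}{hair remodeling index `(H0 - H) / H0`, from the
#'     distance `H` between the hair follicles closest to the wound borders
#'     and its day-7 baseline `H0`.}
#'   \item{`mri(B0, B)`}{matrix remodeling index `(B0 - B) / B0`, from the
#'     dense (blue-stained) scar tissue area `B` and its day-7 baseline `B0`.}
#'   \item{`gci(sci, dci)`}{global contraction index, `SCI + DCI`.}
#'   \item{`ghi(sci, dci, wsi)`}{global healing index, `GCI - WSI`.}
#'   \item{`gri(rhi, mri)`}{global remodeling index, `(RHI + MRI) / 2`.}
#' }
#' Contraction proceeds toward 1; negative remodeling indices indicate
#' expansion relative to the day-7 baseline. All functions are vectorized; a
#' nonpositive denominator yields `NA` with a warning.
#'
#' @param L,S,N,D,T,H,H0,B,B0 wound-geometry measurements (see above).
#' @param sci,dci,wsi,rhi,mri component index values.
#' @return numeric index value(s).
#' @examples
#' dci(N = 1434.4, D = 527.2)   # 0.63
#' gci(sci = 0.46, dci = 0.62)  # 1.08
#' @name healing_indices
NULL

index_ratio <- function(base, x, what) {
  out <- rep(NA_real_, length(x))
  bad <- !is.finite(base) | base <= 0
  if (any(bad)) warning(sprintf("%s undefined: nonpositive denominator", what))
  out[!bad] <- (base[!bad] - x[!bad]) / base[!bad]
  out
}

#' @rdname healing_indices
#' @export
sci <- function(L, S) index_ratio(L, S, "SCI")

#' @rdname healing_indices
#' @export
dci <- function(N, D) index_ratio(N, D, "DCI")

#' @rdname healing_indices
#' @export
wsi <- function(N, T) index_ratio(N, T, "WSI")

#' @rdname healing_indices
#' @export
rhi <- function(H0, H) index_ratio(H0, H, "RHI")

#' @rdname healing_indices
#' @export
mri <- function(B0, B) index_ratio(B0, B, "MRI")

#' @rdname healing_indices
#' @export
gci <- function(sci, dci) sci + dci

#' @rdname healing_indices
#' @export
ghi <- function(sci, dci, wsi) gci(sci, dci) - wsi

#' @rdname healing_indices
#' @export
gri <- function(rhi, mri) (rhi + mri) / 2

#' Compute all eight healing indices for one set of wound measurements
#'
#' @param m named list or one-row data.frame with wound measurements `D`,
#'   `L`, `N`, `S`, `T`, `H`, `B` (micrometres; `B` in square micrometres).
#'   Aliases `E`/`EPI`, `NE`/`NEO`, `HRI`/`RHI` are accepted on input tables;
#'   the canonical names are `EPI`, `NEO`, `RHI`.
#' @param b named list with day-7 baselines `H0` (micrometres) and `B0`
#'   (square micrometres), both positive.
#' @return named list with `SCI`, `DCI`, `WSI`, `GCI`, `GHI`, `RHI`, `MRI`,
#'   `GRI`.
#' @examples
#' compute_indices(list(D = 527.2, L = 1909.8, N = 1434.4, S = 1533.2,
#'                      T = 915.5, H = 1604.5, B = 189079.1),
#'                 list(H0 = 1604.5, B0 = 189079.1))
#' @export
compute_indices <- function(m, b) {
  s <- sci(m$L, m$S); d <- dci(m$N, m$D); w <- wsi(m$N, m$T)
  rh <- rhi(b$H0, m$H); mr <- mri(b$B0, m$B)
  list(SCI = s, DCI = d, WSI = w, GCI = gci(s, d), GHI = ghi(s, d, w),
       RHI = rh, MRI = mr, GRI = gri(rh, mr))
}

#' Meeh-Rubner allometric body surface area
#'
#' `A = k * mass^(2/3)` in square centimetres; the default Meeh constant
#' `k = 10` gives about 400 cm2 for a 250 g rat, the value used when scaling
#' an intradermally treated skin area to the whole body surface.
#'
#' @param mass_g body mass in grams, positive.
#' @param k Meeh constant, default 10.
#' @return body surface area in cm2.
#' @examples
#' body_surface_area_meeh(250)  # ~397 cm2
#' @export
body_surface_area_meeh <- function(mass_g, k = 10) {
  if (any(mass_g <= 0)) stop("mass must be positive")
  if (any(k <= 0)) stop("Meeh constant must be positive")
  k * mass_g^(2 / 3)
}

#' Fraction of body surface covered by the treated skin area
#'
#' @param treated_cm2 treated skin area in cm2, positive.
#' @param bsa_cm2 total body surface area in cm2, positive
#'   (see [body_surface_area_meeh()]).
#' @return `treated_cm2 / bsa_cm2`.
#' @examples
#' treated_area_fraction(4, 400)  # 0.01
#' @export
treated_area_fraction <- function(treated_cm2, bsa_cm2) {
  if (any(treated_cm2 <= 0) || any(bsa_cm2 <= 0))
    stop("areas must be positive")
  treated_cm2 / bsa_cm2
}

# Map input-table aliases onto the canonical measurement names.
canonical_measurements <- function(df) {
  nm <- names(df)
  nm[nm == "E"] <- "EPI"
  nm[nm == "NE"] <- "NEO"
  names(df) <- nm
  df
}

#' Reference morphometry summary table
#'
#' Published group-level summary (mean and SD) of the ten wound-geometry
#' measurements and eight healing indices in a rat incisional-wound model
#' with pre-incisional N-acetylcysteine, by harvest day (7, 14, 60) and group
#' column (`CONT`, `gNAC` — the pooled NAC arms — and, at day 7, `NAC30`).
#' Bundled as plain CSV; used as the default parameterization of
#' [morphometry_sim_spec()] and as the consistency reference for the locked
#' index formulas.
#'
#' @return data.frame with columns `day`, `group`, `variable`, `mean`, `sd`.
#' @export
reference_morphometry <- function() {
  path <- system.file("extdata", "reference_morphometry.csv",
                      package = "scarkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Pull one reference cell (internal).
ref_cell <- function(ref, day, group, variable) {
  r <- ref[ref$day == day & ref$group == group & ref$variable == variable, ]
  if (nrow(r) != 1) stop("reference cell not found")
  r
}

#' Per-sample healing indices and group summaries for a measurement table
#'
#' Computes the eight indices for every sample of a long measurement table
#' and summarizes them as group-by-day mean and SD (the mean of per-sample
#' ratios, not the ratio of group means). Baselines `H0` and `B0` are, under
#' the default policy, the same-group day-7 means of `H` and `B`; day-7
#' samples are therefore scored against their own group mean, so day-7
#' remodeling indices scatter around 0.
#'
#' @param measurements data.frame with columns `animal`, `group`, `day` and
#'   the measurement columns `D`, `DPA`, `EPI`, `L`, `N`, `NEO`, `S`, `T`,
#'   `H`, `B` (aliases `E`, `NE` accepted).
#' @param baseline_policy `"group_day7"` (default) or `"explicit"`.
#' @param baselines data.frame with columns `group`, `H0`, `B0`; required
#'   when `baseline_policy = "explicit"`.
#' @return list with `per_sample` (indices per row) and `summary`
#'   (group x day x index mean, sd, n).
#' @export
index_table <- function(measurements, baseline_policy = c("group_day7",
                                                          "explicit"),
                        baselines = NULL) {
  baseline_policy <- match.arg(baseline_policy)
  df <- canonical_measurements(as.data.frame(measurements))
  need <- c("animal", "group", "day", "D", "L", "N", "S", "T", "H", "B")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (baseline_policy == "group_day7") {
    d7 <- df[df$day == 7, ]
    if (nrow(d7) == 0) stop("no day-7 rows to serve as baselines")
    baselines <- do.call(rbind, lapply(split(d7, d7$group), function(g)
      data.frame(group = g$group[1], H0 = mean(g$H), B0 = mean(g$B))))
  }
  if (is.null(baselines)) stop("explicit baseline policy requires `baselines`")
  df <- merge(df, baselines, by = "group", all.x = TRUE, sort = FALSE)
  if (anyNA(df$H0)) stop("no baseline for group(s): ",
                         paste(unique(df$group[is.na(df$H0)]), collapse = ", "))
  idx <- with(df, {
    s <- sci(L, S); d <- dci(N, D); w <- wsi(N, T)
    rh <- rhi(H0, H); mr <- mri(B0, B)
    data.frame(SCI = s, DCI = d, WSI = w, GCI = gci(s, d),
               GHI = ghi(s, d, w), RHI = rh, MRI = mr, GRI = gri(rh, mr))
  })
  per_sample <- cbind(df[c("animal", "group", "day")], idx)
  long <- stats::reshape(per_sample, direction = "long",
                         varying = names(idx), v.names = "value",
                         times = names(idx), timevar = "index")
  agg <- stats::aggregate(value ~ group + day + index, data = long,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  summary <- data.frame(agg[c("group", "day", "index")],
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                        n = agg$value[, "n"])
  summary <- summary[order(summary$day, summary$group, summary$index), ]
  rownames(summary) <- NULL
  list(per_sample = per_sample, summary = summary)
}
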