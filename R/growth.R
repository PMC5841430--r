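#' Growth parameters from one OD600 time series
#'
#' Three direct curve statistics, matching common small-scale fermentation
#' practice: maximal OD is the plateau `max(od)`; the lag phase ends at the
#' first (linearly interpolated) time the OD has risen by 5% of its total
#' increase over the starting OD; the maximal growth rate is the largest
#' per-interval slope of log2(OD), in divisions per hour. A curve counts as
#' grown only when the OD rise exceeds `delta_grow`; non-growing curves get
#' `r_max = 0` and an undefined lag. Interval pairs with a non-positive OD
#' are skipped for the rate.
#'
#' @param times hours, increasing, starting at 0 (inoculation).
#' @param od OD600 readings, same length as `times` (>= 3 points).
#' @param delta_grow minimum OD rise to count as growth (default 0.2).
#' @return list: `lag_h`, `r_max`, `od_max`, `grew`.
#' @export
growth_params <- function(times, od, delta_grow = 0.2) {
  stopifnot(length(times) == length(od), length(od) >= 3L,
            !is.unsorted(times, strictly = TRUE), times[1] == 0,
            all(od >= 0))
  od_max <- max(od)
  od0 <- od[1]
  grew <- od_max >= od0 + delta_grow
  if (!grew) {
    return(list(lag_h = NA_real_, r_max = 0, od_max = od_max, grew = FALSE))
  }
  thr <- od0 + 0.05 * (od_max - od0)
  above <- which(od >= thr)
  first <- above[1]
  lag_h <- if (first == 1L) 0 else {
    t0 <- times[first - 1L]; t1 <- times[first]
    y0 <- od[first - 1L]; y1 <- od[first]
    t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
  }
  dt <- diff(times)
  ok <- od[-length(od)] > 0 & od[-1] > 0
  rates <- (log2(od[-1]) - log2(od[-length(od)])) / dt
  r_max <- if (any(ok)) max(rates[ok]) else 0
  list(lag_h = lag_h, r_max = max(r_max, 0), od_max = od_max, grew = TRUE)
}

#' Growth parameters for a long-format curve table
#'
#' @param curves data.frame with columns `strain`, `dose`, `replicate`,
#'   `time_h`, `od600`.
#' @param delta_grow passed to [growth_params()].
#' @return data.frame with one row per (strain, dose, replicate):
#'   `lag_h`, `r_max`, `od_max`, `grew`.
#' @export
growth_param_table <- function(curves, delta_grow = 0.2) {
  need <- c("strain", "dose", "replicate", "time_h", "od600")
  stopifnot(all(need %in% names(curves)))
  key <- interaction(curves$strain, curves$dose, curves$replicate, drop = TRUE)
  rows <- lapply(split(curves, key), function(cc) {
    cc <- cc[order(cc$time_h), ]
    gp <- growth_params(cc$time_h, cc$od600, delta_grow)
    data.frame(strain = cc$strain[1], dose = cc$dose[1],
               replicate = cc$replicate[1],
               lag_h = gp$lag_h, r_max = gp$r_max, od_max = gp$od_max,
               grew = gp$grew, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$strain, out$dose, out$replicate), ]
}

#' Classify a strain's sulfite response as sensitive (S) or tolerant (T)
#'
#' Per parameter (`r_max`, `od_max`) a Kruskal-Wallis test is run across
#' doses. A strain is sensitive when growth is absent in every replicate at
#' some non-zero dose, or when a parameter differs significantly across
#' doses (`p < alpha`) *and* its mean at some non-zero dose is lower than
#' at dose 0 by more than `min_decline` (relative; a rank test can reach
#' significance on biologically meaningless wobble when replicates are
#' very reproducible, e.g. grid-phasing effects of 24 h sampling on the
#' interval-slope rate). Lag prolongation alone never makes a strain
#' sensitive:
#' tolerant strains may delay growth yet reach the same rate and plateau.
#' A secondary effect-size flag (`s_effect_size`) marks strains whose mean
#' `r_max` declines monotonically by >= 50% at some dose, independent of
#' the rank test (useful at triplicate-level power).
#'
#' @param params parameter table for one strain ([growth_param_table()]
#'   rows), doses in the same unit, dose 0 present with >= 2 replicates.
#' @param alpha significance level (default 0.05).
#' @param min_decline minimum relative drop below the dose-0 mean for a
#'   significant parameter to count as altered growth (default 0.05).
#' @return list: `klass` (`"S"`/`"T"`, or `NA` when replication is
#'   insufficient), `tests` (per-parameter H and p), `s_effect_size`,
#'   `no_growth_doses`, `defined`.
#' @export
classify_tolerance <- function(params, alpha = 0.05, min_decline = 0.05) {
  stopifnot(all(c("dose", "r_max", "od_max", "grew") %in% names(params)))
  doses <- sort(unique(params$dose))
  reps_per_dose <- table(params$dose)
  defined <- (0 %in% doses) && reps_per_dose[["0"]] >= 2L &&
    sum(reps_per_dose >= 2L) >= 2L
  if (!defined) {
    return(list(klass = NA_character_, tests = NULL,
                s_effect_size = FALSE, no_growth_doses = numeric(0),
                defined = FALSE))
  }
  no_growth <- vapply(doses[doses > 0], function(d) {
    all(!params$grew[params$dose == d])
  }, logical(1))
  no_growth_doses <- doses[doses > 0][no_growth]
  tests <- do.call(rbind, lapply(c("r_max", "od_max"), function(par) {
    vals <- params[[par]]
    if (stats::sd(vals) == 0) {
      return(data.frame(parameter = par, H = 0, p = 1,
                        lower_at_dose = FALSE))
    }
    kw <- stats::kruskal.test(vals, factor(params$dose))
    m0 <- mean(vals[params$dose == 0])
    md <- vapply(doses[doses > 0], function(d) mean(vals[params$dose == d]),
                 numeric(1))
    data.frame(parameter = par, H = unname(kw$statistic), p = kw$p.value,
               lower_at_dose = any(md < m0 * (1 - min_decline) - 1e-8))
  }))
  sensitive <- length(no_growth_doses) > 0 ||
    any(tests$p < alpha & tests$lower_at_dose)
  # effect-size flag: monotone non-increasing mean r_max with >= 50% decline
  mr <- vapply(doses, function(d) mean(params$r_max[params$dose == d]),
               numeric(1))
  eff <- all(diff(mr) <= 1e-8) && any(mr <= 0.5 * mr[1] + 1e-12) && mr[1] > 0
  list(klass = if (sensitive) "S" else "T", tests = tests,
       s_effect_size = eff, no_growth_doses = no_growth_doses,
       defined = TRUE)
}

#' Classify every strain in a curve table
#'
#' @param curves long-format curve table (see [growth_param_table()]).
#' @param alpha significance level.
#' @param delta_grow minimum OD rise to count as growth.
#' @return data.frame per strain: `strain`, `klass`, `s_effect_size`,
#'   `p_r_max`, `p_od_max`, `no_growth_doses`.
#' @export
tolerance_table <- function(curves, alpha = 0.05, delta_grow = 0.2,
                            min_decline = 0.05) {
  pt <- growth_param_table(curves, delta_grow)
  rows <- lapply(split(pt, pt$strain), function(p1) {
    cl <- classify_tolerance(p1, alpha, min_decline)
    data.frame(
      strain = p1$strain[1], klass = cl$klass,
      s_effect_size = cl$s_effect_size,
      p_r_max = if (is.null(cl$tests)) NA_real_ else
        cl$tests$p[cl$tests$parameter == "r_max"],
      p_od_max = if (is.null(cl$tests)) NA_real_ else
        cl$tests$p[cl$tests$parameter == "od_max"],
      no_growth_doses = paste(cl$no_growth_doses, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
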