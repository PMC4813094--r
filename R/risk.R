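# WHO severity classification, population-weighted wasted-children counts by
# zone, and the descriptive survey summary table.

WHO_CLASSES <- c("acceptable", "alert", "serious", "critical", "very_critical")

#' WHO wasting-severity class of a prevalence
#'
#' The five WHO trigger levels for wasting prevalence: acceptable (< 5\%),
#' alert (5 to < 10\%), serious (10 to < 15\%), critical (15--20\%, closed at
#' 20\%), very critical (> 20\%). A total monotone step function on [0, 1].
#'
#' @param prevalence numeric vector in [0, 1].
#' @return ordered factor with levels acceptable < alert < serious <
#'   critical < very_critical.
#' @examples
#' classify_who(c(0.04, 0.12, 0.20, 0.2000001))
#' @export
classify_who <- function(prevalence) {
  if (any(!is.finite(prevalence)) ||
      any(prevalence < 0) || any(prevalence > 1)) {
    stop("prevalence must lie in [0, 1]")
  }
  idx <- ifelse(prevalence < 0.05, 1L,
         ifelse(prevalence < 0.10, 2L,
         ifelse(prevalence < 0.15, 3L,
         ifelse(prevalence <= 0.20, 4L, 5L))))
  factor(WHO_CLASSES[idx], levels = WHO_CLASSES, ordered = TRUE)
}

#' Population-weighted wasted-children counts by zone and severity class
#'
#' Per-pixel expected wasted children = posterior mean prevalence x under-five
#' population, aggregated by zone, year--season and WHO class. Counts are kept
#' real-valued; the "<50" masking of small cells is a formatting layer
#' ([format_risk_table()]).
#'
#' @param prevalence a [predict_prevalence()] result, or a named list of
#'   \code{list(year =, season =, mean = wm_grid)} entries, or a single
#'   \code{wm_grid} (then \code{year}/\code{season} label the single surface).
#' @param population under-five population [pixel_grid()], geometrically
#'   aligned with the prevalence grids.
#' @param region a [make_study_region()] whose zones cover all populated
#'   pixels.
#' @param year,season labels used when \code{prevalence} is a bare grid.
#' @return data.frame of class \code{wm_risk_table}: \code{zone},
#'   \code{year}, \code{season}, \code{who_class}, \code{wasted}.
#' @export
wasted_children_counts <- function(prevalence, population, region,
                                   year = NA, season = NA) {
  stopifnot(inherits(population, "wm_grid"), inherits(region, "wm_region"))
  surfaces <- if (inherits(prevalence, "wm_prevalence")) {
    prevalence$surfaces
  } else if (inherits(prevalence, "wm_grid")) {
    list(single = list(year = year, season = season, mean = prevalence))
  } else prevalence

  popdf <- grid_df(population)
  zones <- zone_of(region, popdf$x, popdf$y)
  orphan <- which(popdf$value > 0 & is.na(zones))
  if (length(orphan) > 0) {
    stop("populated pixel(s) outside every zone at grid row(s): ",
         paste(utils::head(orphan, 10L), collapse = ", "))
  }

  rows <- list()
  for (key in names(surfaces)) {
    s <- surfaces[[key]]
    if (!same_geometry(s$mean, population)) {
      stop("prevalence and population grids are not geometrically aligned (",
           key, ")")
    }
    prev <- grid_df(s$mean)$value
    ok <- !is.na(prev) & !is.na(zones)
    if (any(popdf$value[is.na(prev)] > 0)) {
      # populated but unpredicted (masked) pixels are excluded from the totals
      ok <- ok
    }
    cls <- rep(NA_character_, length(prev))
    cls[ok] <- as.character(classify_who(prev[ok]))
    expected <- prev * popdf$value
    df <- data.frame(zone = zones[ok], who_class = cls[ok],
                     wasted = expected[ok], stringsAsFactors = FALSE)
    agg <- stats::aggregate(wasted ~ zone + who_class, data = df, FUN = sum)
    agg$year <- s$year
    agg$season <- s$season
    rows[[key]] <- agg
  }
  out <- do.call(rbind, rows)
  out <- out[c("zone", "year", "season", "who_class", "wasted")]
  out$who_class <- factor(out$who_class, levels = WHO_CLASSES, ordered = TRUE)
  out <- out[order(out$year, match(out$season, WM_SEASONS), out$zone,
                   out$who_class), ]
  rownames(out) <- NULL
  class(out) <- c("wm_risk_table", "data.frame")
  out
}

#' Format a risk table with the "<50" reporting convention
#'
#' Rounds counts half-up and masks cells below the threshold as \code{"<50"},
#' mirroring the reporting convention of seasonal case-count tables; the raw
#' values remain in the unformatted table.
#'
#' @param risk_table a [wasted_children_counts()] result.
#' @param threshold masking threshold (default 50).
#' @return data.frame with a character \code{wasted} column.
#' @export
format_risk_table <- function(risk_table, threshold = 50) {
  out <- as.data.frame(risk_table)
  rounded <- floor(out$wasted + 0.5)
  out$wasted <- ifelse(rounded < threshold, paste0("<", threshold),
                       format(rounded, big.mark = ",", trim = TRUE))
  out
}

#' Descriptive summary of survey data by region
#'
#' Reproduces the survey description table: per region, the number of
#' clusters, children examined, children wasted, and the percentage wasted
#' (2 decimals), plus a totals row. Input rows may be individual clusters
#' (each contributing one cluster) or region-aggregated records carrying an
#' \code{n_clusters} column.
#'
#' @param observations data.frame with columns \code{region},
#'   \code{n_examined}, \code{n_wasted}, and optionally \code{n_clusters}
#'   and \code{zone}.
#' @return data.frame with one row per region plus a \code{Total} row:
#'   \code{region}, \code{n_clusters}, \code{n_examined}, \code{n_wasted},
#'   \code{percent}. Regions with zero examined get \code{NA} percent and a
#'   warning.
#' @export
summarize_table1 <- function(observations) {
  if (!is.data.frame(observations) || nrow(observations) == 0) {
    stop("observations must be a nonempty data frame")
  }
  need <- c("region", "n_examined", "n_wasted")
  if (!all(need %in% names(observations))) {
    stop("missing column(s): ",
         paste(setdiff(need, names(observations)), collapse = ", "))
  }
  obs <- observations
  if (!"n_clusters" %in% names(obs)) obs$n_clusters <- 1L
  agg <- stats::aggregate(cbind(n_clusters, n_examined, n_wasted) ~ region,
                          data = obs, FUN = sum)
  agg <- agg[order(match(agg$region, unique(obs$region))), ]
  zero <- agg$n_examined == 0
  if (any(zero)) {
    warning("region(s) with zero children examined: ",
            paste(agg$region[zero], collapse = ", "))
  }
  agg$percent <- ifelse(zero, NA_real_,
                        round(100 * agg$n_wasted / agg$n_examined, 2))
  tot <- data.frame(
    region = "Total",
    n_clusters = sum(agg$n_clusters),
    n_examined = sum(agg$n_examined),
    n_wasted = sum(agg$n_wasted),
    percent = round(100 * sum(agg$n_wasted) / max(sum(agg$n_examined), 1), 2)
  )
  out <- rbind(agg, tot)
  rownames(out) <- NULL
  out
}

#' Packaged region-aggregated survey description fixture
#'
#' The 18-region description of the 2007--2010 FSNAU survey data (zone,
#' region, clusters, children examined, children wasted), packaged so the
#' descriptive summary is reproducible without the (undeposited) microdata.
#'
#' @return data.frame with 18 rows and columns \code{zone}, \code{region},
#'   \code{n_clusters}, \code{n_examined}, \code{n_wasted}.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_regions.csv", package = "wastemap")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Mean dry-minus-wet prevalence difference surface
#'
#' Per-pixel difference between the mean of the dry-season surfaces (Jilaal,
#' Hagaa) and the mean of the wet-season surfaces (Gu, Deyr), averaged over
#' the years present.
#'
#' @param prevalence a [predict_prevalence()] result containing all four
#'   seasons for the years used.
#' @return a [pixel_grid()] of differences.
#' @export
dry_wet_difference <- function(prevalence) {
  stopifnot(inherits(prevalence, "wm_prevalence"))
  surf <- prevalence$surfaces
  seas <- vapply(surf, function(s) s$season, character(1))
  dry <- surf[seas %in% c("Jilaal", "Hagaa")]
  wet <- surf[seas %in% c("Gu", "Deyr")]
  if (length(dry) == 0 || length(wet) == 0) {
    stop("need at least one dry and one wet season surface")
  }
  avg <- function(lst) {
    Reduce(`+`, lapply(lst, function(s) s$mean$values)) / length(lst)
  }
  g1 <- dry[[1]]$mean
  pixel_grid(g1$xs, g1$ys, avg(dry) - avg(wet))
}
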