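# Out-plant experiment: design allocation, survival status, relative growth
# rate, and the site-level performance metrics that feed model selection.

#' Relative growth rate from rosette diameters
#'
#' Per-day rate of change in log squared rosette diameter:
#' `(ln(final^2) - ln(initial^2)) / days`. Negative when the plant shrank.
#'
#' @param initial_diameter,final_diameter Diameters in cm, both > 0.
#' @param days Growth period in days, > 0.
#' @return Per-day log-area rate. Vectorised.
#' @export
#' @examples
#' rgr(10, 20, 100) # 2 * log(2) / 100
rgr <- function(initial_diameter, final_diameter, days) {
  if (any(initial_diameter <= 0 | final_diameter <= 0, na.rm = TRUE)) {
    stop("diameters must be positive")
  }
  if (any(days <= 0, na.rm = TRUE)) stop("growth period must be positive")
  (log(final_diameter^2) - log(initial_diameter^2)) / days
}

#' Survival status of a plant at a date
#'
#' A plant is dead at `date` iff a `"dead"` monitoring status occurs on or
#' before `date` (death is absorbing). Flowered plants are treated as
#' living: in a monocarpic species death after flowering is not stress
#' related. A plant missed at an event but recorded later is alive
#' throughout; deaths are recorded affirmatively.
#'
#' @param events Monitoring events for one plant: tibble with `date` and
#'   `status` in `{"alive", "dead", "flowered"}`, dates strictly
#'   increasing.
#' @param date Assessment date.
#' @return `"alive"` or `"dead"`.
#' @export
plant_status_at <- function(events, date) {
  if (nrow(events) == 0) stop("plant has no monitoring events")
  date <- as.Date(date)
  ev <- events[as.Date(events$date) <= date, ]
  if (any(ev$status == "dead")) "dead" else "alive"
}

# final diameter used for RGR: last measurement at or before the assessment
# date; for flowered plants, the final pre-flowering measurement
.final_measurement <- function(events, assessment_date) {
  ev <- events[as.Date(events$date) <= as.Date(assessment_date), ]
  flw <- which(ev$status == "flowered")
  if (length(flw)) {
    pre <- ev[seq_len(min(flw) - 1), ]
    pre <- pre[!is.na(pre$diameter), ]
  } else {
    pre <- ev[!is.na(ev$diameter), ]
  }
  if (nrow(pre) == 0) return(NULL)
  pre[nrow(pre), c("date", "diameter")]
}

#' Site-level survival and growth performance
#'
#' Cumulative percent survival and mean relative growth rate among
#' survivors at the assessment date. Mean RGR is undefined (`NA`, flagged)
#' when fewer than two plants survive, since a single RGR measurement
#' carries no site-level information.
#'
#' @param plants Tibble with `plant_id`, `site_id`, `initial_diameter`
#'   (cm, at planting).
#' @param events Tibble of monitoring events: `plant_id`, `date`,
#'   `diameter`, `status`. Every plant must have at least one event.
#' @param assessment_date Date at which survival is evaluated.
#' @param planting_date Date of out-planting (start of the growth period).
#' @return One row per site: `site_id`, `n_planted`, `n_surviving`,
#'   `percent_survival` (0-100), `mean_rgr` (per day, `NA` if < 2
#'   survivors), `rgr_defined`.
#' @export
site_performance <- function(plants, events, assessment_date,
                             planting_date) {
  assessment_date <- as.Date(assessment_date)
  planting_date <- as.Date(planting_date)
  no_events <- setdiff(plants$plant_id, unique(events$plant_id))
  if (length(no_events)) {
    stop("plant with no monitoring events: ", no_events[1])
  }
  ev_by_plant <- split(events, events$plant_id)
  per_plant <- lapply(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    ev <- ev_by_plant[[as.character(p$plant_id)]]
    ev <- ev[order(as.Date(ev$date)), ]
    status <- plant_status_at(ev, assessment_date)
    g <- NA_real_
    if (status == "alive") {
      fin <- .final_measurement(ev, assessment_date)
      if (!is.null(fin)) {
        g <- rgr(p$initial_diameter, fin$diameter,
                 as.numeric(as.Date(fin$date) - planting_date))
      }
    }
    tibble::tibble(site_id = p$site_id, alive = status == "alive", rgr = g)
  }) |> dplyr::bind_rows()
  per_plant |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_planted = dplyr::n(),
      n_surviving = sum(.data$alive),
      percent_survival = 100 * .data$n_surviving / .data$n_planted,
      mean_rgr = if (sum(.data$alive & !is.na(.data$rgr)) >= 2) {
        mean(.data$rgr[.data$alive], na.rm = TRUE)
      } else NA_real_,
      rgr_defined = sum(.data$alive & !is.na(.data$rgr)) >= 2,
      .groups = "drop"
    )
}

#' Allocate seedlings to out-plant sites
#'
#' Builds the balanced allocation used in the field design: each site
#' receives `sum(per_site_by_source)` plants split by seed-source
#' elevation (default 14 mid + 28 high), with between `min_per_line` and
#' `max_per_line` siblings from each maternal line per site. Within each
#' site the planting order is randomised under `seed`.
#'
#' @param maternal_counts Tibble with `maternal_id`, `source_elevation`
#'   (`"mid"` or `"high"`) and `n_seedlings` available per line.
#' @param n_sites Number of out-plant sites (default 9).
#' @param per_site_by_source Named counts per site, e.g.
#'   `c(mid = 14, high = 28)`.
#' @param min_per_line,max_per_line Sibling bounds per maternal line per
#'   site (defaults 2 and 8).
#' @param seed Integer seed for the within-site order randomisation.
#' @return Tibble of plants: `plant_id`, `site_id`, `maternal_id`,
#'   `source_elevation`, `position` (randomised order within site).
#' @export
build_design <- function(maternal_counts, n_sites = 9,
                         per_site_by_source = c(mid = 14, high = 28),
                         min_per_line = 2, max_per_line = 8, seed = 1) {
  mc <- maternal_counts
  stopifnot(all(c("maternal_id", "source_elevation", "n_seedlings") %in%
                  names(mc)))
  per_site <- sum(per_site_by_source)
  # feasibility: per-line minimum across all sites
  short <- mc$n_seedlings < min_per_line * n_sites
  if (any(short)) {
    stop("maternal line ", mc$maternal_id[which(short)[1]], " has only ",
         mc$n_seedlings[which(short)[1]], " seedlings; minimum ",
         min_per_line, "/site over ", n_sites, " sites needs ",
         min_per_line * n_sites)
  }
  alloc <- list()
  for (src in names(per_site_by_source)) {
    lines <- mc[mc$source_elevation == src, ]
    q <- per_site_by_source[[src]]
    nl <- nrow(lines)
    if (nl == 0) stop("no maternal lines with source elevation '", src, "'")
    if (q < min_per_line * nl || q > max_per_line * nl) {
      stop("per-site quota ", q, " for source '", src,
           "' infeasible with ", nl, " lines and per-line bounds [",
           min_per_line, ", ", max_per_line, "]")
    }
    if (sum(lines$n_seedlings) < q * n_sites) {
      stop("source '", src, "' has ", sum(lines$n_seedlings),
           " seedlings; design needs ", q * n_sites)
    }
    remaining <- stats::setNames(lines$n_seedlings, lines$maternal_id)
    for (s in seq_len(n_sites)) {
      counts <- stats::setNames(rep(min_per_line, nl), lines$maternal_id)
      sites_left <- n_sites - s + 1
      extra <- q - min_per_line * nl
      for (e in seq_len(extra)) {
        # give the next plant to the line with most spare stock beyond its
        # commitments at the remaining sites
        spare <- remaining - counts - min_per_line * (sites_left - 1)
        spare[counts >= max_per_line] <- -Inf
        pick <- names(which.max(spare))
        if (spare[pick] <= 0) {
          stop("allocation infeasible for source '", src,
               "': per-line stocks cannot meet site quotas")
        }
        counts[pick] <- counts[pick] + 1
      }
      remaining <- remaining - counts
      alloc[[length(alloc) + 1]] <- tibble::tibble(
        site_id = s,
        maternal_id = rep(names(counts), counts),
        source_elevation = src
      )
    }
  }
  plants <- dplyr::bind_rows(alloc)
  withr::with_seed(seed, {
    plants <- plants |>
      dplyr::group_by(.data$site_id) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(position = dplyr::row_number()) |>
      dplyr::ungroup()
  })
  plants <- plants[order(plants$site_id, plants$position), ]
  plants$plant_id <- sprintf("P%03d", seq_len(nrow(plants)))
  plants[, c("plant_id", "site_id", "maternal_id", "source_elevation",
             "position")]
}
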