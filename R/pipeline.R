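# End-to-end pipeline: load -> segment -> summarize -> returns -> prlo, with
# a manifest for reproducibility and a plain-text report renderer.

#' Pipeline configuration
#'
#' @param detections,registry,sightings,temperature input CSV paths.
#' @param out_dir output directory.
#' @param visit_gap_min visit-splitting threshold in minutes (60).
#' @param string_gap_days presence-string threshold in days (30).
#' @param season_start_month,season_end_month mating-window bounds (6, 7).
#' @param min_tag_year,max_tag_year cohort tagging-year bounds.
#' @param as_of_season season used for tag tenure (defaults to
#'   \code{max_tag_year + 10}).
#' @param prlo list of [prlo_params()] arguments for the biennial reference
#'   and mixed alternative.
#' @param seed RNG seed recorded in the manifest.
#' @return validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(detections, registry, sightings, temperature,
                            out_dir, visit_gap_min = 60,
                            string_gap_days = 30,
                            season_start_month = 6, season_end_month = 7,
                            min_tag_year = -Inf, max_tag_year = Inf,
                            as_of_season = NULL, prlo = list(), seed = 1) {
  cfg <- as.list(environment())
  if (visit_gap_min <= 0 || string_gap_days <= 0)
    stop("gap thresholds must be positive", call. = FALSE)
  if (season_end_month < season_start_month)
    stop("season window ends before it starts", call. = FALSE)
  for (p in c(detections, registry, sightings, temperature))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  message(sprintf("[stage %s] start", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[stage %s] done", name))
  out
}

#' Run the full analysis pipeline
#'
#' Executes load, segmentation, within-season summaries, return analysis and
#' the PRLO projection, writes each stage's table under
#' \code{config$out_dir}, and records a manifest (R version, package
#' version, seed, config hash, per-stage record counts).  Any stage failure
#' aborts with the stage name in the error.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of all stage outputs (the report bundle).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  registry <- stage("load", {
    load_registry(config$registry)
  })
  loaded <- stage("load-detections", load_detections(config$detections, registry))
  detections <- loaded$detections
  sightings <- stage("load-sightings", load_sightings(config$sightings, registry))
  temperature <- stage("load-temperature", load_temperature(config$temperature))

  seg <- stage("segment", {
    by_shark <- split(detections, detections$shark_id)
    visits <- do.call(rbind, lapply(by_shark, segment_visits,
                                    gap_minutes = config$visit_gap_min))
    strings <- do.call(rbind, lapply(names(by_shark), function(id) {
      s <- extract_presence_strings(by_shark[[id]],
                                    gap_days = config$string_gap_days)
      tagd <- registry$tagging_date[registry$shark_id == id]
      apply_tagging_exclusion(s, tagd)
    }))
    visits <- visits %||% segment_visits(detections[0, ])
    strings <- strings %||% extract_presence_strings(detections[0, ])
    rownames(visits) <- rownames(strings) <- NULL
    list(visits = visits, strings = strings)
  })

  summaries <- stage("summarize", list(
    season = season_summaries(seg$visits, seg$strings, registry),
    hourly = hourly_profile(detections, registry),
    monthly_events = monthly_event_proportions(seg$strings, registry),
    daily = daily_detection_bins(detections, registry),
    weekly_temp = weekly_max_temperature(temperature)))

  returns <- stage("returns", {
    pres <- build_presence(sightings, detections, registry)
    as_of <- config$as_of_season %||%
      max(pres$histories$tag_season, na.rm = TRUE)
    cls <- do.call(rbind, lapply(pres$histories$intervals, classify_cycles))
    cls <- cbind(shark_id = pres$histories$shark_id, cls)
    report <- cohort_statistics(pres$histories,
                                min_tag_year = config$min_tag_year,
                                max_tag_year = config$max_tag_year,
                                as_of_season = as_of)
    list(histories = pres$histories, season_methods = pres$season_methods,
         classifications = cls, cohort = report)
  })

  prlo_out <- stage("prlo", {
    ref <- do.call(prlo_params, c(config$prlo, list(interval = 2)))
    alt <- do.call(prlo_params, c(config$prlo,
                                  list(schedule = DEFAULT_MIXED_SCHEDULE)))
    reference <- prlo_total(ref, "strict biennial")
    alternative <- prlo_total(alt, "observed mixture")
    list(reference = reference, alternative = alternative,
         reduction_pct = prlo_reduction(reference, alternative))
  })

  bundle <- list(config = config, registry = registry,
                 n_orphans = nrow(loaded$orphans),
                 n_duplicates = loaded$n_duplicates,
                 visits = seg$visits, strings = seg$strings,
                 summaries = summaries, returns = returns, prlo = prlo_out)

  stage("write", {
    write_table(seg$visits, file.path(config$out_dir, "visits.csv"))
    write_table(seg$strings, file.path(config$out_dir, "strings.csv"))
    write_table(summaries$season,
                file.path(config$out_dir, "season_summaries.csv"))
    write_table(summaries$hourly,
                file.path(config$out_dir, "hourly_profile.csv"))
    write_table(summaries$monthly_events,
                file.path(config$out_dir, "monthly_events.csv"))
    write_table(summaries$weekly_temp,
                file.path(config$out_dir, "weekly_temp.csv"))
    hist_flat <- returns$histories
    hist_flat$seasons_present <- vapply(hist_flat$seasons_present,
                                        paste, "", collapse = "|")
    hist_flat$intervals <- vapply(hist_flat$intervals, paste, "",
                                  collapse = "|")
    write_table(hist_flat, file.path(config$out_dir, "histories.csv"))
    write_table(returns$classifications,
                file.path(config$out_dir, "cycles.csv"))
    yaml::write_yaml(returns$cohort,
                     file.path(config$out_dir, "cohort_report.yaml"))
    yaml::write_yaml(list(reference = as.list(prlo_out$reference),
                          alternative = as.list(prlo_out$alternative),
                          reduction_pct = prlo_out$reduction_pct),
                     file.path(config$out_dir, "prlo.yaml"))
  })

  cfg_plain <- unclass(config)
  cfg_plain$out_dir <- NULL  # output location is not an analytic parameter
  cfg_plain <- lapply(cfg_plain, function(x) if (is.numeric(x)) unname(x) else x)
  manifest <- list(
    package_version = as.character(utils::packageVersion("matesite")),
    seed = config$seed,
    config_hash = config_hash(cfg_plain),
    counts = list(detections = nrow(detections), orphans = nrow(loaded$orphans),
                  duplicates_removed = loaded$n_duplicates,
                  sightings = nrow(sightings), visits = nrow(seg$visits),
                  strings = nrow(seg$strings),
                  shark_seasons = nrow(summaries$season),
                  sharks = nrow(registry)))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  bundle$manifest <- manifest
  invisible(bundle)
}

# order-stable hash of the configuration (no external digest dependency:
# serialize deterministically and fold into hex)
config_hash <- function(x) {
  s <- yaml::as.yaml(x[order(names(x))])
  bytes <- utf8ToInt(s)
  h <- rep(5381, 4)
  for (i in seq_along(bytes))
    h[(i %% 4) + 1] <- (h[(i %% 4) + 1] * 33 + bytes[i]) %% 2^26
  paste(sprintf("%07x", h), collapse = "")
}

#' Render a human-readable report from a pipeline bundle
#'
#' Produces a markdown summary: cohort return and cycle statistics,
#' return-interval histograms, monthly arrival/departure proportions,
#' within-season metric medians by sex, and the PRLO table.  Missing bundle
#' sections are listed and the rest rendered.
#'
#' @param bundle the list returned by [run_pipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(bundle) {
  lines <- c("# Mating-site monitoring report", "")
  missing <- setdiff(c("returns", "summaries", "prlo"), names(bundle))
  if (length(missing))
    lines <- c(lines, paste("Missing sections:",
                            paste(missing, collapse = ", ")), "")
  if ("returns" %in% names(bundle)) {
    ch <- bundle$returns$cohort
    lines <- c(lines, "## Long-term returns",
      sprintf("- %d of %d tagged sharks (%d%%) returned in a later mating season",
              ch$n_returning, ch$n_tagged, ch$pct_returning),
      sprintf("- %d%% of returners monitored > 10 y; %d%% > 20 y",
              ch$pct_monitored_gt10y, ch$pct_monitored_gt20y))
    if (is.na(ch$triennial_share_pct)) {
      lines <- c(lines, "- no female intervals")
    } else {
      lines <- c(lines, sprintf(
        "- female triennial share: %.1f%% (%d of %d retained intervals)",
        ch$triennial_share_pct, ch$n_female_three_year,
        ch$n_female_two_year + ch$n_female_three_year),
        sprintf("- switchers among tenured females: %s%% once+, %s%% multiple",
                ch$pct_switched_once, ch$pct_switched_multiple))
    }
    iv <- unlist(bundle$returns$histories$intervals)
    if (length(iv)) {
      tab <- table(iv)
      lines <- c(lines, "", "## Return-interval histogram (years: count)",
                 paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                       collapse = ", "))
    }
  }
  if ("summaries" %in% names(bundle)) {
    ss <- bundle$summaries$season
    if (nrow(ss)) {
      med <- function(sx, col) stats::median(ss[[col]][ss$sex == sx])
      lines <- c(lines, "", "## Within-season medians (per shark-season)")
      for (sx in sort(unique(ss$sex)))
        lines <- c(lines, sprintf(
          "- %s: %.1f visits, mean duration %.2f h, cumulative %.2f d on site",
          sx, med(sx, "n_visits"), med(sx, "mean_visit_duration_h"),
          med(sx, "cumulative_days")))
    }
    me <- bundle$summaries$monthly_events
    if (nrow(me)) {
      lines <- c(lines, "", "## Monthly arrival/departure proportions")
      for (ev in unique(me$event)) for (sx in unique(me$sex)) {
        sub <- me[me$event == ev & me$sex == sx & me$n_events > 0, ]
        if (nrow(sub))
          lines <- c(lines, sprintf("- %s %s: %s", sx, ev,
            paste(sprintf("%s %.0f%%", month.abb[sub$month],
                          100 * sub$proportion), collapse = ", ")))
      }
    }
  }
  if ("prlo" %in% names(bundle)) {
    lines <- c(lines, "", "## Potential reproductive lifetime output",
      sprintf("- %s: %d events, %g pups", bundle$prlo$reference$schedule_label,
              bundle$prlo$reference$n_events, bundle$prlo$reference$total_pups),
      sprintf("- %s: %d events, %g pups",
              bundle$prlo$alternative$schedule_label,
              bundle$prlo$alternative$n_events,
              bundle$prlo$alternative$total_pups),
      sprintf("- reduction: %.1f%%", bundle$prlo$reduction_pct))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
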