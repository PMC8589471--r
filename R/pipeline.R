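# End-to-end orchestration: simulate tooth pairs per group, measure each
# pair, assemble the measured cohort, analyse it and score it, writing a
# machine-readable manifest of every artifact produced.

#' Pipeline configuration
#'
#' One global seed fans out to stable per-stage child seeds, so each stage is
#' independently reproducible. Group geometry is drawn from per-group
#' distributions of the generator parameters, by default mapped from the
#' published per-group feature statistics (contact width from the adjacent
#' line length, contact height from area / width, embrasure angles directly),
#' truncated to the generator's valid ranges.
#'
#' @param seed integer master seed.
#' @param n_per_group synthetic subjects (tooth pairs) per group.
#' @param points_per_tooth surface points per generated tooth.
#' @param noise_sd scan jitter in mm.
#' @param measure a [measure_config()].
#' @param ttest_variant,corr_method passed to [run_full_analysis()].
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_per_group = 20,
                            points_per_tooth = 5000, noise_sd = 0.02,
                            measure = measure_config(),
                            ttest_variant = "welch",
                            corr_method = "spearman",
                            out_dir = file.path(tempdir(), "proxigap_run")) {
  if (n_per_group < 8) stopf("n_per_group must be at least 8")
  structure(list(seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group),
                 points_per_tooth = as.integer(points_per_tooth),
                 noise_sd = noise_sd, measure = measure,
                 ttest_variant = ttest_variant, corr_method = corr_method,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Draw generator specs for one group from its feature distribution,
# truncating to geometrically valid ranges.
group_specs <- function(group_name, n, points_per_tooth, noise_sd, seed) {
  gs <- published_group_stats()
  g <- gs[gs$group == group_name, ]
  par <- function(f) {
    c(g$mean[g$feature == f], g$sd[g$feature == f])
  }
  rtrunc <- function(n, mu, sd, lo, hi) {
    pmin(hi, pmax(lo, rnorm(n, mu, sd)))
  }
  withr::with_seed(seed, {
    w <- rtrunc(n, par("adjacent_line_length_mm")[1],
                par("adjacent_line_length_mm")[2], 2.4, 4.6)
    a <- rtrunc(n, par("adjacent_surface_area_mm2")[1],
                par("adjacent_surface_area_mm2")[2], 4.0, 10.0)
    tb <- rtrunc(n, par("buccal_angle_deg")[1], par("buccal_angle_deg")[2],
                 40, 115)
    tl <- rtrunc(n, par("tongue_angle_deg")[1], par("tongue_angle_deg")[2],
                 40, 115)
    to <- rtrunc(n, par("occlusal_angle_deg")[1], par("occlusal_angle_deg")[2],
                 50, 135)
    lapply(seq_len(n), function(i) {
      tooth_pair_spec(contact_width = w[i],
                      contact_height = min(a[i] / w[i], 2.4),
                      angle_buccal = tb[i], angle_lingual = tl[i],
                      angle_occlusal = to[i],
                      points_per_tooth = points_per_tooth,
                      noise_sd = noise_sd,
                      seed = derive_seed(seed + i, "teeth"))
    })
  })
}

#' Run the full simulate -> measure -> analyse -> score pipeline
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result`: the measured cohort, the
#'   analysis report and the artifact manifest. Artifacts (features CSV,
#'   report bundle, scored table, manifest JSON) are written under
#'   `config$out_dir`; reruns with the same config are byte-identical.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stopf("expected pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s [seed %d, n_per_group %d]",
            name, conditionMessage(e), config$seed, config$n_per_group)
    })
  }
  groups <- c("impaction", "nonimpaction")
  vmsg("simulating %d pairs per group", config$n_per_group)
  specs <- stage("simulate-teeth", {
    s <- lapply(seq_along(groups), function(gi) {
      group_specs(groups[gi], config$n_per_group, config$points_per_tooth,
                  config$noise_sd, derive_seed(config$seed + gi, "teeth"))
    })
    names(s) <- groups
    s
  })
  cohort <- stage("measure", {
    rows <- lapply(groups, function(g) {
      do.call(rbind, lapply(specs[[g]], function(sp) {
        pair <- generate_tooth_pair(sp)
        rec <- measure_all(pair$cloud, config$measure)
        rec$group <- g
        rec
      }))
    })
    tab <- do.call(rbind, rows)
    tab$outcome <- as.integer(tab$group == "impaction")
    rownames(tab) <- NULL
    tab
  })
  features_csv <- file.path(config$out_dir, "features.csv")
  write.csv(cohort, features_csv, row.names = FALSE)

  report <- stage("analyze", run_full_analysis(
    cohort, ttest_variant = config$ttest_variant,
    corr_method = config$corr_method))
  report_paths <- stage("report", write_report(
    report, file.path(config$out_dir, "report")))

  scored <- stage("score", score_features(cohort))
  scored_csv <- file.path(config$out_dir, "scored.csv")
  write.csv(scored, scored_csv, row.names = FALSE)

  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- list(
    config = list(seed = config$seed, n_per_group = config$n_per_group,
                  points_per_tooth = config$points_per_tooth,
                  noise_sd = config$noise_sd,
                  contact_eps = config$measure$contact_eps,
                  extension_len = config$measure$extension_len,
                  alpha = config$measure$alpha,
                  ttest_variant = config$ttest_variant,
                  corr_method = config$corr_method),
    artifacts = c(features_csv, report_paths, scored_csv))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  structure(list(cohort = cohort, report = report,
                 manifest = c(manifest$artifacts, manifest_path),
                 config = config),
            class = "pipeline_result")
}

#' Diagnostic validation of a point-cloud input file
#'
#' Reports format, label counts and per-tooth bounding boxes, with unit
#' sanity warnings when a tooth does not measure between 2 and 30 mm per
#' axis (e.g. metre- or micron-scaled exports). Purely diagnostic: never
#' raises an error for content problems.
#'
#' @param path a PLY file, a pair of STL files, or a [labeled_cloud()].
#' @return A list with `ok` (logical), `messages`, and per-label extents.
#' @export
validate_inputs <- function(path) {
  msgs <- character(0)
  cloud <- tryCatch({
    if (inherits(path, "labeled_cloud")) path else read_model(path)
  }, error = function(e) {
    return(NULL)
  })
  if (is.null(cloud)) {
    return(list(ok = FALSE, messages = "file could not be parsed",
                extents = NULL))
  }
  labs <- sort(unique(cloud$labels))
  if (length(labs) < 2) {
    msgs <- c(msgs, "single label: pair operations unavailable")
  }
  extents <- lapply(labs, function(l) {
    p <- cloud$points[cloud$labels == l, , drop = FALSE]
    apply(p, 2, function(v) diff(range(v)))
  })
  names(extents) <- paste0("label_", labs)
  for (nm in names(extents)) {
    ext <- extents[[nm]]
    if (any(ext < 2) || any(ext > 30)) {
      msgs <- c(msgs, sprintf(
        "%s extent [%s] mm outside the expected 2-30 mm tooth scale: check units",
        nm, paste(sprintf("%.3g", ext), collapse = ", ")))
    }
  }
  list(ok = length(msgs) == 0, messages = if (length(msgs)) msgs else "ok",
       extents = extents)
}
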