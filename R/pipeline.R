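# Provenance manifest echoing every parameter of a run.
run_manifest <- function(arm, params, seed = NULL) {
  list(arm = arm,
       package_version = as.character(utils::packageVersion("gliamorphdyn")),
       seed = seed, params = params, timestamp = format(Sys.time(), tz = "UTC"))
}

write_manifest <- function(manifest, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(NULL)
}

#' Run the in vivo arm: paired dynamics on pre/post time-lapse stacks
#'
#' For each cell, both stacks are registered to their first volume,
#' SD-projected, binarized, and reduced to the mean fractal complexity and
#' the volume-normalized motility index; the paired pre/post values are then
#' compared per metric with the d'Agostino-Pearson-screened paired t-test.
#'
#' @param pairs list of cells, each a list with \code{pre} and \code{post}
#'   ([timelapse_stack()] objects, or [generate_timelapse()] results) and an
#'   optional \code{cell_id}. Cells missing either member are reported and
#'   excluded.
#' @param register run drift registration (default TRUE).
#' @param binarize_method,fixed_threshold forwarded to [binarize()].
#' @param metrics which readouts to compute (\code{"complexity"},
#'   \code{"motility"}, or both).
#' @param out_dir optional directory for the per-cell CSV and run manifest.
#' @return A list with \code{per_cell} (data frame: cell_id, then pre/post
#'   complexity and motility index), \code{tests} (named list of
#'   [paired_comparison()] results for the computed metrics), and
#'   \code{excluded}.
#' @export
run_invivo <- function(pairs, register = TRUE, binarize_method = "otsu",
                       fixed_threshold = NULL,
                       metrics = c("complexity", "motility"),
                       out_dir = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  get_stack <- function(x) {
    if (inherits(x, "timelapse_stack")) x
    else if (!is.null(x$stack)) x$stack
    else NULL
  }
  ok <- vapply(pairs, function(p)
    !is.null(get_stack(p$pre)) && !is.null(get_stack(p$post)), logical(1))
  excluded <- which(!ok)
  if (length(excluded))
    warning(sprintf("%d unpaired cell(s) excluded", length(excluded)))
  pairs <- pairs[ok]
  stopifnot(length(pairs) >= 1)

  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    res <- lapply(list(pre = get_stack(p$pre), post = get_stack(p$post)),
                  analyze_stack_dynamics, register = register,
                  binarize_method = binarize_method,
                  fixed_threshold = fixed_threshold, metrics = metrics)
    row <- data.frame(cell_id = if (!is.null(p$cell_id)) p$cell_id else i)
    if ("complexity" %in% metrics) {
      row$complexity_pre <- res$pre$complexity$mean_dimension
      row$complexity_post <- res$post$complexity$mean_dimension
    }
    if ("motility" %in% metrics) {
      row$motility_pre <- res$pre$motility$normalized_index
      row$motility_post <- res$post$motility$normalized_index
    }
    row
  })
  per_cell <- do.call(rbind, rows)

  tests <- list()
  if (nrow(per_cell) >= 3) {
    if ("complexity" %in% metrics)
      tests$complexity <- paired_comparison(per_cell$complexity_pre,
                                            per_cell$complexity_post,
                                            metric = "complexity")
    if ("motility" %in% metrics)
      tests$motility <- paired_comparison(per_cell$motility_pre,
                                          per_cell$motility_post,
                                          metric = "motility_index")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_cell, file.path(out_dir, "invivo_per_cell.csv"),
                     row.names = FALSE)
    write_manifest(run_manifest("invivo", list(
      register = register, binarize_method = binarize_method,
      fixed_threshold = fixed_threshold, n_cells = nrow(per_cell))), out_dir)
  }
  list(per_cell = per_cell, tests = tests, excluded = excluded)
}

#' Run the ex vivo arm: morphometry and group statistics on section images
#'
#' Segments every image into cells, extracts each cell's skeleton graph and
#' morphometric record, and compares conditions per region with
#' Kruskal-Wallis plus Sidak-corrected post-hoc tests. Border-touching cells
#' are excluded from the statistics by default. Images with no detected
#' cell are logged and skipped.
#'
#' @param images list of entries, each with \code{image} (matrix),
#'   \code{pixel_um}, \code{region}, \code{condition}, optional
#'   \code{image_id}.
#' @param metrics metric columns tested across conditions.
#' @param exclude_border drop border-touching cells from statistics.
#' @param out_dir optional directory for CSV output and the run manifest.
#' @param ... forwarded to [segment_cells()].
#' @return A list with \code{records} (per-cell data frame), \code{summary}
#'   ([summarize_metrics()] table), and \code{tests} (per region x metric
#'   [group_comparison()] results; skipped with a notice when fewer than two
#'   conditions are present).
#' @export
run_exvivo <- function(images,
                       metrics = c("complexity_index", "cea_um2",
                                   "cell_body_area_um2", "cytoplasm_area_um2",
                                   "n_segments", "total_ramification_length_um"),
                       exclude_border = TRUE, out_dir = NULL, ...) {
  recs <- list()
  for (i in seq_along(images)) {
    entry <- images[[i]]
    segs <- segment_cells(entry$image, pixel_um = entry$pixel_um, ...)
    if (!length(segs)) {
      message(sprintf("image %d: no cells detected, skipped", i))
      next
    }
    for (s in segs) {
      g <- tryCatch(extract_graph(s), error = function(e) NULL)
      if (is.null(g)) next
      r <- morphometrics(s, g, region = entry$region,
                         condition = entry$condition)
      r$image_id <- if (!is.null(entry$image_id)) entry$image_id else i
      recs[[length(recs) + 1L]] <- r
    }
  }
  stopifnot(length(recs) >= 1)
  records <- do.call(rbind, recs)
  keep <- if (exclude_border) !records$border_touching else
    rep(TRUE, nrow(records))
  stat_recs <- records[keep, , drop = FALSE]

  summary <- summarize_metrics(stat_recs, metrics)
  tests <- list()
  for (reg in unique(stat_recs$region)) {
    sub <- stat_recs[stat_recs$region == reg, , drop = FALSE]
    conds <- unique(sub$condition)
    if (length(conds) < 2 ||
        any(table(sub$condition) < 3)) {
      message(sprintf(
        "region %s: fewer than two conditions with n >= 3; group tests skipped",
        reg))
      next
    }
    for (met in metrics) {
      groups <- lapply(split(sub[[met]], sub$condition),
                       function(g) g[!is.na(g)])
      if (any(lengths(groups) < 3)) {
        message(sprintf("region %s, metric %s: a group has n < 3; skipped",
                        reg, met))
        next
      }
      tests[[paste(reg, met, sep = ".")]] <-
        group_comparison(groups, metric = met)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "exvivo_records.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "exvivo_summary.csv"),
                     row.names = FALSE)
    write_manifest(run_manifest("exvivo", list(
      metrics = metrics, exclude_border = exclude_border)), out_dir)
  }
  list(records = records, summary = summary, tests = tests)
}

#' One-command synthetic end-to-end demo
#'
#' Generates a small synthetic study from a single seed — a paired in vivo
#' motility cohort with a programmed anesthesia effect, an ex vivo cohort
#' with condition-dependent branching, and the three anesthesia-state EEG
#' presets — runs all pipeline arms, and writes a Markdown report plus CSVs.
#'
#' @param seed RNG seed driving every synthetic input.
#' @param out_dir output directory (default a temporary directory).
#' @param n_cells cells per in vivo cohort.
#' @param effect programmed fractional motility change of the post
#'   condition.
#' @return Invisibly, a list with \code{invivo}, \code{exvivo}, \code{eeg}
#'   (per-state spectral summaries) and \code{report} (path).
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("gliamorphdyn_demo_"),
                     n_cells = 6, effect = -0.17) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  # in vivo arm
  pre <- timelapse_spec(cell = cell_spec(n_roots = 4, branch_prob = 0.6,
                                         max_depth = 3, img_size_px = 96,
                                         segment_len_um = 6,
                                         pixel_size_um = 0.6),
                        n_frames = 3, n_slices = 6, motility_level = 0.10)
  cohort <- generate_paired_cohort(n_cells, pre, effect, seed = seed)
  invivo <- run_invivo(cohort, register = FALSE,
                       out_dir = file.path(out_dir, "invivo"))

  # ex vivo arm: condition-dependent branch probability
  conds <- c(control = 0.9, ketamine_xylazine = 0.45, thiopental = 0.85)
  images <- list()
  for (ci in seq_along(conds)) {
    for (k in 1:4) {
      cs <- cell_spec(n_roots = 4, branch_prob = conds[ci], max_depth = 3,
                      img_size_px = 128, segment_len_um = 7,
                      pixel_size_um = 0.5,
                      seed = seed + 100 * ci + k)
      cell <- generate_cell_image(cs)
      images[[length(images) + 1L]] <-
        list(image = cell$image, pixel_um = rep(cs$pixel_size_um, 2),
             region = "cortex", condition = names(conds)[ci])
    }
  }
  exvivo <- run_exvivo(images, out_dir = file.path(out_dir, "exvivo"))

  # EEG arm
  states <- c("wake", "ketamine_xylazine", "pentobarbital")
  eeg <- lapply(states, function(s) {
    tr <- generate_eeg(eeg_preset(s, duration_s = 60, seed = seed))
    trf <- bandpass(tr, 0.5, 300)
    sp <- power_spectrum(trf)
    ad <- amplitude_distribution(trf)
    list(state = s, whm_hz = sp$whm_hz,
         excess_kurtosis = ad$excess_kurtosis,
         peaks = spectral_peaks(sp, n = 2, max_hz = 10))
  })
  names(eeg) <- states

  report <- file.path(out_dir, "report.md")
  lines <- c(
    "# Synthetic end-to-end demo",
    sprintf("Seed: %d; %d cells per in vivo cohort; programmed motility effect %+.0f%%.",
            seed, n_cells, 100 * effect),
    "", "## EEG state profiles", "",
    "| state | WHM (Hz) | excess kurtosis | dominant peaks < 10 Hz |",
    "|---|---|---|---|",
    vapply(states, function(s) {
      e <- eeg[[s]]
      sprintf("| %s | %.2f | %.2f | %s |", s, e$whm_hz, e$excess_kurtosis,
              paste(sprintf("%.2f Hz", e$peaks$freq_hz), collapse = ", "))
    }, character(1)),
    "", "## In vivo paired comparison", "",
    sprintf("- motility: t = %.2f, p = %.3g (n = %d), mean change %+0.3g /um^3",
            invivo$tests$motility$statistic, invivo$tests$motility$p_value,
            invivo$tests$motility$n, invivo$tests$motility$mean_diff),
    sprintf("- complexity: t = %.2f, p = %.3g",
            invivo$tests$complexity$statistic,
            invivo$tests$complexity$p_value),
    "", "## Ex vivo group summary", "",
    utils::capture.output(print(exvivo$summary[
      exvivo$summary$metric == "complexity_index", ])))
  writeLines(lines, report)
  write_manifest(run_manifest("demo", list(n_cells = n_cells,
                                           effect = effect), seed = seed),
                 out_dir)
  invisible(list(invivo = invivo, exvivo = exvivo, eeg = eeg,
                 report = report))
}
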