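# Orchestration of the full multi-case method-comparison study: for each
# synthetic case, both masking arms feed the hotspot search, two simulated
# observers score manually, and the agreement layer compares all pairs.
# Cases whose serial registration fails are excluded from the VDS arm only
# (pairwise-complete analysis); the rule arm scores every case.

#' Study configuration
#'
#' @param n_cases number of synthetic cases.
#' @param seed master seed; per-case seeds, serial transforms and non-serial
#'   flags derive from it.
#' @param base_spec named list of [slide_spec()] overrides shared by all cases
#'   (the per-case seed, serial transform and serial mode are drawn by the
#'   study).
#' @param nonserial_fraction probability that a case's CK section was not cut
#'   in serial order (0.27 by default: the failure-prone fraction of archival
#'   material the study emulates).
#' @param nonserial_cases optional explicit case indices overriding the random
#'   draw.
#' @param vary_positivity emulate cohort heterogeneity by drawing each case's
#'   baseline positivity from U(0.02, 0.35) and its hotspot peak as baseline +
#'   U(0.15, 0.6) (capped at 0.95), so case-level PIs span the wide range seen
#'   in consecutive clinical series; FALSE keeps the base spec's values for
#'   every case.
#' @param shift_range_um,rot_range_deg per-case serial transform draws
#'   (uniform in +/- range).
#' @param observer_profiles list of two [observer_profile()]s.
#' @param search a [search_params()].
#' @param cell_source "ground_truth" (mask-level study, no rendering) or
#'   "detected" (full image pipeline: render, detect, classify).
#' @param arms DIA arms to run; dropping "vds" skips serial registration
#'   (used for rule-arm-only comparisons).
#' @param mask_resolution_um raster resolution of masks in ground-truth mode.
#' @param vds_fail_threshold registration IoU below which VDS fails.
#' @param out_dir optional output directory (scores.csv, report.json, plots).
#' @return object of class `study_config`.
#' @export
study_config <- function(n_cases = 20, seed = 1, base_spec = list(),
                         nonserial_fraction = 0.27, nonserial_cases = NULL,
                         vary_positivity = TRUE,
                         shift_range_um = 150, rot_range_deg = 2,
                         observer_profiles = list(observer_profile(),
                                                  observer_profile()),
                         search = search_params(),
                         cell_source = c("ground_truth", "detected"),
                         arms = c("rule", "vds"),
                         mask_resolution_um = 4,
                         vds_fail_threshold = 0.6,
                         out_dir = NULL) {
  structure(list(n_cases = n_cases, seed = seed, base_spec = base_spec,
                 nonserial_fraction = nonserial_fraction,
                 nonserial_cases = nonserial_cases,
                 vary_positivity = vary_positivity,
                 shift_range_um = shift_range_um,
                 rot_range_deg = rot_range_deg,
                 observer_profiles = observer_profiles, search = search,
                 cell_source = match.arg(cell_source), arms = arms,
                 mask_resolution_um = mask_resolution_um,
                 vds_fail_threshold = vds_fail_threshold,
                 out_dir = out_dir),
            class = "study_config")
}

epithelium_raster <- function(polys, dims, res) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (rg in polys) {
    if (rg$region_class != "stroma") {
      m <- m | rasterize_polygon(rg$polygon, dims, res)
    }
  }
  m
}

#' Score one case with both DIA arms and two observers
#'
#' @param case a `synthetic_case`.
#' @param config a [study_config()].
#' @return list: per-arm `hotspot`s (vds possibly NULL), observer scores,
#'   the registration result, and the VDS exclusion flag.
#' @export
score_case <- function(case, config = study_config()) {
  res <- config$mask_resolution_um
  ext <- c(case$spec$width_um, case$spec$height_um)
  dims <- c(ceiling(ext[2] / res), ceiling(ext[1] / res))
  exclusions <- Filter(function(r) r$region_class %in%
                         c("benign_epithelium", "carcinoma_in_situ"),
                       case$regions)

  run_vds <- "vds" %in% config$arms
  if (config$cell_source == "detected") {
    dia_cells <- analyse_ki67_image(case$ki67_image)
    ck_epi <- if (run_vds) ck_epithelium_mask(case$ck_image) else NULL
    ck_res <- case$ck_image$resolution_um_per_px
    reg <- if (run_vds) {
      register_serial(case$ck_image, case$ki67_image,
                      fail_threshold = config$vds_fail_threshold)
    }
  } else {
    dia_cells <- case$cells
    ck_res <- res
    ck_epi <- if (run_vds) epithelium_raster(case$ck_regions, dims, res)
    reg <- if (run_vds) {
      register_masks(epithelium_raster(case$regions, dims, res), ck_epi,
                     res_um = res,
                     fail_threshold = config$vds_fail_threshold)
    }
  }

  rule_mask <- build_mask_rule(regions = case$regions, res_um = res,
                               extent_um = ext)
  hs_rule <- find_hotspot(filter_cells_by_mask(dia_cells, rule_mask),
                          config$search, extent_um = ext, method = "rule")
  hs_vds <- NULL
  if (run_vds && reg$status == "success") {
    vds_mask <- build_mask_vds(ck_epi, reg, exclusion_regions = exclusions,
                               res_um = ck_res)
    hs_vds <- tryCatch(
      find_hotspot(filter_cells_by_mask(dia_cells, vds_mask),
                   config$search, extent_um = ext, method = "vds"),
      hotspot_no_window = function(e) NULL)
  }
  obs <- lapply(1:2, function(k) {
    score_manual(case, config$observer_profiles[[k]], observer_id = k,
                 seed = derive_seed(case$spec$seed, paste0("observer", k)))
  })
  list(hotspot_rule = hs_rule, hotspot_vds = hs_vds, observers = obs,
       registration = reg,
       vds_excluded = run_vds && is.null(hs_vds))
}

#' Run the full method-comparison study
#'
#' Generates `n_cases` synthetic cases, scores each with the VDS arm (serial
#' registration + CK mask; excluded on registration failure), the rule arm
#' (always available), and two simulated observers; averages the observers
#' into a consensus; and assembles distribution summaries and pairwise
#' agreement reports (consensus vs VDS on VDS-scored cases only, consensus vs
#' rule, observer 1 vs observer 2).
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: `scores` (long data.frame:
#'   case_id, arm, pi_percent, n_cells), `summaries` (per-arm distribution of
#'   PI and of counted cells), `agreements` (named list of
#'   `agreement_report`s), `vds_excluded` (case ids), `registrations`,
#'   `config`.
#' @export
run_study <- function(config = study_config()) {
  set.seed(derive_seed(config$seed, "study"))
  n <- config$n_cases
  case_seeds <- sample.int(2^31 - 2, n)
  shifts <- matrix(stats::runif(2 * n, -config$shift_range_um,
                                config$shift_range_um), n, 2)
  rots <- stats::runif(n, -config$rot_range_deg, config$rot_range_deg)
  nonserial <- if (!is.null(config$nonserial_cases)) {
    seq_len(n) %in% config$nonserial_cases
  } else {
    stats::runif(n) < config$nonserial_fraction
  }
  base_lo <- stats::runif(n, 0.02, 0.35)
  peak_hi <- pmin(0.95, base_lo + stats::runif(n, 0.15, 0.6))

  rows <- list(); regs <- list(); excluded <- character(0)
  for (i in seq_len(n)) {
    args <- utils::modifyList(config$base_spec, list(
      seed = case_seeds[i], serial_shift_um = shifts[i, ],
      serial_rotation_deg = rots[i],
      serial_mode = if (nonserial[i]) "non_serial" else "serial"))
    if (config$vary_positivity) {
      args$baseline_positivity <- base_lo[i]
      args$hotspot_peak_positivity <- peak_hi[i]
    }
    spec <- do.call(slide_spec, args)
    case <- simulate_case(spec, render = config$cell_source == "detected")
    sc <- score_case(case, config)
    cid <- sprintf("case_%03d", i)
    regs[[cid]] <- sc$registration
    add <- function(arm, pi, n_cells) {
      data.frame(case_id = cid, arm = arm, pi_percent = pi,
                 n_cells = n_cells, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- add("rule", sc$hotspot_rule$pi_percent,
                                    sc$hotspot_rule$n_cells)
    if (!is.null(sc$hotspot_vds)) {
      rows[[length(rows) + 1]] <- add("vds", sc$hotspot_vds$pi_percent,
                                      sc$hotspot_vds$n_cells)
    } else if (sc$vds_excluded) {
      excluded <- c(excluded, cid)
    }
    o1 <- sc$observers[[1]]; o2 <- sc$observers[[2]]
    rows[[length(rows) + 1]] <- add("observer1", o1$pi_percent, o1$n_counted)
    rows[[length(rows) + 1]] <- add("observer2", o2$pi_percent, o2$n_counted)
    rows[[length(rows) + 1]] <- add("consensus",
                                    consensus_mean(o1$pi_percent,
                                                   o2$pi_percent), NA)
  }
  scores <- do.call(rbind, rows)

  arm_scores <- function(arm) {
    s <- scores[scores$arm == arm, ]
    stats::setNames(s$pi_percent, s$case_id)
  }
  summaries <- do.call(rbind, lapply(unique(scores$arm), function(a) {
    s <- scores[scores$arm == a, ]
    data.frame(arm = a, metric = c("pi_percent", "n_cells"),
               rbind(summarize_distribution(s$pi_percent),
                     if (all(is.na(s$n_cells))) rep(NA_real_, 6)
                     else summarize_distribution(s$n_cells)))
  }))

  cons <- arm_scores("consensus"); rule <- arm_scores("rule")
  vds <- arm_scores("vds")
  o1 <- arm_scores("observer1"); o2 <- arm_scores("observer2")
  agreements <- list(
    observer1_vs_observer2 = bland_altman(
      paired_scores(names(o1), o1, o2, "observer 1", "observer 2")),
    rule_vs_consensus = bland_altman(
      paired_scores(names(cons), rule[names(cons)], cons,
                    "rule-arm DIA", "manual consensus")))
  if (length(vds) >= 3) {
    agreements$vds_vs_consensus <- bland_altman(
      paired_scores(names(vds), vds, cons[names(vds)],
                    "VDS-arm DIA", "manual consensus"))
  }
  report <- structure(list(scores = scores, summaries = summaries,
                           agreements = agreements, vds_excluded = excluded,
                           registrations = regs, config = config),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  n <- length(unique(x$scores$case_id))
  if ("vds" %in% x$config$arms) {
    cat(sprintf("study_report: %d cases; VDS arm %d/%d scored (%d excluded)\n",
                n, n - length(x$vds_excluded), n, length(x$vds_excluded)))
  } else {
    cat(sprintf("study_report: %d cases (rule arm only)\n", n))
  }
  for (a in unique(x$scores$arm)) {
    s <- x$scores[x$scores$arm == a, "pi_percent"]
    cat(sprintf("  %-10s mean PI %5.1f%% (median %5.1f%%)\n", a,
                mean(s), stats::median(s)))
  }
  for (nm in names(x$agreements)) {
    g <- x$agreements[[nm]]
    cat(sprintf("  %s: r = %.2f, mean diff = %.1f\n",
                paste(g$label_a, "vs", g$label_b), g$spearman_r,
                g$mean_difference))
  }
  invisible(x)
}

#' Write study outputs (CSV scores, JSON report, agreement plots)
#' @param report a `study_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "scores.csv")
  utils::write.csv(report$scores, paths[1], row.names = FALSE, quote = FALSE)
  strip <- function(g) g[setdiff(names(g), c("means", "differences"))]
  js <- list(n_cases = length(unique(report$scores$case_id)),
             vds_excluded = report$vds_excluded,
             summaries = report$summaries,
             agreements = lapply(report$agreements, function(g)
               strip(unclass(g))),
             registration_scores = lapply(report$registrations, function(r)
               list(score = r$alignment_score, status = r$status)))
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  for (nm in names(report$agreements)) {
    g <- report$agreements[[nm]]
    p1 <- file.path(dir, paste0("bland_altman_", nm, ".png"))
    p2 <- file.path(dir, paste0("scatter_", nm, ".png"))
    ggplot2::ggsave(p1, plot_bland_altman(g), width = 5, height = 4, dpi = 120)
    ggplot2::ggsave(p2, plot_score_scatter(g), width = 5, height = 4, dpi = 120)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
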