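# End-to-end study orchestration: the 48-condition cultivation grid with
# its index strings, and seeded simulate -> segment -> summarise -> OVL ->
# regress (2D) and simulate -> architecture metrics (3D) runs.

#' The full cultivation condition grid
#'
#' All 48 combinations of spore concentration (5e4, 5e5, 5e6 per mL),
#' shaking frequency (150, 250 rpm), talc concentration (0, 1, 5, 10 g/L)
#' and flask baffling, with their condition index strings.
#'
#' @return data.frame with \code{spore_conc}, \code{agitation_rpm},
#'   \code{talc_g_per_l}, \code{baffled}, \code{condition}.
#' @export
condition_grid <- function() {
  g <- expand.grid(spore_conc = c(5e4, 5e5, 5e6),
                   agitation_rpm = c(150, 250),
                   talc_g_per_l = c(0, 1, 5, 10),
                   baffled = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE)
  g$condition <- condition_index(g$spore_conc, g$agitation_rpm,
                                 g$talc_g_per_l, g$baffled)
  g
}

#' Condition index string
#'
#' Formats a cultivation condition as \code{S\{4|5|6\}-A\{L|H\}-T\{0|1|5|10\}-B\{0|1\}},
#' e.g. \code{"S6-AH-T0-B1"} for 5e6 spores/mL, 250 rpm, no talc, baffled.
#'
#' @param spore_conc spores per mL (5e4, 5e5 or 5e6).
#' @param agitation_rpm 150 or 250.
#' @param talc_g_per_l 0, 1, 5 or 10.
#' @param baffled logical.
#' @return character vector of index strings.
#' @export
condition_index <- function(spore_conc, agitation_rpm, talc_g_per_l, baffled) {
  sprintf("S%d-A%s-T%d-B%d",
          as.integer(round(log10(spore_conc / 5))),
          ifelse(agitation_rpm >= 200, "H", "L"),
          as.integer(talc_g_per_l),
          as.integer(baffled))
}

# Per-condition pixel calibration: the opening structuring element (radius
# 10 px) erases objects smaller than ~2 x 10 px, so the pixel size must keep
# 100 um pellets above that limit wherever such pellets can occur. Large-
# pellet conditions (no mass near 100 um) image coarser for speed.
pixel_size_for_median <- function(median_um) if (median_um >= 480) 10 else 4

# maximal leading subset of `preds` whose columns vary and are linearly
# independent of each other (and the intercept) on `dataset`
independent_predictors <- function(dataset, preds) {
  keep <- character(0)
  X <- matrix(1, nrow(dataset), 1)
  for (p in preds) {
    v <- dataset[[p]]
    cand <- cbind(X, v)
    if (qr(cand)$rank == ncol(cand)) {
      keep <- c(keep, p)
      X <- cand
    }
  }
  keep
}

# ground-truth condition model used by the simulator: loglinear in ln(spore),
# ln(agitation) and talc, no baffle effect, plus flask-to-flask noise
true_median_diameter <- function(spore_conc, agitation_rpm, talc_g_per_l,
                                 coef = c(b0 = 19.47, bS = -0.25,
                                          bA = -1.7769, bT = -0.10856)) {
  exp(coef["b0"] + coef["bS"] * log(spore_conc) +
        coef["bA"] * log(agitation_rpm) + coef["bT"] * talc_g_per_l)
}

#' Run a seeded synthetic 2D study
#'
#' For each condition and replicate: draw a pellet diameter population from
#' the condition's ground-truth median, render two aliquot micrographs,
#' segment both and pool the records, and summarise the population. Per
#' condition, the replicate OVL matrix is computed; across conditions, the
#' replicate-median table is assembled and the diameter regression fitted
#' (full model, then backward elimination).
#'
#' @param conditions data.frame as from \code{\link{condition_grid}} (or a
#'   subset of its rows).
#' @param replicates flask replicates per condition.
#' @param seed root seed; every stage derives its own stream from it.
#' @param pixel_size um per pixel of the rendered micrographs; NULL
#'   (default) calibrates per condition so the reconstruction filter cannot
#'   erase admissible 100 um pellets.
#' @param intra_spread ln-scale diameter spread within a flask.
#' @param flask_sd ln-scale flask-to-flask noise on the median.
#' @param pellets_per_replicate pellet count per replicate; default scales
#'   inversely with the condition's median diameter (large pellets are
#'   fewer), clamped to [40, 120].
#' @param out_dir optional directory to write summary and OVL CSVs into.
#' @return list with \code{summaries} (one row per replicate), \code{ovl}
#'   (named list of \code{replicate_ovl} per condition), \code{dataset}
#'   (admissible regression rows), \code{full_model}, \code{reduced_model}.
#' @export
run_2d_study <- function(conditions, replicates = 3, seed = 1L,
                         pixel_size = NULL, intra_spread = 0.22,
                         flask_sd = 0.08, pellets_per_replicate = NULL,
                         out_dir = NULL) {
  rows <- list(); ovls <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    med0 <- true_median_diameter(cond$spore_conc, cond$agitation_rpm,
                                 cond$talc_g_per_l)
    px <- pixel_size %||% pixel_size_for_median(med0)
    diam_lists <- list()
    for (ri in seq_len(replicates)) {
      sd_k <- derive_seed(seed, ci * 1000L + ri)
      med_flask <- with_seed(sd_k, med0 * exp(rnorm(1, 0, flask_sd)))
      n_pel <- pellets_per_replicate %||%
        max(40L, min(120L, round(3e4 / med_flask)))
      spec <- population_spec(
        data.frame(weight = 1, median_diameter = min(med_flask, 3500),
                   spread = intra_spread), n_pel)
      diams <- gen_population_diameters(spec, derive_seed(sd_k, 1L))
      diams <- pmin(diams, 2900) # keep the scene renderable/in range
      split <- rep(1:2, length.out = length(diams))
      samples <- lapply(1:2, function(a) {
        sc <- render_micrograph(diams[split == a], px,
                                seed = derive_seed(sd_k, 10L + a))
        image_sample(sc$image, px,
                     sprintf("%s-%s", cond$condition, paste0("R", ri)))
      })
      recs <- segment_replicate(samples)
      sm <- summarize_population(recs$ed_um)
      diam_lists[[ri]] <- recs$ed_um
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond$condition, spore_conc = cond$spore_conc,
        agitation_rpm = cond$agitation_rpm,
        talc_g_per_l = cond$talc_g_per_l, baffled = cond$baffled,
        replicate_id = paste0("R", ri),
        median_ed_um = sm$median_ed, iqr_um = sm$iqr, n_pellets = sm$n,
        excluded = sm$excluded, modality = sm$modality %||% NA_character_)
    }
    ovls[[cond$condition]] <- ovl_replicates(diam_lists)
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL

  dataset <- build_regression_dataset(summaries)
  # a condition subset may not span the full design: keep the maximal
  # leading set of predictors that vary and stay linearly independent
  preds <- independent_predictors(dataset,
                                  c("ln_spore", "ln_agitation", "talc",
                                    "baffle"))
  full_model <- fit_diameter_model(dataset, preds)
  reduced_model <- eliminate_nonsignificant(dataset, preds)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summaries, file.path(out_dir, "replicate_summaries.csv"),
              row.names = FALSE)
    ovl_tab <- data.frame(condition = names(ovls),
                          mean_ovl = vapply(ovls, `[[`, numeric(1), "mean_ovl"))
    write.csv(ovl_tab, file.path(out_dir, "ovl_by_condition.csv"),
              row.names = FALSE)
  }
  list(summaries = summaries, ovl = ovls, dataset = dataset,
       full_model = full_model, reduced_model = reduced_model)
}

#' Run a seeded synthetic 3D study
#'
#' Generates pellet volumes with varying numbers of spore cores, computes
#' all architecture metrics per pellet (volume-equivalent diameter, spore
#' cluster count, class, centre solid fraction, skeleton metrics) and
#' aggregates class counts and the per-shell population profile (per-shell
#' mean and SD of the solid fraction across pellets).
#'
#' @param n_pellets number of volumes to generate.
#' @param core_counts vector sampled (uniformly) for the per-pellet number
#'   of spore cores.
#' @param fraction_fused fraction of pellets built as fusion constructs.
#' @param voxel_size um per voxel.
#' @param growth growth parameters, see \code{\link{gen_pellet_volume}}.
#' @param talc_fraction talc fraction of solid voxels.
#' @param seed root seed.
#' @param skeleton_from \code{"graph"} (exact, from the ground-truth
#'   geometric graph) or \code{"voxels"} (thinning route).
#' @return list with \code{metrics} (one row per pellet),
#'   \code{class_counts}, \code{profile_mean} (per-shell mean/SD table) and
#'   \code{failures}.
#' @export
run_3d_study <- function(n_pellets = 20, core_counts = 1:3,
                         fraction_fused = 0, voxel_size = 4,
                         growth = list(segment_length = 10,
                                       branch_probability = 0.25,
                                       radial_bias = 0.6, n_steps = 12,
                                       initial_tips = 10),
                         talc_fraction = 0, seed = 1L,
                         skeleton_from = c("graph", "voxels")) {
  skeleton_from <- match.arg(skeleton_from)
  rows <- list(); failures <- list(); profiles <- list()
  n_fused <- round(fraction_fused * n_pellets)
  for (i in seq_len(n_pellets)) {
    sd_i <- derive_seed(seed, i)
    fused <- i <= n_fused
    ncores <- with_seed(derive_seed(sd_i, 99L),
                        sample(rep(core_counts, 2), 1))
    res <- tryCatch({
      pv <- gen_pellet_volume(n_cores = if (fused) 1 else ncores,
                              core_separation = 150, growth = growth,
                              talc_fraction = talc_fraction,
                              voxel_size = voxel_size, fused = fused,
                              seed = sd_i)
      vol <- pv$volume
      prof <- radial_solid_fraction(vol)
      cl <- detect_spore_clusters(vol)
      asym <- asymmetry_score(vol, centre = prof$centre)
      elong <- elongation_score(vol)
      pc <- classify_pellet(cl, prof, asym, elong)
      sk <- if (skeleton_from == "graph") skeleton_metrics(pv$truth$graph)
      else skeleton_metrics(vol)
      profiles[[length(profiles) + 1L]] <- prof
      data.frame(pellet = i,
                 ed3d_um = volume_equivalent_diameter(vol),
                 nSC = cl$n_clusters, class = pc$value,
                 true_n_cores = pv$truth$n_cores,
                 true_class = pv$truth$class_label,
                 centre_solid_fraction = prof$solid_fraction[1],
                 asymmetry = asym, elongation = elong,
                 total_length_um = sk$total_length,
                 n_tips = sk$n_tips, n_branch_points = sk$n_branch_points)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(pellet = i, message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  metrics <- do.call(rbind, rows)
  class_counts <- if (!is.null(metrics)) table(metrics$class) else table(character(0))

  profile_mean <- NULL
  if (length(profiles) > 0) {
    nsh <- max(vapply(profiles, function(p) length(p$solid_fraction),
                      integer(1)))
    mat <- vapply(profiles, function(p) {
      c(p$solid_fraction, rep(0, nsh - length(p$solid_fraction)))
    }, numeric(nsh))
    mat <- matrix(mat, nrow = nsh)
    bounds <- profiles[[which.max(vapply(profiles, function(p)
      length(p$solid_fraction), integer(1)))]]$shell_bounds
    profile_mean <- data.frame(
      shell_lo = bounds[-length(bounds)], shell_hi = bounds[-1],
      mean_solid_fraction = rowMeans(mat, na.rm = TRUE),
      sd_solid_fraction = apply(mat, 1, sd, na.rm = TRUE))
  }
  list(metrics = metrics, class_counts = class_counts,
       profile_mean = profile_mean, failures = failures)
}
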