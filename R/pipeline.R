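#' Pipeline configuration
#'
#' Collects every tunable of the atlas-construction pipeline with its
#' default: the claiming confidence `alpha = 3`, the minimum cluster
#' fraction `min_fraction = 0.10` of the K-selection rule, the EM settings,
#' the smoothing radius applied to the sharp atlas, and the tie-break
#' priority.
#'
#' @param cohort_dir Directory readable by [read_cohort()] (or NULL when an
#'   in-memory cohort is passed to [run_pipeline()]).
#' @param out_dir Output directory.
#' @param alpha Claiming confidence parameter.
#' @param min_fraction Minimum admissible cluster fraction for K selection.
#' @param k_max Largest cluster count tried per territory.
#' @param seed Master seed.
#' @param n_restarts,tol,max_iter EM settings (see [bmm()]).
#' @param smoothing_radius Modal-filter radius (voxels) for the sharp
#'   atlas.
#' @param parcellation Optional [label_volume()] for per-ROI CI summaries.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_dir = NULL, out_dir = tempfile("atlas_"),
                            alpha = 3, min_fraction = 0.10, k_max = 4,
                            seed = 1, n_restarts = 10, tol = 1e-6,
                            max_iter = 500, smoothing_radius = 1,
                            parcellation = NULL) {
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir, alpha = alpha,
                 min_fraction = min_fraction, k_max = k_max, seed = seed,
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter,
                 smoothing_radius = smoothing_radius,
                 parcellation = parcellation,
                 priority = TERRITORY_PRIORITY),
            class = "pipeline_config")
}

#' Run the full atlas-construction pipeline
#'
#' Cohort to atlases in one call: left-lateralize all masks; compute
#' average-method probability maps (written as a 4D file in ACA/MCA/PCA/VB
#' order) and the MCA/ACA and MCA/PCA border-zone ratio maps; fit a
#' Bernoulli mixture per territory with K chosen by the minimum
#' cluster-fraction rule and write the mu_max 4D file and cluster summary
#' table; build the territory-claimed map at the configured alpha, resolve
#' overlaps and water-spread to a full claim atlas; build the sharp atlas
#' from the average maps, smooth it, and merge it to level 2; compute
#' certainty-index maps (and a per-ROI table when a parcellation is
#' supplied); and write a plain-text run log of every setting. Reruns with
#' the same configuration and cohort are identical.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional in-memory [lesion_cohort()]; otherwise read from
#'   `config$cohort_dir`.
#' @param brain_mask Optional brain mask; defaults to the union of all
#'   lesion supports, dilated by nothing (an explicit mask is recommended).
#' @return Invisibly, a list with the main in-memory results and the
#'   output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         brain_mask = NULL) {
  stage <- "load cohort"
  res <- tryCatch({
    if (is.null(cohort)) {
      if (is.null(config$cohort_dir)) stop("no cohort and no cohort_dir")
      cohort <- read_cohort(config$cohort_dir)
    }
    out <- config$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    log_lines <- c("vascter pipeline run log",
                   paste0("  subjects: ", length(cohort$masks)),
                   paste0("  grid: ", format(cohort$grid)),
                   paste0("  alpha: ", config$alpha, " (claiming confidence)"),
                   paste0("  min_fraction: ", config$min_fraction,
                          " (K-selection rule)"),
                   paste0("  k_max: ", config$k_max),
                   paste0("  seed: ", config$seed),
                   paste0("  n_restarts: ", config$n_restarts),
                   paste0("  tol: ", config$tol),
                   paste0("  max_iter: ", config$max_iter),
                   paste0("  smoothing_radius: ", config$smoothing_radius),
                   paste0("  tie priority: ",
                          paste(config$priority, collapse = " > ")))

    stage <- "flip to left"
    cohort <- flip_cohort_to_left(cohort)

    if (is.null(brain_mask)) {
      acc <- array(0L, cohort$grid$shape)
      for (m in cohort$masks) acc <- acc | m
      brain_mask <- array(as.integer(acc), cohort$grid$shape)
      log_lines <- c(log_lines, "  brain mask: union of lesion masks")
    }

    stage <- "average maps"
    avg <- average_prob_maps(cohort)
    terr <- names(avg$maps)
    if (length(setdiff(TERRITORIES, terr)) == 0L)
      write_prob_maps_4d(avg, file.path(out, "prob_average_4d.nii.gz"))

    stage <- "border ratios"
    ratios <- list()
    for (pair in list(c("MCA", "ACA"), c("MCA", "PCA")))
      if (all(pair %in% terr))
        ratios[[paste(pair, collapse = "_")]] <-
          border_ratio(avg, pair[1], pair[2])

    stage <- "certainty index"
    ci <- certainty_index(avg)
    ci_table <- if (!is.null(config$parcellation))
      mean_ci_by_roi(ci, config$parcellation) else NULL
    if (!is.null(ci_table))
      utils::write.table(ci_table, file.path(out, "ci_by_roi.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "mixture fits"
    fits <- list(); summaries <- list()
    for (s in terr) {
      sel <- select_k(cohort, territory = s, k_max = config$k_max,
                      min_fraction = config$min_fraction,
                      seed = config$seed, n_restarts = config$n_restarts,
                      tol = config$tol, max_iter = config$max_iter)
      fits[[s]] <- sel$fit
      tab <- cluster_expectations(sel$fit)
      tab <- cbind(territory = s, tab)
      summaries[[s]] <- tab
      log_lines <- c(log_lines,
                     paste0("  ", s, ": K = ", sel$K, " of ", config$k_max,
                            " (largest all-clusters >= ",
                            config$min_fraction, " fraction)"))
    }
    cluster_table <- do.call(rbind, summaries)
    utils::write.table(cluster_table, file.path(out, "cluster_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bmm_maps <- prob_map_set(lapply(fits, mu_max_map),
                             n_subjects = n_subjects(cohort),
                             method = "bmm", grid = cohort$grid)
    if (length(setdiff(TERRITORIES, terr)) == 0L)
      write_prob_maps_4d(bmm_maps, file.path(out, "prob_bmm_4d.nii.gz"))

    stage <- "territory claiming"
    claim <- claim_voxels(fits, brain_mask, alpha = config$alpha)
    write_volume(claim$data, file.path(out, "territory_voxels_bmm.nii.gz"),
                 grid = cohort$grid, datatype = "uint8")
    resolved <- resolve_overlaps(claim, fits)
    claim_atlas <- water_spread(resolved, brain_mask)

    stage <- "sharp atlas"
    atlas1 <- sharp_atlas_from_prob(avg, brain_mask)
    atlas1 <- smooth_labels(atlas1, config$smoothing_radius)
    atlas2 <- merge_to_level2(atlas1)
    write_volume(atlas1$data, file.path(out, "atlas_level1.nii.gz"),
                 grid = cohort$grid, datatype = "uint8")
    write_volume(atlas2$data, file.path(out, "atlas_level2.nii.gz"),
                 grid = cohort$grid, datatype = "uint8")
    write_label_scheme(atlas1$scheme, file.path(out, "atlas_labels.txt"))

    writeLines(log_lines, file.path(out, "run_log.txt"))
    list(cohort = cohort, average = avg, ratios = ratios, ci = ci,
         ci_table = ci_table, fits = fits, cluster_table = cluster_table,
         bmm_maps = bmm_maps, claim = claim, claim_atlas = claim_atlas,
         atlas_level1 = atlas1, atlas_level2 = atlas2, out_dir = out)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Apply the cohort exclusion flags
#'
#' Keeps participants for whom none of the four exclusion flags is set:
#' confirmed cardioembolic origin, bilateral stroke, stroke exclusively in
#' watershed areas, or multifocal stroke. Reports the identified, excluded
#' and included counts.
#'
#' @param participants data.frame with logical columns `cardioembolic`,
#'   `bilateral`, `watershed_only`, `multifocal`.
#' @return List with `included` (the retained rows) and `counts` (named
#'   vector: identified, excluded, included).
#' @export
exclusion_filter <- function(participants) {
  req <- c("cardioembolic", "bilateral", "watershed_only", "multifocal")
  missing <- setdiff(req, names(participants))
  if (length(missing))
    stop("participants table lacks flag column(s): ",
         paste(missing, collapse = ", "))
  flagged <- Reduce(`|`, lapply(req, function(cl)
    as.logical(participants[[cl]])))
  flagged[is.na(flagged)] <- FALSE
  included <- participants[!flagged, , drop = FALSE]
  counts <- c(identified = nrow(participants),
              excluded = sum(flagged),
              included = nrow(included))
  list(included = included, counts = counts)
}
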