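#' Configuration for an end-to-end concordance run
#'
#' @param mode `"synthetic"` (phantom cohort from a [cohort_scenario]) or
#'   `"files"` (NIfTI volumes listed in a manifest).
#' @param scenario a [cohort_scenario]; required in synthetic mode.
#' @param manifest `data.frame` with columns `lesion`, `suv`, `adc`,
#'   `dwi` (NIfTI paths); required in files mode.
#' @param readers `data.frame` with columns `lesion`, `reader`, `dx`,
#'   `dy`, `dz` giving each reader's MRI-to-PET translation; required in
#'   files mode (synthetic mode generates its own).
#' @param threshold either a fixed match threshold in mm (e.g. 12) or
#'   `"derived"` to compute it from the readers' translation differences
#'   via [accuracy_threshold].
#' @param seg_cfg an [adaptive_threshold_config].
#' @param refine_cfg a [histogram_refine_config].
#' @param sphere_volume_cm3 sphere volume for neighbourhood statistics.
#' @param out_dir optional directory for CSV outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       scenario = NULL, manifest = NULL, readers = NULL,
                       threshold = 12,
                       seg_cfg = adaptive_threshold_config(),
                       refine_cfg = histogram_refine_config(),
                       sphere_volume_cm3 = 1,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (!inherits(scenario, "cohort_scenario"))
      stop("synthetic mode needs a cohort_scenario")
  } else {
    if (is.null(manifest))
      stop("files mode needs a manifest data.frame")
    need <- c("lesion", "suv", "adc", "dwi")
    if (!all(need %in% names(manifest)))
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    missing <- unlist(manifest[, c("suv", "adc", "dwi")])
    missing <- missing[!file.exists(missing)]
    if (length(missing) > 0)
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    if (is.null(readers) ||
        !all(c("lesion", "reader", "dx", "dy", "dz") %in% names(readers)))
      stop("files mode needs a readers table ",
           "(lesion, reader, dx, dy, dz)")
  }
  if (is.numeric(threshold)) {
    if (threshold <= 0) stop("fixed threshold must be > 0")
  } else if (!identical(threshold, "derived")) {
    stop('threshold must be a positive number or "derived"')
  }
  structure(list(mode = mode, scenario = scenario, manifest = manifest,
                 readers = readers, threshold = threshold,
                 seg_cfg = seg_cfg, refine_cfg = refine_cfg,
                 sphere_volume_cm3 = sphere_volume_cm3,
                 out_dir = out_dir),
            class = "run_config")
}

#' Analyze one SUV/ADC/DWI lesion pair
#'
#' The per-lesion engine: segments the PET VOI by adaptive thresholding
#' (seeded at the global SUV maximum unless a seed is given), delineates
#' the lesion on the DWI volume, transfers the mask to the ADC map,
#' refines it by histogram outlier removal, and assembles the full
#' concordance record.
#'
#' @param suv,adc,dwi [image_volume]s of the respective modalities.
#' @param translation [translation_vector] mapping MRI world coordinates
#'   into the PET frame.
#' @param threshold_mm spatial-match threshold in mm.
#' @param seed_point optional PET-frame seed (mm) for the VOI
#'   segmentation; default the global SUV maximum.
#' @param seg_cfg,refine_cfg,sphere_volume_cm3 see [run_config].
#' @param lesion_id,reader_id identifiers for the record.
#' @return list with `record` (one-row data.frame, see [lesion_report]),
#'   `pet_mask`, `adc_mask` (refined), `removed_voxels` (histogram
#'   refinement count).
#' @export
analyze_lesion_pair <- function(suv, adc, dwi, translation,
                                threshold_mm = 12, seed_point = NULL,
                                seg_cfg = adaptive_threshold_config(),
                                refine_cfg = histogram_refine_config(),
                                sphere_volume_cm3 = 1,
                                lesion_id = 1L, reader_id = 1L) {
  if (is.null(seed_point)) {
    w <- which(suv$values == max(suv$values), arr.ind = TRUE)[1, ]
    seed_point <- world_coords(suv, w)
  }
  pet_mask <- segment_pet_voi(suv, seed_point, seg_cfg)
  dwi_mask <- segment_dwi(dwi)
  adc_mask0 <- transfer_mask(dwi_mask, adc)
  ref <- refine_adc_roi(adc, adc_mask0, refine_cfg)
  rec <- lesion_report(suv, adc, pet_mask, ref$mask, translation,
                       threshold_mm = threshold_mm,
                       sphere_volume_cm3 = sphere_volume_cm3,
                       lesion_id = lesion_id, reader_id = reader_id)
  rec$removed_voxels <- ref$removed
  list(record = rec, pet_mask = pet_mask, adc_mask = ref$mask,
       removed_voxels = ref$removed)
}

#' Run the full concordance pipeline over a cohort
#'
#' Generates (or loads) every lesion pair, derives or applies the
#' spatial-match threshold, computes per-lesion records for every
#' reader's translation, and aggregates stratified correlations and
#' Bland-Altman interobserver agreement. Identical configuration and
#' seeds give identical outputs.
#'
#' @param config a [run_config].
#' @return list with `records` (data.frame over lesions x readers),
#'   `threshold_mm`, `registration` ([accuracy_threshold] result or
#'   `NULL` when fixed), `correlations` (per-reader stratified table),
#'   `bland_altman` (distance and ADCmin agreement between the first two
#'   readers, or `NULL` with one reader), `truth` (synthetic mode only).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (config$mode == "synthetic") {
    cohort <- make_cohort(config$scenario)
    lesions <- cohort$lesions
    readers <- cohort$readers
    truth <- cohort$truth
  } else {
    man <- config$manifest
    lesions <- lapply(seq_len(nrow(man)), function(i) {
      list(suv = read_nifti(man$suv[i], "SUV"),
           adc = read_nifti(man$adc[i], "ADC"),
           dwi = read_nifti(man$dwi[i], "DWI_B800"))
    })
    readers <- config$readers
    truth <- NULL
  }

  reader_ids <- sort(unique(readers$reader))
  registration <- NULL
  if (identical(config$threshold, "derived")) {
    if (length(reader_ids) < 2)
      stop("deriving the threshold needs at least two readers")
    r1 <- readers[readers$reader == reader_ids[1], ]
    r2 <- readers[readers$reader == reader_ids[2], ]
    r1 <- r1[order(r1$lesion), ]; r2 <- r2[order(r2$lesion), ]
    diffs <- sqrt((r1$dx - r2$dx)^2 + (r1$dy - r2$dy)^2 +
                  (r1$dz - r2$dz)^2)
    registration <- accuracy_threshold(diffs)
    threshold_mm <- registration$upper95
  } else {
    threshold_mm <- config$threshold
  }

  recs <- list()
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    for (r in reader_ids) {
      row <- readers[readers$lesion == i & readers$reader == r, ]
      tr <- translation_vector(row$dx, row$dy, row$dz)
      res <- analyze_lesion_pair(
        les$suv, les$adc, les$dwi, tr,
        threshold_mm = threshold_mm,
        seg_cfg = config$seg_cfg, refine_cfg = config$refine_cfg,
        sphere_volume_cm3 = config$sphere_volume_cm3,
        lesion_id = i, reader_id = r)
      recs[[length(recs) + 1L]] <- res$record
    }
  }
  records <- do.call(rbind, recs)

  correlations <- do.call(rbind, lapply(reader_ids, function(r) {
    tab <- stratified_correlations(records[records$reader == r, ])
    cbind(data.frame(reader = r), tab)
  }))

  ba <- NULL
  if (length(reader_ids) >= 2) {
    a <- records[records$reader == reader_ids[1], ]
    b <- records[records$reader == reader_ids[2], ]
    a <- a[order(a$lesion), ]; b <- b[order(b$lesion), ]
    if (nrow(a) >= 3)
      ba <- list(distance = bland_altman(a$distance_mm, b$distance_mm),
                 adc_min = bland_altman(a$adc_min, b$adc_min))
  }

  out <- list(records = records, threshold_mm = threshold_mm,
              registration = registration, correlations = correlations,
              bland_altman = ba, truth = truth)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records,
                     file.path(config$out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations,
                     file.path(config$out_dir, "correlations.csv"),
                     row.names = FALSE)
    if (!is.null(truth))
      utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                       row.names = FALSE)
  }
  out
}

#' Verify the bundled simultaneous-cohort summaries
#'
#' Recomputes every summary of the bundled simultaneous PET/MRI cohort
#' (column averages, the reader-1 distance sd, and the distance/size
#' counts) and compares each against its reference value.
#'
#' @param tab cohort table; default the bundled fixture.
#' @return `data.frame` with columns `check`, `expected`, `computed`,
#'   `pass`; attribute `all_pass`.
#' @export
verify_reference_cohort <- function(tab = load_simultaneous_cohort()) {
  if (is.null(tab) || nrow(tab) == 0) stop("empty cohort table")
  s <- cohort_summary(tab)
  expected <- c(suv_max = 10.7, suv_mean = 6.3,
                adc_min_r1 = 329, adc_min_r3 = 312,
                adc_mean_r1 = 1362, adc_mean_r3 = 1331,
                dist_r1 = 22.6, dist_r3 = 21.6,
                diameter_mm = 55.9,
                sd_dist_r1 = 18.1,
                n_dist_lt10 = 4, n_dist_gt20 = 6, n_match_gt3cm = 1)
  computed <- c(s$means, sd_dist_r1 = s$sd_dist_r1,
                n_dist_lt10 = s$n_dist_lt10,
                n_dist_gt20 = s$n_dist_gt20,
                n_match_gt3cm = s$n_match_gt3cm)
  computed <- computed[names(expected)]
  res <- data.frame(check = names(expected),
                    expected = unname(expected),
                    computed = unname(computed),
                    pass = unname(abs(computed - expected) < 1e-9),
                    row.names = NULL)
  attr(res, "all_pass") <- all(res$pass)
  res
}
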