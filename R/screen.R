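# End-to-end orchestration of the screening pipeline.

#' Screen a fundus image end to end
#'
#' Runs preprocessing, vessel segmentation, optic-disc localization and
#' segmentation, macula localization, microaneurysm, hemorrhage and exudate
#' detection, and severity grading, in dependency order. A failing stage is
#' recorded and the stages that can still run do (graceful degradation).
#'
#' @param img A `fundus_image` (or a path, which is read first).
#' @param cfg Configuration list.
#' @param models Optional list with `cascade` (hemorrhage SVM cascade) and
#'   `exudate` (exudate SVM); without them candidates pass unclassified.
#' @param verbose Log per-stage timings to stderr.
#' @return A `screening_report` list: per-stage outputs (`vessels`, `od`,
#'   `macula`, `ma`, `hemorrhages`, `exudates`), `counts`, `grade`,
#'   `failed_stages`, `runtime`, `config`.
#' @export
screen_fundus <- function(img, cfg = default_config(), models = NULL,
                          verbose = FALSE) {
  if (is.character(img)) img <- read_fundus(img)
  set.seed(cfg$seed)
  failed <- character(0)
  out <- list()
  t_start <- as.numeric(Sys.time())

  run_stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e) {
      failed <<- c(failed, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
    log_stage(name, t0, verbose)
    res
  }

  pp <- run_stage("preprocess", preprocess_fundus(img, cfg))
  ves <- if (!is.null(pp))
    run_stage("vessels", segment_vessels(pp$green, pp$enhanced, cfg, img$fov))
  od <- if (!is.null(ves)) run_stage("optic_disc", {
    sk <- skeleton_main_arcade(ves$mask, pp$green)
    par <- choose_arcade_fit(sk$pixels, dim(img$rgb)[1:2])
    loc <- locate_od(img, par, cfg)
    seg <- segment_od(img, loc$center, cfg)
    c(seg, list(parabola = par, window_response = loc$response))
  })
  mac <- if (!is.null(pp)) run_stage("macula",
    locate_macula_stage(pp$green, od = od, cfg = cfg, fov = img$fov))
  ma <- if (!is.null(pp)) run_stage("microaneurysms",
    detect_mas(pp$green, vessels = ves$mask, od_mask = od$mask, cfg = cfg,
               fov = img$fov))
  hem <- if (!is.null(pp) && !is.null(ves)) run_stage("hemorrhages",
    detect_hemorrhages(pp$green, pp$enhanced, ves$mask, cfg, img$fov,
                       cascade = models$cascade, od_mask = od$mask))
  exu <- if (!is.null(pp)) run_stage("exudates",
    detect_exudates(pp$green, od = od, cfg = cfg, fov = img$fov,
                    pc = ves$pc_raw, model = models$exudate))

  n_ma <- if (!is.null(ma)) nrow(ma$centers) else 0L
  n_hem <- if (!is.null(hem)) length(hem$lesions) else 0L
  n_exu <- if (!is.null(exu)) length(exu$lesions) else 0L
  qcenter <- if (!is.null(mac)) mac$center else dim(img$rgb)[1:2] / 2
  qh <- quadrant_counts(if (!is.null(hem)) hem$centroids else NULL, qcenter)
  grading <- grade_npdr(n_ma, n_hem, n_exu, qh)

  structure(list(
    source_id = img$source_id,
    vessels = ves, od = od, macula = mac, ma = ma,
    hemorrhages = hem, exudates = exu,
    counts = grading$counts, quadrant_hem = qh, grade = grading$grade,
    failed_stages = failed,
    runtime = as.numeric(Sys.time()) - t_start,
    config = cfg), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> '%s'\n", x$source_id))
  cat(sprintf("  counts: %d MA, %d hemorrhage, %d exudate\n",
              x$counts["n_ma"], x$counts["n_hem"], x$counts["n_exu"]))
  cat(sprintf("  grade: %s\n", as.character(x$grade)))
  if (length(x$failed_stages))
    cat("  failed stages:", paste(x$failed_stages, collapse = "; "), "\n")
  cat(sprintf("  runtime: %.1fs\n", x$runtime))
  invisible(x)
}

#' Write a screening report as JSON
#'
#' Serializes centers, lesion centroids, counts and the grade (not the
#' full masks) into one JSON document per image.
#'
#' @param report A `screening_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  as_xy <- function(m) if (is.null(m) || !nrow(m)) list() else
    apply(unname(m[, 1:2, drop = FALSE]), 1, function(p)
      list(row = p[1], col = p[2]), simplify = FALSE)
  doc <- list(
    source_id = report$source_id,
    od = if (!is.null(report$od))
      list(center = report$od$center, radius = report$od$radius,
           low_confidence = report$od$low_confidence) else NULL,
    macula = if (!is.null(report$macula))
      list(center = report$macula$center,
           contour_score = report$macula$contour_score) else NULL,
    ma = as_xy(report$ma$centers),
    hemorrhages = as_xy(report$hemorrhages$centroids),
    exudates = lapply(report$exudates$lesions, function(l)
      list(row = l$centroid[1], col = l$centroid[2],
           area = nrow(l$pixels))),
    counts = as.list(report$counts),
    quadrant_hem = report$quadrant_hem,
    grade = as.character(report$grade),
    failed_stages = report$failed_stages,
    config = report$config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Train both lesion classifiers on phantom-derived tables
#'
#' @param n_images Phantoms for the training tables (default 12).
#' @param seed Base seed.
#' @param shape Phantom shape.
#' @param cfg Configuration list.
#' @return List with `cascade` (hemorrhage cascade) and `exudate` models.
#' @export
train_phantom_models <- function(n_images = 12, seed = 100,
                                 shape = c(584, 565), cfg = default_config()) {
  tabs <- make_training_table(n_images, seed = seed, shape = shape, cfg = cfg)
  list(cascade = train_cascade(tabs$hemorrhage, seed = seed),
       exudate = train_exudate_svm(tabs$exudate, seed = seed),
       tables = tabs)
}

#' Phantom pipeline regression study
#'
#' Generates `n_seeds` phantoms, screens each end to end, and measures per
#' image: optic-disc center error (px), macula center error (px),
#' microaneurysm detection (at least one planted MA found within 3 px of a
#' detection, and the per-lesion recall), hemorrhage and exudate image-level
#' detection with lesion-level false-positive counts, and agreement of the
#' predicted grade with the ground-truth grade.
#'
#' @param n_seeds Number of evaluation phantoms (default 10).
#' @param seed0 First evaluation seed (training uses a disjoint range).
#' @param shape Phantom shape (default DRIVE-like 584 x 565).
#' @param cfg Configuration list.
#' @param models Optional pre-trained models; trained on 12 phantoms when
#'   `NULL`.
#' @param verbose Print per-seed progress.
#' @return Data frame, one row per seed, plus attribute `models`.
#' @export
run_phantom_study <- function(n_seeds = 10, seed0 = 1, shape = c(584, 565),
                              cfg = default_config(), models = NULL,
                              verbose = FALSE) {
  if (is.null(models))
    models <- train_phantom_models(12, seed = seed0 + 1000, shape = shape,
                                   cfg = cfg)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    ph <- generate_phantom(phantom_spec(shape = shape, seed = seed0 + i - 1))
    tr <- ph$truth
    rep <- screen_fundus(ph$image, cfg = cfg, models = models,
                         verbose = verbose)
    vessel_dice <- if (!is.null(rep$vessels))
      2 * sum(rep$vessels$mask & tr$vessels) /
        (sum(rep$vessels$mask) + sum(tr$vessels)) else NA_real_
    od_err <- if (!is.null(rep$od))
      sqrt(sum((rep$od$center - tr$od_center)^2)) else NA_real_
    mac_err <- if (!is.null(rep$macula))
      sqrt(sum((rep$macula$center - tr$macula_center)^2)) else NA_real_
    near_any <- function(dets, gts, tol) {
      if (is.null(dets) || !nrow(dets) || !nrow(gts)) return(0L)
      sum(vapply(seq_len(nrow(gts)), function(k)
        any(sqrt((dets[, 1] - gts[k, 1])^2 +
                 (dets[, 2] - gts[k, 2])^2) <= tol), logical(1)))
    }
    fp_count <- function(dets, truth_masks, tol) {
      if (is.null(dets) || !nrow(dets)) return(0L)
      sum(vapply(seq_len(nrow(dets)), function(k) {
        r <- round(dets[k, 1]); c <- round(dets[k, 2])
        !any(vapply(truth_masks, function(m) m[r, c], logical(1))) &&
          near_any(dets[k, , drop = FALSE],
                   do.call(rbind, list(tr$ma_centers, tr$hem_centers)),
                   tol) == 0
      }, logical(1)))
    }
    ma_hit <- near_any(rep$ma$centers, tr$ma_centers, 4)
    hem_cent <- rep$hemorrhages$centroids
    hem_hit <- near_any(hem_cent, tr$hem_centers, 15 * shape[2] / 565)
    exu_cent <- do.call(rbind, lapply(rep$exudates$lesions, `[[`, "centroid"))
    exu_hit <- near_any(exu_cent, tr$exu_centers, 20 * shape[2] / 565)
    hem_fp <- fp_count(hem_cent, list(tr$hemorrhage, tr$ma, tr$vessels),
                       15 * shape[2] / 565)
    rows[[i]] <- data.frame(
      seed = seed0 + i - 1,
      vessel_dice = vessel_dice,
      od_err = od_err, od_radius = tr$od_radius,
      mac_err = mac_err,
      n_ma_true = nrow(tr$ma_centers), n_ma_found = ma_hit,
      n_ma_det = if (!is.null(rep$ma)) nrow(rep$ma$centers) else 0L,
      n_hem_true = nrow(tr$hem_centers), n_hem_found = hem_hit,
      hem_fp = hem_fp,
      n_exu_true = nrow(tr$exu_centers), n_exu_found = exu_hit,
      grade_true = as.character(tr$grade$grade),
      grade_pred = as.character(rep$grade),
      n_failed = length(rep$failed_stages))
    if (verbose)
      message(sprintf("seed %d: od %.1f px, mac %.1f px, MA %d/%d, hem %d/%d (fp %d), exu %d/%d, grade %s/%s",
                      seed0 + i - 1, od_err, mac_err, ma_hit,
                      nrow(tr$ma_centers), hem_hit, nrow(tr$hem_centers),
                      hem_fp, exu_hit, nrow(tr$exu_centers),
                      rows[[i]]$grade_pred, rows[[i]]$grade_true))
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}
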