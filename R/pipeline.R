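#' Run the full mapping pipeline on an in-memory scene
#'
#' Chains every stage: per-season enhanced images from the SAR stack, NDVI
#' and the cropland image from the optical pairs, K-Means classification of
#' each product, cluster-to-class assignment (heuristic by default),
#' priority decision-tree fusion into the early/middle and late maps, the
#' double-cropping area, and — when the scene carries truth — a design-based
#' accuracy assessment of both maps.
#'
#' @param scene Output of [generate_scene()] (or a list with the same
#'   shape built from files).
#' @param calendar A [pheno_calendar]; defaults to the scene config's.
#' @param k,max_iter K-Means settings (workflow defaults: 10 classes,
#'   20 iterations).
#' @param seed Integer seed for the classifier (one derived seed per
#'   product).
#' @param mappings Optional named list (`early`, `middle`, `late`,
#'   `cropland`) of explicit cluster-to-class mappings overriding
#'   [auto_assign_clusters()].
#' @return List: `enhanced` (per rice type), `cropland_image`, `clusters`,
#'   `layers`, `early_middle_map`, `late_map`, `double_crop_km2`, and — with
#'   truth — `assessment` with per-map reports.
#' @export
run_pipeline <- function(scene, calendar = NULL, k = 10L, max_iter = 20L,
                         seed = 1L, mappings = NULL) {
  if (is.null(calendar)) calendar <- scene$config$calendar
  enhanced <- lapply(stats::setNames(nm = c("early", "middle", "late")),
                     function(ty) build_enhanced_image(scene$sar, calendar, ty))
  tags <- vapply(scene$optical, `[[`, character(1), "tag")
  ndvis <- lapply(scene$optical, function(p) ndvi(p$red, p$nir))
  cropland_img <- build_cropland_image(ndvis[tags == "growing"],
                                       ndvis[tags == "winter"])

  products <- c(enhanced, list(cropland = cropland_img))
  clusters <- mapply(function(img, off)
    kmeans_classify(img, k = k, max_iter = max_iter, seed = seed + off),
    products, seq_along(products) - 1L, SIMPLIFY = FALSE)

  layer_of <- function(prod, kind, wanted) {
    mp <- if (!is.null(mappings[[prod]])) mappings[[prod]]
          else auto_assign_clusters(clusters[[prod]], kind)
    layers <- merge_clusters(clusters[[prod]], mp)
    empty <- function(nm) class_layer(
      grid_like(clusters[[prod]]$labels,
                ifelse(is.na(clusters[[prod]]$labels$values), NA_real_, 0)),
      nm)
    stats::setNames(lapply(wanted, function(nm)
      if (!is.null(layers[[nm]])) layers[[nm]] else empty(nm)), wanted)
  }
  rice_layers <- lapply(stats::setNames(nm = c("early", "middle", "late")),
                        function(ty)
                          layer_of(ty, "rice_enhanced", "rice")$rice)
  crop_layers <- layer_of("cropland", "cropland_image",
                          c("cropland", "forest"))

  em_map <- fuse_early_middle(scene$water_layer, crop_layers$forest,
                              crop_layers$cropland, rice_layers$middle,
                              rice_layers$early)
  late_map <- fuse_late(scene$water_layer, crop_layers$forest,
                        crop_layers$cropland, rice_layers$late)
  out <- list(enhanced = enhanced, cropland_image = cropland_img,
              clusters = clusters,
              layers = c(rice_layers, crop_layers,
                         list(water = scene$water_layer)),
              early_middle_map = em_map, late_map = late_map,
              double_crop_km2 = double_crop_area(em_map, late_map))
  if (!is.null(scene$truth)) {
    out$assessment <- list(
      early_middle = assessment_report(
        build_error_matrix(em_map, truth_fused_map(scene$truth,
                                                   "early_middle"))),
      late = assessment_report(
        build_error_matrix(late_map, truth_fused_map(scene$truth, "late")))
    )
  }
  out
}

# ---------------------------------------------------------------------------
# File-based workflow (CLI backend)

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$out_dir)) stop("config is missing `out_dir`", call. = FALSE)
  cfg
}

config_calendar <- function(cfg) {
  if (is.null(cfg$calendar)) return(default_calendar())
  pheno_calendar(early = cfg$calendar$early, middle = cfg$calendar$middle,
                 late = cfg$calendar$late)
}

config_scene <- function(cfg) {
  args <- cfg$scene
  if (is.null(args)) args <- list()
  args$calendar <- config_calendar(cfg)
  if (!is.null(args$class_fractions))
    args$class_fractions <- unlist(args$class_fractions)
  do.call(scene_config, args)
}

log_stage <- function(out_dir, stage, params) {
  line <- jsonlite::toJSON(c(list(stage = stage,
                                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                             params), auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out_dir, "run_log.jsonl"),
      append = TRUE)
}

need_file <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("missing artifact for `%s`: %s", stage, path), call. = FALSE)
  path
}

write_enhanced <- function(img, out_dir, stem) {
  for (b in c("min", "max", "diff"))
    write_asc(img[[paste0("band_", b)]],
              file.path(out_dir, sprintf("%s_%s.asc", stem, b)))
}

read_enhanced <- function(out_dir, stem, stage) {
  bmin <- read_asc(need_file(file.path(out_dir, sprintf("%s_min.asc", stem)),
                             stage))
  bmax <- read_asc(need_file(file.path(out_dir, sprintf("%s_max.asc", stem)),
                             stage))
  new_enhanced_image(bmin, bmax)
}

#' Run one pipeline stage against a config file
#'
#' File-based counterpart of [run_pipeline()], the engine behind the
#' `ricesar` command-line script. The config is a YAML document with at
#' least `out_dir`; `scene` (arguments to [scene_config()]), `calendar`,
#' `classifier` (`k`, `max_iter`, `seed`) and `mappings` sections are
#' optional. Stages exchange deterministic file names under `out_dir` and
#' each stage appends one structured line to `run_log.jsonl`. `"all"` chains
#' simulate, enhance, cropland, classify, fuse and assess.
#'
#' @param name One of `"simulate"`, `"enhance"`, `"cropland"`,
#'   `"classify"`, `"fuse"`, `"assess"`, `"all"`.
#' @param config Path to a YAML config file, or an equivalent list.
#' @return Invisibly, a character vector of the artifacts written.
#' @export
run_subcommand <- function(name = c("simulate", "enhance", "cropland",
                                    "classify", "fuse", "assess", "all"),
                           config) {
  name <- match.arg(name)
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config is missing `out_dir`", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") {
    written <- unlist(lapply(c("simulate", "enhance", "cropland", "classify",
                               "fuse", "assess"),
                             run_subcommand, config = cfg))
    return(invisible(written))
  }
  switch(name,
    simulate = {
      sc <- config_scene(cfg)
      scene <- generate_scene(sc)
      paths <- character(0)
      for (i in seq_along(scene$sar$dates)) {
        p <- file.path(out_dir, sprintf("sar_%s.asc", scene$sar$dates[i]))
        write_asc(scene$sar$grids[[i]], p); paths <- c(paths, p)
      }
      for (pair in scene$optical) {
        pr <- file.path(out_dir, sprintf("red_%s.asc", pair$date))
        pn <- file.path(out_dir, sprintf("nir_%s.asc", pair$date))
        write_asc(pair$red, pr); write_asc(pair$nir, pn)
        paths <- c(paths, pr, pn)
      }
      pw <- file.path(out_dir, "water_layer.asc")
      write_asc(scene$water_layer$mask, pw)
      pt_em <- file.path(out_dir, "truth_early_middle.asc")
      pt_l <- file.path(out_dir, "truth_late.asc")
      write_map(truth_fused_map(scene$truth, "early_middle"), pt_em)
      write_map(truth_fused_map(scene$truth, "late"), pt_l)
      manifest <- list(sar_dates = as.character(scene$sar$dates),
                       optical = lapply(scene$optical, function(p)
                         list(date = as.character(p$date), tag = p$tag)),
                       pixel_size = sc$pixel_size, seed = sc$seed,
                       class_fractions = as.list(sc$class_fractions))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage(out_dir, "simulate", list(seed = sc$seed,
                                          rows = sc$rows, cols = sc$cols))
      invisible(c(paths, pw, pt_em, pt_l))
    },
    enhance = {
      manifest <- jsonlite::read_json(
        need_file(file.path(out_dir, "manifest.json"), "enhance"),
        simplifyVector = TRUE)
      dates <- as.Date(manifest$sar_dates)
      grids <- lapply(dates, function(d)
        read_asc(need_file(file.path(out_dir, sprintf("sar_%s.asc", d)),
                           "enhance"), unit = "dB"))
      stack <- acq_stack(dates, grids)
      cal <- config_calendar(cfg)
      for (ty in c("early", "middle", "late"))
        write_enhanced(build_enhanced_image(stack, cal, ty), out_dir,
                       paste0("enhanced_", ty))
      log_stage(out_dir, "enhance", list(n_dates = length(dates)))
      invisible(file.path(out_dir, outer(paste0("enhanced_",
                                                c("early", "middle", "late")),
                                         c("_min.asc", "_max.asc",
                                           "_diff.asc"), paste0)))
    },
    cropland = {
      manifest <- jsonlite::read_json(
        need_file(file.path(out_dir, "manifest.json"), "cropland"),
        simplifyVector = FALSE)
      ndvis <- list(growing = list(), winter = list())
      for (o in manifest$optical) {
        red <- read_asc(need_file(file.path(out_dir,
                                            sprintf("red_%s.asc", o$date)),
                                  "cropland"), unit = "reflectance")
        nir <- read_asc(need_file(file.path(out_dir,
                                            sprintf("nir_%s.asc", o$date)),
                                  "cropland"), unit = "reflectance")
        ndvis[[o$tag]] <- c(ndvis[[o$tag]], list(ndvi(red, nir)))
      }
      write_enhanced(build_cropland_image(ndvis$growing, ndvis$winter),
                     out_dir, "cropland")
      log_stage(out_dir, "cropland",
                list(n_growing = length(ndvis$growing),
                     n_winter = length(ndvis$winter)))
      invisible(file.path(out_dir, paste0("cropland_",
                                          c("min", "max", "diff"), ".asc")))
    },
    classify = {
      cls <- cfg$classifier
      k <- if (is.null(cls$k)) 10L else cls$k
      max_iter <- if (is.null(cls$max_iter)) 20L else cls$max_iter
      seed <- if (is.null(cls$seed)) 1L else cls$seed
      paths <- character(0)
      products <- list(early = "rice_enhanced", middle = "rice_enhanced",
                       late = "rice_enhanced", cropland = "cropland_image")
      off <- 0L
      for (prod in names(products)) {
        stem <- if (prod == "cropland") "cropland" else paste0("enhanced_", prod)
        img <- read_enhanced(out_dir, stem, "classify")
        cm <- kmeans_classify(img, k = k, max_iter = max_iter,
                              seed = seed + off)
        off <- off + 1L
        pclu <- file.path(out_dir, sprintf("clusters_%s.asc", prod))
        write_asc(cm$labels, pclu); paths <- c(paths, pclu)
        mp <- if (!is.null(cfg$mappings[[prod]])) unlist(cfg$mappings[[prod]])
              else auto_assign_clusters(cm, products[[prod]])
        for (layer in merge_clusters(cm, mp)) {
          nm <- if (layer$class_name == "rice") paste0(prod, "_rice")
                else layer$class_name
          pl <- file.path(out_dir, sprintf("layer_%s.asc", nm))
          write_asc(layer$mask, pl); paths <- c(paths, pl)
        }
      }
      log_stage(out_dir, "classify",
                list(k = k, max_iter = max_iter, seed = seed))
      invisible(paths)
    },
    fuse = {
      lay <- function(nm) {
        p <- need_file(file.path(out_dir, sprintf("layer_%s.asc", nm)), "fuse")
        class_layer(read_asc(p, unit = "label"), nm)
      }
      water <- class_layer(read_asc(need_file(file.path(out_dir,
                                                        "water_layer.asc"),
                                              "fuse"), unit = "label"),
                           "water")
      em_map <- fuse_early_middle(water, lay("forest"), lay("cropland"),
                                  lay("middle_rice"), lay("early_rice"))
      late_map <- fuse_late(water, lay("forest"), lay("cropland"),
                            lay("late_rice"))
      p1 <- file.path(out_dir, "map_early_middle.asc")
      p2 <- file.path(out_dir, "map_late.asc")
      write_map(em_map, p1); write_map(late_map, p2)
      dc <- double_crop_area(em_map, late_map)
      jsonlite::write_json(list(double_crop_km2 = dc),
                           file.path(out_dir, "double_crop.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage(out_dir, "fuse", list(double_crop_km2 = dc))
      invisible(c(p1, p2, file.path(out_dir, "double_crop.json")))
    },
    assess = {
      reports <- list()
      for (w in c("early_middle", "late")) {
        map <- read_map(need_file(file.path(out_dir,
                                            sprintf("map_%s.asc", w)),
                                  "assess"))
        ref <- read_map(need_file(file.path(out_dir,
                                            sprintf("truth_%s.asc", w)),
                                  "assess"))
        rep <- assessment_report(build_error_matrix(map, ref))
        utils::write.csv(rep$table,
                         file.path(out_dir, sprintf("assessment_%s.csv", w)),
                         row.names = FALSE)
        reports[[w]] <- list(overall_accuracy = rep$overall_accuracy,
                             kappa = rep$kappa, table = rep$table)
      }
      jsonlite::write_json(reports, file.path(out_dir, "assessment.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      log_stage(out_dir, "assess",
                list(overall_early_middle =
                       reports$early_middle$overall_accuracy,
                     overall_late = reports$late$overall_accuracy))
      invisible(c(file.path(out_dir, c("assessment_early_middle.csv",
                                       "assessment_late.csv",
                                       "assessment.json"))))
    })
}
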