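#' Pipeline orchestration and command-line interface
#'
#' The full identification run has four steps: locate metaphases at 10x,
#' extract chromosome objects at 100x, triage and split adhesive masses,
#' and identify dicentrics with the two-stage CNN cascade. Spreads whose
#' individual-chromosome count falls outside 46 +/- 3 are flagged by the
#' screen and excluded from DIC statistics. Every discarded object keeps
#' its discard reason so kept + discarded always equals detected.
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' Every tunable constant of the method is surfaced here with its published
#' default: the triage band (25-65 px width, at most 3 internal holes), the
#' 150-px watershed seed-area threshold, 151-px tiles, the 46 +/- 3 spread
#' screen, the 0.5 score threshold, and the locator radii.
#'
#' @param locator,extractor,rule,segmenter,screen,score_threshold Module
#'   parameter blocks.
#' @param seed Integer seed threaded through every stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(locator = list(se_radius = 4,
                                           cleanup_radius = 2,
                                           highlight_radius = 6,
                                           min_area = 600),
                            extractor = list(se_radius = 40, kernel = 3),
                            rule = triage_rule(),
                            segmenter = segmenter_config(),
                            screen = list(expected = 46L, tolerance = 3L),
                            score_threshold = 0.5,
                            seed = 1) {
  structure(list(locator = locator, extractor = extractor, rule = rule,
                 segmenter = segmenter, screen = screen,
                 score_threshold = score_threshold, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(y), c("locator", "extractor", "screen"))) {
    cfg[[nm]][names(y[[nm]])] <- y[[nm]]
  }
  if (!is.null(y$rule))
    cfg$rule <- do.call(triage_rule, y$rule)
  if (!is.null(y$segmenter))
    cfg$segmenter <- do.call(segmenter_config, y$segmenter)
  if (!is.null(y$score_threshold)) cfg$score_threshold <- y$score_threshold
  if (!is.null(y$seed)) cfg$seed <- y$seed
  cfg
}

# Dominant ground-truth label of an object from a truth label mask.
.truth_label_for <- function(object, label_mask, dic_ids) {
  bb <- object$bbox  # 0-based half-open
  sub <- label_mask[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4], drop = FALSE]
  ids <- sub[object$mask_crop > 0]
  ids <- ids[ids > 0]
  if (length(ids) == 0) return("nonDIC")
  dom <- as.integer(names(which.max(table(ids))))
  if (dom %in% dic_ids) "DIC" else "nonDIC"
}

#' Analyze one metaphase image
#'
#' extraction -> triage/segmentation -> screen -> (optional) cascade.
#'
#' @param image A `metaphase_image` or RGB array.
#' @param config A [pipeline_config()].
#' @param models Optional list with `stage1`/`stage2` `trained_model`s;
#'   `stage2 = NULL` runs first-stage-only identification.
#' @param truth Optional `ground_truth` (from [render_metaphase()]) or an
#'   integer truth label mask plus `dic_ids`.
#' @return List: `objects` data frame (WH, IH, category, discard reason,
#'   scores, labels), `n_individual`, `screened` (TRUE = accepted),
#'   `tiles` (normalized tiles of kept individuals).
#' @export
analyze_metaphase <- function(image, config = pipeline_config(),
                              models = NULL, truth = NULL) {
  mask <- extraction_mask(image,
                          se_radius = config$extractor$se_radius,
                          kernel = config$extractor$kernel,
                          seed = config$seed)
  objs <- extract_objects(image, mask)
  objs <- triage_objects(objs, config$rule, config$segmenter)
  cat_v <- vapply(objs, `[[`, "", "category")
  n_ind <- sum(cat_v == "individual")
  screened <- screen_spread(n_ind, config$screen$expected,
                            config$screen$tolerance)

  dic_ids <- integer(0)
  label_mask <- NULL
  if (inherits(truth, "ground_truth")) {
    label_mask <- truth$label_mask
    kinds <- vapply(truth$objects, `[[`, "", "kind")
    dic_ids <- which(kinds == "dicentric")
  } else if (is.matrix(truth)) {
    label_mask <- truth
  }

  keep <- which(cat_v == "individual")
  tiles <- lapply(objs[keep], normalize_tile)
  s1 <- s2 <- rep(NA_real_, length(objs))
  final <- rep(NA_character_, length(objs))
  if (!is.null(models) && length(keep) > 0) {
    raw <- .as_tile_raw(tiles)
    sc1 <- cnn_predict(models$stage1, raw)
    s1[keep] <- sc1
    lab <- score_to_label(sc1)
    if (!is.null(models$stage2)) {
      pos <- which(lab == "DIC")
      if (length(pos) > 0) {
        sc2 <- cnn_predict(models$stage2, raw, pos)
        s2[keep[pos]] <- sc2
        lab[pos] <- score_to_label(sc2)
      }
    }
    final[keep] <- lab
  }

  truth_lab <- rep(NA_character_, length(objs))
  if (!is.null(label_mask))
    truth_lab <- vapply(objs, .truth_label_for, "",
                        label_mask = label_mask, dic_ids = dic_ids)

  df <- data.frame(
    object_id = seq_along(objs),
    WH = vapply(objs, `[[`, integer(1), "WH"),
    IH = vapply(objs, `[[`, integer(1), "IH"),
    area_px = vapply(objs, `[[`, integer(1), "area_px"),
    category = cat_v,
    discard_reason = ifelse(cat_v == "impurity", "impurity rule",
                            ifelse(cat_v == "mass", "unsplittable mass",
                                   "")),
    stage1_score = s1, stage2_score = s2, final_label = final,
    truth_label = truth_lab, stringsAsFactors = FALSE)
  list(objects = df, n_individual = n_ind, screened = screened,
       tiles = tiles)
}

#' Run the full pipeline over a set of metaphase images
#'
#' @param inputs Either a list of `render_metaphase()` results (image +
#'   truth), a list of `metaphase_image`s, or a directory containing
#'   `metaphase_*.png` and optionally `manifest.json` with truth label
#'   masks.
#' @param config A [pipeline_config()].
#' @param models Optional cascade models (see [analyze_metaphase()]).
#' @param log_path Optional JSON-lines log file (one line per image).
#' @return A `run_report`: `per_image` data frame, `objects` data frame,
#'   and — when truth is available — `confusion` + `metrics` over objects
#'   of screened spreads.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), models = NULL,
                         log_path = NULL) {
  if (is.character(inputs)) {
    dirp <- inputs
    man_path <- file.path(dirp, "manifest.json")
    manifest <- if (file.exists(man_path))
      jsonlite::read_json(man_path) else NULL
    entries <- list()
    if (!is.null(manifest)) {
      for (e in manifest$images) {
        if (!identical(e$magnification, "100x")) next
        px <- png::readPNG(file.path(dirp, e$path))
        img <- structure(list(pixels = px, magnification = "100x"),
                         class = "metaphase_image")
        truth <- NULL
        if (!is.null(e$label_mask)) {
          lm <- read_label_png(file.path(dirp, e$label_mask))
          truth <- structure(list(
            label_mask = lm,
            objects = lapply(e$objects, function(o)
              list(kind = o$kind, label = o$label))),
            class = "ground_truth")
        }
        entries[[length(entries) + 1]] <-
          list(name = e$path, image = img, truth = truth)
      }
    } else {
      for (f in sort(list.files(dirp, pattern = "\\.png$",
                                full.names = FALSE))) {
        px <- png::readPNG(file.path(dirp, f))
        entries[[length(entries) + 1]] <- list(
          name = f,
          image = structure(list(pixels = px, magnification = "100x"),
                            class = "metaphase_image"),
          truth = NULL)
      }
    }
  } else {
    entries <- lapply(seq_along(inputs), function(i) {
      x <- inputs[[i]]
      if (!is.null(x$image)) list(name = sprintf("image_%03d", i),
                                  image = x$image, truth = x$truth)
      else list(name = sprintf("image_%03d", i), image = x, truth = NULL)
    })
  }

  per_image <- NULL
  objects <- NULL
  logcon <- if (!is.null(log_path)) file(log_path, "w") else NULL
  on.exit(if (!is.null(logcon)) close(logcon), add = TRUE)
  for (e in entries) {
    res <- analyze_metaphase(e$image, config, models, e$truth)
    df <- res$objects
    df$image <- e$name
    df$screened <- res$screened
    objects <- rbind(objects, df)
    row <- data.frame(image = e$name,
                      n_objects = nrow(df),
                      n_individual = res$n_individual,
                      n_mass = sum(df$category == "mass"),
                      n_impurity = sum(df$category == "impurity"),
                      screened = res$screened)
    per_image <- rbind(per_image, row)
    if (!is.null(logcon))
      writeLines(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), logcon)
  }

  report <- list(per_image = per_image, objects = objects)
  scored <- objects[!is.na(objects$final_label) &
                      !is.na(objects$truth_label) & objects$screened, ,
                    drop = FALSE]
  if (nrow(scored) > 0) {
    report$confusion <- confusion_counts(scored$final_label,
                                         scored$truth_label)
    report$metrics <- classification_metrics(report$confusion)
  }
  structure(report, class = "run_report")
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic corpus), `locate` (10x metaphase
#' locating), `extract` (object crops), `train` (cascade training on a tile
#' corpus), `identify` (cascade or `--stage1-only`), `evaluate` (metrics
#' table from counts or a report). Invoked by the `dicascade` script in
#' `inst/scripts/`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 = success).
#' @export
dic_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dicascade <generate|locate|extract|train|identify|evaluate>",
    "  generate --out DIR [--seed N] [--config YAML]",
    "  locate   --input DIR --out CSV [--config YAML]",
    "  extract  --input DIR --out DIR [--config YAML]",
    "  train    --input DIR --out DIR [--seed N] [--epochs N]",
    "  identify --input DIR --models DIR --out JSON [--stage1-only]",
    "  evaluate --counts TP,FN,FP,TN[,TP2,FN2,FP2,TN2]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(1L) }
  sub <- args[1]
  rest <- args[-1]
  flags <- list()
  i <- 1
  while (i <= length(rest)) {
    a <- rest[i]
    if (!startsWith(a, "--")) { message(usage); return(1L) }
    key <- substring(a, 3)
    if (key %in% c("stage1-only")) {
      flags[[key]] <- TRUE; i <- i + 1
    } else {
      if (i == length(rest)) { message("missing value for --", key)
        return(1L) }
      flags[[key]] <- rest[i + 1]; i <- i + 2
    }
  }
  seed <- as.integer(flags$seed %||% 1)
  cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
         else pipeline_config(seed = seed)

  if (sub == "generate") {
    if (is.null(flags$out)) { message(usage); return(1L) }
    gcfg <- if (!is.null(flags$config)) yaml::read_yaml(flags$config)
            else list(n_fields = 2, n_metaphases = 2)
    generate_corpus(gcfg, flags$out, seed = seed)
    return(0L)
  }
  if (sub == "locate") {
    if (is.null(flags$input) || is.null(flags$out)) {
      message(usage); return(1L) }
    rows <- NULL
    for (f in sort(list.files(flags$input, pattern = "^field.*\\.png$"))) {
      px <- png::readPNG(file.path(flags$input, f))
      if (length(dim(px)) == 3) px <- px[, , 1]
      cand <- do.call(locate_metaphases, c(list(px), cfg$locator))
      if (nrow(cand) > 0) rows <- rbind(rows, cbind(image = f, cand))
    }
    if (is.null(rows))
      rows <- data.frame(image = character(0), row = numeric(0),
                         col = numeric(0), area_px = integer(0))
    utils::write.csv(rows, flags$out, row.names = FALSE)
    return(0L)
  }
  if (sub == "extract") {
    if (is.null(flags$input) || is.null(flags$out)) {
      message(usage); return(1L) }
    dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
    index <- NULL
    for (f in sort(list.files(flags$input,
                              pattern = "^metaphase_[0-9]+\\.png$"))) {
      px <- png::readPNG(file.path(flags$input, f))
      mask <- extraction_mask(px, se_radius = cfg$extractor$se_radius,
                              kernel = cfg$extractor$kernel)
      objs <- extract_objects(px, mask)
      for (k in seq_along(objs)) {
        fn <- sprintf("%s_obj%03d.png", sub("\\.png$", "", f), k)
        png::writePNG(objs[[k]]$image_crop, file.path(flags$out, fn))
        index <- rbind(index, data.frame(
          image = f, crop = fn, area_px = objs[[k]]$area_px,
          r0 = objs[[k]]$bbox[1], c0 = objs[[k]]$bbox[2],
          r1 = objs[[k]]$bbox[3], c1 = objs[[k]]$bbox[4]))
      }
    }
    utils::write.csv(index, file.path(flags$out, "objects.csv"),
                     row.names = FALSE)
    return(0L)
  }
  if (sub == "train") {
    if (is.null(flags$input) || is.null(flags$out)) {
      message(usage); return(1L) }
    man <- jsonlite::read_json(file.path(flags$input, "manifest.json"))
    if (is.null(man$tiles)) { message("no tiles in corpus"); return(1L) }
    n <- length(man$tiles)
    raw <- array(as.raw(0), c(TILE_SIDE, TILE_SIDE, 3, n))
    labels <- character(n)
    for (i in seq_len(n)) {
      px <- png::readPNG(file.path(flags$input, man$tiles[[i]]$path))
      raw[, , , i] <- as.raw(round(px * 255))
      labels[i] <- man$tiles[[i]]$label
    }
    epochs <- as.integer(flags$epochs %||% 50)
    mods <- train_cascade(raw, labels,
                          cfg1 = training_config(epochs = epochs,
                                                 dic_oversample = 3,
                                                 seed = seed),
                          cfg2 = training_config(epochs = epochs,
                                                 dic_oversample = 2,
                                                 seed = seed + 1))
    dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
    save_model(mods$stage1, file.path(flags$out, "stage1.rds"))
    save_model(mods$stage2, file.path(flags$out, "stage2.rds"))
    return(0L)
  }
  if (sub == "identify") {
    if (is.null(flags$input) || is.null(flags$models) ||
          is.null(flags$out)) { message(usage); return(1L) }
    m1p <- file.path(flags$models, "stage1.rds")
    m2p <- file.path(flags$models, "stage2.rds")
    if (!file.exists(m1p)) {
      message("missing model checkpoint: ", m1p,
              " (run `dicascade train` first)")
      return(1L)
    }
    models <- list(stage1 = load_model(m1p),
                   stage2 = if (!isTRUE(flags[["stage1-only"]]) &&
                                  file.exists(m2p)) load_model(m2p)
                            else NULL)
    rep <- run_pipeline(flags$input, cfg, models)
    out <- list(per_image = rep$per_image, objects = rep$objects)
    if (!is.null(rep$confusion)) {
      out$confusion <- unclass(rep$confusion)
      out$metrics <- unclass(rep$metrics)
    }
    jsonlite::write_json(out, flags$out, auto_unbox = TRUE, digits = 8,
                         pretty = TRUE, na = "null", dataframe = "rows")
    return(0L)
  }
  if (sub == "evaluate") {
    if (is.null(flags$counts)) { message(usage); return(1L) }
    v <- as.numeric(strsplit(flags$counts, ",")[[1]])
    if (!length(v) %in% c(4, 8)) {
      message("--counts needs 4 or 8 numbers TP,FN,FP,TN[,...]")
      return(1L)
    }
    mk <- function(x) structure(list(TP = x[1], FN = x[2], FP = x[3],
                                     TN = x[4]), class = "confusion_counts")
    tab <- if (length(v) == 4) format_metrics_table("mode" = mk(v))
           else format_metrics_table("first-stage only" = mk(v[1:4]),
                                     "two-stage" = mk(v[5:8]))
    cat(paste(tab, collapse = "\n"), "\n")
    return(0L)
  }
  message(usage)
  1L
}
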