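# End-to-end pipeline: acquire contours (synthetic set, contour CSVs, or
# grayscale images), measure, describe, adjust, test, and export the report
# bundle.

#' Pipeline run configuration
#'
#' Exactly one input mode is active: `"synthetic"` (generator-driven),
#' `"contours"` (metadata CSV + per-otolith contour CSVs) or `"images"`
#' (metadata CSV + grayscale images binarized at `threshold`).
#'
#' @param mode input mode.
#' @param synth a [synth_config()] (synthetic mode); its seed is overridden
#'   by `seed`.
#' @param metadata_csv specimen metadata CSV with columns `specimen_id`,
#'   `TL_mm`, `BW_g`, `sex`, `size_class`, `side` and `contour_path` or
#'   `image_path` (contours / images modes).
#' @param threshold,polarity,min_object_px binarization parameters
#'   (images mode); see [binarize()].
#' @param px_per_mm image resolution (images mode).
#' @param descriptor `"wavelet"` or `"fourier"` for the group tests.
#' @param alpha significance level for the allometric adjustment and test
#'   flags.
#' @param n_perm permutations for the multivariate tests.
#' @param pool_sides pool left and right otoliths for class/sex analyses
#'   once the side comparison is non-significant.
#' @param seed master RNG seed for the run.
#' @param out_dir directory for the report bundle (NULL: nothing written).
#' @return a validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "contours", "images"),
                       synth = synth_config(),
                       metadata_csv = NULL,
                       threshold = 0.05, polarity = "bright_object",
                       min_object_px = 64L, px_per_mm = 100,
                       descriptor = c("wavelet", "fourier"),
                       alpha = 0.05, n_perm = 999L,
                       pool_sides = TRUE,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  descriptor <- match.arg(descriptor)
  if (mode != "synthetic" && is.null(metadata_csv))
    stop("metadata_csv is required for mode '", mode, "'")
  structure(list(mode = mode, synth = synth, metadata_csv = metadata_csv,
                 threshold = threshold, polarity = polarity,
                 min_object_px = min_object_px, px_per_mm = px_per_mm,
                 descriptor = descriptor, alpha = alpha,
                 n_perm = as.integer(n_perm), pool_sides = pool_sides,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.index_vars <- c("OL", "OW", "OP", "OS", "OL_TL", "C", "Re", "E", "AR", "FF", "Ro")

# gather (contours, specimens, quarantine) for each input mode
.acquire <- function(config) {
  quarantine <- character()
  if (config$mode == "synthetic") {
    sc <- config$synth
    sc$seed <- config$seed
    set <- generate_otolith_set(sc)
    return(list(specimens = set$specimens, contours = set$contours,
                quarantine = quarantine))
  }
  meta <- read.csv(config$metadata_csv, stringsAsFactors = FALSE)
  need <- c("specimen_id", "TL_mm", "BW_g", "sex", "size_class", "side")
  if (!all(need %in% names(meta)))
    stop("metadata is missing columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  contours <- list()
  for (i in seq_len(nrow(meta))) {
    key <- paste0(meta$specimen_id[i], "_", meta$side[i])
    res <- tryCatch({
      if (config$mode == "contours") {
        read_contour_csv(meta$contour_path[i])
      } else {
        img <- read_gray_image(meta$image_path[i])
        attr(img, "px_per_mm") <- config$px_per_mm
        mask <- binarize(img, config$threshold, config$polarity,
                         config$min_object_px)
        contour_px_to_mm(extract_outline(mask))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      quarantine <- c(quarantine, setNames(conditionMessage(res), key))
    } else contours[[key]] <- res
  }
  list(specimens = unique(meta[, c("specimen_id", "TL_mm", "BW_g",
                                   "sex", "size_class")]),
       contours = contours, quarantine = quarantine)
}

.try_test <- function(expr) {
  tryCatch(expr, error = function(e)
    list(skipped = TRUE, reason = conditionMessage(e)))
}

#' Run the full otolith shape analysis
#'
#' Executes every stage on the configured input: morphometry table and
#' per-group summaries, side and sex t-tests and per-class ANOVA + Tukey
#' on each variable, Pearson correlations of every morphometric variable
#' against TL and BW, allometrically adjusted descriptor matrices,
#' distance-based permutation tests and LDA for side / sex / size class,
#' group mean shapes, reconstruction and coefficient-position diagnostics,
#' and a machine-readable manifest. Tests that a group structure cannot
#' support (insufficient n) are recorded as skipped rather than silently
#' dropped; unreadable inputs go to a quarantine list and the run
#' continues.
#'
#' @param config a [run_config()].
#' @return an `oto_run` object; if `config$out_dir` is set, the report
#'   bundle (CSV tables, plots, manifest) is also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  acq <- .acquire(config)
  specimens <- acq$specimens
  contours <- acq$contours
  if (!length(contours)) stop("no usable contours")

  records <- morphometry_table(contours, specimens)
  summaries <- list(
    by_class = morphometry_summary(records, "size_class"),
    by_side  = morphometry_summary(records, "side"),
    by_sex   = morphometry_summary(records, "sex"))

  side_t <- lapply(setNames(.index_vars, .index_vars), function(v)
    .try_test(unpaired_t(records[[v]], records$side, factor_name = v)))
  sex_t <- lapply(setNames(.index_vars, .index_vars), function(v)
    .try_test(unpaired_t(records[[v]], records$sex, factor_name = v)))
  class_vars <- c("TL_mm", "BW_g", .index_vars)
  class_anova <- lapply(setNames(class_vars, class_vars), function(v)
    .try_test(anova_tukey(records[[v]], records$size_class, factor_name = v)))
  pearson <- list()
  for (bio in c("TL_mm", "BW_g"))
    for (v in .index_vars)
      pearson[[paste(bio, "vs", v)]] <-
        .try_test(pearson_ci(records[[bio]], records[[v]],
                             factor_name = paste(bio, "vs", v)))

  mat <- descriptor_matrix(contours, kind = config$descriptor)
  sets <- attr(mat, "descriptor_sets")
  adj <- adjust_for_length(mat, records$TL_mm, alpha = config$alpha)
  A <- adj$adjusted

  # side varies within fish, sex and class are fish-level: block on the
  # specimen so paired otoliths are never treated as independent
  perm_side <- .try_test(permutation_anova(
    A, records$side, n_perm = config$n_perm,
    seed = config$seed + 101L, blocks = records$specimen_id,
    factor_name = "side"))
  side_ns <- !isTRUE(perm_side$significant)
  pool <- config$pool_sides && side_ns
  sel <- if (pool) seq_len(nrow(A)) else which(records$side == "L")
  perm_sex <- .try_test(permutation_anova(
    A[sel, , drop = FALSE], records$sex[sel], n_perm = config$n_perm,
    seed = config$seed + 102L, blocks = records$specimen_id[sel],
    factor_name = "sex"))
  perm_class <- .try_test(permutation_anova(
    A[sel, , drop = FALSE], records$size_class[sel], n_perm = config$n_perm,
    seed = config$seed + 103L, blocks = records$specimen_id[sel],
    factor_name = "size_class"))

  lda_side <- .try_test(oto_lda(A, records$side, factor_name = "side"))
  lda_sex <- .try_test(oto_lda(A[sel, , drop = FALSE], records$sex[sel],
                               factor_name = "sex"))
  lda_class <- .try_test(oto_lda(A[sel, , drop = FALSE],
                                 records$size_class[sel],
                                 factor_name = "size_class"))

  wl_sets <- if (config$descriptor == "wavelet") sets else
    attr(descriptor_matrix(contours, kind = "wavelet"), "descriptor_sets")
  mean_class <- .try_test(group_mean_shape(wl_sets, records$size_class))
  mean_sex <- .try_test(group_mean_shape(wl_sets, records$sex))

  diag_rec <- .try_test(reconstruction_diagnostic(
    wl_sets[[1L]], contours[[1L]]))
  diag_pos <- .try_test(position_variation(wl_sets))

  manifest <- list(
    package = "otoshape",
    version = as.character(packageVersion("otoshape")),
    r_version = R.version.string,
    mode = config$mode, seed = config$seed,
    descriptor = config$descriptor, n_perm = config$n_perm,
    n_specimens = nrow(specimens), n_contours = length(contours),
    sides_pooled = pool,
    quarantined = length(acq$quarantine),
    morphometry_hash = .table_hash(records))

  run <- structure(list(
    config = config, specimens = specimens, contours = contours,
    records = records, summaries = summaries,
    tests = list(side_t = side_t, sex_t = sex_t, class_anova = class_anova,
                 pearson = pearson, perm_side = perm_side,
                 perm_sex = perm_sex, perm_class = perm_class),
    lda = list(side = lda_side, sex = lda_sex, size_class = lda_class),
    descriptors = mat, adjustment = adj,
    mean_shapes = list(by_class = mean_class, by_sex = mean_sex),
    diagnostics = list(reconstruction = diag_rec, position = diag_pos),
    quarantine = acq$quarantine, manifest = manifest),
    class = "oto_run")
  if (!is.null(config$out_dir)) .write_bundle(run, config$out_dir)
  run
}

# stable content hash of a numeric table (rounded to avoid platform noise)
.table_hash <- function(df) {
  num <- vapply(df, is.numeric, logical(1L))
  s <- paste(capture.output(write.csv(
    cbind(df[!num], round(df[num], 10L)), row.names = FALSE)),
    collapse = "\n")
  f <- tempfile(); writeLines(s, f); on.exit(unlink(f))
  unname(tools::md5sum(f))
}

.test_row <- function(name, t) {
  if (isTRUE(t$skipped))
    return(data.frame(test = name, statistic = NA_real_, p_value = NA_real_,
                      significant = NA, note = t$reason,
                      stringsAsFactors = FALSE))
  data.frame(test = name, statistic = t$statistic, p_value = t$p_value,
             significant = t$significant, note = "", stringsAsFactors = FALSE)
}

.write_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$records, file.path(dir, "morphometry.csv"), row.names = FALSE)
  for (nm in names(run$summaries))
    write.csv(run$summaries[[nm]],
              file.path(dir, paste0("summary_", nm, ".csv")), row.names = FALSE)
  tests <- run$tests
  flat <- rbind(
    do.call(rbind, lapply(names(tests$side_t), function(v)
      .test_row(paste("side t:", v), tests$side_t[[v]]))),
    do.call(rbind, lapply(names(tests$sex_t), function(v)
      .test_row(paste("sex t:", v), tests$sex_t[[v]]))),
    do.call(rbind, lapply(names(tests$class_anova), function(v)
      .test_row(paste("class ANOVA:", v), tests$class_anova[[v]]))),
    do.call(rbind, lapply(names(tests$pearson), function(v)
      .test_row(paste("Pearson:", v), tests$pearson[[v]]))),
    .test_row("permutation: side", tests$perm_side),
    .test_row("permutation: sex", tests$perm_sex),
    .test_row("permutation: size_class", tests$perm_class))
  write.csv(flat, file.path(dir, "tests.csv"), row.names = FALSE)
  tukey <- do.call(rbind, lapply(names(tests$class_anova), function(v) {
    t <- tests$class_anova[[v]]
    if (isTRUE(t$skipped) || is.null(t$details)) return(NULL)
    cbind(variable = v, t$details)
  }))
  if (!is.null(tukey))
    write.csv(tukey, file.path(dir, "tukey_pairs.csv"), row.names = FALSE)
  write.csv(run$adjustment$report, file.path(dir, "allometry_report.csv"),
            row.names = FALSE)
  write.csv(cbind(id = rownames(run$descriptors),
                  as.data.frame(run$adjustment$adjusted)),
            file.path(dir, "descriptors_adjusted.csv"), row.names = FALSE)
  for (nm in names(run$lda)) {
    l <- run$lda[[nm]]
    if (isTRUE(l$skipped)) next
    write.csv(cbind(id = rownames(run$descriptors)[seq_len(nrow(l$scores))],
                    group = as.character(l$groups),
                    as.data.frame(l$scores)),
              file.path(dir, paste0("lda_scores_", nm, ".csv")),
              row.names = FALSE)
    png(file.path(dir, paste0("lda_", nm, ".png")), 700, 700)
    plot(l); dev.off()
  }
  for (nm in names(run$mean_shapes)) {
    ms <- run$mean_shapes[[nm]]
    if (isTRUE(ms$skipped)) next
    overlay_export(ms, file.path(dir, paste0("mean_shapes_", nm)))
  }
  if (!isTRUE(run$diagnostics$position$skipped))
    write.csv(run$diagnostics$position,
              file.path(dir, "position_variation.csv"), row.names = FALSE)
  if (length(run$quarantine))
    writeLines(paste(names(run$quarantine), run$quarantine, sep = ": "),
               file.path(dir, "quarantine.txt"))
  mf <- run$manifest
  writeLines(paste0(names(mf), ": ", unlist(mf)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.oto_run <- function(x, ...) {
  cat(sprintf("<oto_run> mode=%s  %d specimens, %d contours (%d quarantined)\n",
              x$config$mode, nrow(x$specimens), length(x$contours),
              length(x$quarantine)))
  cat(sprintf("  sides pooled: %s\n", x$manifest$sides_pooled))
  for (nm in c("perm_side", "perm_sex", "perm_class")) {
    t <- x$tests[[nm]]
    if (isTRUE(t$skipped)) cat(sprintf("  %s: skipped (%s)\n", nm, t$reason))
    else cat(sprintf("  %s: pseudo-F = %.3f, p = %.4g%s\n", nm,
                     t$statistic, t$p_value, if (t$significant) " *" else ""))
  }
  for (nm in names(x$lda)) {
    l <- x$lda[[nm]]
    if (!isTRUE(l$skipped))
      cat(sprintf("  LDA %s: LOO accuracy = %.3f\n", nm, l$accuracy))
  }
  invisible(x)
}

#' @export
summary.oto_run <- function(object, ...) {
  print(object)
  cat("\nSize-class summary (sagittal convention table):\n")
  print(utils::head(object$summaries$by_class, 22L))
  invisible(object)
}
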