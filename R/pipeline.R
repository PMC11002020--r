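# Subject-level workflow: subcutaneous fat segmentation, subject-specific
# fat-T2 calibration, voxel-wise muscle mapping with any of the three
# estimators, Dixon fat-fraction reference, ROI statistics.

# voxel signals under a mask; stack may be (x, y, echo) or (x, y, z, echo)
stack_signals <- function(stack, mask) {
  d <- dim(stack)
  if (length(d) == 3) stack <- array(stack, dim = c(d[1], d[2], 1L, d[3]))
  d <- dim(stack)
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!all(dim(mask) == d[1:3])) {
    stop("mask geometry does not match the MESE stack", call. = FALSE)
  }
  idx <- which(mask)
  etl <- d[4]
  sig <- matrix(0, length(idx), etl)
  plane <- prod(d[1:3])
  for (e in seq_len(etl)) sig[, e] <- stack[(e - 1L) * plane + idx]
  list(signals = sig, idx = idx, dim = d[1:3])
}

# 4-connected component labeling (iterative frontier flood fill)
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo) > 0) {
    cur <- cur + 1L
    frontier <- todo[1]
    lab[frontier] <- cur
    while (length(frontier) > 0) {
      i <- ((frontier - 1L) %% d[1]) + 1L
      j <- ((frontier - 1L) %/% d[1]) + 1L
      nb <- c(frontier[i > 1] - 1L, frontier[i < d[1]] + 1L,
              frontier[j > 1] - d[1], frontier[j < d[2]] + d[1])
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Segment subcutaneous fat from the first MESE echo
#'
#' Lloyd's k-means clustering of the voxel intensities; the cluster with
#' the highest mean intensity is taken as fat, and its largest connected
#' component — the subcutaneous ring — is returned.  Deterministic for a
#' given seed.
#'
#' @param first_echo_image 2-D numeric matrix (first echo magnitudes).
#' @param k_clusters Number of intensity clusters (>= 2; default 3:
#'   background / muscle / fat).
#' @param seed Seed for the k-means initialization.
#' @return Logical matrix: the subcutaneous fat mask.
#' @export
segment_subcutaneous_fat <- function(first_echo_image, k_clusters = 3, seed = 1) {
  stopifnot(is.matrix(first_echo_image), k_clusters >= 2)
  v <- as.vector(first_echo_image)
  if (length(unique(v)) < k_clusters) {
    stop("image intensities are not separable into ", k_clusters,
         " clusters; supply a manual fat mask", call. = FALSE)
  }
  set.seed(seed)
  km <- kmeans(v, centers = k_clusters, algorithm = "Lloyd",
               nstart = 5, iter.max = 100)
  fat_cluster <- which.max(km$centers)
  mask <- matrix(km$cluster == fat_cluster, nrow(first_echo_image))
  if (!any(mask)) stop("empty fat cluster; supply a manual fat mask", call. = FALSE)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Calibrate the subject's fat T2 in the subcutaneous region
#'
#' Applies the chosen estimator voxel-wise in the fat mask (FF fixed at
#' 0.9) and aggregates the per-voxel T2f estimates into one scalar
#' (median by default, robust to mask impurities).  Poorly fitting voxels
#' are excluded before aggregation: dictionary score below `min_score`,
#' NLSQ relative residual above `max_resid`, or regressor outputs clipped
#' at the training range.
#'
#' @param stack MESE array (x, y\[, z\], echo).
#' @param fat_mask Logical mask on the stack grid.
#' @param seq A [sequence_config()].
#' @param method `"nn"`, `"dict"` or `"nlsq"`.
#' @param fat_model Trained fat [build_model()] (method `"nn"`).
#' @param fat_dict Fat [build_dictionary()]; built on a coarsened default
#'   grid if omitted (method `"dict"`).
#' @param aggregator Function reducing per-voxel T2f to a scalar.
#' @param step_scale Coarsening for the default fat dictionary.
#' @param n_max Random subsample cap on calibration voxels (the NLSQ
#'   estimator in particular needs no more than a few hundred).
#' @param min_score,max_resid Quality thresholds for voxel exclusion.
#' @param seed Seed for the voxel subsample.
#' @return A `t2f_calibration`: `t2f_ms`, per-voxel tibble, `n_valid`,
#'   `low_coverage` flag (fewer than 50 valid voxels).
#' @export
calibrate_t2f <- function(stack, fat_mask, seq,
                          method = c("nn", "dict", "nlsq"),
                          fat_model = NULL, fat_dict = NULL,
                          aggregator = stats::median, step_scale = 4,
                          n_max = 400, min_score = 0.999, max_resid = 0.05,
                          seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(seq, "sequence_config"))
  ss <- stack_signals(stack, fat_mask)
  if (nrow(ss$signals) == 0) stop("fat mask is empty", call. = FALSE)
  set.seed(seed)
  if (nrow(ss$signals) > n_max) {
    take <- sort(sample.int(nrow(ss$signals), n_max))
    ss$signals <- ss$signals[take, , drop = FALSE]
  }

  vox <- switch(method,
    nn = {
      stopifnot(inherits(fat_model, "regressor_bundle"),
                fat_model$kind == "fat")
      check_seq_hash(fat_model$seq_hash, seq)
      pr <- predict_fat(fat_model, ss$signals)
      dplyr::mutate(pr, ok = !pr$clipped)
    },
    dict = {
      if (is.null(fat_dict)) {
        fat_dict <- build_dictionary(build_grid("fat", step_scale = step_scale),
                                     seq)
      }
      check_seq_hash(fat_dict$seq_hash, seq)
      mt <- dict_match(ss$signals, fat_dict)
      dplyr::mutate(mt, ok = mt$valid & mt$score >= min_score)
    },
    nlsq = {
      ft <- fit_nlsq(ss$signals, seq, kind = "fat")
      rel <- ft$residual / pmax(rowSums(ss$signals^2), 1e-24)
      dplyr::mutate(ft, ok = ft$valid & rel <= max_resid)
    })

  ok <- vox$ok & is.finite(vox$t2f_ms)
  n_valid <- sum(ok)
  if (n_valid == 0) stop("no valid fat voxels for calibration", call. = FALSE)
  structure(list(t2f_ms = aggregator(vox$t2f_ms[ok]), voxels = vox,
                 n_valid = n_valid, low_coverage = n_valid < 50,
                 method = method),
            class = "t2f_calibration")
}

#' @export
print.t2f_calibration <- function(x, ...) {
  cat(sprintf("<t2f_calibration> T2f = %.1f ms (%s, %d valid voxels%s)\n",
              x$t2f_ms, x$method, x$n_valid,
              if (x$low_coverage) ", LOW COVERAGE" else ""))
  invisible(x)
}

check_seq_hash <- function(resource_hash, seq) {
  if (!is.null(resource_hash) && !identical(resource_hash, seq_hash(seq))) {
    stop("sequence fingerprint mismatch: this model/dictionary was built ",
         "for a different acquisition; rebuild or retrain", call. = FALSE)
  }
}

#' Voxel-wise muscle parameter mapping
#'
#' Estimates (FF, T2w, B1) in every voxel of `muscle_mask` (or the whole
#' volume) with the chosen estimator, at the subject's calibrated T2f.
#' Out-of-range estimates are clipped and flagged rather than discarded;
#' voxels with FF > 0.95 are quality-flagged (T2w is unreliable where the
#' water component vanishes) and pure-noise/degenerate voxels are
#' excluded via the flags.
#'
#' @param stack MESE array (x, y\[, z\], echo).
#' @param t2f_ms Calibrated fat T2 in \[50, 250\] ms (scalar or a
#'   [calibrate_t2f()] result).
#' @param seq A [sequence_config()].
#' @param method `"nn"`, `"dict"` or `"nlsq"`.
#' @param muscle_model Trained muscle [build_model()] (method `"nn"`).
#' @param muscle_mask Logical mask; defaults to all voxels.
#' @param step_scale Coarsening of the muscle dictionary (method
#'   `"dict"`); step 1 reproduces the full published grid.
#' @param svd_k If non-`NULL`, match against an SVD-compressed dictionary
#'   with this many components.
#' @param seed Recorded in the provenance.
#' @return A `subject_maps` object: `t2w`, `ff`, `b1` maps (same shape as
#'   the mask grid), `quality` flag map, `t2f_ms`, provenance.
#' @export
map_subject <- function(stack, t2f_ms, seq, method = c("nn", "dict", "nlsq"),
                        muscle_model = NULL, muscle_mask = NULL,
                        step_scale = 2, svd_k = NULL, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(seq, "sequence_config"))
  if (inherits(t2f_ms, "t2f_calibration")) t2f_ms <- t2f_ms$t2f_ms
  if (t2f_ms < 50 || t2f_ms > 250) {
    stop("t2f_ms must lie in [50, 250] ms", call. = FALSE)
  }
  d <- dim(stack)
  if (d[length(d)] != seq$etl) {
    stop("stack echo count does not match the sequence etl", call. = FALSE)
  }
  if (is.null(muscle_mask)) {
    muscle_mask <- array(TRUE, dim = if (length(d) == 3) c(d[1:2], 1) else d[1:3])
  }
  ss <- stack_signals(stack, muscle_mask)

  est <- switch(method,
    nn = {
      stopifnot(inherits(muscle_model, "regressor_bundle"),
                muscle_model$kind == "muscle")
      check_seq_hash(muscle_model$seq_hash, seq)
      pr <- predict_muscle(muscle_model, ss$signals, t2f_ms)
      dplyr::mutate(pr, ok = TRUE, flagged = pr$clipped | pr$ff > 0.95)
    },
    dict = {
      dict <- build_dictionary(build_grid("muscle", t2f_ms = t2f_ms,
                                          step_scale = step_scale), seq)
      mt <- if (is.null(svd_k)) {
        dict_match(ss$signals, dict)
      } else {
        match_compressed(ss$signals, compress_svd(dict, svd_k))
      }
      # a low matching score marks voxels the signal model cannot explain
      # (pure noise, artifacts)
      dplyr::mutate(mt, ok = mt$valid,
                    flagged = !mt$valid | mt$ff > 0.95 | mt$score < 0.99)
    },
    nlsq = {
      ft <- fit_nlsq(ss$signals, seq, kind = "muscle", t2f_ms = t2f_ms)
      rel <- ft$residual / pmax(rowSums(ss$signals^2), 1e-24)
      dplyr::mutate(ft, ok = ft$valid,
                    flagged = !ft$valid | ft$flag != "ok" | rel > 0.05)
    })

  shp <- ss$dim
  mk_map <- function(vals) {
    m <- array(NA_real_, dim = shp)
    m[ss$idx] <- vals
    if (shp[3] == 1L) m <- m[, , 1]
    m
  }
  qual <- array(FALSE, dim = shp)
  qual[ss$idx] <- est$flagged | !est$ok
  if (shp[3] == 1L) qual <- qual[, , 1]

  structure(list(t2w = mk_map(ifelse(est$ok, est$t2w_ms, NA_real_)),
                 ff = mk_map(ifelse(est$ok, est$ff, NA_real_)),
                 b1 = mk_map(ifelse(est$ok, est$b1, NA_real_)),
                 quality = qual, t2f_ms = t2f_ms, method = method,
                 provenance = list(method = method, seed = seed,
                                   seq_hash = seq_hash(seq),
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                   n_voxels = nrow(est))),
            class = "subject_maps")
}

#' @export
print.subject_maps <- function(x, ...) {
  cat("<subject_maps>", x$method, "fit of", x$provenance$n_voxels,
      "voxels, T2f =", round(x$t2f_ms, 1), "ms,",
      sum(x$quality), "flagged\n")
  invisible(x)
}

#' @rdname map_subject
#' @param x A `subject_maps` object.
#' @param ... Unused.
#' @export
tidy.subject_maps <- function(x, ...) {
  t2w <- as.vector(x$t2w)
  keep <- !is.na(t2w)
  idx <- which(keep)
  tibble::tibble(voxel = idx, t2w_ms = t2w[idx],
                 ff = as.vector(x$ff)[idx], b1 = as.vector(x$b1)[idx],
                 flagged = as.vector(x$quality)[idx])
}

#' @rdname map_subject
#' @export
glance.subject_maps <- function(x, ...) {
  v <- tidy(x)
  ok <- !v$flagged
  tibble::tibble(method = x$method, t2f_ms = x$t2f_ms,
                 n_voxels = nrow(v), n_flagged = sum(v$flagged),
                 t2w_mean = mean(v$t2w_ms[ok]), t2w_sd = sd(v$t2w_ms[ok]),
                 ff_mean = mean(v$ff[ok]))
}

#' Parameter-map panel plot
#'
#' @param object A `subject_maps` object.
#' @param ... Unused.
#' @return A ggplot with the T2w, FF and B1 maps.
#' @export
autoplot.subject_maps <- function(object, ...) {
  stopifnot(is.matrix(object$t2w))
  sh <- dim(object$t2w)
  grid <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]))
  df <- dplyr::bind_rows(
    dplyr::mutate(grid, value = as.vector(object$t2w), panel = "T2w (ms)"),
    dplyr::mutate(grid, value = as.vector(object$ff), panel = "FF"),
    dplyr::mutate(grid, value = as.vector(object$b1), panel = "B1")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Dixon fat-fraction map
#'
#' `FF = If / (Iw + If) * 100` (percent), voxel-wise from the water-only
#' and fat-only images.  Voxels where both images are zero are returned
#' as `NA` (invalid); the result is invariant under a common intensity
#' rescaling of both inputs.
#'
#' @param water_img,fat_img Nonnegative arrays of identical shape.
#' @return FF map in percent, same shape.
#' @export
dixon_ff <- function(water_img, fat_img) {
  if (!all(dim(water_img) == dim(fat_img))) {
    stop("water and fat images must have the same shape", call. = FALSE)
  }
  if (any(water_img < 0, na.rm = TRUE) || any(fat_img < 0, na.rm = TRUE)) {
    stop("Dixon intensities must be nonnegative", call. = FALSE)
  }
  denom <- water_img + fat_img
  out <- 100 * fat_img / denom
  out[denom == 0] <- NA_real_
  out
}

#' Per-ROI summary of a parameter map
#'
#' Mean, SD and voxel count over each region of interest, excluding
#' quality-flagged voxels; ROIs left empty after flagging are reported
#' with `n_voxels = 0`.
#'
#' @param map Numeric map (matrix/array) such as `subject_maps$t2w`.
#' @param roi_masks Named list of logical masks on the map grid.
#' @param quality_mask Logical mask of voxels to exclude (optional).
#' @return Tibble: `roi`, `mean`, `sd`, `n_voxels`.
#' @export
roi_stats <- function(map, roi_masks, quality_mask = NULL) {
  stopifnot(is.list(roi_masks), !is.null(names(roi_masks)))
  if (is.null(quality_mask)) quality_mask <- array(FALSE, dim = dim(map))
  purrr::imap_dfr(roi_masks, function(m, nm) {
    if (!all(dim(m) == dim(map))) {
      stop("ROI '", nm, "' does not match the map geometry", call. = FALSE)
    }
    vals <- map[m & !quality_mask]
    vals <- vals[is.finite(vals)]
    tibble::tibble(roi = nm, mean = if (length(vals)) mean(vals) else NA_real_,
                   sd = if (length(vals) > 1) sd(vals) else NA_real_,
                   n_voxels = length(vals))
  })
}

#' Sensitivity of mapped T2w to the calibrated fat T2
#'
#' Re-runs the muscle mapping with the calibrated T2f biased by the given
#' offsets and reports the change in mean (unflagged) T2w.  Even small
#' fat-T2 miscalibrations shift the estimated water T2 by milliseconds,
#' which is why subject-specific calibration matters.
#'
#' @param stack,seq,method,muscle_model,muscle_mask,step_scale As in
#'   [map_subject()].
#' @param t2f_ms Reference calibrated fat T2.
#' @param deltas_ms Offsets applied to `t2f_ms` (default -20 to +20 ms).
#' @return Tibble: `delta_ms`, `t2f_ms`, `mean_t2w_ms`, `shift_ms`
#'   (relative to the reference).
#' @export
t2f_sensitivity <- function(stack, t2f_ms, seq, method = "nn",
                            muscle_model = NULL, muscle_mask = NULL,
                            deltas_ms = c(-20, -10, 0, 10, 20),
                            step_scale = 2) {
  runs <- purrr::map_dfr(deltas_ms, function(dl) {
    maps <- map_subject(stack, t2f_ms + dl, seq, method = method,
                        muscle_model = muscle_model,
                        muscle_mask = muscle_mask, step_scale = step_scale)
    v <- tidy(maps)
    tibble::tibble(delta_ms = dl, t2f_ms = t2f_ms + dl,
                   mean_t2w_ms = mean(v$t2w_ms[!v$flagged]))
  })
  ref <- runs$mean_t2w_ms[runs$delta_ms == 0]
  if (length(ref) == 0) ref <- NA_real_
  dplyr::mutate(runs, shift_ms = .data$mean_t2w_ms - ref)
}

#' Write subject maps to NIfTI + JSON provenance
#'
#' @param maps A `subject_maps` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_subject_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "subject_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("t2w", "ff", "b1")) {
    img <- maps[[nm]]; img[is.na(img)] <- 0
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  RNifti::writeNifti(maps$quality * 1, file.path(dir, "quality_flag.nii.gz"))
  prov <- c(maps$provenance, list(t2f_ms = maps$t2f_ms))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Read / write a sequence configuration as YAML
#'
#' The YAML file holds `te_ms`, `etl`, `tr_ms` and either a profile
#' preset name (`profile_preset`, `n_bins`) or explicit profile vectors.
#'
#' @param path YAML file path.
#' @return A [sequence_config()].
#' @export
read_sequence_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$te_ms), !is.null(y$etl))
  if (!is.null(y$profile_preset)) {
    prof <- slice_profile_preset(y$profile_preset,
                                 n_bins = y$n_bins %||% 64)
    sequence_config(y$te_ms, y$etl, y$tr_ms %||% 3000,
                    ex_profile = prof$ex_profile,
                    ref_profile = prof$ref_profile,
                    profile_weights = prof$weights)
  } else {
    sequence_config(y$te_ms, y$etl, y$tr_ms %||% 3000,
                    ex_profile = y$ex_profile %||% 90,
                    ref_profile = y$ref_profile %||% 180,
                    profile_weights = y$profile_weights)
  }
}

#' @rdname read_sequence_yaml
#' @param seq A [sequence_config()].
#' @export
write_sequence_yaml <- function(seq, path) {
  stopifnot(inherits(seq, "sequence_config"))
  yaml::write_yaml(list(te_ms = seq$te_ms, etl = seq$etl, tr_ms = seq$tr_ms,
                        ex_profile = seq$ex_profile,
                        ref_profile = seq$ref_profile,
                        profile_weights = seq$profile_weights),
                   path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
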