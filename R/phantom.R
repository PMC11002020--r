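# Digital thigh phantom: synthetic multi-echo spin-echo subjects with
# known ground truth, standing in for in vivo acquisitions so the whole
# pipeline can be validated end to end.

#' Specify a synthetic MESE phantom
#'
#' A single-slice layout: elliptical "thigh" with a subcutaneous fat ring
#' (FF 0.9), non-overlapping elliptical muscle compartments with known
#' (T2w, FF), a shared fat T2, a smooth polynomial B1 field, and Rician
#' noise at a stated first-echo SNR.
#'
#' @param shape Image dimensions `c(nx, ny)`.
#' @param compartments Tibble with columns `label`, `cx`, `cy`, `rx`,
#'   `ry` (voxel units), `t2w_ms`, `ff`.
#' @param t2f_ms Shared fat T2 (ms), in \[50, 250\].
#' @param outer,inner Outer/inner ellipse semi-axes `c(rx, ry)` of the
#'   subcutaneous ring (centered in the image).
#' @param b1_range B1 multiplier range `c(lo, hi)` of the left-to-right
#'   linear gradient; must stay within the estimators' \[0.4, 1.2\] range.
#' @param snr First-echo signal-to-noise ratio (Gaussian sigma relative
#'   to the mean noiseless first-echo amplitude over the foreground);
#'   `Inf` for noiseless.
#' @param ring_t2w_ms Water T2 of the residual water in the fat ring.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 160), compartments,
                         t2f_ms = 150, outer = c(62, 56), inner = c(50, 45),
                         b1_range = c(0.8, 1.1), snr = 100,
                         ring_t2w_ms = 30) {
  stopifnot(length(shape) == 2, all(shape >= 16))
  stopifnot(is.data.frame(compartments),
            all(c("label", "cx", "cy", "rx", "ry", "t2w_ms", "ff") %in%
                  names(compartments)))
  if (t2f_ms < 50 || t2f_ms > 250) stop("t2f_ms must lie in [50, 250]", call. = FALSE)
  if (!(snr > 0)) stop("snr must be > 0", call. = FALSE)
  stopifnot(b1_range[1] >= 0.4, b1_range[2] <= 1.2, b1_range[1] <= b1_range[2])
  spec <- structure(list(shape = as.integer(shape),
                         compartments = tibble::as_tibble(compartments),
                         t2f_ms = t2f_ms, outer = outer, inner = inner,
                         b1_range = b1_range, snr = snr,
                         ring_t2w_ms = ring_t2w_ms),
                    class = "phantom_spec")
  masks <- compartment_masks(spec)
  counts <- Reduce(`+`, lapply(masks, as.integer))
  if (any(counts > 1)) stop("compartments overlap", call. = FALSE)
  spec
}

ellipse_mask <- function(shape, cx, cy, rx, ry) {
  x <- matrix(seq_len(shape[1]), shape[1], shape[2])
  y <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

compartment_masks <- function(spec) {
  lapply(seq_len(nrow(spec$compartments)), function(i) {
    cc <- spec$compartments[i, ]
    ellipse_mask(spec$shape, cc$cx, cc$cy, cc$rx, cc$ry)
  })
}

#' Default thigh phantom layout
#'
#' 160 x 160 single-slice layout: background, subcutaneous fat ring
#' (FF 0.9, shared fat T2 150 ms), and ten elliptical muscle compartments
#' arranged in a ring, with fat fractions 0, 0.05, 0.1, 0.2, ..., 0.8 and
#' water T2 values spread over \[25, 45\] ms in an order chosen to be
#' uncorrelated with the fat fractions (so a regression of estimated T2w
#' on true FF tests fat suppression, not the layout).  B1 varies smoothly
#' from 0.8 to 1.1 left to right.  All ground-truth values lie inside the
#' estimators' training/dictionary ranges.
#'
#' @param snr First-echo SNR of the generated data (default 100,
#'   muscle-like).
#' @return A [phantom_spec()].
#' @export
default_thigh_phantom <- function(snr = 100) {
  ang <- (0:9) * 36 * pi / 180
  comp <- tibble::tibble(
    label = paste0("muscle_", 1:10),
    cx = 80 + 32 * cos(ang),
    cy = 78 + 30 * sin(ang),
    rx = 8, ry = 6.5,
    t2w_ms = c(35, 27, 43, 31, 39, 25, 41, 29, 45, 33),
    ff = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  )
  phantom_spec(compartments = comp, snr = snr)
}

#' Generate a synthetic MESE subject from a phantom specification
#'
#' Simulates every foreground voxel's noiseless echo train with the
#' two-component EPG model under the local B1, then adds two-channel
#' Gaussian noise and takes the magnitude (Rician noise, as in acquired
#' magnitude images) with `sigma = mean(first echo) / snr`.  Fully
#' reproducible for a given seed.
#'
#' @param spec A [phantom_spec()].
#' @param seq A [sequence_config()].
#' @param seed Integer seed for the noise.
#' @return A `mese_phantom`: `stack` (nx x ny x 1 x etl array), truth
#'   maps (`t2w`, `ff`, `b1` matrices, `NA` outside the foreground),
#'   `masks` (list: `foreground`, `ring`, per-compartment), `labels`
#'   (compartment label matrix), `sigma`, `spec`, `seq_hash`.
#' @export
make_phantom <- function(spec, seq, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(seq, "sequence_config"))
  shape <- spec$shape
  outer <- ellipse_mask(shape, shape[1] / 2, shape[2] / 2,
                        spec$outer[1], spec$outer[2])
  inner <- ellipse_mask(shape, shape[1] / 2, shape[2] / 2,
                        spec$inner[1], spec$inner[2])
  ring <- outer & !inner
  cmasks <- compartment_masks(spec)
  for (m in cmasks) {
    if (any(m & !inner)) stop("compartments must lie inside the ring", call. = FALSE)
  }

  t2w <- matrix(NA_real_, shape[1], shape[2])
  ffm <- matrix(NA_real_, shape[1], shape[2])
  lab <- matrix(NA_character_, shape[1], shape[2])
  t2w[ring] <- spec$ring_t2w_ms; ffm[ring] <- 0.9; lab[ring] <- "ring"
  for (i in seq_along(cmasks)) {
    cc <- spec$compartments[i, ]
    t2w[cmasks[[i]]] <- cc$t2w_ms
    ffm[cmasks[[i]]] <- cc$ff
    lab[cmasks[[i]]] <- cc$label
  }
  fg <- !is.na(t2w)

  u <- (matrix(seq_len(shape[1]), shape[1], shape[2]) - 1) / (shape[1] - 1)
  b1 <- spec$b1_range[1] + diff(spec$b1_range) * u
  b1m <- matrix(NA_real_, shape[1], shape[2]); b1m[fg] <- b1[fg]

  vox <- tibble::tibble(t2w_ms = t2w[fg], t2f_ms = spec$t2f_ms,
                        ff = ffm[fg], b1 = b1[fg])
  sig <- mese_simulate_table(vox, seq)

  etl <- seq$etl
  stack <- array(0, dim = c(shape[1], shape[2], 1L, etl))
  sigma <- if (is.finite(spec$snr)) mean(sig[, 1]) / spec$snr else 0
  set.seed(seed)
  for (e in seq_len(etl)) {
    plane <- matrix(0, shape[1], shape[2])
    plane[fg] <- sig[, e]
    if (sigma > 0) {
      n1 <- matrix(rnorm(prod(shape), 0, sigma), shape[1], shape[2])
      n2 <- matrix(rnorm(prod(shape), 0, sigma), shape[1], shape[2])
      plane <- sqrt((plane + n1)^2 + n2^2)
    }
    stack[, , 1, e] <- plane
  }

  masks <- c(list(foreground = fg, ring = ring),
             setNames(cmasks, spec$compartments$label))
  structure(list(stack = stack, t2w = t2w, ff = ffm, b1 = b1m,
                 labels = lab, masks = masks, sigma = sigma,
                 spec = spec, seq_hash = seq_hash(seq), seed = seed),
            class = "mese_phantom")
}

#' @export
print.mese_phantom <- function(x, ...) {
  cat("<mese_phantom>", paste(dim(x$stack), collapse = " x "),
      "stack,", sum(x$masks$foreground), "foreground voxels, sigma =",
      signif(x$sigma, 3), "\n")
  invisible(x)
}

#' Ground truth of a phantom as a voxel table
#'
#' @param phantom A [make_phantom()] result.
#' @return Tibble: voxel indices, compartment label, true `t2w_ms`, `ff`,
#'   `b1`.
#' @export
phantom_truth <- function(phantom) {
  stopifnot(inherits(phantom, "mese_phantom"))
  fg <- which(phantom$masks$foreground, arr.ind = TRUE)
  tibble::tibble(x = fg[, 1], y = fg[, 2],
                 label = phantom$labels[fg],
                 t2w_ms = phantom$t2w[fg], ff = phantom$ff[fg],
                 b1 = phantom$b1[fg])
}

#' Write a phantom to NIfTI + JSON files
#'
#' Writes the MESE stack, the truth maps, and the masks as NIfTI-1
#' volumes plus a JSON sidecar with the specification.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "mese_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(phantom$stack, file.path(dir, "mese.nii.gz"))
  for (nm in c("t2w", "ff", "b1")) {
    img <- phantom[[nm]]; img[is.na(img)] <- 0
    RNifti::writeNifti(img, file.path(dir, paste0("truth_", nm, ".nii.gz")))
  }
  for (nm in names(phantom$masks)) {
    RNifti::writeNifti(phantom$masks[[nm]] * 1,
                       file.path(dir, paste0("mask_", nm, ".nii.gz")))
  }
  meta <- list(compartments = as.data.frame(phantom$spec$compartments),
               t2f_ms = phantom$spec$t2f_ms, snr = phantom$spec$snr,
               b1_range = phantom$spec$b1_range, sigma = phantom$sigma,
               seed = phantom$seed, seq_hash = phantom$seq_hash)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot a phantom's ground truth and first echo
#'
#' @param object A [make_phantom()] result.
#' @param ... Unused.
#' @return A ggplot faceted over first echo and truth maps.
#' @export
autoplot.mese_phantom <- function(object, ...) {
  sh <- dim(object$stack)[1:2]
  grid <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]))
  df <- dplyr::bind_rows(
    dplyr::mutate(grid, value = as.vector(object$stack[, , 1, 1]),
                  panel = "first echo"),
    dplyr::mutate(grid, value = as.vector(object$t2w), panel = "true T2w (ms)"),
    dplyr::mutate(grid, value = as.vector(object$ff), panel = "true FF"),
    dplyr::mutate(grid, value = as.vector(object$b1), panel = "true B1")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
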