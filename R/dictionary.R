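# EPG signal dictionaries: parameter grids, atom simulation, dot-product
# matching, and SVD compression.

#' Build a fitting parameter grid
#'
#' Constructs the standard fat-calibration or muscle-processing grids.
#' The fat grid fixes FF = 0.9 (subcutaneous fat) and spans
#' T2f in \[50, 250\] ms (step 0.25), T2w in \[10, 110\] ms (step 0.5) and
#' B1 in \[0.4, 1.2\] (step 0.025).  The muscle grid fixes T2f at the
#' subject's calibrated value and spans FF in \[0, 1\] (step 0.015),
#' T2w in \[10, 80\] ms (step 0.2) and B1 in \[0.4, 1.2\] (step 0.025).
#' The B1 step is dimensionless.
#'
#' @param kind `"fat"` or `"muscle"`.
#' @param t2f_ms Calibrated fat T2 (ms) for the muscle grid; must lie in
#'   \[50, 250\].
#' @param overrides Named list of axis overrides, each a numeric
#'   `c(min, max, step)`; axis names are `t2f_ms`, `t2w_ms`, `b1`, `ff`.
#' @param step_scale Multiply every axis step by this factor (coarsening
#'   for quick runs); grid point counts shrink accordingly.
#' @return A `param_grid` with an `axes` tibble (`name`, `min`, `max`,
#'   `step`, `n`) and a `fixed` named list.
#' @examples
#' build_grid("muscle", t2f_ms = 151, step_scale = 4)
#' @export
build_grid <- function(kind = c("fat", "muscle"), t2f_ms = NULL,
                       overrides = list(), step_scale = 1) {
  kind <- match.arg(kind)
  stopifnot(step_scale > 0)
  if (kind == "fat") {
    axes <- list(t2f_ms = c(50, 250, 0.25), t2w_ms = c(10, 110, 0.5),
                 b1 = c(0.4, 1.2, 0.025))
    fixed <- list(ff = 0.9)
  } else {
    if (is.null(t2f_ms)) stop("muscle grid needs the calibrated t2f_ms", call. = FALSE)
    if (t2f_ms < 50 || t2f_ms > 250) {
      stop("calibrated t2f_ms must lie in [50, 250] ms", call. = FALSE)
    }
    axes <- list(ff = c(0, 1, 0.015), t2w_ms = c(10, 80, 0.2),
                 b1 = c(0.4, 1.2, 0.025))
    fixed <- list(t2f_ms = t2f_ms)
  }
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (!nm %in% names(axes) || length(ov) != 3) {
      stop("override for unknown axis or wrong length: ", nm, call. = FALSE)
    }
    axes[[nm]] <- ov
  }
  ax <- purrr::imap_dfr(axes, function(v, nm) {
    step <- v[3] * step_scale
    if (!is.finite(step) || step <= 0 || v[2] < v[1]) {
      stop("axis ", nm, " must have min <= max and step > 0", call. = FALSE)
    }
    tibble::tibble(name = nm, min = v[1], max = v[2], step = step,
                   n = floor((v[2] - v[1]) / step + 1e-9) + 1L)
  })
  structure(list(kind = kind, axes = ax, fixed = fixed), class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("<param_grid>", x$kind, "grid,", prod(x$axes$n), "points\n")
  print(x$axes)
  cat("fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                      collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the points of a parameter grid
#'
#' Points are ordered lexicographically over the axes as listed (the first
#' axis varies slowest), which fixes atom ordering and hence tie-breaking
#' in [dict_match()].
#'
#' @param grid A [build_grid()] result.
#' @return Tibble with one column per axis plus the fixed parameters.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  vals <- purrr::pmap(grid$axes, function(name, min, max, step, n) {
    min + step * (seq_len(n) - 1)
  })
  names(vals) <- grid$axes$name
  # first-listed axis slowest: expand.grid varies the first fastest, so
  # reverse, expand, then reorder columns
  pts <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  pts <- tibble::as_tibble(pts[, rev(seq_along(vals)), drop = FALSE])
  for (nm in names(grid$fixed)) pts[[nm]] <- grid$fixed[[nm]]
  pts
}

#' Simulate a signal dictionary on a parameter grid
#'
#' One unit-norm EPG echo train per grid point, simulated with
#' [mese_simulate_table()] (shared single-component trains make large
#' grids affordable).  Atom order is the [grid_points()] order and the
#' dictionary records the sequence fingerprint so it cannot be matched
#' against data from a different acquisition.
#'
#' @param grid A [build_grid()] result.
#' @param seq A [sequence_config()].
#' @param atom_limit Refuse grids with more points than this unless
#'   `force = TRUE` (memory guard).
#' @param force Build despite exceeding `atom_limit`.
#' @return A `signal_dictionary`: `atoms` (n_atoms x etl, unit rows),
#'   `params` tibble, `grid`, `seq_hash`.
#' @export
build_dictionary <- function(grid, seq, atom_limit = 2e7, force = FALSE) {
  stopifnot(inherits(grid, "param_grid"), inherits(seq, "sequence_config"))
  n_atoms <- prod(grid$axes$n)
  if (n_atoms > atom_limit && !force) {
    stop("grid has ", n_atoms, " points (> atom_limit = ", atom_limit,
         "); pass force = TRUE to build anyway", call. = FALSE)
  }
  pts <- grid_points(grid)
  atoms <- mese_simulate_table(pts, seq)
  nrm <- sqrt(rowSums(atoms^2))
  atoms <- atoms / nrm
  structure(list(atoms = atoms, params = pts, grid = grid,
                 seq_hash = seq_hash(seq)),
            class = "signal_dictionary")
}

#' @export
print.signal_dictionary <- function(x, ...) {
  cat("<signal_dictionary>", nrow(x$atoms), "atoms x", ncol(x$atoms),
      "echoes (", x$grid$kind, "grid )\n")
  invisible(x)
}

# shared matching kernel: signals (n x etl, unit rows assumed valid),
# template matrix (m x q), returns best index + score per signal
match_engine <- function(signals, templates, chunk = 50000L) {
  n <- nrow(signals)
  best_idx <- integer(n); best_sc <- rep(-Inf, n)
  m <- nrow(templates)
  for (start in seq(1L, m, by = chunk)) {
    end <- min(start + chunk - 1L, m)
    p <- signals %*% t(templates[start:end, , drop = FALSE])
    idx <- max.col(p, ties.method = "first")
    sc <- p[cbind(seq_len(n), idx)]
    upd <- sc > best_sc
    best_idx[upd] <- start - 1L + idx[upd]
    best_sc[upd] <- sc[upd]
  }
  list(idx = best_idx, score = best_sc)
}

normalize_signals <- function(signals, etl) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != etl) {
    stop("signal length ", ncol(signals), " does not match dictionary ETL ",
         etl, call. = FALSE)
  }
  nrm <- sqrt(rowSums(signals^2))
  ok <- is.finite(nrm) & nrm > 0
  signals[ok, ] <- signals[ok, , drop = FALSE] / nrm[ok]
  list(signals = signals, valid = ok)
}

#' Match measured signals against a dictionary
#'
#' Each signal is scaled to unit norm and assigned the parameters of the
#' atom with the largest dot product (ties broken by lowest atom index).
#' All-zero or non-finite signals are flagged invalid and returned with
#' `NA` parameters.
#'
#' @param signals Numeric vector (one voxel) or matrix (voxels x echoes).
#' @param dict A [build_dictionary()] result.
#' @param chunk Atoms per matching block (memory/speed trade-off).
#' @return Tibble: matched grid parameters, dot-product `score`, `atom`
#'   index and `valid` flag, one row per signal.
#' @export
dict_match <- function(signals, dict, chunk = 50000L) {
  stopifnot(inherits(dict, "signal_dictionary"))
  ns <- normalize_signals(signals, ncol(dict$atoms))
  n <- nrow(ns$signals)
  out <- dict$params[rep(NA_integer_, n), ]
  score <- rep(NA_real_, n); atom <- rep(NA_integer_, n)
  if (any(ns$valid)) {
    mt <- match_engine(ns$signals[ns$valid, , drop = FALSE], dict$atoms, chunk)
    out[ns$valid, ] <- dict$params[mt$idx, ]
    score[ns$valid] <- mt$score
    atom[ns$valid] <- mt$idx
  }
  dplyr::mutate(tibble::as_tibble(out), score = score, atom = atom,
                valid = ns$valid)
}

#' Compress a dictionary with the singular value decomposition
#'
#' Computes the SVD of the (uncentered) atom matrix, keeps the top `k`
#' right singular vectors as a basis, and stores the atom projections.
#' The explained-variance ratios are the squared singular values over
#' their total; atoms are not mean-centered, consistent with matching on
#' raw dot products (centered ratios are also reported for diagnostics).
#'
#' @param dict A [build_dictionary()] result.
#' @param k Number of components, `1 <= k <= etl`.
#' @return A `compressed_dictionary`: `basis` (etl x k),
#'   `projected_atoms` (n_atoms x k), `explained_variance_ratio`,
#'   `explained_variance_ratio_centered`, `params`, `seq_hash`.
#' @export
compress_svd <- function(dict, k) {
  stopifnot(inherits(dict, "signal_dictionary"))
  etl <- ncol(dict$atoms)
  if (k < 1 || k > etl) stop("k must lie in [1, ", etl, "]", call. = FALSE)
  cp <- crossprod(dict$atoms)                   # etl x etl
  eg <- eigen(cp, symmetric = TRUE)
  evr <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  mu <- colMeans(dict$atoms)
  egc <- eigen(cp / nrow(dict$atoms) - tcrossprod(mu), symmetric = TRUE)
  evr_c <- pmax(egc$values, 0) / sum(pmax(egc$values, 0))
  basis <- eg$vectors[, seq_len(k), drop = FALSE]
  structure(list(basis = basis,
                 projected_atoms = dict$atoms %*% basis,
                 explained_variance_ratio = evr[seq_len(k)],
                 explained_variance_ratio_centered = evr_c[seq_len(k)],
                 all_variance_ratio = evr,
                 params = dict$params, grid = dict$grid,
                 seq_hash = dict$seq_hash, k = k),
            class = "compressed_dictionary")
}

#' @export
print.compressed_dictionary <- function(x, ...) {
  cat("<compressed_dictionary> k =", x$k, ", cumulative explained variance",
      sprintf("%.3f%%", 100 * sum(x$explained_variance_ratio)), "\n")
  invisible(x)
}

#' Match signals against an SVD-compressed dictionary
#'
#' As [dict_match()], but dot products are computed between `k`-dimensional
#' projections; with `k = etl` the result is identical to full matching.
#'
#' @param signals Numeric vector or matrix (voxels x echoes).
#' @param cdict A [compress_svd()] result.
#' @param chunk Atoms per matching block.
#' @return Tibble as for [dict_match()].
#' @export
match_compressed <- function(signals, cdict, chunk = 50000L) {
  stopifnot(inherits(cdict, "compressed_dictionary"))
  ns <- normalize_signals(signals, nrow(cdict$basis))
  n <- nrow(ns$signals)
  out <- cdict$params[rep(NA_integer_, n), ]
  score <- rep(NA_real_, n); atom <- rep(NA_integer_, n)
  if (any(ns$valid)) {
    proj <- ns$signals[ns$valid, , drop = FALSE] %*% cdict$basis
    mt <- match_engine(proj, cdict$projected_atoms, chunk)
    out[ns$valid, ] <- cdict$params[mt$idx, ]
    score[ns$valid] <- mt$score
    atom[ns$valid] <- mt$idx
  }
  dplyr::mutate(tibble::as_tibble(out), score = score, atom = atom,
                valid = ns$valid)
}

#' Persist a dictionary as plain-text files
#'
#' Writes `atoms.csv`, `params.csv` and `meta.json` (axes, fixed values,
#' sequence fingerprint) into a directory.
#'
#' @param dict A [build_dictionary()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dictionary <- function(dict, dir) {
  stopifnot(inherits(dict, "signal_dictionary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dict$atoms), file.path(dir, "atoms.csv"),
                   row.names = FALSE)
  utils::write.csv(dict$params, file.path(dir, "params.csv"), row.names = FALSE)
  meta <- list(kind = dict$grid$kind,
               axes = as.data.frame(dict$grid$axes),
               fixed = dict$grid$fixed, seq_hash = dict$seq_hash)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a dictionary saved by [save_dictionary()]
#'
#' @param dir Directory written by [save_dictionary()].
#' @return A `signal_dictionary`.
#' @export
load_dictionary <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  atoms <- as.matrix(utils::read.csv(file.path(dir, "atoms.csv")))
  dimnames(atoms) <- NULL
  params <- tibble::as_tibble(utils::read.csv(file.path(dir, "params.csv")))
  grid <- structure(list(kind = meta$kind,
                         axes = tibble::as_tibble(meta$axes),
                         fixed = as.list(meta$fixed)),
                    class = "param_grid")
  structure(list(atoms = atoms, params = params, grid = grid,
                 seq_hash = meta$seq_hash),
            class = "signal_dictionary")
}
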