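#' Describe a multi-echo spin-echo acquisition
#'
#' Bundles the timing and slice-profile information needed to simulate a
#' 2-D MESE echo train: echo spacing, echo-train length and the effective
#' flip angle of the excitation and refocusing pulses at each sub-slice
#' position.  The default single-bin 90/180 profiles describe an ideal
#' (CPMG) acquisition without slice-profile effects.
#'
#' @param te_ms Echo spacing in milliseconds (> 0).
#' @param etl Echo-train length: number of refocusing pulses (>= 1).
#' @param tr_ms Repetition time in ms (informational; steady-state recovery
#'   between excitations is not modeled because clinical MESE protocols use
#'   TR long relative to T1).
#' @param ex_profile,ref_profile Numeric vectors of equal length giving the
#'   excitation and refocusing flip angles (degrees) per sub-slice position.
#' @param profile_weights Optional quadrature weights for the sub-slice
#'   summation (one per profile bin, positive).  Defaults to equal weights;
#'   [sequence_preset()] uses Gauss-Legendre weights, which makes the
#'   slice-profile integral converge much faster in the bin count.
#' @return An object of class `sequence_config`.
#' @examples
#' seq <- sequence_config(te_ms = 7.5, etl = 17)
#' mese_single_component(t2_ms = 50, b1 = 1, seq = seq)
#' @export
sequence_config <- function(te_ms, etl, tr_ms = 3000,
                            ex_profile = 90, ref_profile = 180,
                            profile_weights = NULL) {
  stopifnot(is.numeric(te_ms), length(te_ms) == 1L, is.finite(te_ms), te_ms > 0)
  stopifnot(is.numeric(etl), length(etl) == 1L, etl >= 1, etl == round(etl))
  stopifnot(is.numeric(tr_ms), length(tr_ms) == 1L, tr_ms > 0)
  if (length(ex_profile) != length(ref_profile)) {
    stop("ex_profile and ref_profile must have equal length", call. = FALSE)
  }
  if (length(ex_profile) < 1L || !all(is.finite(ex_profile)) ||
      !all(is.finite(ref_profile))) {
    stop("slice profiles must be non-empty and finite", call. = FALSE)
  }
  if (is.null(profile_weights)) {
    profile_weights <- rep(1, length(ex_profile))
  }
  if (length(profile_weights) != length(ex_profile) ||
      any(!is.finite(profile_weights) | profile_weights <= 0)) {
    stop("profile_weights must be positive, one per profile bin", call. = FALSE)
  }
  structure(
    list(te_ms = te_ms, etl = as.integer(etl), tr_ms = tr_ms,
         ex_profile = as.numeric(ex_profile),
         ref_profile = as.numeric(ref_profile),
         profile_weights = as.numeric(profile_weights)),
    class = "sequence_config"
  )
}

#' @export
print.sequence_config <- function(x, ...) {
  cat("<sequence_config> MESE: TE", x$te_ms, "ms, ETL", x$etl,
      ", TR", x$tr_ms, "ms,", length(x$ex_profile), "slice-profile bin(s)\n")
  invisible(x)
}

#' Fingerprint of a sequence configuration
#'
#' Used to tag dictionaries and trained regressors so that a model built for
#' one acquisition cannot silently be applied to another.
#' @param seq A [sequence_config()].
#' @return A short character hash.
#' @export
seq_hash <- function(seq) {
  stopifnot(inherits(seq, "sequence_config"))
  rlang::hash(list(seq$te_ms, seq$etl,
                   round(seq$ex_profile, 6), round(seq$ref_profile, 6),
                   round(seq$profile_weights, 9)))
}

#' Voxel tissue model parameters
#'
#' Parameters of the two-component (fat + water) voxel signal model.  The
#' longitudinal relaxation times default to literature values for fat
#' (365 ms) and muscle water (1400 ms) at 3 T; only T2f, T2w, the fat
#' fraction and the B1 efficiency are normally estimated.  The water
#' fraction is always `1 - ff` and is never stored separately.
#'
#' @param t2w_ms,t2f_ms Transverse relaxation times (ms) of the water and
#'   fat components (> 0).
#' @param ff Fat signal fraction in \[0, 1\].
#' @param b1 Pulse efficiency ratio (achieved/nominal flip angle, > 0).
#' @param t1w_ms,t1f_ms Longitudinal relaxation times (ms); fixed defaults.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t2w_ms, t2f_ms, ff, b1,
                          t1w_ms = 1400, t1f_ms = 365) {
  vals <- c(t2w_ms = t2w_ms, t2f_ms = t2f_ms, t1w_ms = t1w_ms, t1f_ms = t1f_ms)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("relaxation times must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(ff) || ff < 0 || ff > 1) stop("ff must lie in [0, 1]", call. = FALSE)
  if (!is.finite(b1) || b1 <= 0) stop("b1 must be > 0", call. = FALSE)
  structure(list(t2w_ms = t2w_ms, t2f_ms = t2f_ms, ff = ff, b1 = b1,
                 t1w_ms = t1w_ms, t1f_ms = t1f_ms),
            class = "tissue_params")
}

# ---- pure-R EPG state operators ---------------------------------------------
# Reference implementation of the elementary EPG operators, used directly in
# unit tests and kept deliberately independent of the compiled fast path.
# Convention: f_plus[k+1] = F(+k), f_minus[k+1] = Conj(F(-k)), z[k+1] = Z(k),
# dephasing orders k = 0..kmax.

#' Initial EPG state
#'
#' Pure equilibrium longitudinal magnetization: Z0 = 1, all other states 0.
#' @param etl Echo-train length; the state is truncated at order `etl + 1`,
#'   which is exact for a train of `etl` refocusing pulses.
#' @return An `epg_state` with complex vectors `f_plus`, `f_minus`, `z`.
#' @export
epg_state_init <- function(etl) {
  kmax <- as.integer(etl) + 1L
  zero <- complex(real = rep(0, kmax + 1L))
  z <- zero; z[1] <- 1 + 0i
  structure(list(f_plus = zero, f_minus = zero, z = z, kmax = kmax),
            class = "epg_state")
}

#' Apply an RF rotation to an EPG state
#'
#' Mixes the F+, F- and Z configuration states with the standard EPG
#' rotation matrix for an instantaneous RF pulse of the given flip angle
#' and phase.  Without relaxation the rotation is unitary, so total signal
#' energy is conserved.
#'
#' @param state An `epg_state`.
#' @param flip_deg Flip angle in degrees (finite).
#' @param phase_deg RF phase in degrees (0 = x axis).
#' @return The rotated `epg_state`.
#' @export
epg_rf_rotation <- function(state, flip_deg, phase_deg = 0) {
  stopifnot(inherits(state, "epg_state"))
  if (!is.finite(flip_deg) || !is.finite(phase_deg)) {
    stop("flip and phase must be finite", call. = FALSE)
  }
  a <- flip_deg * pi / 180
  phi <- phase_deg * pi / 180
  eip <- exp(1i * phi); ei2p <- exp(2i * phi)
  TT <- matrix(c(
    cos(a / 2)^2,              ei2p * sin(a / 2)^2,       -1i * eip * sin(a),
    Conj(ei2p) * sin(a / 2)^2, cos(a / 2)^2,               1i * Conj(eip) * sin(a),
    -0.5i * Conj(eip) * sin(a), 0.5i * eip * sin(a),       cos(a) + 0i
  ), nrow = 3, byrow = TRUE)
  s <- rbind(state$f_plus, state$f_minus, state$z)
  s <- TT %*% s
  state$f_plus <- s[1, ]; state$f_minus <- s[2, ]; state$z <- s[3, ]
  state
}

#' Relaxation and gradient-shift EPG operator
#'
#' Scales transverse states by `exp(-dt/T2)`, relaxes longitudinal states
#' toward equilibrium with `exp(-dt/T1)` (Z0 regrows), then advances the
#' dephasing order of the transverse states by one (Z orders are not
#' shifted).  The highest order is truncated at the state cap.
#'
#' @param state An `epg_state`.
#' @param t1_ms,t2_ms Relaxation times in ms (> 0).
#' @param dt_ms Interval duration in ms (>= 0).
#' @param shift Apply the unit dephasing shift (default TRUE).
#' @return The evolved `epg_state`.
#' @export
epg_relax_shift <- function(state, t1_ms, t2_ms, dt_ms, shift = TRUE) {
  stopifnot(inherits(state, "epg_state"))
  if (!is.finite(dt_ms) || dt_ms < 0) stop("dt_ms must be >= 0", call. = FALSE)
  stopifnot(t1_ms > 0, t2_ms > 0)
  e2 <- exp(-dt_ms / t2_ms); e1 <- exp(-dt_ms / t1_ms)
  state$f_plus <- state$f_plus * e2
  state$f_minus <- state$f_minus * e2
  state$z <- state$z * e1
  state$z[1] <- state$z[1] + (1 - e1)
  if (shift) {
    n <- state$kmax + 1L
    state$f_plus <- c(0i, state$f_plus[-n])
    state$f_minus <- c(state$f_minus[-1], 0i)
    state$f_plus[1] <- Conj(state$f_minus[1])
  }
  state
}

# ---- echo-train simulation --------------------------------------------------

#' Simulate a single-component MESE echo train
#'
#' Runs the EPG recursion at every sub-slice position of the sequence's
#' slice profiles (excitation with the local excitation flip; `etl` CPMG
#' cycles of refocusing at `b1` times the local refocusing flip, with
#' relaxation over each TE/2 and a unit crusher shift), records the F0
#' configuration at each echo, and returns the magnitude of the complex
#' sub-slice sum.  The sum is normalized by the excited transverse
#' magnetization mass (the profile-weighted `sin` of the excitation
#' flips), so amplitudes lie in \[0, 1\] for unit equilibrium
#' magnetization and the overall scale matches an ideal single-bin
#' acquisition; this fixes the meaning of absolute noise variances added
#' to simulated signals.
#'
#' B1 scales the refocusing flip angles only: the excitation is assumed
#' calibrated, matching common stimulated-echo fitting practice; set
#' `scale_excitation = TRUE` to scale both.
#'
#' @param t2_ms Transverse relaxation time (ms).
#' @param b1 Pulse efficiency ratio.
#' @param seq A [sequence_config()].
#' @param t1_ms Longitudinal relaxation time (ms).
#' @param scale_excitation Also multiply the excitation profile by `b1`.
#' @return Numeric vector of `seq$etl` echo amplitudes.
#' @export
mese_single_component <- function(t2_ms, b1, seq, t1_ms = 1400,
                                  scale_excitation = FALSE) {
  stopifnot(inherits(seq, "sequence_config"))
  stopifnot(is.finite(t2_ms), t2_ms > 0, is.finite(t1_ms), t1_ms > 0,
            is.finite(b1), b1 > 0)
  epg_mese_cpp(seq$ex_profile, seq$ref_profile, seq$profile_weights,
               b1, t1_ms, t2_ms, seq$te_ms, seq$etl, scale_excitation)
}

#' Simulate a two-component (fat + water) MESE echo train
#'
#' The voxel signal is the fat-fraction-weighted sum of a fat and a water
#' echo train, each simulated with [mese_single_component()] under the
#' shared B1 efficiency:
#' `S = ff * S(T1f, T2f) + (1 - ff) * S(T1w, T2w)`.
#' The result is exactly linear in `ff`.
#'
#' @param params A [tissue_params()].
#' @param seq A [sequence_config()].
#' @param scale_excitation Passed to [mese_single_component()].
#' @return Numeric vector of `seq$etl` echo amplitudes.
#' @export
mese_two_component <- function(params, seq, scale_excitation = FALSE) {
  stopifnot(inherits(params, "tissue_params"))
  s_fat <- mese_single_component(params$t2f_ms, params$b1, seq,
                                 t1_ms = params$t1f_ms,
                                 scale_excitation = scale_excitation)
  s_wat <- mese_single_component(params$t2w_ms, params$b1, seq,
                                 t1_ms = params$t1w_ms,
                                 scale_excitation = scale_excitation)
  params$ff * s_fat + (1 - params$ff) * s_wat
}

# Batched two-component simulation over a parameter table.  Exploits the
# linearity of the model in ff: unique (t2, b1) single-component trains are
# simulated once and combined, which makes large dictionaries cheap.
#
# `params` is a data frame with columns t2w_ms, t2f_ms, ff, b1 (and
# optionally t1w_ms, t1f_ms).  Returns a matrix n x etl.
#' Simulate many two-component echo trains at once
#'
#' Vectorized version of [mese_two_component()] over the rows of a
#' parameter table; duplicate single-component simulations are shared.
#'
#' @param params Data frame with columns `t2w_ms`, `t2f_ms`, `ff`, `b1`
#'   (optional `t1w_ms`, `t1f_ms` override the defaults).
#' @param seq A [sequence_config()].
#' @param scale_excitation Passed through to the EPG simulation.
#' @return Numeric matrix with `nrow(params)` rows and `seq$etl` columns.
#' @export
mese_simulate_table <- function(params, seq, scale_excitation = FALSE) {
  stopifnot(is.data.frame(params),
            all(c("t2w_ms", "t2f_ms", "ff", "b1") %in% names(params)))
  t1w <- if ("t1w_ms" %in% names(params)) params$t1w_ms else rep(1400, nrow(params))
  t1f <- if ("t1f_ms" %in% names(params)) params$t1f_ms else rep(365, nrow(params))

  sim_unique <- function(t1, t2, b1) {
    key <- paste(signif(t1, 12), signif(t2, 12), signif(b1, 12))
    uk <- !duplicated(key)
    um <- epg_mese_batch_cpp(cbind(t1[uk], t2[uk], b1[uk]),
                             seq$ex_profile, seq$ref_profile,
                             seq$profile_weights,
                             seq$te_ms, seq$etl, scale_excitation)
    um[match(key, key[uk]), , drop = FALSE]
  }
  s_wat <- sim_unique(t1w, params$t2w_ms, params$b1)
  s_fat <- sim_unique(t1f, params$t2f_ms, params$b1)
  params$ff * s_fat + (1 - params$ff) * s_wat
}
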