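# Shared fixtures and the independent Bloch-isochromat oracle.

# Ideal (single-bin 90/180) acquisition matching the Siemens-style timing.
seq_ideal <- sequence_config(te_ms = 7.5, etl = 17, tr_ms = 5633)

# Realistic profile preset (memoized inside the package, cheap to re-request).
seq_preset <- function(n_bins = 64) sequence_preset("siemens", n_bins = n_bins)

# Time-domain isochromat (Bloch) simulation of the same CPMG pulse train:
# for every sub-slice bin, `niso` isochromats with uniformly spaced crusher
# dephasing angles are rotated/relaxed sample by sample.  Completely
# independent of the package's EPG recursion.
iso_mese <- function(ex_profile, ref_profile, weights = NULL, b1 = 1,
                     t1 = 1400, t2 = 50, te = 7.5, etl = 17, niso = 2000) {
  nb <- length(ex_profile)
  if (is.null(weights)) weights <- rep(1, nb)
  phi <- rep(2 * pi * (0:(niso - 1)) / niso + 0.1234, nb)  # dephasing per TE/2
  exf <- rep(ex_profile, each = niso) * pi / 180
  reff <- rep(b1 * ref_profile, each = niso) * pi / 180
  w <- rep(weights, each = niso)
  Mx <- rep(0, nb * niso); My <- Mx; Mz <- rep(1, nb * niso)

  rot_x <- function(a) {
    ny <- cos(a) * My - sin(a) * Mz
    nz <- sin(a) * My + cos(a) * Mz
    My <<- ny; Mz <<- nz
  }
  rot_y <- function(a) {
    nx <- cos(a) * Mx + sin(a) * Mz
    nz <- -sin(a) * Mx + cos(a) * Mz
    Mx <<- nx; Mz <<- nz
  }
  relax <- function(dt) {
    e2 <- exp(-dt / t2); e1 <- exp(-dt / t1)
    Mx <<- Mx * e2; My <<- My * e2; Mz <<- Mz * e1 + (1 - e1)
  }
  dephase <- function() {
    nx <- cos(phi) * Mx - sin(phi) * My
    ny <- sin(phi) * Mx + cos(phi) * My
    Mx <<- nx; My <<- ny
  }

  rot_x(exf)
  echoes <- numeric(etl)
  mass <- sum(w * abs(sin(exf))) / niso
  for (n in seq_len(etl)) {
    relax(te / 2); dephase()
    rot_y(reff)
    relax(te / 2); dephase()
    echoes[n] <- Mod(sum(w * complex(real = Mx, imaginary = My)) / niso) / mass
  }
  echoes
}

# tiny toy dictionary used by several tests
toy_muscle_dict <- function(seq = seq_preset(32), n = 10) {
  grid <- build_grid("muscle", t2f_ms = 150, overrides = list(
    ff = c(0, 0.9, 0.9 / (n - 1)),
    t2w_ms = c(20, 65, 45 / (n - 1)),
    b1 = c(0.5, 1.1, 0.6 / (n - 1))
  ))
  build_dictionary(grid, seq)
}
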