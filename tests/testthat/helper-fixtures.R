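# Shared fixtures: a tiny enumerable imaging problem and the standard
# experimental calibrations.

toy_calib <- function() {
  psf_calibration(s0_x = 0.8, gamma_x = 0, d_x = 0.5, A_x = 0,
                  z_range = c(-0.2, 0.2), modality = "astigmatic",
                  plane_offsets = 0, axial_unit = "um")
}

toy_priors <- function(k_max = 2) {
  prior_set(toy_calib(), roi = 2, intensity_prior(mean = 30, width = 10),
            margin_px = 0, background = c(1, 10), k_max = k_max)
}

toy_jumps <- function() {
  jump_sizes(sigma_x = 0.15, sigma_y = 0.15, sigma_z = 0.05, sigma_I = 4,
             sigma_b = 0.8, split_xy = 0.7, split_z = 0.15)
}

astig_priors <- function(preset = "P0", ...) {
  prior_set(astigmatic_calibration(), roi = 20,
            intensity_prior_preset(preset, ...))
}

# two in-focus emitters m sigma_PSF apart along x, centre of mass mid-ROI
two_emitter_truth <- function(m, calib = astigmatic_calibration(), roi = 20) {
  d_px <- m * calib$s0_x
  c0 <- roi / 2
  frame_params(c0 + c(-1, 1) * d_px / 2, c(c0, c0), c(0, 0),
               c(2000, 2000), 20)
}
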