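# Frozen outputs of calibrate_synthetic_defaults(): the synthetic
# generator's ground-truth radii (the self-consistent fixed point of the
# analysis metric under the generator's forward model) and the fallback
# B-factor slope table (median per-structure slope over the calibration
# sample). See the methods vignette for the calibration conditions.
.synthetic_defaults <- list(
  radii = c(
    C_single = 0.78, C_single_bb = 0.74, C_double = 0.67,
    C_double_bb = 0.69, C_intermediate = 0.73, O_single = 0.80,
    O_double = 0.78, O_double_bb = 0.76, O_intermediate = 0.79,
    N_single = 0.82, N_single_bb = 0.75, N_intermediate = 0.78,
    S_single = 0.83
  ),
  slopes = c(
    C_single = -0.6227, C_single_bb = -0.5531, C_double = -0.4695,
    C_double_bb = -0.4976, C_intermediate = -0.5240, O_single = -0.6388,
    O_double = -0.5715, O_double_bb = -0.5994, O_intermediate = -0.6076,
    N_single = -0.6571, N_single_bb = -0.5759, N_intermediate = -0.6055,
    S_single = -0.6709
  )
)

#' Ground-truth radii of the synthetic generator
#'
#' The radii at which the per-type median corrected chain deviation
#' fractions vanish for entries drawn from [fixture_spec()] defaults; the
#' fixed point of [optimize_radii()] under the generator's forward model,
#' frozen from [calibrate_synthetic_defaults()].
#'
#' @return An `ed_radii` set with provenance `"synthetic"`.
#' @export
synthetic_true_radii <- function() {
  radii_set(.synthetic_defaults$radii, provenance = "synthetic")
}
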