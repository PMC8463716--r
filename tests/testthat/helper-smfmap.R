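# Shared fixtures: noiseless decay curves and small synthetic studies built
# in code at test time.

protocol_heights <- c(15, 20, 25, 30, 55)

noiseless_curve <- function(r_mm, I_mA, T_mm, mu_r = 5000,
                            z = protocol_heights) {
  data.frame(z_mm = z, B_uT = slc_field(z, r_mm, I_mA, T_mm, mu_r))
}

# single-loop ground truth (Model 1 UPPER parameters unless overridden)
single_loop_truth <- function(x_mm = 0, y_mm = 70, r_mm = 8, I_mA = 17.2,
                              geom = phone_geometry(146.9, 70.9, 8.4, "M1")) {
  ground_truth_phone(
    geom,
    data.frame(
      label = "UPPER", x_mm = x_mm, y_mm = y_mm,
      r_mm = r_mm, I_mA = I_mA
    )
  )
}

# process a study to per-height magnitude maps (averaged, background
# subtracted), sorted by z
study_magnitudes <- function(study) {
  bg <- average_replicates(study$background_maps)$mean
  lapply(sort(study$z_list_mm), function(z) {
    reps <- Filter(function(m) isTRUE(all.equal(m$z_nominal_mm, z)), study$maps)
    avg <- average_replicates(reps)
    magnitude(subtract_background(avg$mean, bg), sd = avg$sd)
  })
}
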