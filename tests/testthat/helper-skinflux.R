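# Shared fixtures, all built in code.

# A cumulative_profile lying exactly on Q(t) = slope * (t - lag_h), clamped
# at zero, over the given times. Bypasses the constructor deliberately so
# degenerate shapes (for error paths) can be built too.
linear_profile <- function(times, slope, lag_h = 0, code = "LIN", rep = 1L) {
  structure(list(solvent_code = code, replicate = rep, times = times,
                 Q = pmax(slope * (times - lag_h), 0), flags = character()),
            class = "cumulative_profile")
}

# Reference plate plan at C_D = 1 mg/mL, used widely below.
plate_plan <- function(C_D = 1) pampa_sampling_plan(C_D)

# Synthetic paired table: y = a + b*x plus optional per-point offsets.
collinear_pairs <- function(n = 6, a = 1, b = 2, offsets = 0) {
  x <- seq_len(n)
  y <- a + b * x + rep_len(offsets, n)
  structure(data.frame(code = paste0("S", x), logPm_pampa = x, logKp_skin = y,
                       auc_norm_pampa = x, Qt_skin = y, J_pampa = 10^x,
                       J_skin = 10^x, stringsAsFactors = FALSE),
            class = c("paired_permeability", "data.frame"))
}
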