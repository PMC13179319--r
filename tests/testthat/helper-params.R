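# chart-read parameter sets used throughout: the 5 mg / 5 wt% base
# condition and the 5 mg / 3 wt% condition (s_f on the mL/min scale)
base_case_params <- function(rate_unit = "mL/min") {
  four_params(0.007291, 0.026052, 159.6, 1599.6, rate_unit = rate_unit)
}

sucrose3_params <- function(rate_unit = "mL/min") {
  four_params(0.007545, 0.026433, 140.7833, 1002.617, rate_unit = rate_unit)
}

# one random valid parameter set; caller controls the RNG seed
random_four_params <- function(rate_unit = "mL/min") {
  four_params(
    s_f = runif(1, 0.004, 0.012),
    s_t = runif(1, 0.012, 0.05),
    t_i = runif(1, 80, 300),
    t_e = runif(1, 600, 1800),
    rate_unit = rate_unit
  )
}

param_fields <- function(p) {
  unlist(p[intersect(names(p), c("s_f", "s_t", "t_i", "t_e", "t_s", "t_ds"))])
}

max_rel_err <- function(fitted, truth) {
  max(abs(param_fields(fitted) / param_fields(truth) - 1))
}
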