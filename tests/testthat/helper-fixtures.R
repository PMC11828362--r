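# Shared fixtures, built in code at test time.

# small BRUV-style frame table: two rigs, 1-s aligned time bins
make_frames <- function() {
  data.frame(
    set_id = 1,
    rig_id = c(1, 1, 1, 2, 2),
    time_bin = c(0, 10, 20, 10, 20),
    species = "silky",
    count = c(1, 3, 1, 2, 0))
}

# survey generated from a planted kernel, acceptance-style conditions
make_survey <- function(seed, mult = 20, base = 0.5, R = 5, n = 350,
                        theta = 1.5) {
  gen_radial_survey(
    sim_config(seed = seed, n = n, design = "stations",
               distance_range = c(0, 20), theta = theta),
    enrichment_kernel(base, mult, R), family = "nb")
}

# null survey: flat mean, same noise level
make_null_survey <- function(seed, base = 2, n = 350, theta = 1.5) {
  make_survey(seed, mult = 1, base = base, n = n, theta = theta)
}

# brute-force k-medoids cost oracle: global optimum by full enumeration
brute_pam <- function(x, k = 2) {
  combs <- utils::combn(length(x), k)
  costs <- apply(combs, 2, function(idx)
    sum(apply(abs(outer(x, x[idx], "-")), 1, min)))
  list(cost = min(costs), medoid_idx = combs[, which.min(costs)])
}
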