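# Expensive shared objects (representative solutions, reduction lineages)
# are computed once per test session and reused across files.

.speedred_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .speedred_test_cache, inherits = FALSE)) {
    assign(name, expr, envir = .speedred_test_cache)
  }
  get(name, envir = .speedred_test_cache, inherits = FALSE)
}

sm_continuous_traj <- function() {
  cached("sm_cont_traj",
         integrate_system(build_sm(), protocol = protocol_constant("k24", 1),
                          t_end = 180000, dt = 10))
}

# 6-step continuous-input lineage with the first-order active-IKK policy
continuous_lineage <- function() {
  cached("cont_lineage",
         reduce_iteratively(build_sm(), protocol_constant("k24", 1),
                            n_steps = 6, order_policy = list(w = 1)))
}

# 4-step lineage ranked on the pulse-entrained representative solution
pulsed_lineage <- function() {
  cached("pulsed_lineage",
         reduce_iteratively(build_sm(),
                            protocol_pulsed("k24", width = 300, period = 6000,
                                            t_end = 60000),
                            n_steps = 4, t_end = 60000, transient = 12000))
}
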