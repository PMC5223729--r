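# Shared fixtures, all built in code.

# Registry with every distribution collapsed to a point mass: PSA draws
# from it must reproduce the deterministic analysis exactly.
fixed_registry <- function() {
  reg <- default_registry()
  specs <- lapply(reg, function(s) {
    s$dist <- "fixed"
    s$dist_params <- NULL
    s
  })
  structure(specs, class = "param_registry", path = "fixed-in-test")
}

# Hand-built hazard schedule for engine tests that do not need the full
# schedule builders.
toy_schedule <- function(d, h) {
  structure(list(d = d, h = h, subgroup = "toy", strategy = "toy",
                 scenario = "toy"),
            class = "hazard_schedule")
}

# Costing with explicit numbers and an all-zero add-on stream.
toy_costing <- function(cost_h, cost_nh, horizon, addon = numeric(horizon)) {
  structure(list(cost_h = cost_h, cost_nh = cost_nh, addon = addon,
                 strategy = "toy"),
            class = "strategy_costing")
}

# Cached synthetic life table for the many tests that need one.
default_lt <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- generate_life_table()
    lt
  }
})
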