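# Scenario fixtures shared across test files. Mini scenarios keep unit
# tests fast; the defaults are exercised by the acceptance suite. Expensive
# runs are cached per session so several test blocks can inspect the same
# result.

mini_scenario_config <- function(seed, families = c("Nup98", "Rae1",
                                                    "Sec13", "Tpr"),
                                 egt_families = "Nup98",
                                 length_range = c(150L, 250L), ...) {
  scenario_config(seed, families = families, egt_families = egt_families,
                  length_range = length_range, ...)
}

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# Default-scenario pipeline run, shared by the acceptance blocks.
cached_default_run <- function(seed) {
  cached(paste0("default_run_", seed), {
    bundle <- generate_scenario(scenario_config(seed = seed))
    list(bundle = bundle,
         result = run_all(run_config(seed = seed, bundle = bundle)))
  })
}

# Support of the edge separating `side` from the rest of the tree (NA when
# that bipartition is absent).
bipartition_support <- function(tree, side) {
  idx <- egtscreen:::tree_index(tree)
  sup <- node_supports(tree)
  ntip <- idx$ntip
  found <- NA_integer_
  for (node in (ntip + 1L):(ntip + idx$nnode)) {
    leaves <- sort(tree$tip.label[idx$leafsets[[node]]])
    if (identical(leaves, sort(side)) ||
        identical(leaves, sort(setdiff(tree$tip.label, side)))) {
      if (!is.na(sup[node - ntip])) return(sup[node - ntip])
      found <- sup[node - ntip]
    }
  }
  found
}

cached_mini_bundle <- function() {
  cached("mini_bundle", generate_scenario(mini_scenario_config(3)))
}

cached_mini_profiles <- function() {
  cached("mini_profiles", {
    bundle <- cached_mini_bundle()
    lapply(bundle$alignments, function(a) {
      calibrate(build_profile(a), n_decoys = 200, decoy_length = 200,
                seed = egtscreen:::stage_seed(3, a$family))
    })
  })
}
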