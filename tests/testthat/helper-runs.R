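## Shared, lazily-computed experiment runs for the heavier suites.
## The study conditions are those of the reference experiment: 25 sets
## (600 trials), master seed 1 (the package default), noise sd 0.005.

.run_cache <- new.env(parent = emptyenv())

cached_experiment <- function(key, config) {
  if (!exists(key, .run_cache))
    assign(key, run_experiment(config), .run_cache)
  get(key, .run_cache)
}

optimised_run <- function() {
  cached_experiment("opt", crt_config(n_sets = 25, seed = 1))
}

first_study_run <- function() {
  cached_experiment("fail", crt_config(n_sets = 25, seed = 1,
                                       factors = c(dd = 0.35, Dd = 0.2,
                                                   DD = 0)))
}

## pooled left/right condition means from an experiment
lateral_means <- function(ex) {
  m <- ex$measures
  lr <- m[m$target_position != "middle" & m$success & !is.na(m$il), ]
  list(
    md = sapply(c("dd", "Dd", "DD"), function(dc)
      mean(lr$md[lr$distractor_config == dc])),
    il = lapply(c(small = "small", large = "large"), function(sz)
      sapply(c("dd", "Dd", "DD"), function(dc)
        mean(lr$il[lr$distractor_config == dc & lr$target_size == sz]))),
    cells = aggregate(md ~ target_size + distractor_config, lr, mean),
    mid_md = mean(m$md[m$target_position == "middle" & m$success],
                  na.rm = TRUE),
    lat_md = mean(lr$md)
  )
}
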