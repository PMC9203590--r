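# shared fixtures: all data is generated in code at test time

# a tiny deterministic dataset for contract tests (no simulation noise)
toy_dataset <- function() {
  pb_dataset(P = c(0, 0.2, -0.4), B = seq(-1, 1, length.out = 10))
}

# independent evaluation of a degree-d polynomial link model (used to probe
# profiling results without going through the package's evaluators)
link_transform_probe <- function(link, b0, rest, B) {
  x <- B[, 1]
  g <- b0
  for (p in seq_along(rest)) g <- g + rest[p] * x^p
  switch(link,
         logistic = 1 / (1 + exp(g)),
         exponential = exp(g),
         cloglog = 1 - exp(-exp(g)))
}

# small simulated dataset cached per session to keep the suite fast
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(model_name, n1, n0, seed) {
  key <- paste(model_name, n1, n0, seed, sep = "_")
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_pb(catalog_model(model_name), n1, n0,
                                    seed = seed, model_id = model_name)
  }
  sim_cache[[key]]
}
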