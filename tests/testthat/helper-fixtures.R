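# Shared fixtures for the heavier simulation studies.  Computed once per
# test run and cached, so several test blocks can interrogate the same
# inference without re-running it.

.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE))
    assign(key, force(expr), envir = .fx)
  get(key, envir = .fx, inherits = FALSE)
}

# constant-size truth: theta = 4.8e-4 per site (N = 10,000 diploids at
# mu = 1.2e-8), n = 20 haploids, 10 Mb of sites, exact multinomial generator
fx_constant <- function() fx("constant", {
  set.seed(1)
  truth <- epoch_theta(20, rep(4.8e-4, 19))
  x <- simulate_skyline_sfs(truth, L = 1e7)
  run_full_inference(x, inference_config(B = 50, mu = 1.2e-8, seed = 1),
                     quiet = TRUE)
})

# one zig-zag coalescent simulation analysed both unfolded and folded
fx_zigzag <- function() fx("zigzag", {
  set.seed(1)
  model <- model_presets()$zigzag
  x <- simulate_coalescent_sfs(model, n = 20, L = 1e7, mu = 1.2e-8)
  cfg <- inference_config(B = 50, mu = 1.2e-8, seed = 1)
  list(model = model,
       unfolded = run_full_inference(x, cfg, quiet = TRUE),
       folded = run_full_inference(fold_sfs(x), cfg, quiet = TRUE))
})

# repeated zig-zag simulations for the model-selection comparison
fx_overfit <- function() fx("overfit", {
  model <- model_presets()$zigzag
  G_sel <- G_full <- m_sel <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    x <- fold_sfs(simulate_coalescent_sfs(model, n = 20, L = 1e7,
                                          mu = 1.2e-8))
    ens <- run_ensemble(x, inference_config(B = 10, mu = 1.2e-8, seed = s))
    G_sel[s] <- ens$G[[as.character(ens$chosen_m)]]
    G_full[s] <- ens$G[[length(ens$G)]]
    m_sel[s] <- ens$chosen_m
  }
  list(G_sel = G_sel, G_full = G_full, m_sel = m_sel)
})

# truth curve helper on a summary grid
truth_on_grid <- function(model, times) population_size(model, times)
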