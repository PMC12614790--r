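# parameter sets used throughout the suite (the reference figure constants)
hyp_params <- function() attraction_params(A = 10, a = 0.4, N_c = 10)

fig3a_config <- function()
  model_b_config(b = 1, total_area = 1,
                 params = attraction_params(A_w = 1, A_c = 1,
                                            a_w = 0.4, a_c = 0.4))

fig3b_config <- function()
  model_b_config(b = 1, total_area = 1,
                 params = attraction_params(A_w = 10, A_c = 1,
                                            a_w = 0.4, a_c = 0.4))

# random saturating-family draws for property tests (fixed seed per call site)
draw_hyperbolic <- function(n) {
  data.frame(A = runif(n, 0.1, 20), a = runif(n, 0.05, 5),
             N_c = runif(n, 0, 20), c = runif(n, 0.01, 50))
}
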