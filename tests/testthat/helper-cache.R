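## memoized heavy computations shared across test files

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

cached_switch <- function() {
  memo("switch", find_attractor_switch(eco_params()))
}

cached_pnr <- function() {
  memo("pnr", find_point_of_no_return(eco_params()))
}

## the reference study case: white noise, sigma = 2.2, year-over-year
## deseasonalization, desk profile
cached_white22 <- function() {
  memo("white22", run_case(case_config(noise = "white", sigma = 2.2,
                                       seed = 4242)))
}
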