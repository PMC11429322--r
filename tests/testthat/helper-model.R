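# shared fixtures: the published typical subject and random valid parameter
# draws for property-style checks

typical_params <- function() pk_params(CL = 12.4, V1 = 8.26, Q = 5.22, V2 = 4.06)

# random physiologically plausible parameter sets (log-uniform around typical)
random_params <- function(n, seed = 42) {
  with_seed_local(seed, lapply(seq_len(n), function(i) {
    pk_params(CL = exp(runif(1, log(3), log(30))),
              V1 = exp(runif(1, log(4), log(25))),
              Q = exp(runif(1, log(1), log(15))),
              V2 = exp(runif(1, log(2), log(20))))
  }))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

pop_from_params_list <- function(plist) {
  data.frame(id = seq_along(plist),
             CL = vapply(plist, `[[`, numeric(1), "CL"),
             V1 = vapply(plist, `[[`, numeric(1), "V1"),
             Q = vapply(plist, `[[`, numeric(1), "Q"),
             V2 = vapply(plist, `[[`, numeric(1), "V2"))
}
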