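# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
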