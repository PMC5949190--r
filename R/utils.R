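# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards so seeded package
# functions never perturb the session RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# shared validation helper: ±1 label vector
check_labels <- function(y, require_both = FALSE) {
  if (!all(y %in% c(-1, 1)))
    stop("labels must be -1/+1", call. = FALSE)
  if (require_both && length(unique(y)) < 2L)
    stop("both classes (+1 and -1) must be present", call. = FALSE)
  invisible(y)
}
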