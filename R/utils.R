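# Seed the RNG for the remainder of the calling function, restoring the
# caller's RNG stream on exit so seeded package functions compose with the
# user's own set.seed() (the withr::local_seed idiom, hand-rolled to avoid
# a runtime dependency).
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  restore <- if (had) bquote(assign(".Random.seed", .(old), globalenv()))
  else quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv()))
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}
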