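# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Leveled logger; default threshold INFO. Set options(dama.verbose = FALSE)
# to silence INFO lines.
dama_log <- function(level = c("INFO", "DEBUG", "WARN"), fmt, ...) {
  level <- match.arg(level)
  verbose <- getOption("dama.verbose", TRUE)
  if (level == "DEBUG" && !isTRUE(getOption("dama.debug", FALSE))) return(invisible())
  if (level == "INFO" && !isTRUE(verbose)) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
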