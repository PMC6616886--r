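# Structured error conditions so callers (and the CLI) can map failure
# classes to exit codes without string-matching messages.

hcr_error <- function(message, class, call = sys.call(-1)) {
  structure(
    class = c(class, "hcr_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stop_input <- function(...) stop(hcr_error(paste0(...), "hcr_input_error"))
stop_format <- function(...) stop(hcr_error(paste0(...), "hcr_format_error"))
stop_parse <- function(...) stop(hcr_error(paste0(...), "hcr_parse_error"))
stop_config <- function(...) stop(hcr_error(paste0(...), "hcr_config_error"))
stop_usage <- function(...) stop(hcr_error(paste0(...), "hcr_usage_error"))
stop_env <- function(...) stop(hcr_error(paste0(...), "hcr_environment_error"))
stop_partial <- function(...) stop(hcr_error(paste0(...), "hcr_partial_error"))

# Run an expression with a locally seeded Mersenne-Twister RNG, restoring
# the caller's RNG state afterwards; keeps synthetic generation reproducible
# without clobbering the session seed.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_input("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}
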