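# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_swapalign <- function(..., class) {
  stop(structure(
    class = c(class, "swapalign_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# User-facing input problems (bad file, bad value): distinguished so the CLI
# can map them to exit status 2.
stop_input <- function(...) stop_swapalign(..., class = "swapalign_input_error")

# Contract violations (precondition broken by caller).
stop_contract <- function(...) stop_swapalign(..., class = "swapalign_contract_error")

assert_file <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || is.na(path)) {
    stop_input(what, " path must be a single file path")
  }
  if (!file.exists(path)) stop_input(what, " file not found: ", path)
  invisible(path)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
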