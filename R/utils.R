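# internal helpers shared across modules

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage child seeds so partial reruns reproduce (cli design).
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000000L) * 1000L + offset %% 1000L
}

# Tab/comma auto-detection by header inspection; override with `sep`.
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a
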