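# Shared internal helpers: seeded evaluation, seed fan-out, structured logging.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic stages go through this so a master
# seed reproduces any stage in isolation.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a master seed; stays inside the
# 32-bit signed integer range R requires.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483647)
}

# Structured log line: "stage | key=value ..." to stderr (and an optional file
# connection kept in options for CLI runs).
if_log <- function(stage, ...) {
  kv <- list(...)
  txt <- if (length(kv)) {
    paste(vapply(names(kv), function(k) paste0(k, "=", format(kv[[k]], digits = 6)),
                 character(1)), collapse = " ")
  } else ""
  line <- sprintf("[%s] %s", stage, txt)
  if (isTRUE(getOption("isofusion.verbose", TRUE))) message(line)
  logf <- getOption("isofusion.logfile", NULL)
  if (!is.null(logf)) cat(line, "\n", file = logf, append = TRUE)
  invisible(line)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kaiming-style dense layer initialization (gain for leaky-rectifier hidden
# layers); draws from the current RNG stream.
init_dense <- function(d_in, d_out, scale = sqrt(2 / d_in)) {
  matrix(stats::rnorm(d_in * d_out, 0, scale), d_in, d_out)
}

zeros_bias <- function(d) matrix(0, 1L, d)

# Plain (non-tape) numerics shared across modules.
sigmoid <- function(x) 1 / (1 + exp(-x))
lrelu <- function(x, alpha = 0.01) ifelse(x > 0, x, alpha * x)

# Column-wise max of rows within groups; groups is an integer vector 1..G.
rowgroup_max <- function(x, groups, n_groups = max(groups)) {
  out <- matrix(0, n_groups, ncol(x))
  for (gi in seq_len(n_groups)) {
    rows <- which(groups == gi)
    out[gi, ] <- if (length(rows) == 1L) x[rows, ] else apply(x[rows, , drop = FALSE], 2L, max)
  }
  out
}
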