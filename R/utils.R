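#' @keywords internal
"_PACKAGE"

# Deterministic child seeds: one root seed per run, one independent stream per
# artifact, so regenerating one artifact never perturbs the others.  Kept
# strictly below 2^31 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  streams <- c(
    expression = 11L, probe_map = 13L, ppi = 17L, catalog = 19L,
    qpcr = 23L, fdr = 29L, null = 31L, misc = 37L
  )
  if (is.character(stream)) {
    if (!stream %in% names(streams)) {
      stop("unknown seed stream: ", stream, call. = FALSE)
    }
    stream <- streams[[stream]]
  }
  as.integer((abs(as.numeric(seed)) * 1009 + 7919 * stream) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation failures are user errors (CLI exit code 1), distinct from
# internal errors (exit code 2).
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) {
    stop(errorCondition(paste0(...),
                        class = c("perturbnet_user_error", "error")))
  }
  invisible(TRUE)
}
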