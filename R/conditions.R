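# Classed conditions so callers (and the multi-pose driver) can react to
# specific failure modes instead of matching message strings.

stop_dbfe <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("dbfe_", subclass, "_error"), "dbfe_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

warn_dbfe <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("dbfe_", subclass, "_warning"), "dbfe_warning",
              "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}

# run expr with a temporary, seeded RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds derived from a base seed; kept < 2^31
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + as.double(o) * 2654435761) %% 2147483647
  as.integer(s %% 2147483629 + 1)
}
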