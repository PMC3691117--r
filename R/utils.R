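#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a given RNG seed without disturbing the caller's
# RNG state. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

# Derive a child seed from a base seed and a stream index; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 104729) %% 2147483647
}

# Percent rounded half-up to integer (Table-style reporting).
percent_half_up <- function(ratio) {
  ifelse(is.na(ratio), NA_real_, floor(ratio * 100 + 0.5))
}

check_class_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) {
    stop("class labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  labels
}

# Tiny FNV-1a hash of a character scalar, for manifests.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
}
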