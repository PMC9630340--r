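# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#: candidate regulatory factors, in model order (time last, as the only
#: continuous covariate)
FACTOR_VARS <- c("eomesa", "bcatenin", "smad2", "time")
GENES <- c("ndr1", "ndr2")

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs the
# user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_("seed must be a single non-missing integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Per-repetition seeds derived from a base seed by counter; kept inside the
# 32-bit integer range.
rep_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + as.numeric(counter)) %% 2147483647)
}

# Map model variable names to the embryo-table column that carries them.
# Names not in the map are taken to be literal column names (this is how
# refuters inject auxiliary covariates).
var_column <- function(vars) {
  map <- c(eomesa = "x_eomesa", bcatenin = "x_bcatenin", smad2 = "x_smad2",
           time = "time_hpf", ndr1 = "y_ndr1", ndr2 = "y_ndr2")
  ifelse(vars %in% names(map), unname(map[vars]), vars)
}

require_columns <- function(data, cols, what = "dataset") {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop_("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(TRUE)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
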