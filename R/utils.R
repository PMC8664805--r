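# internal helpers shared across modules

# basal area (m^2) of a stem from its diameter at breast height (cm)
ba_from_dbh <- function(dbh_cm) pi * (dbh_cm / 200)^2

M2_PER_HA <- 1e4

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ef <- function(..., call. = FALSE) stop(..., call. = call.)

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_ef(sprintf("`%s` is missing required columns: %s",
                    name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# deterministic sub-seed for a named substream, kept below 2^31
substream_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + offs * 7919) %% .Machine$integer.max)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
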