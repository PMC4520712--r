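# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed for (base seed, variable name), so the
# integration order of unrelated variables never changes their draws.
# Plain polynomial string hash folded into [0, 2^31 - 2].
var_seed <- function(seed, var) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(var)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Left-pad a geo identifier to the 5-character county FIPS form. When a
# 2-digit state prefix is declared for the file, 1-3 digit ids are read as
# bare county codes within that state; otherwise ids are zero-padded.
pad_fips <- function(x, state_prefix = NULL) {
  x <- trimws(x)
  zero_pad <- function(s, width) paste0(strrep("0", pmax(0L, width - nchar(s))), s)
  short <- !is.na(x) & nchar(x) < 5L & grepl("^[0-9]+$", x)
  if (!is.null(state_prefix) && nzchar(state_prefix)) {
    fixable <- short & nchar(x) <= 3L
    x[fixable] <- paste0(state_prefix, zero_pad(x[fixable], 3L))
    short <- !is.na(x) & nchar(x) < 5L & grepl("^[0-9]+$", x)
  }
  x[short] <- zero_pad(x[short], 5L)
  x
}

state_prefix_of <- function(geo_id) substr(geo_id, 1L, 2L)

round_half_up <- function(x) floor(x + 0.5)

is_number_string <- function(x) {
  !is.na(suppressWarnings(as.numeric(x))) & is.finite(suppressWarnings(as.numeric(x)))
}

# Missing-value tokens recognised in user CSVs.
MISSING_TOKENS <- c("", "na", "n/a", "nan")

is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(x)) %in% MISSING_TOKENS
}
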