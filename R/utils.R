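# Shared helpers: identifier keys, seeded sub-streams, TSV dialect.

# Canonical ";"-joined key for a set of identifiers (sorted, case-sensitive).
set_key <- function(ids) {
  if (length(ids) == 0) return("")
  paste(sort(ids), collapse = ";")
}

key_to_set <- function(key) {
  if (is.na(key) || !nzchar(key)) return(character(0))
  strsplit(key, ";", fixed = TRUE)[[1]]
}

# Canonical unordered-pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Derive an independent sub-seed (< 2^31) from a base seed and a phase label.
# Sub-streams keep, e.g., topology draws unaffected by how many noise values
# an earlier phase consumed.
sub_seed <- function(seed, phase) {
  offsets <- c(
    activities = 11L, weights = 23L, topology = 37L,
    noise = 53L, evidence = 71L, general = 97L
  )
  off <- offsets[[phase]]
  as.integer((as.double(seed) * 48271 + off * 2654435) %% 2147483647)
}

with_sub_seed <- function(seed, phase, code) {
  set.seed(sub_seed(seed, phase))
  force(code)
}

# Fixed tabular dialect: UTF-8, tab separator, "." decimal, "NA" missing.
read_tsv_strict <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, na = "NA",
                  progress = FALSE, show_col_types = FALSE)
}

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
}

# Format numbers for deterministic text output (no scientific notation drift).
num_chr <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "coregulon_config_error")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1]", name),
          class = "coregulon_config_error")
  }
  invisible(as.numeric(x))
}
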