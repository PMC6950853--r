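# package-level caches: parsed structures, fingerprints, SA calibration
.molcycle_cache <- new.env(parent = emptyenv())

.cache_get <- function(key) {
  if (exists(key, envir = .molcycle_cache, inherits = FALSE))
    get(key, envir = .molcycle_cache, inherits = FALSE)
  else NULL
}

.cache_set <- function(key, value) {
  assign(key, value, envir = .molcycle_cache)
  invisible(value)
}
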