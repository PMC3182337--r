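# Provenance headers for written outputs: package version, seed, and a short
# hash of the configuration so identical runs produce identical files.

config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(config, seed = NA) {
  ver <- tryCatch(as.character(utils::packageVersion("fpgcm")),
                  error = function(e) "dev")
  c(sprintf("# fpgcm %s", ver),
    sprintf("# seed: %s", ifelse(is.na(seed), "none", format(seed))),
    sprintf("# config: %s", config_hash(config)))
}
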