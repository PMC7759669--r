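# categorized error conditions so the command-line wrapper can map failures
# to machine-parsable categories (io, config, data, usage)
stsaStop <- function(category, ...) {
  cond <- structure(
    class = c(paste0("stsa_", category, "_error"), "error", "condition"),
    list(message = paste0(...), call = sys.call(-1)))
  stop(cond)
}

errorCategory <- function(e) {
  cls <- class(e)
  hit <- grep("^stsa_(.*)_error$", cls, value = TRUE)
  if (length(hit)) sub("^stsa_(.*)_error$", "\\1", hit[1]) else "internal"
}
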