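# write `content` to a fresh temporary file and return its path
withr_local_tempfile <- function(content) {
  f <- tempfile(fileext = ".yaml")
  writeLines(content, f)
  f
}
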