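# The default synthetic study takes a minute to build (full inference
# ensemble over 20 drug MOA profiles); build it once per test session.
get_default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_default_fixture(seed = 1)
    cache
  }
})
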