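# One synthetic family shared across test files (built once per run).
# Generated at the default study conditions; tests that need other
# conditions build their own.

family_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      anc <- generateAncestor(seed = 101)
      fam <- evolveFamily(anc, seed = 101)
      cache <<- list(anc = anc, fam = fam)
    }
    cache
  }
})
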