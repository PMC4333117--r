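# report every expectation even when many fail (the acceptance checks assert
# reference values that the faithful model does not all reach)
options(testthat.progress.max_fails = 500)
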